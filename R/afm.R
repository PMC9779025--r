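#' AFM topography image
#'
#' Wraps a numeric height matrix (nm) with its physical field size. The
#' standard acquisition geometry is 512 x 512 pixels over a 5 x 5 um field,
#' i.e. a nominal 9.766 nm/px.
#'
#' @param heights Numeric matrix of heights in nm (rows = slow scan axis).
#' @param field_nm Physical edge length of the (square-pixel) field in nm,
#'   measured along the columns.
#' @return An `afm_image` object.
#' @export
afm_image <- function(heights, field_nm = 5000) {
  stopifnot(is.matrix(heights), is.numeric(heights))
  if (any(!is.finite(heights))) stop("heights must be finite", call. = FALSE)
  structure(
    list(heights = heights, pixels_x = ncol(heights),
         pixels_y = nrow(heights), field_nm = field_nm,
         nm_per_px = field_nm / ncol(heights)),
    class = "afm_image"
  )
}

#' @export
print.afm_image <- function(x, ...) {
  cat(sprintf(
    "<afm_image> %d x %d px, %.0f nm field (%.3f nm/px), height range [%.2f, %.2f] nm\n",
    x$pixels_y, x$pixels_x, x$field_nm, x$nm_per_px,
    min(x$heights), max(x$heights)
  ))
  invisible(x)
}

#' Read an AFM height map from a TIFF or PNG file
#'
#' Grayscale image values are interpreted as heights; multi-channel images
#' are averaged. `height_scale` converts stored values to nm (TIFF exports
#' are often normalized to [0, 1]).
#'
#' @param path File path (`.tif`/`.tiff` or `.png`).
#' @param field_nm Physical field edge length in nm.
#' @param height_scale Multiplier from stored values to nm.
#' @return An [afm_image()].
#' @export
read_afm_image <- function(path, field_nm = 5000, height_scale = 1) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format `", ext, "`", call. = FALSE)
  )
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  afm_image(img * height_scale, field_nm = field_nm)
}

#' Write an AFM height map to a TIFF file
#'
#' Heights are scaled into [0, 1] by `height_scale` (pass the same value to
#' [read_afm_image()] to recover nm); negative values are clipped to zero.
#'
#' @param img An [afm_image()].
#' @param path Output path (`.tif`/`.tiff`).
#' @param height_scale nm value mapped to full scale; defaults to the image
#'   maximum.
#' @return `height_scale`, invisibly (needed to re-read the file in nm).
#' @export
write_afm_image <- function(img, path, height_scale = NULL) {
  stopifnot(inherits(img, "afm_image"))
  if (is.null(height_scale)) height_scale <- max(img$heights, 1e-12)
  h <- pmin(pmax(img$heights / height_scale, 0), 1)
  tiff::writeTIFF(h, path, bits.per.sample = 16L)
  invisible(height_scale)
}

#' Segment above-threshold molecules in an AFM image
#'
#' Thresholds the height map and extracts maximal 8-connected components of
#' at least `min_area_px` pixels.
#'
#' @param img An [afm_image()].
#' @param height_threshold Height threshold in nm; must sit above the
#'   background noise floor.
#' @param min_area_px Minimum component area in pixels.
#' @return A tibble with `molecule_id`, `area_px` and a `pixels` list-column
#'   of coordinate matrices. Empty images give zero rows.
#' @export
afm_segment <- function(img, height_threshold, min_area_px = 10L) {
  stopifnot(inherits(img, "afm_image"))
  comps <- label_components(img$heights > height_threshold,
                            min_area_px = min_area_px)
  tibble::tibble(
    molecule_id = seq_along(comps),
    area_px = vapply(comps, nrow, integer(1)),
    pixels = comps
  )
}

#' Freeman chain-code length of an 8-connected pixel path
#'
#' The plain chain-code estimator: orthogonal steps count 1 pixel, diagonal
#' steps sqrt(2). For closed paths the closing step from the last pixel back
#' to the first is included.
#'
#' @param path Integer matrix of ordered pixel coordinates (columns row,
#'   col); consecutive pixels must be 8-neighbours.
#' @param closed Include the closing step.
#' @return Length in pixel units.
#' @examples
#' chain_code_length(cbind(1, 1:11)) # 10
#' @export
chain_code_length <- function(path, closed = FALSE) {
  path <- as.matrix(path)
  n <- nrow(path)
  if (n < 2L) return(0)
  dr <- diff(path[, 1]); dc <- diff(path[, 2])
  if (closed) {
    dr <- c(dr, path[1, 1] - path[n, 1])
    dc <- c(dc, path[1, 2] - path[n, 2])
  }
  adr <- abs(dr); adc <- abs(dc)
  if (any(adr > 1 | adc > 1 | (adr + adc) == 0)) {
    stop("invalid path: consecutive pixels must be distinct 8-neighbours",
         call. = FALSE)
  }
  diag <- adr == 1 & adc == 1
  sum(!diag) + sqrt(2) * sum(diag)
}

# Bilinear interpolation of a height matrix at fractional (row, col).
interp_height <- function(m, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  if (r0 < 1 || c0 < 1 || r0 + 1 > nrow(m) || c0 + 1 > ncol(m)) return(0)
  fr <- r - r0; fc <- c - c0
  m[r0, c0] * (1 - fr) * (1 - fc) + m[r0 + 1, c0] * fr * (1 - fc) +
    m[r0, c0 + 1] * (1 - fr) * fc + m[r0 + 1, c0 + 1] * fr * fc
}

# Sub-pixel extension of an open skeleton end: march along the end tangent
# through the interpolated height field until it drops below the threshold.
# The tangent is the principal axis of the last few path pixels (a chain-code
# step direction can be off by 10-15 degrees on staircase ends), and three
# lateral probes make the march robust to the residual direction error.
# Returns the marched distance in pixels (capped).
end_extension <- function(heights, path, threshold, from_start = TRUE,
                          step = 0.25, max_px = 10, k = 10L) {
  n <- nrow(path)
  if (n < 2L) return(0)
  k <- min(k, n)
  idx <- if (from_start) seq_len(k) else seq(n - k + 1L, n)
  seg <- path[idx, , drop = FALSE]
  p0 <- if (from_start) path[1, ] else path[n, ]
  ctr <- colMeans(seg)
  sv <- svd(sweep(seg, 2, ctr))
  dir <- sv$v[, 1]
  # orient outward (from the segment centroid towards the end pixel)
  if (sum(dir * (p0 - ctr)) < 0) dir <- -dir
  perp <- c(-dir[2], dir[1])
  ext <- 0
  for (t in seq(step, max_px, by = step)) {
    vals <- vapply(c(-0.6, 0, 0.6), function(o) {
      interp_height(heights, p0[1] + t * dir[1] + o * perp[1],
                    p0[2] + t * dir[2] + o * perp[2])
    }, 1)
    if (max(vals) < threshold) break
    ext <- t
  }
  ext
}

# Corner-corrected digital length (Vossepoel-Smeulders): compensates the
# orientation-dependent bias of the plain chain code (up to +8% on straight
# segments). n_c counts chain-code direction changes.
corrected_chain_length <- function(path, closed = FALSE) {
  path <- as.matrix(path)
  n <- nrow(path)
  if (n < 2L) return(0)
  dr <- diff(path[, 1]); dc <- diff(path[, 2])
  if (closed) {
    dr <- c(dr, path[1, 1] - path[n, 1])
    dc <- c(dc, path[1, 2] - path[n, 2])
  }
  diag <- abs(dr) == 1 & abs(dc) == 1
  code <- dr * 3 + dc # unique per direction
  n_corner <- sum(code[-1] != code[-length(code)])
  if (closed && length(code) > 1) {
    n_corner <- n_corner + (code[1] != code[length(code)])
  }
  0.980 * sum(!diag) + 1.406 * sum(diag) - 0.091 * n_corner
}

#' Skeletonize and trace one segmented molecule
#'
#' Thins the component to a one-pixel-wide curve and walks it. Open curves
#' are traced endpoint to endpoint, closed loops all the way around.
#' Skeletons with junction pixels or more than two endpoints are marked
#' branched and carry no usable length (crossing or overlapping molecules
#' are excluded from length statistics rather than cut apart).
#'
#' @param pixels Coordinate matrix of the component (columns row, col).
#' @param dim Dimensions of the source image, `c(nrow, ncol)`.
#' @param spur_px Spur-pruning length passed to [prune_spurs()] (0 disables).
#' @return A list: `pixel_path` (ordered coordinates), `length_px` (plain
#'   chain-code length), `closed`, `branched`, `area_px`.
#' @export
skeleton_trace <- function(pixels, dim, spur_px = 6L) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0L) stop("empty component", call. = FALSE)
  # work in a padded local window
  r0 <- min(pixels[, 1]) - 2L; c0 <- min(pixels[, 2]) - 2L
  nr <- max(pixels[, 1]) - r0 + 2L; nc <- max(pixels[, 2]) - c0 + 2L
  m <- matrix(FALSE, nr, nc)
  m[cbind(pixels[, 1] - r0, pixels[, 2] - c0)] <- TRUE
  sk <- thin_mask(m)
  sk <- minimal_skeleton(sk)
  if (spur_px > 0L) sk <- prune_spurs(sk, spur_px = spur_px)
  sk <- minimal_skeleton(sk)
  pts <- which(sk, arr.ind = TRUE)
  np <- nrow(pts)
  out <- function(path, closed, branched) {
    if (!is.null(path)) {
      path <- cbind(row = path[, 1] + r0, col = path[, 2] + c0)
    }
    list(pixel_path = path,
         length_px = if (branched) NA_real_ else
           chain_code_length(path, closed = closed),
         closed = closed, branched = branched, area_px = nrow(pixels))
  }
  if (np == 1L) return(out(pts, closed = FALSE, branched = FALSE))
  # neighbour counts on the skeleton
  key <- (pts[, 2] - 1L) * nr + pts[, 1]
  on <- logical(nr * nc); on[key] <- TRUE
  offs <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  nb_count <- integer(np)
  for (o in offs) nb_count <- nb_count + on[pmax(pmin(key + o, nr * nc), 1L)]
  ends <- which(nb_count == 1L)
  if (any(nb_count > 2L) || length(ends) > 2L) {
    return(out(NULL, closed = FALSE, branched = TRUE))
  }
  closed <- length(ends) == 0L
  start <- if (closed) 1L else ends[1]
  # walk the curve
  lookup <- integer(nr * nc); lookup[key] <- seq_len(np)
  visited <- logical(np)
  path_idx <- integer(np)
  cur <- start
  for (i in seq_len(np)) {
    path_idx[i] <- cur
    visited[cur] <- TRUE
    if (i == np) break
    nxt <- 0L
    for (o in offs) {
      cand <- key[cur] + o
      if (cand >= 1L && cand <= nr * nc && on[cand]) {
        j <- lookup[cand]
        if (!visited[j]) { nxt <- j; break }
      }
    }
    if (nxt == 0L) {
      # disconnected remainder: should not happen on a clean skeleton
      return(out(NULL, closed = FALSE, branched = TRUE))
    }
    cur <- nxt
  }
  out(pts[path_idx, , drop = FALSE], closed = closed, branched = FALSE)
}

#' Pixel-to-nm calibration from full-length ruler molecules
#'
#' Spread-out full-length circular molecules of known contour serve as
#' internal rulers: the scale is the known contour divided by the median
#' measured pixel length (median for robustness against partially compacted
#' rulers).
#'
#' @param ruler_lengths_px Measured pixel lengths of the ruler molecules.
#' @param spec A [plasmid_spec()] giving the true contour.
#' @return nm per pixel.
#' @examples
#' afm_calibrate(150, pbr322()) # 1482.74 / 150
#' @export
afm_calibrate <- function(ruler_lengths_px, spec = pbr322()) {
  ruler_lengths_px <- ruler_lengths_px[is.finite(ruler_lengths_px)]
  if (length(ruler_lengths_px) == 0L) {
    stop("no ruler molecules supplied", call. = FALSE)
  }
  spec$contour_nm / stats::median(ruler_lengths_px)
}

#' Measure apparent molecule lengths in an AFM image
#'
#' The full measurement pipeline: segmentation, skeletonization, curve
#' tracing and length estimation. Lengths default to the corner-corrected
#' digital estimator (`estimator = "corrected"`), which removes the
#' orientation bias of the plain Freeman chain code; `"freeman"` gives the
#' uncorrected value. For open curves an end correction of half the stroke
#' width per endpoint (width estimated as area / length) compensates the
#' skeleton's end erosion.
#'
#' @param img An [afm_image()].
#' @param height_threshold Segmentation threshold in nm.
#' @param min_area_px Minimum component area.
#' @param nm_per_px Scale; defaults to the image's nominal geometry. Pass a
#'   value from [afm_calibrate()] to use internal rulers.
#' @param estimator `"corrected"` or `"freeman"`.
#' @param end_correction Apply the open-curve end correction: each skeleton
#'   end is extended along its tangent through the interpolated height field
#'   up to the threshold contour (sub-pixel), and the constant point-spread
#'   overshoot beyond the true molecule end is subtracted.
#' @param end_overshoot_px Expected overshoot of the threshold contour
#'   beyond the molecule end, per end (pixels); depends on tip point-spread
#'   and threshold, calibrated on rendered ground truth for the default
#'   imaging model.
#' @param smooth_sigma_px Gaussian pre-smoothing of the height map before
#'   thresholding (pixels; 0 disables). Useful for noisier images; off by
#'   default.
#' @param spur_px Spur-pruning length passed to [skeleton_trace()].
#' @return A tibble with one row per molecule: `molecule_id`, `area_px`,
#'   `length_px`, `length_nm`, `closed`, `branched`. Branched molecules have
#'   `NA` lengths.
#' @export
afm_measure <- function(img, height_threshold, min_area_px = 10L,
                        nm_per_px = NULL, estimator = c("corrected", "freeman"),
                        end_correction = TRUE, end_overshoot_px = 0.6,
                        smooth_sigma_px = 0, spur_px = 6L) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(img, "afm_image"))
  if (is.null(nm_per_px)) nm_per_px <- img$nm_per_px
  if (smooth_sigma_px > 0) {
    img <- afm_image(gaussian_blur(img$heights, smooth_sigma_px),
                     field_nm = img$field_nm)
  }
  seg <- afm_segment(img, height_threshold, min_area_px = min_area_px)
  dims <- c(img$pixels_y, img$pixels_x)
  traces <- purrr::map(seg$pixels, skeleton_trace, dim = dims,
                       spur_px = spur_px)
  len_px <- purrr::map2_dbl(traces, seg$area_px, function(tr, area) {
    if (tr$branched) return(NA_real_)
    len <- if (estimator == "corrected") {
      corrected_chain_length(tr$pixel_path, closed = tr$closed)
    } else {
      chain_code_length(tr$pixel_path, closed = tr$closed)
    }
    if (end_correction && !tr$closed && len > 0) {
      # march each end through the height field to the threshold contour,
      # then remove the constant point-spread overshoot beyond the true end
      ext <- end_extension(img$heights, tr$pixel_path, height_threshold,
                           from_start = TRUE) +
        end_extension(img$heights, tr$pixel_path, height_threshold,
                      from_start = FALSE)
      len <- len + ext - 2 * end_overshoot_px
    }
    len
  })
  tibble::tibble(
    molecule_id = seg$molecule_id,
    area_px = seg$area_px,
    length_px = len_px,
    length_nm = len_px * nm_per_px,
    closed = purrr::map_lgl(traces, "closed"),
    branched = purrr::map_lgl(traces, "branched")
  )
}

#' Relative-frequency length distribution in 50-nm bins
#'
#' Histograms apparent molecule lengths into half-open 50-nm bins over
#' 0-1550 nm (31 bins). Relative frequencies are computed over the in-range
#' molecules and sum to one; lengths at or beyond the upper edge are counted
#' in a separate overflow tally.
#'
#' @param lengths_nm Apparent lengths in nm (non-negative; `NA` dropped).
#' @param bin_nm Bin width in nm.
#' @param range_nm Upper edge of the binned range in nm.
#' @return A `length_distribution`: tibble with `bin_lo_nm`, `bin_hi_nm`,
#'   `count`, `rel_freq`, and attributes `n_molecules` (in-range) and
#'   `n_overflow`.
#' @export
length_distribution <- function(lengths_nm, bin_nm = 50, range_nm = 1550) {
  lengths_nm <- lengths_nm[!is.na(lengths_nm)]
  if (any(lengths_nm < 0)) stop("lengths must be >= 0", call. = FALSE)
  edges <- seq(0, range_nm, by = bin_nm)
  nbin <- length(edges) - 1L
  in_range <- lengths_nm < range_nm
  n_in <- sum(in_range)
  counts <- if (n_in > 0) {
    tabulate(findInterval(lengths_nm[in_range], edges), nbins = nbin)
  } else integer(nbin)
  out <- tibble::tibble(
    bin_lo_nm = edges[-length(edges)],
    bin_hi_nm = edges[-1],
    count = counts,
    rel_freq = if (n_in > 0) counts / n_in else rep(0, nbin)
  )
  structure(out, class = c("length_distribution", class(out)),
            n_molecules = n_in, n_overflow = sum(!in_range))
}

#' Mean of the binned length distribution
#'
#' Bin-midpoint weighted mean, the summary used to compare distributions
#' across doses.
#'
#' @param dist A [length_distribution()].
#' @return Mean apparent length in nm (`NA` for empty distributions).
#' @export
mean_binned_length <- function(dist) {
  stopifnot(inherits(dist, "length_distribution"))
  if (attr(dist, "n_molecules") == 0L) return(NA_real_)
  mid <- (dist$bin_lo_nm + dist$bin_hi_nm) / 2
  sum(mid * dist$rel_freq)
}

#' Plot a length distribution
#'
#' @param object A [length_distribution()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.length_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_lo_nm + diff(c(
    object$bin_lo_nm[1], object$bin_hi_nm[1]
  )) / 2, y = .data$rel_freq)) +
    ggplot2::geom_col(width = object$bin_hi_nm[1] - object$bin_lo_nm[1],
                      fill = "steelblue", colour = "grey30", linewidth = 0.2) +
    ggplot2::labs(x = "apparent length (nm)", y = "relative frequency") +
    ggplot2::theme_minimal()
}
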