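# Synthetic AFM image rendering: fragments drawn as discrete worm-like
# chains adsorbed on a flat substrate, rasterized with a Gaussian tip
# point-spread and additive background noise. Ground truth is returned for
# every placed molecule so the measurement pipeline can be validated.

# Discrete 2-D worm-like chain: unit steps of `step_nm` with Gaussian
# angular increments of variance step/persistence (the 2-D WLC tangent
# decorrelation). persistence = Inf gives a straight rod.
wlc_path <- function(length_nm, persistence_nm, step_nm = 5) {
  n_steps <- max(1L, round(length_nm / step_nm))
  sd_theta <- if (is.finite(persistence_nm)) sqrt(step_nm / persistence_nm) else 0
  theta <- cumsum(c(stats::runif(1, 0, 2 * pi),
                    stats::rnorm(n_steps - 1, 0, sd_theta)))
  step_len <- length_nm / n_steps
  x <- cumsum(c(0, step_len * cos(theta)))
  y <- cumsum(c(0, step_len * sin(theta)))
  cbind(x = x, y = y)
}

# Closed ring of the given circumference with a mild low-order radial
# wobble, for calibration-ruler rendering.
ring_path <- function(circumference_nm, wobble = 0.03, n_pts = 256L) {
  r0 <- circumference_nm / (2 * pi)
  phase <- stats::runif(2, 0, 2 * pi)
  t <- seq(0, 2 * pi, length.out = n_pts + 1L)[-(n_pts + 1L)]
  r <- r0 * (1 + wobble * sin(2 * t + phase[1]) + wobble * sin(3 * t + phase[2]))
  # rescale to the requested circumference
  xy <- cbind(r * cos(t), r * sin(t))
  seglen <- sqrt(rowSums((xy - xy[c(2:n_pts, 1), ])^2))
  xy <- xy * circumference_nm / sum(seglen)
  colnames(xy) <- c("x", "y")
  xy
}

# Resample a polyline (or polygon) at ~1-px spacing for rasterization.
densify <- function(xy, spacing, closed = FALSE) {
  if (closed) xy <- rbind(xy, xy[1, , drop = FALSE])
  d <- sqrt(rowSums(diff(xy)^2))
  keep <- d > 0
  if (!any(keep)) return(xy[1, , drop = FALSE])
  cum <- c(0, cumsum(d))
  s <- seq(0, cum[length(cum)], by = spacing)
  x <- stats::approx(cum, xy[, 1], xout = s)$y
  y <- stats::approx(cum, xy[, 2], xout = s)$y
  cbind(x = x, y = y)
}

# Separable Gaussian blur with edge renormalization-free zero padding.
gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-half, half), sd = sigma_px)
  k <- k / sum(k)
  conv1 <- function(mat) {
    out <- matrix(0, nrow(mat), ncol(mat))
    for (i in seq_along(k)) {
      off <- i - half - 1L
      out <- out + k[i] * shift_num(mat, off)
    }
    out
  }
  t(conv1(t(conv1(m))))
}

shift_num <- function(m, dr) {
  nr <- nrow(m)
  out <- matrix(0, nr, ncol(m))
  if (dr == 0) return(m)
  if (dr > 0) out[(1 + dr):nr, ] <- m[1:(nr - dr), ]
  else out[1:(nr + dr), ] <- m[(1 - dr):nr, ]
  out
}

#' Render fragments into a synthetic AFM topography image
#'
#' Each fragment is laid down as a discrete worm-like chain (default 5-nm
#' steps, 50-nm persistence length — the canonical dsDNA value), closed
#' molecules as gently wobbling rings. Molecules are placed uniformly at
#' random with rejection sampling so that no two molecules' footprints
#' overlap; the chain is stamped onto the height grid at `height_nm` and
#' blurred with a Gaussian point-spread emulating finite tip radius, then
#' Gaussian background noise is added. The exact placement list is returned
#' as ground truth.
#'
#' @param lengths_nm Contour lengths to render, in nm.
#' @param closed Logical vector (recycled): render as closed ring instead of
#'   an open chain.
#' @param field_nm Field edge length in nm.
#' @param px Image size in pixels (square).
#' @param persistence_nm Worm-like-chain persistence length in nm.
#' @param step_nm Chain discretization step in nm.
#' @param height_nm Stamped molecule height in nm (~0.5 for dsDNA on mica).
#' @param psf_sigma_nm Gaussian point-spread sigma in nm.
#' @param noise_nm Background noise standard deviation in nm.
#' @param margin_nm Keep molecules this far from the field edge.
#' @param clearance_nm Minimum separation between molecule footprints.
#' @param max_attempts Rejection-sampling attempts per molecule before
#'   giving up.
#' @param seed Optional RNG seed.
#' @return A list: `image` (an [afm_image()]) and `truth` (tibble with
#'   `molecule`, `length_nm`, `closed`, `x_nm`, `y_nm`).
#' @export
render_afm <- function(lengths_nm, closed = FALSE, field_nm = 5000, px = 512L,
                       persistence_nm = 50, step_nm = 5, height_nm = 0.5,
                       psf_sigma_nm = 10, noise_nm = 0.03,
                       margin_nm = 100, clearance_nm = 80,
                       max_attempts = 200L, seed = NULL) {
  run <- function() {
    nm_px <- field_nm / px
    canvas <- matrix(0, px, px)
    occupied <- matrix(FALSE, px, px)
    clear_px <- max(1L, ceiling(clearance_nm / nm_px))
    closed <- rep_len(closed, length(lengths_nm))
    truth <- vector("list", length(lengths_nm))
    for (i in seq_along(lengths_nm)) {
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        base <- if (closed[i]) {
          ring_path(lengths_nm[i])
        } else {
          wlc_path(lengths_nm[i], persistence_nm, step_nm)
        }
        base <- sweep(base, 2, colMeans(base))
        ext <- max(abs(base)) + margin_nm
        if (2 * ext > field_nm) next
        ctr <- stats::runif(2, ext, field_nm - ext)
        pts <- sweep(base, 2, ctr, `+`)
        dense <- densify(pts, spacing = nm_px / 2, closed = closed[i])
        rr <- pmin(pmax(round(dense[, 2] / nm_px) + 1L, 1L), px)
        cc <- pmin(pmax(round(dense[, 1] / nm_px) + 1L, 1L), px)
        foot <- unique(cbind(rr, cc))
        # footprint incl. clearance halo
        halo <- expand.grid(dr = -clear_px:clear_px, dc = -clear_px:clear_px)
        halo_r <- pmin(pmax(rep(foot[, 1], each = nrow(halo)) + halo$dr, 1L), px)
        halo_c <- pmin(pmax(rep(foot[, 2], each = nrow(halo)) + halo$dc, 1L), px)
        if (any(occupied[cbind(halo_r, halo_c)] &
                rep(TRUE, length(halo_r)))) next
        occupied[cbind(halo_r, halo_c)] <- TRUE
        canvas[foot] <- height_nm
        truth[[i]] <- tibble::tibble(
          molecule = i, length_nm = lengths_nm[i], closed = closed[i],
          x_nm = ctr[1], y_nm = ctr[2]
        )
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place molecule ", i, " after ", max_attempts,
             " attempts: reduce the number or size of molecules",
             call. = FALSE)
      }
    }
    img <- gaussian_blur(canvas, psf_sigma_nm / nm_px)
    # renormalize peak height towards the stamped height
    if (max(img) > 0) img <- img * (height_nm / max(img))
    if (noise_nm > 0) img <- img + matrix(stats::rnorm(px * px, 0, noise_nm), px, px)
    list(
      image = afm_image(img, field_nm = field_nm),
      truth = dplyr::bind_rows(truth)
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
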