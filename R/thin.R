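# Binary-image primitives for the AFM pipeline: 8-connected component
# labeling and Zhang-Suen morphological thinning. Written here because the
# installed image stacks only provide 4-connected labeling and no thinning.

# Shift a matrix by (dr, dc) with zero fill.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# 8-neighbour offsets in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW),
# rows increasing downward.
zs_offsets <- list(
  c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
  c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L)
)

#' Morphological thinning of a binary image (Zhang-Suen)
#'
#' Iteratively peels boundary pixels while preserving 8-connectivity until a
#' one-pixel-wide skeleton remains.
#'
#' @param mask A logical or 0/1 matrix.
#' @param max_iter Safety cap on thinning iterations.
#' @return A logical matrix of the same dimensions.
#' @export
thin_mask <- function(mask, max_iter = 1000L) {
  m <- matrix(as.integer(as.logical(mask)), nrow(mask), ncol(mask))
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (pass in 1:2) {
      p <- lapply(zs_offsets, function(o) shift_mat(m, -o[1], -o[2]))
      # p[[k]] holds the value of neighbour P(k+1) at each pixel
      b <- Reduce(`+`, p)
      ring <- c(p, p[1])
      a <- Reduce(`+`, lapply(1:8, function(k) {
        (ring[[k]] == 0L) & (ring[[k + 1]] == 1L)
      }))
      if (pass == 1) {
        c1 <- p[[1]] * p[[3]] * p[[5]] == 0L # P2*P4*P6
        c2 <- p[[3]] * p[[5]] * p[[7]] == 0L # P4*P6*P8
      } else {
        c1 <- p[[1]] * p[[3]] * p[[7]] == 0L # P2*P4*P8
        c2 <- p[[1]] * p[[5]] * p[[7]] == 0L # P2*P6*P8
      }
      del <- (m == 1L) & (b >= 2L) & (b <= 6L) & (a == 1L) & c1 & c2
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

#' Reduce a skeleton to a minimal 8-connected curve
#'
#' Thinning can leave staircase corners and locally thick spots where pixels
#' have more than two neighbours without being genuine junctions. A pixel is
#' redundant when its ON neighbours remain mutually 8-connected without it
#' (and it is not an endpoint); redundant pixels are removed sequentially
#' until the curve is minimal, turning E+N staircase corners into single
#' diagonal steps.
#'
#' @param sk Logical skeleton matrix.
#' @return A logical matrix.
#' @export
minimal_skeleton <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  offs_rc <- cbind(
    dr = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
    dc = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  )
  offs <- offs_rc[, "dc"] * nr + offs_rc[, "dr"]
  # neighbour-to-neighbour adjacency within the 3x3 ring (center excluded)
  adj <- outer(seq_len(8), seq_len(8), Vectorize(function(i, j) {
    i != j && max(abs(offs_rc[i, ] - offs_rc[j, ])) <= 1L
  }))
  repeat {
    changed <- FALSE
    for (k in which(sk)) {
      r <- (k - 1L) %% nr + 1L
      if (r == 1L || r == nr) next
      cand <- k + offs
      ok <- cand >= 1L & cand <= nr * nc
      nb_on <- ok & sk[pmax(pmin(cand, nr * nc), 1L)]
      dg <- sum(nb_on)
      if (dg < 2L) next
      idx <- which(nb_on)
      # connected components of ON neighbours without the center pixel
      seen <- logical(length(idx))
      seen[1] <- TRUE
      frontier <- idx[1]
      while (length(frontier)) {
        nxt <- integer(0)
        for (i in seq_along(idx)) {
          if (!seen[i] && any(adj[idx[i], frontier])) {
            seen[i] <- TRUE
            nxt <- c(nxt, idx[i])
          }
        }
        frontier <- nxt
      }
      if (all(seen)) {
        sk[k] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sk
}

#' Prune short spurs from a skeleton
#'
#' Rasterization bumps and background noise leave short side branches on a
#' thinned curve, which would otherwise be classified as genuine junctions.
#' Branches running from an endpoint into a junction in at most `spur_px`
#' pixels are deleted iteratively; a curve without junctions is never
#' touched.
#'
#' @param sk Logical skeleton matrix (output of [thin_mask()]).
#' @param spur_px Maximum branch length (pixels) to remove.
#' @return A logical matrix.
#' @export
prune_spurs <- function(sk, spur_px = 6L) {
  nr <- nrow(sk); nc <- ncol(sk)
  offs <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  repeat {
    key <- which(sk)
    if (length(key) < 3L) break
    on <- logical(nr * nc); on[key] <- TRUE
    deg <- integer(nr * nc)
    for (o in offs) {
      cand <- key + o
      ok <- cand >= 1L & cand <= nr * nc
      deg[key[ok]] <- deg[key[ok]] + on[cand[ok]]
    }
    junctions <- key[deg[key] >= 3L]
    if (!length(junctions)) break
    endpoints <- key[deg[key] == 1L]
    # walk each endpoint branch up to its junction
    branches <- list()
    for (e in endpoints) {
      path <- integer(0)
      cur <- e
      junction <- 0L
      for (step in seq_len(spur_px)) {
        path <- c(path, cur)
        cand <- cur + offs
        cand <- cand[cand >= 1L & cand <= nr * nc]
        cand <- cand[on[cand] & !(cand %in% path)]
        jn <- cand[deg[cand] >= 3L]
        if (length(jn)) { junction <- jn[1L]; break }
        if (length(cand) == 0L) break
        cur <- cand[1L]
      }
      if (junction != 0L) {
        branches[[length(branches) + 1L]] <- list(path = path,
                                                  junction = junction)
      }
    }
    if (!length(branches)) break
    # a junction whose long continuations carry the curve sheds all its
    # short branches; if only one long continuation remains, the longest
    # short branch is the genuine curve end and is kept
    jn_of <- vapply(branches, function(b) b$junction, 0L)
    len_of <- lengths(lapply(branches, function(b) b$path))
    removed <- FALSE
    for (j in unique(jn_of)) {
      idx <- which(jn_of == j)
      long_continuations <- deg[j] - length(idx)
      if (long_continuations < 2L && length(idx) > 1L) {
        idx <- idx[-which.max(len_of[idx])]
      } else if (long_continuations < 2L) {
        idx <- integer(0)
      }
      for (b in idx) {
        sk[branches[[b]]$path] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
    sk <- minimal_skeleton(thin_mask(sk))
  }
  sk
}

#' 8-connected components of a binary image
#'
#' @param mask A logical or 0/1 matrix.
#' @param min_area_px Drop components smaller than this many pixels.
#' @return A list of integer matrices, one per component, each with columns
#'   `row` and `col` (1-based pixel coordinates).
#' @export
label_components <- function(mask, min_area_px = 1L) {
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(list())
  labels <- integer(nr * nc)
  offs <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  comp <- list()
  lab <- 0L
  for (start in idx) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    members <- integer(0)
    while (length(queue)) {
      cur <- queue
      members <- c(members, cur)
      queue <- integer(0)
      for (o in offs) {
        nb <- cur + o
        # guard against wrapping across matrix columns
        ok <- nb >= 1L & nb <= nr * nc
        nb <- nb[ok]; src <- cur[ok]
        r_src <- (src - 1L) %% nr
        r_nb <- (nb - 1L) %% nr
        ok2 <- abs(r_nb - r_src) <= 1L
        nb <- nb[ok2]
        nb <- nb[mask[nb] & labels[nb] == 0L]
        if (length(nb)) {
          nb <- unique(nb)
          labels[nb] <- lab
          queue <- c(queue, nb)
        }
      }
      queue <- unique(queue)
    }
    comp[[lab]] <- members
  }
  comp <- comp[lengths(comp) >= min_area_px]
  lapply(comp, function(v) {
    cbind(row = (v - 1L) %% nr + 1L, col = (v - 1L) %/% nr + 1L)
  })
}
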