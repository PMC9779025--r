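# Shared helpers: hand-built populations and an independent brute-force
# oracle for opposed-pair conversion.

make_population <- function(lesions, n = max(lesions$molecule),
                            window = 10L) {
  if (!"new" %in% names(lesions)) lesions$new <- FALSE
  counts <- function(kind, cls = NULL) {
    sel <- lesions$kind == kind
    if (!is.null(cls)) sel <- sel & !is.na(lesions$base_class) &
        lesions$base_class == cls
    tabulate(lesions$molecule[sel], nbins = n)
  }
  structure(
    list(
      molecules = tibble::tibble(
        molecule = seq_len(n),
        n_ssb = counts("ssb"),
        n_dsb = counts("dsb"),
        n_base_purine = counts("base", "purine"),
        n_base_pyrimidine = counts("base", "pyrimidine")
      ),
      lesions = tibble::as_tibble(lesions),
      spec = pbr322(), cluster_window_bp = as.integer(window),
      dose_gy = 1, enzyme = "none", n = n
    ),
    class = "plasmid_population"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent greedy opposed-pair count: all pairs enumerated, converted
# shortest-circular-distance first; pairs must lie on opposite strands
# within `window`, and (if require_new) involve at least one new break.
brute_opposed_pairs <- function(pos, strand, new, L, window,
                                require_new = TRUE) {
  alive <- rep(TRUE, length(pos))
  made <- 0L
  repeat {
    idx <- which(alive)
    if (length(idx) < 2L) break
    best <- NULL; best_d <- Inf; best_p <- Inf
    for (a in seq_along(idx)) {
      for (b in seq_len(a - 1L)) {
        i <- idx[a]; j <- idx[b]
        if (strand[i] == strand[j]) next
        if (require_new && !(new[i] || new[j])) next
        d <- min(abs(pos[i] - pos[j]), L - abs(pos[i] - pos[j]))
        if (d > window) next
        p <- min(pos[i], pos[j])
        if (d < best_d || (d == best_d && p < best_p)) {
          best <- c(i, j); best_d <- d; best_p <- p
        }
      }
    }
    if (is.null(best)) break
    alive[best] <- FALSE
    made <- made + 1L
  }
  made
}

# Draw a filled disc / annulus mask for skeleton tests.
disc_mask <- function(n, cx, cy, r_outer, r_inner = -1) {
  d <- sqrt(outer(seq_len(n), rep(1, n))^2 * 0 +
            outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, `+`))
  d <- sqrt(outer((seq_len(n) - cy)^2, rep(1, n)) +
            outer(rep(1, n), (seq_len(n) - cx)^2))
  d <= r_outer & d > r_inner
}
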