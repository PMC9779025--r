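#' Hydroxyl-radical scavenging capacity
#'
#' The scavenging capacity of a solution is the pseudo-first-order rate at
#' which a scavenger removes hydroxyl radicals: the product `k * S` of the
#' scavenger's OH rate constant and its molar concentration, in 1/s.
#'
#' @param k Rate constant in 1/(M s) (> 0).
#' @param concentration Scavenger concentration in M (>= 0).
#' @return Capacity in 1/s.
#' @examples
#' scavenging_capacity(1.5e9, 6.6667e-2) # Tris at ~1e8 1/s
#' @export
scavenging_capacity <- function(k, concentration) {
  if (any(k <= 0)) stop("`k` must be positive", call. = FALSE)
  if (any(concentration < 0)) {
    stop("`concentration` must be non-negative", call. = FALSE)
  }
  k * concentration
}

#' Concentration needed for a target scavenging capacity
#'
#' Exact inverse of [scavenging_capacity()]: `target / k`.
#'
#' @param k Rate constant in 1/(M s) (> 0).
#' @param target Target capacity in 1/s (>= 0).
#' @return Concentration in M.
#' @examples
#' concentration_for_capacity(1.5e9, 1e6) # ~6.67e-4 M Tris
#' @export
concentration_for_capacity <- function(k, target) {
  if (any(k <= 0)) stop("`k` must be positive", call. = FALSE)
  if (any(target < 0)) stop("`target` must be non-negative", call. = FALSE)
  target / k
}

#' OH rate constants of the standard scavengers
#'
#' Tris buffer (2-amino-2-(hydroxymethyl)propane-1,3-diol) and the coumarin
#' derivative C3CA (coumarin-3-carboxylic acid).
#'
#' @return Named numeric vector in 1/(M s): `tris` = 1.5e9, `c3ca` = 6.8e9.
#' @export
scavenger_rate_constants <- function() {
  c(tris = 1.5e9, c3ca = 6.8e9)
}

#' Define a scavenging condition
#'
#' Provide either `concentration` or a target `capacity` (exactly one); the
#' other is derived from the rate constant. `name = "none"` represents the
#' no-added-scavenger condition, carried by residual buffer at a capacity of
#' 1e5 1/s rather than zero, so that log-capacity plots and reductions stay
#' well-defined.
#'
#' @param name `"none"`, `"tris"` or `"c3ca"`, or any name if `k` is given.
#' @param k Rate constant in 1/(M s); defaults from
#'   [scavenger_rate_constants()] for the named scavengers.
#' @param concentration Molar concentration.
#' @param capacity Target capacity in 1/s.
#' @param residual_capacity Capacity assigned to `"none"` (default 1e5 1/s).
#' @return A `scavenger_condition` object (list with `name`, `k`,
#'   `concentration`, `capacity`).
#' @examples
#' scavenger_condition("c3ca", capacity = 1e8)
#' scavenger_condition("none")
#' @export
scavenger_condition <- function(name, k = NULL, concentration = NULL,
                                capacity = NULL, residual_capacity = 1e5) {
  stopifnot(is.character(name), length(name) == 1L)
  if (identical(name, "none")) {
    k <- scavenger_rate_constants()[["tris"]] # residual Tris
    capacity <- residual_capacity
    concentration <- concentration_for_capacity(k, capacity)
  } else {
    if (is.null(k)) {
      kk <- scavenger_rate_constants()
      if (!name %in% names(kk)) {
        stop("unknown scavenger `", name, "`: give `k` explicitly",
             call. = FALSE)
      }
      k <- kk[[name]]
    }
    if (is.null(concentration) == is.null(capacity)) {
      stop("give exactly one of `concentration` or `capacity`", call. = FALSE)
    }
    if (is.null(capacity)) {
      capacity <- scavenging_capacity(k, concentration)
    } else {
      concentration <- concentration_for_capacity(k, capacity)
    }
  }
  structure(
    list(name = name, k = k, concentration = concentration,
         capacity = capacity),
    class = "scavenger_condition"
  )
}

#' @export
print.scavenger_condition <- function(x, ...) {
  cat(sprintf(
    "<scavenger_condition> %s: k = %.3g /(M s), S = %.4g M, capacity = %.3g /s\n",
    x$name, x$k, x$concentration, x$capacity
  ))
  invisible(x)
}

#' Protection table: percent damage reduction versus scavenging capacity
#'
#' For each damage metric, computes the percent reduction of the yield at
#' every capacity relative to the reference (lowest-capacity, residual
#' buffer) condition. Non-monotonic runs — a yield rising again with more
#' scavenger — are flagged, not suppressed.
#'
#' @param yields_by_capacity A data frame with columns `capacity_s`,
#'   `metric`, `g_value` (one row per metric and capacity; extra columns
#'   such as `scavenger` are carried through).
#' @param reference_capacity Capacity of the reference row; defaults to the
#'   smallest capacity present (which must exist per metric).
#' @return A tibble with `metric`, `capacity_s`, `g_value`, `reduction_pct`
#'   and `monotonic` (per-metric flag: reductions nondecreasing in capacity).
#'   Reference rows are omitted (their reduction is identically 0).
#' @export
protection_table <- function(yields_by_capacity, reference_capacity = NULL) {
  y <- tibble::as_tibble(yields_by_capacity)
  stopifnot(all(c("capacity_s", "metric", "g_value") %in% names(y)))
  if (is.null(reference_capacity)) reference_capacity <- min(y$capacity_s)
  out <- y |>
    dplyr::group_by(.data$metric) |>
    dplyr::group_modify(function(dat, key) {
      ref <- dat$g_value[dat$capacity_s == reference_capacity]
      if (length(ref) != 1L) {
        stop("missing (or duplicated) reference capacity ",
             format(reference_capacity), " for metric `", key$metric, "`",
             call. = FALSE)
      }
      dat <- dat[dat$capacity_s != reference_capacity, , drop = FALSE]
      if (nrow(dat) == 0L) return(dat["capacity_s" != ""][0, ])
      dat <- dat[order(dat$capacity_s), ]
      dat$reduction_pct <- 100 * (1 - dat$g_value / ref)
      dat$monotonic <- !is.unsorted(dat$reduction_pct)
      dat
    }) |>
    dplyr::ungroup()
  if (nrow(out) > 0 && any(!out$monotonic)) {
    warning("non-monotonic capacity response flagged for metric(s): ",
            paste(unique(out$metric[!out$monotonic]), collapse = ", "),
            call. = FALSE)
  }
  out
}
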