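#' Topology fractions from mean break numbers (Cowan model, forward)
#'
#' Under the Poisson break model for a circular plasmid, a molecule carrying
#' on average `x` single-strand breaks (SSB) and `y` double-strand breaks
#' (DSB) partitions into the four electrophoretic forms as
#' \deqn{f_{SC} = e^{-x-y}, \quad f_C = (1-e^{-x})e^{-y}, \quad
#'       f_L = y e^{-y}, \quad f_F = 1-(1+y)e^{-y}.}
#' Supercoiled (SC) molecules carry no break at all, relaxed circles (C) have
#' at least one SSB and no DSB, linear molecules (L) exactly one DSB, and
#' fragments (F) two or more DSBs. The four fractions sum to one identically.
#'
#' Optionally, DSBs formed by coincident opposite-strand SSBs closer than a
#' gap `h` are folded in to first order: with SSBs placed uniformly and
#' strands assigned at random, the expected number of opposed pairs within
#' `h` bp is `x^2 (2h+1) / (4 L)`, which is moved from the SSB to the DSB
#' channel (`x' = x - 2 d`, `y' = y + d`). This term is off by default; for
#' the SSB numbers reachable before supercoiled-band saturation it is a
#' sub-percent correction to `x` on a 4361-bp plasmid, but a substantial
#' relative addition to `y` at high dose, so enable it only when the matching
#' coincidence rule is active in the data or simulation being inverted.
#'
#' @param breaks A data frame with numeric columns `ssb` and `dsb` (mean
#'   breaks per plasmid, >= 0). Extra columns are carried through.
#' @param coincidence_gap_bp `NULL` (default, no coincidence term) or the
#'   opposed-SSB capture gap in base pairs.
#' @param spec A [plasmid_spec()]; only needed when `coincidence_gap_bp` is
#'   given.
#'
#' @return The input tibble with columns `f_sc`, `f_c`, `f_l`, `f_f` added.
#' @examples
#' cowan_fractions(data.frame(ssb = c(0, 1), dsb = c(0, 0.1)))
#' @seealso [cowan_invert()] for the inverse transform.
#' @export
cowan_fractions <- function(breaks, coincidence_gap_bp = NULL, spec = pbr322()) {
  breaks <- tibble::as_tibble(breaks)
  stopifnot(all(c("ssb", "dsb") %in% names(breaks)))
  x <- breaks$ssb
  y <- breaks$dsb
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x < 0) || any(y < 0)) {
    stop("mean break numbers `ssb` and `dsb` must be finite and >= 0",
         call. = FALSE)
  }
  if (!is.null(coincidence_gap_bp)) {
    stopifnot(inherits(spec, "plasmid_spec"))
    d <- x^2 * (2 * coincidence_gap_bp + 1) / (4 * spec$length_bp)
    x <- pmax(x - 2 * d, 0)
    y <- y + d
  }
  breaks$f_sc <- exp(-x - y)
  breaks$f_c <- (1 - exp(-x)) * exp(-y)
  breaks$f_l <- y * exp(-y)
  breaks$f_f <- 1 - (1 + y) * exp(-y)
  breaks
}

#' Mean break numbers from topology fractions (Cowan model, inverse)
#'
#' Closed-form inversion of [cowan_fractions()]. The SSB load comes from the
#' supercoiled-to-circular ratio, which is invariant to how the lane was
#' normalized:
#' \deqn{x = \ln((f_{SC} + f_C)/f_{SC}).}
#' The DSB load depends on the normalization convention:
#' * `normalization = "all"` — fractions of the entire population (the
#'   fragment fraction is explicit or zero): \eqn{y = -\ln(f_{SC} + f_C)},
#'   with a residual diagnostic `f_l_resid = f_l_obs - y e^{-y}`.
#' * `normalization = "full_length"` (default) — fractions renormalized over
#'   the detected SC/C/L bands because the fragment smear is uncountable,
#'   the usual gel situation. Here \eqn{-\ln(f_{SC}+f_C)} would be biased by
#'   \eqn{\ln(1-f_F)}, and the exact closed form is
#'   \eqn{y = f_L/(f_{SC}+f_C)} (equivalently \eqn{f_L/(1-f_L)} after
#'   renormalization). This estimator is in fact normalization-invariant:
#'   applied to all-population fractions it returns
#'   \eqn{y e^{-y}/e^{-y} = y} as well.
#'
#' A lane with no detectable supercoiled band carries unbounded SSB
#' information ("saturated"): `ssb` is returned as `NA` with `saturated =
#' TRUE` rather than a number. Fractions are clipped to `[eps, 1 - eps]`
#' before logarithms.
#'
#' @param fractions A data frame with numeric columns `f_sc`, `f_c` and
#'   `f_l` (`f_l` may be absent under `normalization = "all"`, where it only
#'   feeds the diagnostic). Extra columns are carried through.
#' @param normalization `"full_length"` (fractions over SC+C+L) or `"all"`
#'   (fractions over the whole population).
#' @param eps Clipping bound applied before taking logarithms.
#' @param saturation_threshold Supercoiled fraction below which the lane is
#'   declared saturated and `ssb` is not reported.
#'
#' @return The input tibble with columns `ssb`, `dsb`, `saturated` and
#'   `f_l_resid` added (`f_l_resid` is `NA` under `"full_length"`, where
#'   the linear band is consumed by the estimate itself).
#' @examples
#' fr <- cowan_fractions(data.frame(ssb = 1, dsb = 0.1))
#' cowan_invert(fr, normalization = "all")[, c("ssb", "dsb")]
#' @export
cowan_invert <- function(fractions, normalization = c("full_length", "all"),
                         eps = 1e-9, saturation_threshold = 1e-6) {
  normalization <- match.arg(normalization)
  fractions <- tibble::as_tibble(fractions)
  stopifnot(all(c("f_sc", "f_c") %in% names(fractions)))
  f_sc <- fractions$f_sc
  f_c <- fractions$f_c
  f_l <- if ("f_l" %in% names(fractions)) fractions$f_l else rep(NA_real_, length(f_sc))
  if (any(!is.finite(f_sc)) || any(!is.finite(f_c)) ||
      any(f_sc < 0) || any(f_c < 0) || any(f_sc > 1) || any(f_c > 1)) {
    stop("`f_sc` and `f_c` must be fractions in [0, 1]", call. = FALSE)
  }
  if (all(f_sc == 0)) {
    stop("saturated lane: no supercoiled band detected, SSB count is unbounded",
         call. = FALSE)
  }
  bad <- f_sc + f_c >= 1 - 1e-12 & !is.na(f_l) & f_l > 1e-9
  if (any(bad)) {
    stop("inconsistent fractions: f_sc + f_c >= 1 while f_l > 0 (rows ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  }
  full <- pmax(f_sc + f_c, eps)
  sc <- pmax(f_sc, eps)
  saturated <- f_sc < saturation_threshold
  if (normalization == "all") {
    y <- -log(full)
    resid <- f_l - y * exp(-y)
  } else {
    if (all(is.na(f_l))) {
      stop("`f_l` is required under normalization = \"full_length\"",
           call. = FALSE)
    }
    y <- f_l / full
    resid <- rep(NA_real_, length(y))
  }
  x <- log(full / sc)
  x[saturated] <- NA_real_
  fractions$ssb <- x
  fractions$dsb <- y
  fractions$saturated <- saturated
  fractions$f_l_resid <- resid
  fractions
}

#' Delta-method variances for inverted break numbers
#'
#' Propagates counting noise (a lane built from `n` molecules) and
#' multiplicative band-intensity noise (densitometry, coefficient of
#' variation `noise_cv` per band) through the Cowan inversion by the delta
#' method. With `u = f_sc` and `v = f_sc + f_c`, the SSB variance is
#' `var(x) = (1/u - 1/v)/n + 2 cv^2 ((v-u)/v)^2` under either normalization
#' (`x` is a band ratio). The DSB variance follows the estimator in use:
#' under `"all"`, `var(y) = (1-v)/(n v) + 2 cv^2 (1-v)^2`; under
#' `"full_length"` (`y = f_l / v`),
#' `var(y) = f_l/(n v^2) + f_l^2/(n v^3) + 2 cv^2 (f_l/v)^2`.
#'
#' These variances feed the weighted G-value regression; they are first-order
#' approximations, adequate away from saturation.
#'
#' @param fractions Data frame with `f_sc`, `f_c` (and `f_l` under
#'   `"full_length"`) columns, e.g. the output of [cowan_invert()].
#' @param normalization Fraction convention, as in [cowan_invert()].
#' @param n_molecules Molecules contributing to the lane (Inf for pure
#'   densitometry noise).
#' @param noise_cv Per-band intensity coefficient of variation.
#' @param eps Clipping bound.
#' @return The input tibble with columns `var_ssb` and `var_dsb` added.
#' @export
cowan_invert_var <- function(fractions,
                             normalization = c("full_length", "all"),
                             n_molecules = Inf, noise_cv = 0, eps = 1e-9) {
  normalization <- match.arg(normalization)
  fractions <- tibble::as_tibble(fractions)
  u <- pmin(pmax(fractions$f_sc, eps), 1 - eps)
  v <- pmin(pmax(fractions$f_sc + fractions$f_c, eps), 1 - eps)
  var_x <- (1 / u - 1 / v) / n_molecules + 2 * noise_cv^2 * ((v - u) / v)^2
  if (normalization == "all") {
    var_y <- (1 - v) / (n_molecules * v) + 2 * noise_cv^2 * (1 - v)^2
  } else {
    fl <- pmax(fractions$f_l, 0)
    var_y <- fl / (n_molecules * v^2) + fl^2 / (n_molecules * v^3) +
      2 * noise_cv^2 * (fl / v)^2
  }
  fractions$var_ssb <- var_x
  fractions$var_dsb <- var_y
  fractions
}
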