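#' Fit a damage-induction G-value (events per Mbp per Gy)
#'
#' The G-value of a damage class is the slope of mean events per Mbp against
#' dose, fitted with a free intercept over the linear regime. When per-point
#' variances are supplied the fit is weighted (WLS) and the slope standard
#' error is reported as the larger of the variance-propagated ("known
#' variance") standard error and the residual-based one — a deliberately
#' conservative convention, because the inverted break numbers are strongly
#' heteroscedastic near supercoiled-band saturation and either estimate alone
#' can undercover.
#'
#' @param points A data frame with columns `dose_gy` and `events_per_mbp`,
#'   optionally `var_events` (variance of each response point, same units
#'   squared).
#' @param var_col Name of the variance column, or `NULL` for ordinary least
#'   squares.
#'
#' @return An object of class `g_fit` with elements `g_value` (slope),
#'   `sem`, `intercept`, `n`, `doses`, and the underlying `lm` fit.
#'   [generics::tidy()] and [generics::glance()] methods are provided.
#' @examples
#' fit_g_value(data.frame(dose_gy = 0:2, events_per_mbp = c(0, 101.1, 202.2)))
#' @export
fit_g_value <- function(points, var_col = "var_events") {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("dose_gy", "events_per_mbp") %in% names(points)))
  points <- points[is.finite(points$events_per_mbp) & is.finite(points$dose_gy), ]
  doses <- unique(points$dose_gy)
  if (length(doses) < 3L || stats::sd(points$dose_gy) == 0) {
    stop("insufficient data: need >= 3 distinct doses with nonzero variance",
         call. = FALSE)
  }
  use_w <- !is.null(var_col) && var_col %in% names(points) &&
    any(is.finite(points[[var_col]]))
  # residual-based standard errors get the Student-t small-sample
  # correction so that +/- 2 sem keeps ~95% coverage at the fit's df
  t_corr <- function(df) {
    if (df < 1) return(1)
    stats::qt(stats::pnorm(2), df) / 2
  }
  if (use_w) {
    v <- points[[var_col]]
    floor_v <- max(v, na.rm = TRUE) * 1e-8 + 1e-300
    w <- 1 / pmax(v, floor_v)
    fit <- stats::lm(events_per_mbp ~ dose_gy, data = points, weights = w)
    # slope variance with the supplied variances taken as known
    d <- points$dose_gy
    dbar <- sum(w * d) / sum(w)
    sww <- sum(w * (d - dbar)^2)
    sem_known <- sqrt(1 / sww)
    sem_resid <- summary(fit)$coefficients["dose_gy", "Std. Error"]
    sem <- max(sem_known, sem_resid * t_corr(fit$df.residual))
  } else {
    fit <- stats::lm(events_per_mbp ~ dose_gy, data = points)
    s <- withCallingHandlers(
      summary(fit),
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    sem <- s$coefficients["dose_gy", "Std. Error"] * t_corr(fit$df.residual)
  }
  co <- stats::coef(fit)
  structure(
    list(
      g_value = unname(co["dose_gy"]),
      sem = unname(sem),
      intercept = unname(co["(Intercept)"]),
      n = nrow(points),
      doses = sort(doses),
      weighted = use_w,
      fit = fit
    ),
    class = "g_fit"
  )
}

#' @export
print.g_fit <- function(x, ...) {
  cat(sprintf(
    "<g_fit> G = %.4f +/- %.4f events Mbp^-1 Gy^-1 (%d points, doses %s Gy%s)\n",
    x$g_value, x$sem, x$n, paste(x$doses, collapse = "/"),
    if (x$weighted) ", weighted" else ""
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a G-value fit
#'
#' @param x A `g_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.g_fit <- function(x, ...) {
  tibble::tibble(
    term = "g_value",
    estimate = x$g_value,
    std.error = x$sem
  )
}

#' Glance at a G-value fit
#'
#' @param x A `g_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with fit-level summaries.
#' @export
glance.g_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    g_value = x$g_value,
    sem = x$sem,
    intercept = x$intercept,
    r.squared = s$r.squared,
    n = x$n,
    n_doses = length(x$doses),
    dose_max_gy = max(x$doses),
    weighted = x$weighted
  )
}

#' Damage-based relative biological effectiveness
#'
#' The ratio of DSB induction rates, test radiation over reference radiation
#' (conventionally X-rays). A damage-based ("apparent") RBE, not a
#' cell-survival RBE.
#'
#' @param dsb_test DSB induction rate of the test radiation (> 0 expected,
#'   >= 0 allowed).
#' @param dsb_reference DSB induction rate of the reference radiation (> 0).
#' @param digits Rounding used for display; the unrounded value is returned
#'   invisibly as an attribute-free number when `digits = NULL`.
#' @return `dsb_test / dsb_reference`, rounded to `digits` (default 2, the
#'   conventional display precision).
#' @examples
#' rbe(1.914, 3.147) # 0.61
#' @export
rbe <- function(dsb_test, dsb_reference, digits = 2) {
  if (any(dsb_reference <= 0)) {
    stop("`dsb_reference` must be positive", call. = FALSE)
  }
  out <- dsb_test / dsb_reference
  if (!is.null(digits)) out <- round(out, digits) else out
  out
}

#' Damage yield ratio
#'
#' Plain quotient used for the standard summaries: non-DSB clusters per DSB,
#' base lesions per SSB, SSB per DSB.
#'
#' @param numerator Numerator yield.
#' @param denominator Denominator yield (> 0).
#' @param digits Display rounding; `NULL` for the raw quotient.
#' @return `numerator / denominator`.
#' @examples
#' damage_ratio(14.723, 3.147, digits = 1) # 4.7
#' @export
damage_ratio <- function(numerator, denominator, digits = NULL) {
  if (any(denominator <= 0)) {
    stop("`denominator` must be positive", call. = FALSE)
  }
  out <- numerator / denominator
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Percent reduction of a damage yield by a protective treatment
#'
#' @param reference Yield without the treatment (> 0).
#' @param treated Yield with the treatment (>= 0).
#' @return `100 * (1 - treated / reference)`, in percent; negative when the
#'   treatment increased the yield.
#' @examples
#' percent_reduction(100, 2) # 98
#' @export
percent_reduction <- function(reference, treated) {
  if (any(reference <= 0)) {
    stop("`reference` must be positive", call. = FALSE)
  }
  if (any(treated < 0)) {
    stop("`treated` must be non-negative", call. = FALSE)
  }
  100 * (1 - treated / reference)
}

#' Base lesions and non-DSB clusters from enzyme differences
#'
#' Glycosylase treatment (Fpg for oxidized purines, Nth for oxidized
#' pyrimidines) converts base lesions into extra strand breaks. The excess
#' SSB yield of each enzyme over the untreated series measures base lesions,
#' and the excess DSB yield measures non-DSB clustered lesions (opposed
#' lesions within a short gap that become a DSB upon cleavage):
#' \deqn{G_{base} = (SSB_{Fpg} - SSB_{none}) + (SSB_{Nth} - SSB_{none})}
#' \deqn{G_{cluster} = (DSB_{Fpg} - DSB_{none}) + (DSB_{Nth} - DSB_{none})}
#' Purine and pyrimidine lesion classes are disjoint, so the two excesses are
#' summed by default; `combine = "mean"` averages them instead. Standard
#' errors combine in quadrature. Negative point estimates are reported as-is
#' with `negative = TRUE` (clipping would bias simulation nulls).
#'
#' @param g_table A data frame with columns `enzyme` (`"none"`, `"fpg"`,
#'   `"nth"`), `metric` (`"ssb"`, `"dsb"`), `g_value` and `sem`, e.g. from
#'   [g_values()].
#' @param combine `"sum"` (default) or `"mean"`.
#' @return A tibble with one row per derived metric (`base_lesions`,
#'   `non_dsb_clusters`): columns `metric`, `g_value`, `sem`, `negative`.
#' @export
enzyme_differences <- function(g_table, combine = c("sum", "mean")) {
  combine <- match.arg(combine)
  g_table <- tibble::as_tibble(g_table)
  stopifnot(all(c("enzyme", "metric", "g_value", "sem") %in% names(g_table)))
  need <- expand.grid(enzyme = c("none", "fpg", "nth"),
                      metric = c("ssb", "dsb"), stringsAsFactors = FALSE)
  have <- paste(g_table$enzyme, g_table$metric)
  missing <- !(paste(need$enzyme, need$metric) %in% have)
  if (any(missing)) {
    stop("enzyme-difference alignment error: missing yields for ",
         paste(paste(need$enzyme[missing], need$metric[missing]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(have)) {
    stop("enzyme-difference alignment error: duplicated enzyme/metric rows",
         call. = FALSE)
  }
  pick <- function(enz, met, col) {
    g_table[[col]][g_table$enzyme == enz & g_table$metric == met]
  }
  scale <- if (combine == "sum") 1 else 0.5
  diff_of <- function(met) {
    d_fpg <- pick("fpg", met, "g_value") - pick("none", met, "g_value")
    d_nth <- pick("nth", met, "g_value") - pick("none", met, "g_value")
    # (G_fpg - G_0) + (G_nth - G_0): the untreated slope enters with
    # coefficient -2, so its variance contributes four-fold
    value <- scale * (d_fpg + d_nth)
    sem <- scale * sqrt(
      pick("fpg", met, "sem")^2 + pick("nth", met, "sem")^2 +
        4 * pick("none", met, "sem")^2
    )
    c(value, sem)
  }
  base <- diff_of("ssb")
  clus <- diff_of("dsb")
  out <- tibble::tibble(
    metric = c("base_lesions", "non_dsb_clusters"),
    g_value = c(base[1], clus[1]),
    sem = c(base[2], clus[2]),
    negative = c(base[1] < 0, clus[1] < 0)
  )
  if (any(out$negative)) {
    warning("negative enzyme-difference point estimate reported as-is",
            call. = FALSE)
  }
  out
}
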