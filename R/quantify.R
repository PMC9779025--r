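#' Normalize gel-band intensities and invert to break numbers
#'
#' Takes a raw lane table (one row per gel lane with band intensities
#' `i_sc`, `i_c`, `i_l`), normalizes the detected full-length bands to
#' fractions, applies the Cowan inversion and converts per-plasmid breaks to
#' events per Mbp. The fragment smear is not part of the normalization, as
#' is standard when it cannot be integrated reliably.
#'
#' Delta-method variances of the inverted break numbers are attached when the
#' lane noise model is given (`n_molecules`, `noise_cv`); they feed the
#' weighted G-value fits downstream.
#'
#' @param lanes A lane table as returned by [read_lane_table()] or
#'   [simulate_lane_table()]: columns `dose_gy`, `enzyme`, `replicate`,
#'   `i_sc`, `i_c`, `i_l` (any grouping columns such as `condition_id` are
#'   carried through).
#' @param spec A [plasmid_spec()].
#' @param n_molecules Molecules per lane for the counting-noise part of the
#'   variance model (`Inf` to ignore).
#' @param noise_cv Per-band densitometry coefficient of variation for the
#'   variance model.
#' @return A tibble: the input plus `f_sc`, `f_c`, `f_l`, `ssb`, `dsb`,
#'   `saturated`, `f_l_resid`, `ssb_mbp`, `dsb_mbp`, `var_ssb_mbp`,
#'   `var_dsb_mbp` columns. Break columns are per plasmid; `*_mbp` columns
#'   are events per Mbp.
#' @export
quantify_lanes <- function(lanes, spec = pbr322(), n_molecules = Inf,
                           noise_cv = 0.05) {
  lanes <- tibble::as_tibble(lanes)
  stopifnot(all(c("dose_gy", "i_sc", "i_c", "i_l") %in% names(lanes)))
  if (any(lanes$i_sc < 0 | lanes$i_c < 0 | lanes$i_l < 0)) {
    stop("band intensities must be non-negative", call. = FALSE)
  }
  tot <- lanes$i_sc + lanes$i_c + lanes$i_l
  if (any(tot <= 0)) {
    stop("degenerate lane(s) with zero total full-length intensity: rows ",
         paste(which(tot <= 0), collapse = ", "), call. = FALSE)
  }
  lanes$f_sc <- lanes$i_sc / tot
  lanes$f_c <- lanes$i_c / tot
  lanes$f_l <- lanes$i_l / tot
  out <- cowan_invert(lanes, normalization = "full_length")
  # variance weights are evaluated at the dose-level mean fractions rather
  # than each lane's own, so that weight fluctuations do not correlate with
  # the lane errors (empirical per-lane weights bias a WLS slope downward)
  keys <- intersect(c("condition_id", "enzyme", "dose_gy"), names(out))
  grp <- do.call(paste, c(out[keys], sep = "\r"))
  mean_by <- function(x) stats::ave(x, grp, FUN = mean)
  vf <- cowan_invert_var(
    tibble::tibble(f_sc = mean_by(out$f_sc), f_c = mean_by(out$f_c),
                   f_l = mean_by(out$f_l)),
    normalization = "full_length",
    n_molecules = n_molecules, noise_cv = noise_cv
  )
  out$var_ssb <- vf$var_ssb
  out$var_dsb <- vf$var_dsb
  out$ssb_mbp <- per_mbp_allow_na(out$ssb, spec)
  out$dsb_mbp <- per_mbp_allow_na(out$dsb, spec)
  scale2 <- (1e6 / spec$length_bp)^2
  out$var_ssb_mbp <- out$var_ssb * scale2
  out$var_dsb_mbp <- out$var_dsb * scale2
  out
}

per_mbp_allow_na <- function(x, spec) x / (spec$length_bp / 1e6)

#' Random-coincidence background correction for enzyme lanes
#'
#' Enzymatic cleavage multiplies the SSB load, and some of the new breaks
#' land opposite an unrelated existing break by chance, registering as
#' spurious "clustered" DSBs. For breaks placed independently, the expected
#' number of opposed pairs within a gap `h` on a plasmid of `L` bp grows as
#' `x^2 (2h+1)/(4L)`; the excess attributable to the enzyme in a lane with
#' measured SSB loads `x_enz` (treated) and `x_0` (matched untreated lane) is
#' \deqn{(x_{enz}^2 - x_0^2)\,(2h+1)/(4L),}
#' the accidental-coincidence background familiar from counting experiments.
#' This function subtracts it from the per-lane DSB numbers of enzyme-treated
#' lanes, matching lanes on dose and replicate (plus any extra grouping
#' columns present). Lanes without a usable SSB estimate (saturated) are left
#' uncorrected; they sit outside the regression window anyway.
#'
#' @param quantified Output of [quantify_lanes()] including an `enzyme`
#'   column with `"none"` rows to match against.
#' @param gap_bp Opposed-break capture gap in bp.
#' @param spec A [plasmid_spec()].
#' @return `quantified` with `dsb` and `dsb_mbp` corrected in enzyme lanes
#'   and a `dsb_coincidence_mbp` column recording the subtracted background.
#' @export
coincidence_correct <- function(quantified, gap_bp = 10, spec = pbr322()) {
  q <- tibble::as_tibble(quantified)
  stopifnot(all(c("enzyme", "dose_gy", "ssb", "dsb") %in% names(q)))
  keys <- intersect(c("condition_id", "dose_gy", "replicate"), names(q))
  none <- q[q$enzyme == "none", c(keys, "ssb")]
  names(none)[names(none) == "ssb"] <- "ssb_none"
  q <- dplyr::left_join(q, none, by = keys)
  L <- spec$length_bp
  corr <- (q$ssb^2 - q$ssb_none^2) * (2 * gap_bp + 1) / (4 * L)
  corr[q$enzyme == "none" | !is.finite(corr)] <- 0
  corr <- pmax(corr, 0)
  # each accidental fusion registers one spurious DSB; in the Poisson-mean
  # scale of the inversion the full-length fraction loses exp(-corr), so the
  # measured SSB mean drops by corr (the converting molecules stay
  # full-length-visible through their SC/C ratio only once)
  q$dsb <- q$dsb - corr
  q$ssb <- q$ssb + corr
  q$dsb_coincidence_mbp <- per_mbp_allow_na(corr, spec)
  if ("dsb_mbp" %in% names(q)) q$dsb_mbp <- per_mbp_allow_na(q$dsb, spec)
  if ("ssb_mbp" %in% names(q)) q$ssb_mbp <- per_mbp_allow_na(q$ssb, spec)
  q$ssb_none <- NULL
  q
}

#' G-values for each enzyme treatment of a dose series
#'
#' Fits SSB and DSB G-values per enzyme stratum from quantified lanes,
#' restricting each fit to its linear regime: doses where the mean
#' supercoiled fraction is at least `min_fsc` (the supercoiled band is
#' effectively gone above ~1%, and the SSB inversion saturates there). The
#' same window is used for the DSB fit by default so that enzyme differences
#' compare like with like; set `dsb_all_doses = TRUE` to extend DSB fits to
#' the full panel when break induction is known to be linear throughout.
#'
#' @param quantified Output of [quantify_lanes()] (optionally after
#'   [coincidence_correct()]).
#' @param min_fsc Minimum mean supercoiled fraction for a dose to enter the
#'   fit window (default 0.01).
#' @param dsb_all_doses If `TRUE`, DSB fits use every dose.
#' @return A tibble with columns `enzyme`, `metric` (`"ssb"`/`"dsb"`),
#'   `g_value`, `sem`, `n_points`, `dose_max_gy` and a list-column `fit`
#'   holding each [fit_g_value()] object.
#' @export
g_values <- function(quantified, min_fsc = 0.01, dsb_all_doses = FALSE) {
  q <- tibble::as_tibble(quantified)
  if (!"enzyme" %in% names(q)) q$enzyme <- "none"
  stopifnot(all(c("dose_gy", "ssb_mbp", "dsb_mbp") %in% names(q)))
  fit_one <- function(dat, metric) {
    resp <- if (metric == "ssb") "ssb_mbp" else "dsb_mbp"
    vcol <- if (metric == "ssb") "var_ssb_mbp" else "var_dsb_mbp"
    mean_fsc <- tapply(dat$f_sc, dat$dose_gy, mean)
    in_window <- as.numeric(names(mean_fsc))[mean_fsc >= min_fsc]
    use <- if (metric == "dsb" && dsb_all_doses) dat else
      dat[dat$dose_gy %in% in_window, ]
    pts <- tibble::tibble(
      dose_gy = use$dose_gy,
      events_per_mbp = use[[resp]],
      var_events = if (vcol %in% names(use)) use[[vcol]] else NA_real_
    )
    fit <- fit_g_value(pts)
    tibble::tibble(
      metric = metric,
      g_value = fit$g_value,
      sem = fit$sem,
      n_points = fit$n,
      dose_max_gy = max(fit$doses),
      fit = list(fit)
    )
  }
  q |>
    dplyr::group_by(.data$enzyme) |>
    dplyr::group_modify(function(dat, key) {
      dplyr::bind_rows(fit_one(dat, "ssb"), fit_one(dat, "dsb"))
    }) |>
    dplyr::ungroup()
}

#' Full yield table for one irradiation condition
#'
#' Runs the complete quantification for one dose series: Cowan inversion,
#' optional coincidence background correction, per-enzyme G-value fits and
#' the enzyme-difference lesion classes.
#'
#' @inheritParams quantify_lanes
#' @inheritParams g_values
#' @param gap_bp Opposed-break gap for [coincidence_correct()]; `NULL`
#'   disables the correction.
#' @param combine Combination rule for [enzyme_differences()].
#' @return A tibble with columns `metric` (`ssb`, `dsb`, `base_lesions`,
#'   `non_dsb_clusters`), `g_value`, `sem` (events per Mbp per Gy) and
#'   `negative`. The `ssb`/`dsb` rows are the untreated yields.
#' @export
damage_yields <- function(lanes, spec = pbr322(), n_molecules = Inf,
                          noise_cv = 0.05, gap_bp = 10, min_fsc = 0.01,
                          dsb_all_doses = FALSE, combine = "sum") {
  q <- quantify_lanes(lanes, spec = spec, n_molecules = n_molecules,
                      noise_cv = noise_cv)
  has_enzymes <- "enzyme" %in% names(q) &&
    all(c("none", "fpg", "nth") %in% q$enzyme)
  if (has_enzymes && !is.null(gap_bp)) {
    q <- coincidence_correct(q, gap_bp = gap_bp, spec = spec)
  }
  gtab <- g_values(q, min_fsc = min_fsc, dsb_all_doses = dsb_all_doses)
  none <- gtab[gtab$enzyme == "none", c("metric", "g_value", "sem")]
  none$negative <- none$g_value < 0
  if (!has_enzymes) {
    return(tibble::as_tibble(none))
  }
  diffs <- enzyme_differences(gtab, combine = combine)
  dplyr::bind_rows(tibble::as_tibble(none), diffs)
}
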