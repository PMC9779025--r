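#' Read a gel lane-intensity table
#'
#' The lane table is the numeric hand-off from gel densitometry: one row per
#' lane with raw band intensities for the supercoiled, circular and linear
#' bands. Required columns: `condition_id`, `position`, `enzyme`, `dose_gy`,
#' `replicate`, `i_sc`, `i_c`, `i_l` (comma-separated, UTF-8, header
#' mandatory; doses in Gy; intensities in arbitrary units >= 0).
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_lane_table <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("condition_id", "position", "enzyme", "dose_gy", "replicate",
                "i_sc", "i_c", "i_l")
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    stop("lane table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("i_sc", "i_c", "i_l")) {
    bad <- which(x[[col]] < 0)
    if (length(bad)) {
      stop("negative intensity in `", col, "` at row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  key <- paste(x$condition_id, x$enzyme, x$dose_gy, x$replicate)
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop("duplicated (condition, enzyme, dose, replicate) key at row(s) ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  bad_enz <- which(!x$enzyme %in% c("none", "fpg", "nth"))
  if (length(bad_enz)) {
    stop("unknown enzyme label at row(s) ", paste(bad_enz, collapse = ", "),
         " (expected none/fpg/nth)", call. = FALSE)
  }
  if (any(x$dose_gy < 0)) stop("doses must be >= 0", call. = FALSE)
  x
}

#' Write a lane table to CSV
#'
#' @param lanes Lane table (tibble).
#' @param path Output CSV path.
#' @return `lanes`, invisibly.
#' @export
write_lane_table <- function(lanes, path) {
  readr::write_csv(lanes, path)
  invisible(lanes)
}

#' Read a simulation scenario from YAML
#'
#' A scenario describes a condition grid for the simulator: the plasmid,
#' lane noise, dose panel, replicate count, and one entry per irradiation
#' condition with its assay-level yields and scavenging condition (given as
#' either `concentration` or target `capacity`).
#'
#' @param path YAML file path.
#' @return A `scenario` list.
#' @export
read_scenario <- function(path) {
  scn <- yaml::read_yaml(path)
  if (is.null(scn$conditions) || !length(scn$conditions)) {
    stop("scenario has no `conditions`", call. = FALSE)
  }
  ids <- vapply(scn$conditions, function(x) x$id %||% "", "")
  if (any(ids == "") || anyDuplicated(ids)) {
    stop("every scenario condition needs a unique `id`", call. = FALSE)
  }
  if (!is.null(scn$reference) && !scn$reference %in% ids) {
    stop("scenario `reference` (", scn$reference,
         ") is not among the condition ids", call. = FALSE)
  }
  structure(scn, class = "scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scenario_plasmid <- function(scn) {
  p <- scn$plasmid
  if (is.null(p)) return(pbr322())
  plasmid_spec(p$name %||% "plasmid", p$length_bp, p$bp_nm %||% 0.34)
}

scenario_config <- function(scn, cond) {
  y <- cond$yields
  sim_config(
    plasmid = scenario_plasmid(scn),
    g_ssb = y$ssb, g_dsb = y$dsb,
    g_base_purine = y$base_purine %||% (y$base_lesions / 2),
    g_base_pyrimidine = y$base_pyrimidine %||% (y$base_lesions / 2),
    g_cluster = y$cluster %||% 0,
    indirect_fraction = scn$indirect_fraction %||% 0.9,
    half_capacity = scn$half_capacity %||% 1e5,
    cluster_window_bp = scn$cluster_window_bp %||% 10L,
    doses = unlist(scn$doses %||% c(0, 1, 2, 4, 8, 10)),
    n_molecules = scn$n_molecules %||% 2000L,
    noise_cv = scn$noise_cv %||% 0.05
  )
}

# In a scenario the configured yields are the yields OF that condition, so
# a missing scavenger entry (or "none") applies no further attenuation; an
# explicit scavenger with concentration/capacity invokes the competition law.
scenario_scavenger <- function(cond) {
  sv <- cond$scavenger
  if (is.null(sv) || identical(sv$name, "none")) return(NULL)
  scavenger_condition(sv$name, k = sv$k,
                      concentration = sv$concentration,
                      capacity = sv$capacity)
}

#' Simulate every condition of a scenario
#'
#' @param scn A [read_scenario()] result (or an equivalent list).
#' @param seed RNG seed reproducing the full grid.
#' @return A lane table covering all conditions, with a `conditions`
#'   attribute (metadata tibble) and per-table `noise_cv`/`n_molecules`
#'   attributes.
#' @export
simulate_scenario <- function(scn, seed = NULL) {
  run <- function() {
    tabs <- lapply(scn$conditions, function(cond) {
      cfg <- scenario_config(scn, cond)
      sv <- scenario_scavenger(cond)
      simulate_lane_table(
        cfg, scavenger = sv,
        enzyme_doses = scn$enzyme_doses,
        replicates = scn$replicates %||% 3L,
        condition_id = cond$id,
        position = cond$position %||% NA_character_
      )
    })
    out <- dplyr::bind_rows(tabs)
    attr(out, "noise_cv") <- scn$noise_cv %||% 0.05
    attr(out, "n_molecules") <- scn$n_molecules %||% 2000L
    attr(out, "conditions") <- tibble::tibble(
      condition_id = vapply(scn$conditions, function(x) x$id, ""),
      position = vapply(scn$conditions, function(x)
        x$position %||% NA_character_, ""),
      let_kev_um = vapply(scn$conditions, function(x)
        as.numeric(x$let_kev_um %||% NA_real_), 1),
      scavenger = vapply(scn$conditions, function(x)
        (x$scavenger$name) %||% "none", ""),
      capacity_s = vapply(scn$conditions, function(x) {
        sv <- scenario_scavenger(x)
        if (is.null(sv)) 0 else sv$capacity
      }, 1)
    )
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' End-to-end damage report
#'
#' Runs the whole quantification for every condition in a lane table:
#' band-fraction normalization, Cowan inversion, coincidence background
#' correction, G-value fits, enzyme-difference lesion classes, the summary
#' ratios (clusters/DSB, base lesions/SSB, SSB/DSB) and, when a reference
#' condition is named, damage-based RBE values against its DSB yield.
#' Deterministic given its inputs.
#'
#' @param lanes A lane table ([read_lane_table()] / [simulate_scenario()]).
#' @param conditions Optional metadata tibble (`condition_id`, `position`,
#'   `let_kev_um`, `scavenger`, `capacity_s`); defaults to the table's
#'   `conditions` attribute.
#' @param reference_condition `condition_id` whose DSB yield is the RBE
#'   reference (typically the X-ray condition), or `NULL`.
#' @param spec A [plasmid_spec()].
#' @param n_molecules,noise_cv Lane noise model for the variance weights;
#'   default to the table's attributes when present.
#' @param seed Seed recorded in the report header (reports are themselves
#'   deterministic).
#' @param ... Passed to [damage_yields()].
#' @return A `damage_report`: list with `yields`, `ratios`, `rbe`, `meta`.
#' @export
run_report <- function(lanes, conditions = NULL, reference_condition = NULL,
                       spec = pbr322(),
                       n_molecules = attr(lanes, "n_molecules") %||% Inf,
                       noise_cv = attr(lanes, "noise_cv") %||% 0.05,
                       seed = NULL, ...) {
  lanes <- tibble::as_tibble(lanes)
  if (!"condition_id" %in% names(lanes)) lanes$condition_id <- "all"
  conditions <- conditions %||% attr(lanes, "conditions")
  if (!is.null(reference_condition) &&
      !reference_condition %in% lanes$condition_id) {
    stop("reference condition `", reference_condition,
         "` not present in the lane table", call. = FALSE)
  }
  yields <- lanes |>
    dplyr::group_by(.data$condition_id) |>
    dplyr::group_modify(function(dat, key) {
      damage_yields(dat, spec = spec, n_molecules = n_molecules,
                    noise_cv = noise_cv, ...)
    }) |>
    dplyr::ungroup()
  if (!is.null(conditions)) {
    yields <- dplyr::left_join(yields, conditions, by = "condition_id")
  }
  wide <- yields |>
    dplyr::select("condition_id", "metric", "g_value") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "g_value")
  ratios <- tibble::tibble(
    condition_id = wide$condition_id,
    clusters_per_dsb = ifelse(
      "non_dsb_clusters" %in% names(wide) & wide$dsb > 0,
      (wide$non_dsb_clusters %||% NA_real_) / wide$dsb, NA_real_),
    base_per_ssb = ifelse(
      "base_lesions" %in% names(wide) & wide$ssb > 0,
      (wide$base_lesions %||% NA_real_) / wide$ssb, NA_real_),
    ssb_per_dsb = ifelse(wide$dsb > 0, wide$ssb / wide$dsb, NA_real_)
  )
  rbe_tab <- NULL
  if (!is.null(reference_condition)) {
    ref_dsb <- wide$dsb[wide$condition_id == reference_condition]
    rbe_tab <- tibble::tibble(
      condition_id = wide$condition_id,
      rbe = rbe(wide$dsb, ref_dsb)
    )
    rbe_tab <- rbe_tab[rbe_tab$condition_id != reference_condition, ]
  }
  structure(
    list(
      yields = yields, ratios = ratios, rbe = rbe_tab,
      meta = list(
        package_version = as.character(utils::packageVersion("radbreaks")),
        config_hash = rlang::hash(list(lanes, conditions,
                                       reference_condition)),
        seed = seed,
        n_lanes = nrow(lanes)
      )
    ),
    class = "damage_report"
  )
}

#' @export
print.damage_report <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<damage_report> radbreaks %s | config %s | seed %s | %d lanes\n",
              m$package_version, substr(m$config_hash, 1, 8),
              m$seed %||% "none", m$n_lanes))
  for (cid in unique(x$yields$condition_id)) {
    y <- x$yields[x$yields$condition_id == cid, ]
    cat(sprintf("\n== %s ==\n", cid))
    for (i in seq_len(nrow(y))) {
      cat(sprintf("  %-18s %9.3f +/- %7.3f  events Mbp^-1 Gy^-1%s\n",
                  y$metric[i], y$g_value[i], y$sem[i],
                  if (isTRUE(y$negative[i])) "  [negative estimate]" else ""))
    }
    r <- x$ratios[x$ratios$condition_id == cid, ]
    if (nrow(r)) {
      cat(sprintf("  clusters/DSB %.1f | base/SSB %.1f | SSB/DSB %.0f\n",
                  r$clusters_per_dsb, r$base_per_ssb, r$ssb_per_dsb))
    }
    if (!is.null(x$rbe)) {
      rb <- x$rbe[x$rbe$condition_id == cid, ]
      if (nrow(rb)) cat(sprintf("  apparent RBE %.2f\n", rb$rbe))
    }
  }
  invisible(x)
}

#' Write a damage report to CSV with a provenance header
#'
#' The yields table is written in the standard schema (condition, position,
#' LET_keV_um, scavenger, capacity_s, metric, value, sem, units), preceded
#' by comment lines recording package version, configuration hash and seed.
#'
#' @param report A [run_report()] result.
#' @param path Output CSV path.
#' @return `report`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "damage_report"))
  m <- report$meta
  header <- sprintf(
    "# radbreaks %s | config %s | seed %s",
    m$package_version, m$config_hash, m$seed %||% "none"
  )
  y <- report$yields
  col_or <- function(col, default) {
    if (col %in% names(y)) y[[col]] else default
  }
  out <- tibble::tibble(
    condition = y$condition_id,
    position = col_or("position", NA_character_),
    LET_keV_um = col_or("let_kev_um", NA_real_),
    scavenger = col_or("scavenger", NA_character_),
    capacity_s = col_or("capacity_s", NA_real_),
    metric = y$metric,
    value = y$g_value,
    sem = y$sem,
    units = "events_per_Mbp_per_Gy"
  )
  writeLines(header, path)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  invisible(report)
}
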