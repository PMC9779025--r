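#' Configure the plasmid damage simulator
#'
#' Defines the Monte Carlo generator that stands in for the wet-lab
#' experiment: Poisson lesion induction proportional to dose, a scavenger
#' competition law, enzymatic conversion of base lesions to breaks, gel-band
#' noise and AFM rendering all start from this configuration.
#'
#' Rates are parameterized at the assay level: `g_ssb` is the total SSB yield
#' a noiseless gel assay would report (including the break member of each
#' clustered lesion), `g_base_*` the net base-lesion yields revealed by the
#' enzyme differences, and `g_cluster` the yield of non-DSB clustered lesions
#' (a strand break plus an opposed base lesion within `cluster_window_bp`)
#' that surface as excess DSBs after cleavage. Internally the generator
#' plants isolated-lesion rates that reproduce those assay expectations in
#' the low-dose limit. Defaults are the proton beam-entrance condition.
#'
#' The scavenger competition law scales every yield by
#' `(1 - phi) + phi * c0 / (c0 + capacity)` with `phi = indirect_fraction`
#' (default 0.9: the dominant, scavengeable indirect pathway) and
#' `c0 = half_capacity` (default 1e5 1/s). The reference (`capacity = 0`)
#' yield is the configured rate. This law is a modeling choice for test
#' generation; it is monotone and saturating, which is all the downstream
#' analysis assumes.
#'
#' @param plasmid A [plasmid_spec()].
#' @param g_ssb,g_dsb Assay-level SSB and DSB yields, events/Mbp/Gy.
#' @param g_base_purine,g_base_pyrimidine Net base-lesion yields by class
#'   (Fpg reveals purine lesions, Nth pyrimidine lesions), events/Mbp/Gy.
#' @param g_cluster Non-DSB clustered lesion yield, events/Mbp/Gy. Must not
#'   exceed `g_ssb`.
#' @param indirect_fraction Scavengeable fraction of each yield, in [0, 1].
#' @param half_capacity Capacity at which the indirect component is halved,
#'   1/s.
#' @param cluster_window_bp Opposed-lesion capture gap in bp (default 10).
#' @param doses Dose panel in Gy.
#' @param n_molecules Molecules per simulated lane.
#' @param noise_cv Per-band lognormal intensity coefficient of variation.
#' @param sc_dye_factor Relative dye yield of the supercoiled band.
#' @return A `sim_config` object (list).
#' @examples
#' cfg <- sim_config(n_molecules = 500)
#' @export
sim_config <- function(plasmid = pbr322(),
                       g_ssb = 101.101,
                       g_dsb = 1.914,
                       g_base_purine = 137.926,
                       g_base_pyrimidine = 137.926,
                       g_cluster = 10.908,
                       indirect_fraction = 0.9,
                       half_capacity = 1e5,
                       cluster_window_bp = 10L,
                       doses = c(0, 1, 2, 4, 8, 10, 15, 20, 30, 50),
                       n_molecules = 2000L,
                       noise_cv = 0.05,
                       sc_dye_factor = 1) {
  stopifnot(inherits(plasmid, "plasmid_spec"))
  rates <- c(g_ssb, g_dsb, g_base_purine, g_base_pyrimidine, g_cluster)
  if (any(rates < 0)) stop("all yields must be >= 0", call. = FALSE)
  if (g_cluster > g_ssb) {
    stop("`g_cluster` cannot exceed `g_ssb` (each cluster carries one SSB)",
         call. = FALSE)
  }
  if (indirect_fraction < 0 || indirect_fraction > 1) {
    stop("`indirect_fraction` must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      plasmid = plasmid, g_ssb = g_ssb, g_dsb = g_dsb,
      g_base_purine = g_base_purine, g_base_pyrimidine = g_base_pyrimidine,
      g_cluster = g_cluster, indirect_fraction = indirect_fraction,
      half_capacity = half_capacity,
      cluster_window_bp = as.integer(cluster_window_bp),
      doses = doses, n_molecules = as.integer(n_molecules),
      noise_cv = noise_cv, sc_dye_factor = sc_dye_factor
    ),
    class = "sim_config"
  )
}

#' Scavenger attenuation factor of the simulator competition law
#'
#' @param cfg A [sim_config()].
#' @param scavenger A [scavenger_condition()] or `NULL` (capacity 0, no
#'   attenuation).
#' @return Multiplier in (0, 1].
#' @export
scavenging_factor <- function(cfg, scavenger = NULL) {
  cap <- if (is.null(scavenger)) 0 else scavenger$capacity
  phi <- cfg$indirect_fraction
  (1 - phi) + phi * cfg$half_capacity / (cfg$half_capacity + cap)
}

#' Simulate a population of damaged plasmid molecules
#'
#' Draws per-molecule lesion counts as Poisson with mean
#' `G_eff * dose * length_bp / 1e6` per channel, with lesion positions
#' uniform on the circular map (0-based bp coordinates) and strands assigned
#' at random. Clustered lesions are planted as a strand break plus an
#' opposed base lesion offset uniformly within the cluster window.
#'
#' @param cfg A [sim_config()].
#' @param dose_gy Dose in Gy (>= 0).
#' @param scavenger A [scavenger_condition()] or `NULL`.
#' @param n Number of molecules.
#' @param seed Optional RNG seed for bitwise reproducibility.
#' @return A `plasmid_population`: list with `molecules` (tibble: `molecule`,
#'   `n_ssb`, `n_dsb`, `n_base_purine`, `n_base_pyrimidine`), `lesions`
#'   (tibble: `molecule`, `kind` in ssb/dsb/base, `pos`, `strand`,
#'   `base_class`, `new`), the `spec`, `cluster_window_bp`, `dose_gy`,
#'   `enzyme` ("none") and `n`.
#' @export
simulate_population <- function(cfg, dose_gy, scavenger = NULL,
                                n = cfg$n_molecules, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (dose_gy < 0) stop("`dose_gy` must be >= 0", call. = FALSE)
  run <- function() {
    s <- scavenging_factor(cfg, scavenger)
    spec <- cfg$plasmid
    L <- spec$length_bp
    pfb <- cfg$g_base_purine + cfg$g_base_pyrimidine
    pf <- if (pfb > 0) cfg$g_base_purine / pfb else 0.5
    # assay-level -> internal planted rates (events per plasmid per Gy)
    r <- function(g) s * per_plasmid(g, spec) * dose_gy
    mean_ssb_iso <- r(cfg$g_ssb - cfg$g_cluster)
    mean_dsb <- r(cfg$g_dsb)
    mean_cl_pur <- r(cfg$g_cluster * pf)
    mean_cl_pyr <- r(cfg$g_cluster * (1 - pf))
    mean_bp_iso <- r(cfg$g_base_purine + cfg$g_cluster * pf)
    mean_bq_iso <- r(cfg$g_base_pyrimidine + cfg$g_cluster * (1 - pf))

    k_ssb <- stats::rpois(n, mean_ssb_iso)
    k_dsb <- stats::rpois(n, mean_dsb)
    k_bp <- stats::rpois(n, mean_bp_iso)
    k_bq <- stats::rpois(n, mean_bq_iso)
    k_cp <- stats::rpois(n, mean_cl_pur)
    k_cq <- stats::rpois(n, mean_cl_pyr)

    ids <- seq_len(n)
    mk_simple <- function(counts, what, base_class = NA_character_) {
      tot <- sum(counts)
      if (tot == 0L) return(NULL)
      strand <- if (what == "dsb") rep.int(NA_integer_, tot) else
        sample.int(2L, tot, replace = TRUE) - 1L
      tibble::new_tibble(list(
        molecule = rep.int(ids, counts),
        kind = rep.int(what, tot),
        pos = sample.int(L, tot, replace = TRUE) - 1L,
        strand = strand,
        base_class = rep.int(base_class, tot)
      ), nrow = tot)
    }
    mk_cluster <- function(counts, base_class) {
      tot <- sum(counts)
      if (tot == 0L) return(NULL)
      mol <- rep.int(ids, counts)
      p <- sample.int(L, tot, replace = TRUE) - 1L
      s0 <- sample.int(2L, tot, replace = TRUE) - 1L
      h <- cfg$cluster_window_bp
      off <- sample.int(2L * h + 1L, tot, replace = TRUE) - h - 1L
      p2 <- (p + off) %% L
      dplyr::bind_rows(
        tibble::new_tibble(list(
          molecule = mol, kind = rep.int("ssb", tot), pos = p, strand = s0,
          base_class = rep.int(NA_character_, tot)), nrow = tot),
        tibble::new_tibble(list(
          molecule = mol, kind = rep.int("base", tot), pos = p2,
          strand = 1L - s0, base_class = rep.int(base_class, tot)),
          nrow = tot)
      )
    }
    lesions <- dplyr::bind_rows(
      mk_simple(k_ssb, "ssb"),
      mk_simple(k_dsb, "dsb"),
      mk_simple(k_bp, "base", "purine"),
      mk_simple(k_bq, "base", "pyrimidine"),
      mk_cluster(k_cp, "purine"),
      mk_cluster(k_cq, "pyrimidine")
    )
    if (is.null(lesions) || ncol(lesions) == 0L) {
      lesions <- tibble::tibble(
        molecule = integer(), kind = character(), pos = integer(),
        strand = integer(), base_class = character()
      )
    }
    lesions$new <- FALSE
    molecules <- tibble::tibble(
      molecule = ids,
      n_ssb = k_ssb + k_cp + k_cq,
      n_dsb = k_dsb,
      n_base_purine = k_bp + k_cp,
      n_base_pyrimidine = k_bq + k_cq
    )
    structure(
      list(
        molecules = molecules, lesions = lesions, spec = spec,
        cluster_window_bp = cfg$cluster_window_bp, dose_gy = dose_gy,
        enzyme = "none", n = n
      ),
      class = "plasmid_population"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.plasmid_population <- function(x, ...) {
  cat(sprintf(
    "<plasmid_population> %d molecules of %s at %.3g Gy (enzyme: %s)\n",
    x$n, x$spec$name, x$dose_gy, x$enzyme
  ))
  cat(sprintf(
    "  mean SSB %.3f, DSB %.3f, base lesions %.3f per molecule\n",
    mean(x$molecules$n_ssb), mean(x$molecules$n_dsb),
    mean(x$molecules$n_base_purine + x$molecules$n_base_pyrimidine)
  ))
  invisible(x)
}

# Minimal circular distance between bp positions on a plasmid of L bp.
circ_dist <- function(p1, p2, L) {
  d <- abs(p1 - p2)
  pmin(d, L - d)
}

# Greedy conversion of opposed SSB pairs within `window` bp into DSBs.
# Pairs are converted shortest-distance first (ties: lowest position).
# When `require_new` is TRUE only pairs involving at least one `new` SSB
# (enzyme-created) are eligible. Returns the modified population.
convert_opposed_pairs <- function(pop, window, require_new) {
  les <- pop$lesions
  is_ssb <- les$kind == "ssb"
  if (!any(is_ssb) || is.null(window)) return(pop)
  L <- pop$spec$length_bp
  ss <- les[is_ssb, ]
  ord <- order(ss$molecule, ss$pos)
  m <- ss$molecule[ord]; p <- ss$pos[ord]; s <- ss$strand[ord]
  k <- length(m)
  if (k < 2L) return(pop)
  # any opposed pair within the window implies an opposed *adjacent* pair
  # (in circular sorted order) within the window, so adjacency gates the
  # exact per-molecule pass
  same <- m[-1L] == m[-k]
  adj <- same & (s[-1L] != s[-k]) & (p[-1L] - p[-k] <= window)
  cand <- unique(m[-k][adj])
  first <- !duplicated(m); last <- !duplicated(m, fromLast = TRUE)
  multi <- m[first][m[first] %in% m[last][last & !first]] # molecules with >=2
  fm <- m[first]; lm <- m[last]
  both <- intersect(fm, lm)
  fp <- p[first][match(both, fm)]; lp <- p[last][match(both, lm)]
  fs <- s[first][match(both, fm)]; ls <- s[last][match(both, lm)]
  wrap_ok <- (fs != ls) & ((L - (lp - fp)) <= window) & (lp != fp)
  cand <- union(cand, both[wrap_ok])
  if (require_new) {
    has_new <- unique(ss$molecule[ss$new])
    cand <- intersect(cand, has_new)
  }
  if (length(cand) == 0L) return(pop)

  ssb_idx_all <- which(is_ssb)
  mol_of <- les$molecule[ssb_idx_all]
  keep_rows <- mol_of %in% cand
  grp <- split(ssb_idx_all[keep_rows], mol_of[keep_rows])
  drop_list <- vector("list", length(grp))
  made_mol <- vector("list", length(grp))
  made_pos <- vector("list", length(grp))
  pos_v <- les$pos; str_v <- les$strand; new_v <- les$new
  for (ci in seq_along(grp)) {
    rows <- grp[[ci]]
    alive <- rep(TRUE, length(rows))
    made <- integer(0)
    dropped <- integer(0)
    repeat {
      a <- rows[alive]
      if (length(a) < 2L) break
      pp <- pos_v[a]; st <- str_v[a]; nw <- new_v[a]
      na <- length(a)
      i1 <- rep.int(seq_len(na - 1L), (na - 1L):1L)
      i2 <- sequence((na - 1L):1L) + i1
      dd <- circ_dist(pp[i1], pp[i2], L)
      ok <- st[i1] != st[i2] & dd <= window
      if (require_new) ok <- ok & (nw[i1] | nw[i2])
      if (!any(ok)) break
      dd[!ok] <- Inf
      best <- which.min(dd + pmin(pp[i1], pp[i2]) / (L * 10)) # tie: lowest pos
      r1 <- a[i1[best]]; r2 <- a[i2[best]]
      made <- c(made, min(pos_v[r1], pos_v[r2]))
      alive[match(c(r1, r2), rows)] <- FALSE
      dropped <- c(dropped, r1, r2)
    }
    drop_list[[ci]] <- dropped
    if (length(made)) {
      made_mol[[ci]] <- rep.int(les$molecule[rows[1L]], length(made))
      made_pos[[ci]] <- made
    }
  }
  drop_rows <- unlist(drop_list)
  mm <- unlist(made_mol)
  if (length(drop_rows)) {
    add <- tibble::new_tibble(list(
      molecule = mm, kind = rep.int("dsb", length(mm)),
      pos = unlist(made_pos), strand = rep.int(NA_integer_, length(mm)),
      base_class = rep.int(NA_character_, length(mm)),
      new = rep.int(TRUE, length(mm))
    ), nrow = length(mm))
    conv <- tabulate(les$molecule[drop_rows], nbins = pop$n) %/% 2L
    les <- les[-drop_rows, ]
    pop$molecules$n_ssb <- pop$molecules$n_ssb - 2L * conv
    pop$molecules$n_dsb <- pop$molecules$n_dsb + conv
    pop$lesions <- dplyr::bind_rows(les, add)
  }
  pop
}

#' Apply a base-excision enzyme to a simulated population
#'
#' Fpg cleaves at oxidized purines and Nth at oxidized pyrimidines; with
#' their lyase activity each lesion of the matching class becomes an SSB at
#' its position. Newly created breaks that end up opposite another break
#' within the cluster window fuse into a DSB — this is how non-DSB clustered
#' lesions surface as excess DSB in the assay. Break counts never decrease
#' under enzyme action (two SSBs fusing yields one DSB, i.e. breaks are
#' conserved or converted upward in severity).
#'
#' @param pop A `plasmid_population`.
#' @param enzyme `"fpg"` or `"nth"`.
#' @param cluster_window_bp Opposed-break fusion gap; defaults to the
#'   population's configured window.
#' @return The modified `plasmid_population` (lesions and counts updated,
#'   `enzyme` recorded).
#' @export
apply_enzyme <- function(pop, enzyme = c("fpg", "nth"),
                         cluster_window_bp = pop$cluster_window_bp) {
  enzyme <- match.arg(enzyme)
  stopifnot(inherits(pop, "plasmid_population"))
  cls <- if (enzyme == "fpg") "purine" else "pyrimidine"
  les <- pop$lesions
  hit <- les$kind == "base" & les$base_class == cls
  if (any(hit)) {
    les$kind[hit] <- "ssb"
    les$new[hit] <- TRUE
    conv <- tabulate(les$molecule[hit], nbins = pop$n)
    pop$molecules$n_ssb <- pop$molecules$n_ssb + conv
    if (cls == "purine") {
      pop$molecules$n_base_purine <- pop$molecules$n_base_purine - conv
    } else {
      pop$molecules$n_base_pyrimidine <- pop$molecules$n_base_pyrimidine - conv
    }
    pop$lesions <- les
  }
  pop <- convert_opposed_pairs(pop, cluster_window_bp, require_new = TRUE)
  pop$enzyme <- enzyme
  pop
}

#' Classify each molecule into its electrophoretic form
#'
#' Supercoiled (no breaks), circular (>= 1 SSB, no DSB), linear (exactly one
#' DSB) or fragmented (>= 2 DSBs; `m` cuts of a circle give `m` fragments).
#' Base lesions are invisible to topology. Optionally, opposed prompt SSBs
#' within the cluster window are fused into DSBs before classification
#' (`convert_opposed = TRUE`); the default leaves prompt breaks as drawn,
#' matching the plain Poisson topology model and its closed-form inversion.
#'
#' @param pop A `plasmid_population`.
#' @param convert_opposed Fuse opposed prompt SSB pairs before classifying.
#' @param cluster_window_bp Fusion gap when `convert_opposed = TRUE`.
#' @return A factor of length `pop$n` with levels `SC`, `C`, `L`, `F`.
#' @export
classify_topology <- function(pop, convert_opposed = FALSE,
                              cluster_window_bp = pop$cluster_window_bp) {
  stopifnot(inherits(pop, "plasmid_population"))
  if (convert_opposed) {
    pop <- convert_opposed_pairs(pop, cluster_window_bp, require_new = FALSE)
  }
  ns <- pop$molecules$n_ssb
  nd <- pop$molecules$n_dsb
  code <- 1L + (ns >= 1L & nd == 0L) + 2L * (nd == 1L) + 3L * (nd >= 2L)
  factor(c("SC", "C", "L", "F")[code], levels = c("SC", "C", "L", "F"))
}

#' Fragment lengths of each molecule
#'
#' Cuts the circular map at every DSB position; arc lengths in bp times the
#' per-bp rise give apparent fragment lengths in nm. Lengths per molecule
#' always sum to the full contour. Molecules without a DSB (supercoiled or
#' relaxed circles) contribute their full contour; a single DSB linearizes
#' the molecule into one full-length fragment.
#'
#' @param pop A `plasmid_population`.
#' @param spec A [plasmid_spec()]; defaults to the population's.
#' @return A tibble with `molecule`, `n_dsb` and `length_nm` (one row per
#'   fragment).
#' @export
fragment_lengths <- function(pop, spec = pop$spec) {
  stopifnot(inherits(pop, "plasmid_population"))
  L <- spec$length_bp
  dsb <- pop$lesions[pop$lesions$kind == "dsb", ]
  cut_mols <- pop$molecules$molecule[pop$molecules$n_dsb > 0L]
  uncut <- pop$molecules$molecule[pop$molecules$n_dsb == 0L]
  out_uncut <- tibble::tibble(
    molecule = uncut, n_dsb = 0L,
    length_nm = rep.int(spec$contour_nm, length(uncut))
  )
  if (nrow(dsb) == 0L) return(out_uncut)
  ord <- order(dsb$molecule, dsb$pos)
  m <- dsb$molecule[ord]; p <- dsb$pos[ord]
  k <- length(m)
  first <- !duplicated(m)
  last <- !duplicated(m, fromLast = TRUE)
  arc <- integer(k)
  if (k > 1L) {
    same <- m[-1L] == m[-k]
    arc[which(same)] <- p[-1L][same] - p[-k][same]
  }
  fp <- p[first][match(m[last], m[first])]
  arc[last] <- L - (p[last] - fp)
  counts <- tabulate(factor(m, levels = unique(m)))
  out_cut <- tibble::tibble(
    molecule = m, n_dsb = rep.int(counts, counts),
    length_nm = arc * spec$bp_nm
  )
  dplyr::bind_rows(out_cut, out_uncut)
}

#' Simulate the gel readout of a population
#'
#' Classifies the population, forms band intensities proportional to the
#' molecule counts of the full-length forms (supercoiled intensity scaled by
#' the dye factor), applies multiplicative lognormal densitometry noise of
#' the given coefficient of variation, and renormalizes over the detected
#' SC/C/L bands — the fragment smear is not countable, as in the real assay.
#'
#' @param pop A `plasmid_population`.
#' @param noise_cv Band intensity coefficient of variation (lognormal,
#'   mean 1).
#' @param sc_dye_factor Relative dye yield of the supercoiled band.
#' @param convert_opposed Passed to [classify_topology()].
#' @param seed Optional RNG seed.
#' @return One-row tibble: `dose_gy`, `enzyme`, `n_sc`, `n_c`, `n_l`, `n_f`,
#'   `i_sc`, `i_c`, `i_l`, `f_sc`, `f_c`, `f_l`, `degenerate`.
#' @export
gel_lane <- function(pop, noise_cv = 0.05, sc_dye_factor = 1,
                     convert_opposed = FALSE, seed = NULL) {
  run <- function() {
    form <- classify_topology(pop, convert_opposed = convert_opposed)
    cnt <- as.integer(table(form))
    names(cnt) <- levels(form)
    sdlog <- sqrt(log(1 + noise_cv^2))
    eta <- if (noise_cv > 0) {
      stats::rlnorm(3, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else rep(1, 3)
    i <- c(cnt[["SC"]] * sc_dye_factor, cnt[["C"]], cnt[["L"]]) * eta
    full <- sum(i)
    degenerate <- cnt[["SC"]] + cnt[["C"]] + cnt[["L"]] == 0L
    if (degenerate) {
      warning("degenerate lane: no full-length molecules detected",
              call. = FALSE)
    }
    tibble::tibble(
      dose_gy = pop$dose_gy, enzyme = pop$enzyme,
      n_sc = cnt[["SC"]], n_c = cnt[["C"]], n_l = cnt[["L"]],
      n_f = cnt[["F"]],
      i_sc = i[1], i_c = i[2], i_l = i[3],
      f_sc = if (degenerate) NA_real_ else i[1] / full,
      f_c = if (degenerate) NA_real_ else i[2] / full,
      f_l = if (degenerate) NA_real_ else i[3] / full,
      degenerate = degenerate
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a full lane table for one irradiation condition
#'
#' Generates independent populations for every dose, enzyme treatment and
#' replicate, and returns the raw band-intensity table in the same schema
#' the real-data reader produces, ready for [quantify_lanes()] or
#' [damage_yields()]. Ground truth (the configured assay-level yields and
#' the per-lane populations' mean break counts) is attached as the
#' `"truth"` attribute.
#'
#' @param cfg A [sim_config()].
#' @param scavenger A [scavenger_condition()] or `NULL`.
#' @param enzymes Treatments to simulate (subset of none/fpg/nth).
#' @param doses Dose panel in Gy; defaults to the configuration's.
#' @param enzyme_doses Optional named list giving a different dose panel for
#'   specific enzymes (e.g. a shorter panel for enzyme-treated series, whose
#'   supercoiled band saturates at roughly a third of the untreated dose).
#' @param replicates Number of independent replicates per dose and enzyme.
#' @param n Molecules per lane.
#' @param condition_id,position Metadata columns carried into the table.
#' @param seed Optional RNG seed (one seed reproduces the whole table).
#' @return A tibble with columns `condition_id`, `position`, `enzyme`,
#'   `dose_gy`, `replicate`, `i_sc`, `i_c`, `i_l` plus the lane counts, and
#'   attributes `noise_cv`, `n_molecules`, `truth`.
#' @export
simulate_lane_table <- function(cfg, scavenger = NULL,
                                enzymes = c("none", "fpg", "nth"),
                                doses = cfg$doses, enzyme_doses = NULL,
                                replicates = 3L,
                                n = cfg$n_molecules,
                                condition_id = "sim", position = NA_character_,
                                seed = NULL) {
  stopifnot(all(enzymes %in% c("none", "fpg", "nth")))
  run <- function() {
    grid <- dplyr::bind_rows(lapply(enzymes, function(enz) {
      d <- if (!is.null(enzyme_doses) && enz %in% names(enzyme_doses)) {
        enzyme_doses[[enz]]
      } else doses
      expand.grid(
        replicate = seq_len(replicates), dose_gy = sort(d),
        enzyme = enz, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
      )
    }))
    rows <- purrr::pmap(grid, function(replicate, dose_gy, enzyme) {
      pop <- simulate_population(cfg, dose_gy, scavenger = scavenger, n = n)
      if (enzyme != "none") pop <- apply_enzyme(pop, enzyme)
      lane <- gel_lane(pop, noise_cv = cfg$noise_cv,
                       sc_dye_factor = cfg$sc_dye_factor)
      lane$replicate <- replicate
      lane$true_mean_ssb <- mean(pop$molecules$n_ssb)
      lane$true_mean_dsb <- mean(pop$molecules$n_dsb)
      lane
    })
    out <- dplyr::bind_rows(rows)
    out$condition_id <- condition_id
    out$position <- position
    out <- out[, c("condition_id", "position", "enzyme", "dose_gy",
                   "replicate", "i_sc", "i_c", "i_l", "n_sc", "n_c", "n_l",
                   "n_f", "f_sc", "f_c", "f_l", "degenerate",
                   "true_mean_ssb", "true_mean_dsb")]
    attr(out, "noise_cv") <- cfg$noise_cv
    attr(out, "n_molecules") <- n
    attr(out, "truth") <- tibble::tibble(
      metric = c("ssb", "dsb", "base_lesions", "non_dsb_clusters"),
      g_value = scavenging_factor(cfg, scavenger) *
        c(cfg$g_ssb, cfg$g_dsb, cfg$g_base_purine + cfg$g_base_pyrimidine,
          cfg$g_cluster)
    )
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
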