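# Monte Carlo generator: lesion placement, topology classification, enzyme
# action, fragmentation and the gel readout.

test_that("zero dose leaves every molecule lesion-free and supercoiled", {
  cfg <- sim_config(n_molecules = 200)
  pop <- simulate_population(cfg, 0, seed = 1)
  expect_equal(nrow(pop$lesions), 0L)
  expect_true(all(pop$molecules$n_ssb == 0))
  expect_true(all(classify_topology(pop) == "SC"))
})

test_that("classification follows the break-count rules", {
  les <- tibble::tibble(
    molecule = c(2L, 2L, 2L, 3L, 4L, 4L, 5L),
    kind = c("ssb", "ssb", "ssb", "dsb", "dsb", "dsb", "base"),
    pos = c(100L, 900L, 2000L, 50L, 10L, 2180L, 700L),
    strand = c(0L, 0L, 1L, NA, NA, NA, 0L),
    base_class = c(NA, NA, NA, NA, NA, NA, "purine")
  )
  pop <- make_population(les, n = 5L)
  form <- classify_topology(pop)
  expect_equal(as.character(form),
               c("SC", "C", "L", "F", "SC")) # base lesion alone stays SC
})

test_that("opposed prompt SSBs fuse only when conversion is enabled", {
  les <- tibble::tibble(
    molecule = c(1L, 1L), kind = "ssb", pos = c(100L, 104L),
    strand = c(0L, 1L), base_class = NA_character_
  )
  pop <- make_population(les, n = 1L)
  expect_equal(as.character(classify_topology(pop)), "C")
  expect_equal(as.character(classify_topology(pop, convert_opposed = TRUE)),
               "L")
})

test_that("enzyme action converts matching lesions and opposed pairs", {
  les <- tibble::tibble(
    molecule = c(1L, 1L), kind = c("base", "ssb"), pos = c(100L, 104L),
    strand = c(0L, 1L), base_class = c("purine", NA)
  )
  pop <- make_population(les, n = 1L)
  fpg <- apply_enzyme(pop, "fpg")
  expect_equal(fpg$molecules$n_ssb, 0L)
  expect_equal(fpg$molecules$n_dsb, 1L)
  # the non-matching enzyme leaves the map identical
  nth <- apply_enzyme(pop, "nth")
  expect_equal(nth$molecules$n_ssb, 1L)
  expect_equal(nth$molecules$n_dsb, 0L)
  expect_equal(nth$molecules$n_base_purine, 1L)
})

test_that("pair conversion matches an independent brute-force oracle", {
  set.seed(42)
  L <- 500L; window <- 10L
  for (trial in 1:40) {
    k <- sample(2:8, 1)
    les <- tibble::tibble(
      molecule = rep(1L, k), kind = "ssb",
      pos = sample.int(L, k, replace = TRUE) - 1L,
      strand = sample(0:1, k, replace = TRUE),
      base_class = NA_character_,
      new = sample(c(TRUE, FALSE), k, replace = TRUE)
    )
    pop <- make_population(les, n = 1L, window = window)
    pop$spec <- plasmid_spec("mini", L)
    conv <- radbreaks:::convert_opposed_pairs(pop, window, require_new = TRUE)
    expected <- brute_opposed_pairs(les$pos, les$strand, les$new, L, window,
                                    require_new = TRUE)
    expect_equal(conv$molecules$n_dsb, expected,
                 info = paste("trial", trial))
    expect_equal(conv$molecules$n_ssb, k - 2L * expected)
  }
})

test_that("population-level enzyme excess matches the opposed-pair rate", {
  # analytic expectation for independently placed breaks:
  # (n^2 + 2 n p) (2h+1) / (4L) with n new and p prompt breaks per molecule
  cfg <- sim_config(g_ssb = 1.5 / 0.004361, g_dsb = 0,
                    g_base_purine = 2 / 0.004361, g_base_pyrimidine = 0,
                    g_cluster = 0, n_molecules = 1)
  pop <- simulate_population(cfg, 1, n = 150000, seed = 11)
  after <- apply_enzyme(pop, "fpg")
  excess <- mean(after$molecules$n_dsb)
  analytic <- (2^2 + 2 * 2 * 1.5) * 21 / (4 * 4361)
  expect_lt(abs(excess - analytic), 3 * sqrt(analytic / 150000) + 0.05 * analytic)
})

test_that("enzyme action never decreases break counts", {
  cfg <- sim_config(n_molecules = 2000)
  pop <- simulate_population(cfg, 6, seed = 9)
  for (enz in c("fpg", "nth")) {
    after <- apply_enzyme(pop, enz)
    breaks_before <- pop$molecules$n_ssb + 2L * pop$molecules$n_dsb
    breaks_after <- after$molecules$n_ssb + 2L * after$molecules$n_dsb
    expect_true(all(breaks_after >= breaks_before))
    expect_true(all(after$molecules$n_dsb >= pop$molecules$n_dsb))
  }
})

test_that("fragment lengths conserve the full contour", {
  cfg <- sim_config(g_ssb = 200, g_dsb = 300, g_base_purine = 0,
                    g_base_pyrimidine = 0, g_cluster = 0, n_molecules = 400)
  pop <- simulate_population(cfg, 2, seed = 7)
  fl <- fragment_lengths(pop)
  tot <- tapply(fl$length_nm, fl$molecule, sum)
  expect_lt(max(abs(tot - pbr322()$contour_nm)), 1e-9)
  # m cuts of a circle give m fragments; uncut molecules one full contour
  n_frag <- table(fl$molecule)
  n_dsb <- tapply(fl$n_dsb, fl$molecule, max)
  expect_true(all(as.integer(n_frag) == pmax(n_dsb, 1)))
  # two cuts at bp 0 and 2180 split 1482.74 nm into 741.2 + 741.54
  les <- tibble::tibble(molecule = c(1L, 1L), kind = "dsb",
                        pos = c(0L, 2180L), strand = NA_integer_,
                        base_class = NA_character_)
  fl2 <- fragment_lengths(make_population(les, n = 1L))
  expect_equal(sort(fl2$length_nm), c(741.2, 741.54), tolerance = 1e-6)
})

test_that("noiseless gel lanes reproduce exact class proportions", {
  cfg <- sim_config(n_molecules = 3000)
  pop <- simulate_population(cfg, 4, seed = 13)
  lane <- gel_lane(pop, noise_cv = 0, sc_dye_factor = 1)
  form <- classify_topology(pop)
  full <- sum(form != "F")
  expect_equal(lane$f_sc, sum(form == "SC") / full)
  expect_equal(lane$f_c, sum(form == "C") / full)
  expect_equal(lane$f_l, sum(form == "L") / full)
  expect_false(lane$degenerate)
})

test_that("a lane of only fragments is flagged degenerate", {
  les <- tibble::tibble(molecule = c(1L, 1L, 2L, 2L), kind = "dsb",
                        pos = c(1L, 100L, 5L, 900L), strand = NA_integer_,
                        base_class = NA_character_)
  pop <- make_population(les, n = 2L)
  expect_warning(lane <- gel_lane(pop, noise_cv = 0), "degenerate")
  expect_true(lane$degenerate)
  expect_true(is.na(lane$f_sc))
})

test_that("gel fraction estimates are unbiased under band noise", {
  cfg <- sim_config(n_molecules = 1500)
  pop <- simulate_population(cfg, 4, seed = 17)
  form <- classify_topology(pop)
  truth <- prop.table(table(form)[c("SC", "C", "L")])
  lanes <- withr::with_seed(99, dplyr::bind_rows(
    lapply(1:300, function(i) gel_lane(pop, noise_cv = 0.05))
  ))
  for (col in c("f_sc", "f_c", "f_l")) {
    tr <- truth[[c(f_sc = "SC", f_c = "C", f_l = "L")[[col]]]]
    se <- stats::sd(lanes[[col]]) / sqrt(nrow(lanes))
    expect_lt(abs(mean(lanes[[col]]) - tr), 3 * se + 1e-4)
  }
})

test_that("generation is bitwise reproducible from the seed", {
  cfg <- sim_config(n_molecules = 300)
  p1 <- simulate_population(cfg, 5, seed = 123)
  p2 <- simulate_population(cfg, 5, seed = 123)
  expect_identical(p1$lesions, p2$lesions)
  t1 <- simulate_lane_table(cfg, doses = c(0, 2, 4), replicates = 2,
                            seed = 5)
  t2 <- simulate_lane_table(cfg, doses = c(0, 2, 4), replicates = 2,
                            seed = 5)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
})

test_that("scavenging reduces yields toward the direct fraction", {
  cfg <- sim_config(n_molecules = 20000, indirect_fraction = 0.9)
  ref <- simulate_population(cfg, 10, n = 20000, seed = 31)
  strong <- simulate_population(
    cfg, 10, scavenger = scavenger_condition("c3ca", capacity = 1e12),
    n = 20000, seed = 32
  )
  ratio <- mean(strong$molecules$n_ssb) / mean(ref$molecules$n_ssb)
  # capacity -> infinity leaves ~10% of the reference yield
  expect_lt(abs(ratio - 0.1), 0.02)
})
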