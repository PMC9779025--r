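# Scavenging-capacity arithmetic and the capacity-yield summaries.

test_that("capacity is the k x S product and inverts exactly", {
  expect_equal(scavenging_capacity(1.5e9, 0), 0)
  expect_equal(scavenging_capacity(6.8e9, 1.4706e-2), 1e8, tolerance = 1e-4)
  expect_equal(scavenging_capacity(1.5e9, 6.6667e-2), 1e8, tolerance = 1e-4)
  expect_equal(concentration_for_capacity(1.5e9, 1e6), 6.667e-4,
               tolerance = 1e-4)
  expect_equal(concentration_for_capacity(6.8e9, 0), 0)
  # bilinear round trip at random positive values
  set.seed(3)
  k <- runif(20, 1e8, 1e10); s <- runif(20, 1e-6, 1e-1)
  expect_equal(concentration_for_capacity(k, scavenging_capacity(k, s)), s,
               tolerance = 1e-12)
  expect_error(scavenging_capacity(-1, 1), "positive")
  expect_error(concentration_for_capacity(0, 1), "positive")
})

test_that("scavenger conditions resolve concentration and capacity", {
  sv <- scavenger_condition("c3ca", capacity = 1e8)
  expect_equal(sv$k, 6.8e9)
  expect_equal(sv$capacity, 1e8)
  expect_equal(scavenging_capacity(sv$k, sv$concentration), 1e8,
               tolerance = 1e-9)
  none <- scavenger_condition("none")
  expect_equal(none$capacity, 1e5)
  expect_error(scavenger_condition("tris"), "exactly one")
  expect_error(scavenger_condition("tris", concentration = 1e-3,
                                   capacity = 1e6), "exactly one")
  expect_error(scavenger_condition("mystery", capacity = 1), "unknown")
})

test_that("protection table reduces against the reference capacity", {
  y <- tibble::tibble(
    capacity_s = rep(c(1e5, 1e6, 1e8), 2),
    metric = rep(c("ssb", "dsb"), each = 3),
    g_value = c(100, 60, 2, 10, 7, 1)
  )
  p <- protection_table(y)
  expect_equal(p$reduction_pct[p$metric == "ssb" & p$capacity_s == 1e8], 98)
  expect_equal(p$reduction_pct[p$metric == "ssb" & p$capacity_s == 1e6], 40)
  expect_true(all(p$monotonic))
  # reference-only input gives no reduction rows
  p0 <- protection_table(y[y$capacity_s == 1e5, ])
  expect_equal(nrow(p0), 0L)
  # missing reference errors
  expect_error(protection_table(y[y$capacity_s != 1e5, ],
                                reference_capacity = 1e5), "reference")
})

test_that("protection reductions are invariant to common yield rescaling", {
  y <- tibble::tibble(capacity_s = c(1e5, 1e6, 1e7), metric = "ssb",
                      g_value = c(80, 40, 10))
  p1 <- protection_table(y)
  y2 <- y; y2$g_value <- y2$g_value * 3.7
  p2 <- protection_table(y2)
  expect_equal(p1$reduction_pct, p2$reduction_pct)
})

test_that("non-monotonic capacity responses are flagged", {
  y <- tibble::tibble(capacity_s = c(1e5, 1e6, 1e7), metric = "dsb",
                      g_value = c(10, 2, 5))
  expect_warning(p <- protection_table(y), "non-monotonic")
  expect_false(all(p$monotonic))
})

test_that("simulator yields decrease with capacity under the competition law", {
  cfg <- sim_config(n_molecules = 1000)
  caps <- c(1e5, 1e6, 1e7, 1e8)
  fac <- vapply(caps, function(cp) {
    scavenging_factor(cfg, scavenger_condition("tris", capacity = cp))
  }, 1)
  expect_true(all(diff(fac) < 0))
  # capacity -> infinity leaves the direct fraction
  expect_equal(scavenging_factor(cfg,
                                 scavenger_condition("tris", capacity = 1e15)),
               1 - cfg$indirect_fraction, tolerance = 1e-6)
  expect_equal(scavenging_factor(cfg, NULL), 1)
})
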