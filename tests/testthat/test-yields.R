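# G-value fitting, enzyme differences and the summary statistics.

test_that("fit_g_value recovers exact linear data with zero error", {
  fit <- fit_g_value(data.frame(dose_gy = c(0, 1, 2),
                                events_per_mbp = c(0, 101.1, 202.2)))
  expect_equal(fit$g_value, 101.1)
  expect_equal(fit$sem, 0, tolerance = 1e-10)
  # all-zero response
  fit0 <- fit_g_value(data.frame(dose_gy = c(0, 1, 2, 4),
                                 events_per_mbp = rep(0, 4)))
  expect_equal(fit0$g_value, 0)
})

test_that("fit_g_value rejects insufficient designs", {
  expect_error(fit_g_value(data.frame(dose_gy = c(0, 1),
                                      events_per_mbp = c(0, 1))),
               "insufficient")
  expect_error(fit_g_value(data.frame(dose_gy = c(2, 2, 2),
                                      events_per_mbp = c(1, 2, 3))),
               "insufficient")
})

test_that("fit_g_value is invariant to reordering and scales linearly", {
  set.seed(11)
  d <- data.frame(dose_gy = rep(c(0, 1, 2, 4, 8), each = 3))
  d$events_per_mbp <- 5 * d$dose_gy + rnorm(nrow(d), 0, 0.5)
  f1 <- fit_g_value(d)
  f2 <- fit_g_value(d[sample(nrow(d)), ])
  expect_equal(f1$g_value, f2$g_value)
  expect_equal(f1$sem, f2$sem)
  d3 <- d; d3$events_per_mbp <- 10 * d3$events_per_mbp
  f3 <- fit_g_value(d3)
  expect_equal(f3$g_value, 10 * f1$g_value)
  expect_equal(f3$sem, 10 * f1$sem)
})

test_that("weighted fits report the conservative of known and residual sem", {
  set.seed(21)
  d <- data.frame(dose_gy = rep(c(0, 1, 2, 4, 8), each = 4))
  d$var_events <- (0.2 + 0.1 * d$dose_gy)^2
  d$events_per_mbp <- 3 * d$dose_gy + rnorm(nrow(d), 0, sqrt(d$var_events))
  fit <- fit_g_value(d)
  expect_true(fit$weighted)
  # known-variance bound: sem can never undercut 1/sqrt(sum w (d - dbar)^2)
  w <- 1 / d$var_events
  dbar <- sum(w * d$dose_gy) / sum(w)
  expect_gte(fit$sem, sqrt(1 / sum(w * (d$dose_gy - dbar)^2)) - 1e-12)
})

test_that("tidy and glance summarize a g_fit", {
  fit <- fit_g_value(data.frame(dose_gy = c(0, 1, 2, 4),
                                events_per_mbp = c(0.1, 1.2, 1.9, 4.2)))
  td <- tidy(fit)
  expect_equal(td$term, "g_value")
  expect_equal(td$estimate, fit$g_value)
  gl <- glance(fit)
  expect_equal(gl$n, 4L)
  expect_equal(gl$dose_max_gy, 4)
  expect_true(gl$r.squared > 0.9)
})

test_that("enzyme differences follow the summation convention", {
  g <- tibble::tibble(
    enzyme = rep(c("none", "fpg", "nth"), each = 2),
    metric = rep(c("ssb", "dsb"), 3),
    g_value = c(100, 2, 250, 5, 126, 4),
    sem = c(1, 0.1, 2, 0.2, 1.5, 0.15)
  )
  d <- enzyme_differences(g)
  expect_equal(d$g_value[d$metric == "base_lesions"], (250 - 100) + (126 - 100))
  expect_equal(d$g_value[d$metric == "non_dsb_clusters"], (5 - 2) + (4 - 2))
  # quadrature with the untreated slope entering twice
  expect_equal(d$sem[d$metric == "base_lesions"],
               sqrt(2^2 + 1.5^2 + 4 * 1^2))
  # mean convention halves both
  dm <- enzyme_differences(g, combine = "mean")
  expect_equal(dm$g_value, d$g_value / 2)
  expect_equal(dm$sem, d$sem / 2)
})

test_that("identical enzyme and untreated yields give zero differences", {
  g <- tibble::tibble(
    enzyme = rep(c("none", "fpg", "nth"), each = 2),
    metric = rep(c("ssb", "dsb"), 3),
    g_value = rep(c(100, 2), 3),
    sem = rep(c(1, 0.1), 3)
  )
  d <- enzyme_differences(g)
  expect_equal(d$g_value, c(0, 0))
  expect_false(any(d$negative))
})

test_that("negative differences are flagged, not clipped", {
  g <- tibble::tibble(
    enzyme = rep(c("none", "fpg", "nth"), each = 2),
    metric = rep(c("ssb", "dsb"), 3),
    g_value = c(100, 2, 95, 1.8, 98, 1.9), sem = rep(1, 6)
  )
  expect_warning(d <- enzyme_differences(g), "negative")
  expect_lt(d$g_value[d$metric == "base_lesions"], 0)
  expect_true(all(d$negative))
})

test_that("misaligned or incomplete yield tables are rejected", {
  g <- tibble::tibble(enzyme = c("none", "fpg"), metric = c("ssb", "ssb"),
                      g_value = c(1, 2), sem = c(0.1, 0.1))
  expect_error(enzyme_differences(g), "alignment")
})

test_that("rbe and ratios match the published summary arithmetic", {
  expect_equal(rbe(1.914, 3.147), 0.61)
  expect_equal(rbe(1.529, 3.147), 0.49)
  expect_equal(rbe(0.579, 3.147), 0.18)
  expect_equal(rbe(2.5, 2.5), 1.0)
  expect_error(rbe(1, 0), "positive")
  expect_equal(damage_ratio(14.723, 3.147, digits = 1), 4.7)
  expect_equal(damage_ratio(10.908, 1.914, digits = 1), 5.7)
  expect_equal(damage_ratio(275.852, 101.101, digits = 1), 2.7)
  expect_equal(damage_ratio(0, 5), 0)
  expect_error(damage_ratio(1, 0), "positive")
  # scale invariance
  expect_equal(rbe(3 * 1.914, 3 * 3.147), rbe(1.914, 3.147))
  expect_equal(damage_ratio(7 * 2, 7 * 4), damage_ratio(2, 4))
})

test_that("percent reduction brackets the protection range", {
  expect_equal(percent_reduction(100, 2), 98)
  expect_equal(percent_reduction(100, 45), 55)
  expect_equal(percent_reduction(100, 100), 0)
  expect_lt(percent_reduction(100, 150), 0)
  expect_error(percent_reduction(0, 1), "positive")
  expect_error(percent_reduction(10, -1), "non-negative")
})
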