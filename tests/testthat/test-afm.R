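# AFM measurement pipeline: segmentation, skeleton tracing, chain-code
# lengths, calibration and binned distributions.

test_that("segmentation finds maximal 8-connected components", {
  img0 <- afm_image(matrix(0, 64, 64))
  expect_equal(nrow(afm_segment(img0, 0.1)), 0L)
  m <- matrix(0, 64, 64)
  m[10, 5:25] <- 1          # horizontal stroke
  m[40:55, 40] <- 1         # vertical stroke
  seg <- afm_segment(afm_image(m), 0.5, min_area_px = 3)
  expect_equal(nrow(seg), 2L)
  # a diagonal chain is one component under 8-connectivity
  d <- matrix(0, 32, 32)
  for (i in 1:10) d[i, i] <- 1
  expect_equal(nrow(afm_segment(afm_image(d), 0.5, min_area_px = 2)), 1L)
  # min_area filter drops specks
  m[1, 1] <- 1
  seg2 <- afm_segment(afm_image(m), 0.5, min_area_px = 3)
  expect_equal(nrow(seg2), 2L)
})

test_that("chain code counts orthogonal and diagonal steps", {
  expect_equal(chain_code_length(cbind(1, 1:11)), 10)
  expect_equal(chain_code_length(cbind(1:11, 1:11)), 10 * sqrt(2),
               tolerance = 1e-12)
  # closed square of side 2 includes the closing step
  sq <- rbind(c(1, 1), c(1, 2), c(2, 2), c(2, 1))
  expect_equal(chain_code_length(sq, closed = TRUE), 4)
  expect_error(chain_code_length(rbind(c(1, 1), c(3, 1))), "invalid path")
  expect_error(chain_code_length(rbind(c(1, 1), c(1, 1))), "invalid path")
})

test_that("chain code is invariant under reversal and rotation", {
  set.seed(5)
  # random 8-connected walk
  steps <- sample(1:8, 40, replace = TRUE)
  drc <- rbind(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1), c(1, 0), c(1, -1),
               c(0, -1), c(-1, -1))[steps, ]
  path <- apply(rbind(c(50, 50), drc), 2, cumsum)
  len <- chain_code_length(path)
  expect_equal(chain_code_length(path[nrow(path):1, ]), len)
  rot90 <- cbind(path[, 2], -path[, 1]) # 90-degree rotation
  expect_equal(chain_code_length(rot90), len)
  mirror <- path[, c(2, 1)] # diagonal mirror swaps rows/cols
  expect_equal(chain_code_length(mirror), len)
})

test_that("skeleton tracing classifies bar, annulus and cross shapes", {
  # 3-px-wide straight bar -> open path along the axis
  bar <- matrix(0, 40, 40); bar[18:20, 5:35] <- 1
  tr <- skeleton_trace(which(bar == 1, arr.ind = TRUE), dim(bar))
  expect_false(tr$branched)
  expect_false(tr$closed)
  expect_gt(tr$length_px, 24)
  # painted annulus -> closed loop
  ann <- disc_mask(64, 32, 32, 20, 15)
  tra <- skeleton_trace(which(ann, arr.ind = TRUE), c(64, 64))
  expect_true(tra$closed)
  expect_false(tra$branched)
  # X-shaped cross -> branched, no length
  x <- matrix(0, 41, 41)
  for (i in 5:37) { x[i, i] <- 1; x[i, 42 - i] <- 1 }
  trx <- skeleton_trace(which(x == 1, arr.ind = TRUE), dim(x), spur_px = 2)
  expect_true(trx$branched)
  expect_true(is.na(trx$length_px))
})

test_that("a digitized circle of radius 50 px measures close to 2 pi r", {
  ann <- disc_mask(128, 64, 64, 51.5, 48.5)
  tr <- skeleton_trace(which(ann, arr.ind = TRUE), c(128, 128))
  expect_true(tr$closed)
  len <- radbreaks:::corrected_chain_length(tr$pixel_path, closed = TRUE)
  expect_lt(abs(len - 2 * pi * 50) / (2 * pi * 50), 0.05)
})

test_that("ruler calibration is the contour over the median pixel length", {
  expect_equal(afm_calibrate(150, pbr322()), 1482.74 / 150)
  expect_equal(afm_calibrate(c(148, 150, 152, 400), pbr322()),
               1482.74 / 151) # median robust to one compacted outlier
  expect_error(afm_calibrate(numeric(0)), "ruler")
  expect_equal(round(bp_to_nm(42)), 14)
})

test_that("length distribution bins 0-1550 nm with an overflow tally", {
  d0 <- length_distribution(numeric(0))
  expect_equal(sum(d0$rel_freq), 0)
  expect_equal(attr(d0, "n_molecules"), 0L)
  d1 <- length_distribution(75)
  expect_equal(d1$rel_freq[d1$bin_lo_nm == 50], 1)
  expect_equal(sum(d1$rel_freq), 1)
  expect_equal(nrow(d1), 31L)
  # half-open bins: a length exactly on an edge falls in the upper bin
  d2 <- length_distribution(c(50, 99.999))
  expect_equal(d2$count[d2$bin_lo_nm == 50], 2L)
  # recount oracle on simulated lengths
  set.seed(8)
  lens <- rexp(10000, 1 / 300)
  d3 <- length_distribution(lens)
  brute <- vapply(seq(0, 1500, by = 50), function(lo) {
    sum(lens >= lo & lens < lo + 50)
  }, 1)
  expect_equal(d3$count, as.integer(brute))
  expect_equal(d3$rel_freq, brute / sum(brute))
  expect_equal(attr(d3, "n_overflow"), sum(lens >= 1550))
  expect_equal(sum(d3$rel_freq), 1, tolerance = 1e-12)
  expect_error(length_distribution(-1), ">= 0")
})

test_that("rendered rods are recovered within tolerance by the pipeline", {
  r <- render_afm(rep(500, 12), persistence_nm = Inf, seed = 301)
  m <- afm_measure(r$image, height_threshold = 0.15)
  ok <- !m$branched
  expect_gte(sum(ok), 10)
  expect_true(all(abs(m$length_nm[ok] - 500) / 500 < 0.05))
})

test_that("rendered rings close and calibrate the pixel scale", {
  r <- render_afm(rep(1482.74, 6), closed = TRUE, seed = 302)
  m <- afm_measure(r$image, height_threshold = 0.15)
  ok <- m$closed & !m$branched
  expect_gte(sum(ok), 5)
  nm_px <- afm_calibrate(m$length_px[ok], pbr322())
  expect_lt(abs(nm_px - 5000 / 512) / (5000 / 512), 0.02)
})

test_that("an empty render is background only", {
  r <- render_afm(numeric(0), seed = 1)
  expect_equal(nrow(r$truth), 0L)
  expect_lt(max(r$image$heights), 0.15)
  expect_equal(nrow(afm_segment(r$image, 0.15)), 0L)
})

test_that("image round trip through TIFF and PNG preserves the pipeline", {
  r <- render_afm(rep(400, 4), persistence_nm = Inf, seed = 303,
                  noise_nm = 0)
  h <- r$image$heights
  scale <- max(h)
  tmp <- tempfile(fileext = ".tiff")
  tiff::writeTIFF(h / scale, tmp, bits.per.sample = 16L)
  back <- read_afm_image(tmp, field_nm = 5000, height_scale = scale)
  expect_equal(back$heights, h, tolerance = 1e-4)
  m1 <- afm_measure(r$image, 0.15)
  m2 <- afm_measure(back, 0.15)
  expect_equal(m2$length_nm, m1$length_nm, tolerance = 0.02)
})
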