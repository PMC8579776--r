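test_that("ambient calibration is the stated per-pixel linear model", {
  raw <- swath_frame(matrix(runif(12, 100, 200), 3, 4), 0, 0)
  ident <- list(c0 = matrix(0, 3, 4), c1 = matrix(1, 3, 4),
                c2 = matrix(0, 3, 4))
  expect_equal(apply_ambient_calibration(raw, ident, 30)$values, raw$values)
  # linearity in the ambient term
  warm <- ident; warm$c2 <- matrix(0.1, 3, 4)
  expect_equal(apply_ambient_calibration(raw, warm, 30)$values,
               raw$values + 3.0)
  # a frame built as the inverse of a radial intercept ramp flattens out
  d <- sqrt(outer((1:3 - 2)^2, (1:4 - 2.5)^2, "+"))
  vign <- list(c0 = 2 * d, c1 = matrix(1, 3, 4), c2 = matrix(0, 3, 4))
  inv <- swath_frame(35 - 2 * d, 0, 0)
  expect_equal(apply_ambient_calibration(inv, vign, 30)$values,
               matrix(35, 3, 4))
  expect_error(apply_ambient_calibration(raw, list(c0 = matrix(0, 2, 2),
                                                   c1 = ident$c1,
                                                   c2 = ident$c2), 30),
               "congruent")
})

test_that("swath overlap averaging matches a brute-force accumulation", {
  # single frame: identity over its footprint, nodata elsewhere
  f <- swath_frame(matrix(1:6, 2, 3), 1, 1)
  strip <- average_swath_overlap(swath_stack(list(f), c(4, 5)))
  expect_equal(strip[2:3, 2:4], matrix(1:6, 2, 3))
  expect_true(all(is.na(strip[1, ])))
  # two fully overlapping frames T and T+2 average to T+1
  base <- matrix(runif(6, 20, 40), 2, 3)
  st <- swath_stack(list(swath_frame(base, 0, 0, 1),
                         swath_frame(base + 2, 0, 0, 2)), c(2, 3))
  expect_equal(average_swath_overlap(st), base + 1)
  # N = 7 randomly offset frames vs an independent coverage-and-mean loop
  set.seed(11)
  nr <- 12; nc <- 15; fr <- 4; fc <- 5
  frames <- lapply(1:7, function(k) {
    swath_frame(matrix(rnorm(fr * fc, 30, 2), fr, fc),
                sample(0:(nr - fr), 1), sample(0:(nc - fc), 1), k)
  })
  strip7 <- average_swath_overlap(swath_stack(frames, c(nr, nc)))
  acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  for (fx in frames) for (i in 1:fr) for (j in 1:fc) {
    acc[fx$row_off + i, fx$col_off + j] <- acc[fx$row_off + i, fx$col_off + j] +
      fx$values[i, j]
    cnt[fx$row_off + i, fx$col_off + j] <- cnt[fx$row_off + i, fx$col_off + j] + 1
  }
  exp7 <- acc / cnt; exp7[cnt == 0] <- NA
  expect_equal(strip7, exp7)
  # idempotence on a single-strip stack
  expect_equal(average_swath_overlap(swath_stack(list(f), c(4, 5))), strip)
})

test_that("chain normalization recovers injected additive offsets", {
  base <- matrix(rnorm(200, 30, 3), 10, 20)
  # identical strips: zero offsets
  r0 <- chain_normalize_swaths(list(base, base, base))
  expect_equal(r0$offsets, c(0, 0, 0))
  # +2 degC in the overlap: offset recovered, corrected difference zero
  r1 <- chain_normalize_swaths(list(base, base + 2))
  expect_equal(r1$offsets, c(0, 2))
  expect_equal(mean(r1$strips[[2]] - r1$strips[[1]]), 0)
  # injected (0, +1, +3) on partially overlapping strips, sequential means
  s1 <- base; s1[, 15:20] <- NA
  s2 <- base + 1; s2[, c(1:8, 19:20)] <- NA
  s3 <- base + 3; s3[, 1:12] <- NA
  r2 <- chain_normalize_swaths(list(s1, s2, s3))
  expect_equal(r2$offsets, c(0, 1, 3), tolerance = 1e-12)
  # chain break is reported with the swath pair
  s3b <- base + 3; s3b[, 1:18] <- NA  # no shared valid pixels with s2
  s2b <- s2; s2b[, 17:20] <- NA
  expect_error(chain_normalize_swaths(list(s1, s2b, s3b)), "swaths 2 and 3")
})

test_that("mosaic assembly copies, averages sidelap, conserves nodata", {
  a <- matrix(NA_real_, 4, 6); a[, 1:4] <- 20
  b <- matrix(NA_real_, 4, 6); b[, 3:6] <- 24
  m <- assemble_mosaic(list(a, b))
  expect_equal(unique(as.vector(m$values[, 1:2])), 20)
  expect_equal(unique(as.vector(m$values[, 3:4])), 22)
  expect_equal(unique(as.vector(m$values[, 5:6])), 24)
  # disjoint strips tile without modification
  b2 <- matrix(NA_real_, 4, 6); b2[, 5:6] <- 24
  m2 <- assemble_mosaic(list(a, b2))
  expect_equal(m2$values[, 1:4], a[, 1:4])
  expect_equal(m2$values[, 5:6], b2[, 5:6])
  # nodata iff covered by no strip
  a3 <- matrix(NA_real_, 4, 6); a3[1:2, 1:2] <- 20
  m3 <- assemble_mosaic(list(a3))
  expect_equal(is.na(m3$values), is.na(a3))
})

test_that("a simulated flight with drift reconstructs the scene", {
  cfg <- noise_free_config(swath_offset_sd = 1.5)
  fl <- generate_flight(cfg, seed = 5)
  expect_gt(length(fl$stacks), 3)
  res <- build_thermal_mosaic(fl$stacks, fl$georef)
  # zero pixel noise: offsets recovered exactly and scene reproduced
  expect_equal(res$offsets, fl$offsets, tolerance = 1e-6)
  expect_equal(res$mosaic$values, fl$truth$temp_true, tolerance = 1e-9)
})
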