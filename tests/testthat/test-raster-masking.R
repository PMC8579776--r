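test_that("nearest-neighbor resampling matches an exhaustive center lookup", {
  # identical georeference: identity
  v <- array(runif(2 * 3 * 4 * 3), c(6, 12, 3))
  g <- georef(0, 0, 0.005)
  fine <- reflectance_grid(v, g)
  out <- resample_nearest(fine, g, c(6, 12))
  expect_equal(out$values, v)
  # constant source, 3x coarser target: constant
  cg <- georef(-0.005, 0.005, 0.005)
  const <- reflectance_grid(array(0.4, c(9, 9, 3)), cg)
  out3 <- resample_nearest(const, georef(0, 0, 0.015), c(3, 3))
  expect_true(all(out3$values == 0.4))
  # checkerboard vs brute-force nearest-center search
  ch <- array(rep(outer(1:10, 1:14, function(r, c) (r + c) %% 2), 3),
              c(10, 14, 3))
  sg <- georef(0.001, 0.002, 0.004)
  tg <- georef(0.004, -0.001, 0.007)
  res <- resample_nearest(reflectance_grid(ch, sg), tg, c(5, 7))
  sx <- 0.001 + (1:14 - 1) * 0.004
  sy <- 0.002 - (1:10 - 1) * 0.004
  for (r in 1:5) for (cc in 1:7) {
    x <- 0.004 + (cc - 1) * 0.007
    y <- -0.001 - (r - 1) * 0.007
    jj <- which.min(abs(sx - x)); ii <- which.min(abs(sy - y))
    expect_equal(res$values[r, cc, 1], ch[ii, jj, 1])
  }
  expect_error(resample_nearest(fine, georef(10, 10, 0.015), c(3, 3)),
               "disjoint")
})

test_that("GRVI is the normalized green-red contrast with nodata on zero sum", {
  v <- array(NA_real_, c(1, 3, 3))
  v[1, 1, ] <- c(0.3, 0.3, 0.1)   # green = red -> 0
  v[1, 2, ] <- c(0.2, 0.4, 0.1)   # (0.4-0.2)/0.6
  v[1, 3, ] <- c(0, 0, 0)         # undefined ratio -> nodata
  gi <- compute_grvi(reflectance_grid(v, georef(0, 0, 0.015)))
  expect_equal(gi$values[1, 1], 0)
  expect_equal(gi$values[1, 2], 1 / 3)
  expect_true(is.na(gi$values[1, 3]))
})

test_that("tag removal cuts strictly above the per-plant blue percentile", {
  # constant blue: ties, nothing strictly above the percentile
  expect_true(all(remove_tag_pixels(rep(0.2, 50))))
  # 995 dull + 5 bright pixels: exactly the bright ones removed
  blue <- c(rep(0.2, 995), rep(0.9, 5))
  keep <- remove_tag_pixels(blue)
  expect_equal(which(!keep), 996:1000)
  # 10-pixel plant with one outlier: hand-computed interpolated percentile
  b10 <- c(rep(0.2, 9), 0.9)
  thr <- 0.2 + ((10 - 1) * 0.995 + 1 - 9) * (0.9 - 0.2)  # type-7 at h = 9.955
  expect_equal(as.numeric(quantile(b10, 0.995, type = 7)), thr)
  expect_equal(sum(!remove_tag_pixels(b10)), 1)
  expect_error(remove_tag_pixels(numeric(0)), "empty")
})

test_that("the 2-means GRVI threshold attains the exact sorted-split optimum", {
  # two tight groups: boundary between them, all points split correctly
  set.seed(3)
  x <- c(rnorm(60, -0.2, 0.01), rnorm(40, 0.3, 0.01))
  for (m in c("exact", "iterative")) {
    fit <- kmeans_grvi_threshold(x, seed = 2, method = m)
    expect_gt(fit$threshold, -0.15)
    expect_lt(fit$threshold, 0.25)
    expect_equal(sum(x > fit$threshold), 40)
  }
  # the iterative WSS equals the exhaustive loop optimum on random mixtures
  for (i in 1:25) {
    set.seed(100 + i)
    n <- sample(10:200, 1)
    y <- c(rnorm(n %/% 2, -0.1, 0.05), rnorm(n - n %/% 2, runif(1, 0, 0.4), 0.05))
    it <- kmeans_grvi_threshold(y, seed = i, method = "iterative")
    expect_equal(it$wss, brute_force_two_means_wss(y), tolerance = 1e-8)
    expect_equal(kmeans_grvi_threshold(y, method = "exact")$wss, it$wss,
                 tolerance = 1e-8)
  }
  expect_error(kmeans_grvi_threshold(rep(0.1, 5)), "degenerate")
})

test_that("a senesced-scene mixture can yield a negative GRVI threshold", {
  set.seed(9)
  # mostly senesced material just below zero plus a green minority
  x <- c(rnorm(300, -0.08, 0.03), rnorm(80, 0.25, 0.05))
  thr <- kmeans_grvi_threshold(x, seed = 4)$threshold
  expect_lt(thr, 0.2)
  expect_gt(thr, -0.2)
})

test_that("the vegetation mask applies strict GRVI and ceiling conventions", {
  g <- index_grid(matrix(c(0.1, 0.1, 0, 0.1, -0.2, NA), 1, 6),
                  georef(0, 0, 0.015))
  tmp <- temperature_grid(matrix(c(35, 40, 33, 39, 33, 33), 1, 6),
                          georef(0, 0, 0.015))
  cm <- vegetation_mask(g, tmp, ta = 30)  # ceiling at 39
  codes <- pixel_class_codes()
  expect_equal(cm[1, 1], codes[["vegetation"]])   # GRVI>0, Ta+5
  expect_equal(cm[1, 2], codes[["overtemp"]])     # GRVI>0, Ta+10
  expect_equal(cm[1, 3], codes[["background"]])   # GRVI = 0 is not vegetation
  expect_equal(cm[1, 4], codes[["vegetation"]])   # exactly Ta+9 is retained
  expect_equal(cm[1, 5], codes[["background"]])
  expect_equal(cm[1, 6], codes[["nodata"]])
  # partition: every pixel gets exactly one class
  expect_true(all(cm %in% codes))
  expect_error(vegetation_mask(g, temperature_grid(matrix(30, 2, 2),
                                                   georef()), 30),
               "congruent")
})

test_that("sunlit/shaded split thresholds at the darkest cluster's maximum", {
  set.seed(21)
  modes <- c(0.05, 0.12, 0.20, 0.30, 0.45)
  blue <- as.vector(vapply(modes, function(m) rnorm(40, m, 0.005),
                           numeric(40)))
  sp <- sunlit_shaded_split(blue, k = 5, seed = 8)
  # the darkest mode is shaded, everything else sunlit
  expect_equal(sum(!sp$sunlit), 40)
  expect_equal(sp$threshold, max(blue[blue < 0.08]))
  # partition of the vegetation pixels
  expect_equal(sum(sp$sunlit) + sum(!sp$sunlit), length(blue))
  expect_error(sunlit_shaded_split(rep(0.1, 50), k = 5), "degenerate")
})

test_that("the elbow criterion finds well-separated modes and small k for one", {
  set.seed(31)
  x5 <- as.vector(vapply(c(0, 2, 4, 6, 8), function(m) rnorm(60, m, 0.05),
                         numeric(60)))
  el <- elbow_optimal_k(x5, k_max = 10, seed = 14)
  expect_equal(el$k, 5)
  # inertia non-increasing in k (allowing tiny numerical slack)
  expect_true(all(diff(el$inertia) <= 1e-6))
  x1 <- rnorm(200, 0, 0.05)
  expect_lte(elbow_optimal_k(x1, k_max = 8, seed = 3)$k, 2)
})
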