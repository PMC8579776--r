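make_class_temp <- function(tvals, cls) {
  g <- georef(0, 0, 0.015)
  list(cm = matrix(cls, nrow(tvals), ncol(tvals)),
       temp = temperature_grid(tvals, g))
}

test_that("zonal statistics match hand arithmetic and a brute-force loop", {
  codes <- pixel_class_codes()
  # single vegetation pixel
  x <- make_class_temp(matrix(31.5, 1, 1), codes[["vegetation"]])
  st <- zonal_stats(cbind(1, 1), x$cm, x$temp)
  expect_equal(unlist(st[c("min_c", "max_c", "mean_c", "median_c")]),
               c(min_c = 31.5, max_c = 31.5, mean_c = 31.5, median_c = 31.5))
  expect_equal(st$sd_c, 0)
  expect_equal(st$pixel_count, 1L)
  # {1,2,3}: mean 2, median 2, population sd sqrt(2/3)
  y <- make_class_temp(matrix(c(1, 2, 3), 1, 3), codes[["vegetation"]])
  st3 <- zonal_stats(cbind(1, 1:3), y$cm, y$temp)
  expect_equal(st3$mean_c, 2)
  expect_equal(st3$median_c, 2)
  expect_equal(st3$sd_c, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(zonal_stats(cbind(1, 1:3), y$cm, y$temp,
                           sd_type = "sample")$sd_c, 1)
  # 500 random pixels, mixed classes, vs an independent accumulation
  set.seed(17)
  tv <- matrix(rnorm(900, 33, 2), 30, 30)
  cls <- matrix(sample(codes, 900, replace = TRUE), 30, 30)
  z <- list(cm = cls, temp = temperature_grid(tv, georef(0, 0, 0.015)))
  pix <- cbind(sample(1:30, 500, TRUE), sample(1:30, 500, TRUE))
  pix <- pix[!duplicated(pix), , drop = FALSE]
  st500 <- zonal_stats(pix, z$cm, z$temp)
  vals <- c()
  for (i in seq_len(nrow(pix))) {
    if (cls[pix[i, 1], pix[i, 2]] == codes[["vegetation"]]) {
      vals <- c(vals, tv[pix[i, 1], pix[i, 2]])
    }
  }
  n <- length(vals)
  expect_equal(st500$pixel_count, n)
  expect_equal(st500$min_c, min(vals))
  expect_equal(st500$max_c, max(vals))
  expect_equal(st500$mean_c, sum(vals) / n)
  expect_equal(st500$median_c, median(vals))
  expect_equal(st500$sd_c, sqrt(sum((vals - mean(vals))^2) / n))
  # permutation invariance in pixel order
  perm <- pix[sample(nrow(pix)), , drop = FALSE]
  expect_equal(zonal_stats(perm, z$cm, z$temp), st500)
  expect_error(zonal_stats(cbind(31, 1), z$cm, z$temp), "outside")
})

test_that("the retention rule keeps exactly 10% and above", {
  expect_false(retention_filter(9, 100))
  expect_true(retention_filter(10, 100))
  expect_false(retention_filter(0, 100))
  expect_error(retention_filter(1, 0), "positive")
})

test_that("empty vegetation sets yield undefined stats and no retention", {
  codes <- pixel_class_codes()
  x <- make_class_temp(matrix(45, 2, 2), codes[["background"]])
  st <- zonal_stats(cbind(c(1, 2), c(1, 2)), x$cm, x$temp)
  expect_equal(st$pixel_count, 0L)
  expect_true(is.na(st$mean_c))
})

test_that("per-plant retrieval drops senesced plants and keeps live ones", {
  cfg <- noise_free_config(senescence_fraction = c(control = 0, salt = 0.5))
  sc <- generate_scene(cfg, seed = 23)
  pt <- plant_temperatures(sc$delins,
                           resample_nearest(sc$rgb, sc$temp$georef,
                                            dim(sc$temp$values)),
                           sc$temp, ta = cfg$ta)
  tr <- truth_report(sc$truth)
  m <- merge(pt$plants, tr, by = "plant_id")
  # senesced plants retain no vegetation pixels; live plants are retained
  expect_true(all(!m$retained[m$senesced]))
  expect_true(all(m$retained[!m$senesced]))
  expect_gte(sum(m$retained & m$treatment.x == "control"),
             sum(m$retained & m$treatment.x == "salt"))
  # per-plant mean temperature of live plants tracks the injected deviation
  live <- m[!m$senesced, ]
  expect_lt(max(abs(live$mean_c - cfg$ta - live$true_dtp)), 0.45)
})

test_that("the temperature ceiling never inflates per-plant dispersion", {
  sc <- generate_scene(small_scene_config(), seed = 29)
  rgb_t <- resample_nearest(sc$rgb, sc$temp$georef, dim(sc$temp$values))
  loose <- plant_temperatures(sc$delins, rgb_t, sc$temp, ta = sc$truth$ta,
                              max_offset = 1e6)
  tight <- plant_temperatures(sc$delins, rgb_t, sc$temp, ta = sc$truth$ta,
                              max_offset = 9)
  both <- merge(loose$plants, tight$plants, by = "plant_id",
                suffixes = c("_loose", "_tight"))
  ok <- is.finite(both$sd_c_loose) & is.finite(both$sd_c_tight)
  expect_true(all(both$sd_c_tight[ok] <= both$sd_c_loose[ok] + 1e-9))
})

test_that("polygon delineations rasterize onto the grid", {
  # a 0.06 m square polygon on a 0.015 m grid covers a 3-4 pixel block
  gj <- list(type = "FeatureCollection", features = list(list(
    type = "Feature",
    properties = list(plant_id = 1, plot_id = "c1", treatment = "control",
                      accession_id = "ACC1"),
    geometry = list(type = "Polygon", coordinates = list(list(
      list(0.02, -0.02), list(0.08, -0.02), list(0.08, -0.08),
      list(0.02, -0.08), list(0.02, -0.02)))))))
  p <- tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, p, auto_unbox = TRUE, digits = NA)
  d <- read_delineations_geojson(p, georef(0, 0, 0.015), c(8, 8))
  npx <- sum(d$labels == 1L)
  expect_gte(npx, 9)
  expect_lte(npx, 25)
  # all burned pixels have centers inside the square
  idx <- which(d$labels == 1L, arr.ind = TRUE)
  xs <- (idx[, 2] - 1) * 0.015
  ys <- -(idx[, 1] - 1) * 0.015
  expect_true(all(xs > 0.02 & xs < 0.08 & ys < -0.02 & ys > -0.08))
})

test_that("delineation label raster and attributes round-trip through files", {
  sc <- generate_scene(noise_free_config(), seed = 3)
  lp <- tempfile(fileext = ".tif"); ap <- tempfile(fileext = ".csv")
  write_delineations(sc$delins, lp, ap, sc$temp$georef)
  d2 <- read_delineations(lp, ap)
  expect_equal(d2$labels, sc$delins$labels)
  expect_equal(d2$attrs$plant_id, sc$delins$attrs$plant_id)
})
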