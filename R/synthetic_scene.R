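# Ground-truthed synthetic scene generator emulating a salinity field trial:
# paired RGB/TIR orthomosaics, plant delineations, weather records, and raw
# swath frames with injected per-swath drift. Every emitted raster comes
# with the generative truth needed to validate the analysis stages.

# Truth class codes (distinct from the analysis class codes: the truth also
# distinguishes mixed edge pixels and senesced canopies).
TRUTH_CODES <- c(soil = 0L, vegetation = 1L, edge = 2L, tag = 3L,
                 senesced = 4L)

#' Truth class codes of the scene generator
#'
#' Integer coding of the generator's per-pixel ground truth: 0 soil,
#' 1 vegetation (live canopy), 2 mixed soil/canopy edge, 3 white tag,
#' 4 senesced (dead) canopy.
#'
#' @return Named integer vector.
#' @export
truth_class_codes <- function() TRUTH_CODES

#' Configuration of the synthetic field-trial scene
#'
#' Defaults emulate a four-plot tomato salinity trial (two control, two
#' salt-treated plots of 15 x 20 plants, 1,200 plants in total) imaged at a
#' 0.015 m thermal and 0.005 m RGB ground sample distance. Canopy-air
#' deviations are drawn per plant from Normal(2.5, 1.0) degC in the control
#' arm and Normal(4.2, 1.2) degC in the salt arm; bare soil sits 18 degC
#' above air temperature so mixed soil/canopy pixels are unmistakably
#' warmer than the vegetation ceiling. Plants are rendered as filled discs
#' with a one-pixel mixed boundary ring; a small fraction of pixels per
#' plant is a white identification tag; a per-arm fraction of plants is
#' senesced (dead) and another fraction is "declining" (still green but
#' running hotter, for the early-detection contrast). Plant spacing is
#' compacted relative to a production field so a full trial fits a desk-
#' scale raster; all class contrasts are preserved.
#'
#' @param plots Number of plots (default 4).
#' @param treatments Treatment per plot.
#' @param plant_rows,plant_cols Plants per plot (default 15 x 20).
#' @param spacing_m Plant spacing within a plot, m.
#' @param plot_gap_m Gap between plots, m.
#' @param margin_m Bare-soil margin around the trial, m.
#' @param gsd_tir,gsd_rgb Ground sample distances, m (RGB must divide TIR).
#' @param radius_mean_m,radius_sd_m Plant canopy radius distribution, m.
#' @param soil_offset Soil temperature above air temperature, degC.
#' @param dtp_mean,dtp_sd Named (`control`, `salt`) canopy-air deviation
#'   distribution per arm, degC.
#' @param sunlit_offset,shaded_offset Temperature offsets of sunlit/shaded
#'   canopy pixels, degC.
#' @param sunlit_fraction Fraction of canopy pixels that are sunlit.
#' @param senesced_offset Senesced-canopy temperature above air, degC.
#' @param tag_fraction Fraction of canopy pixels that are tag (at least one
#'   tag pixel per plant).
#' @param tag_offset Tag temperature above air, degC.
#' @param senescence_fraction Named per-arm fraction of dead plants.
#' @param declining_fraction Named per-arm fraction of live plants that are
#'   pre-symptomatically stressed.
#' @param declining_shift Extra canopy-air deviation of declining plants,
#'   degC.
#' @param edge_soil_weight Soil weight in the mixed boundary ring. The
#'   default 0.6 keeps every mixed pixel above the `ta + 9` vegetation
#'   ceiling for any plausible canopy-air deviation, so the ceiling can
#'   remove the whole ring.
#' @param noise_refl Reflectance noise sd (per band).
#' @param noise_temp Thermal sensor noise sd, degC.
#' @param swath_offset_sd Per-swath drift sd, degC (first swath anchored
#'   at 0).
#' @param frame_rows,frame_cols Thermal frame size, px.
#' @param forward_overlap,sidelap Frame/swath overlap fractions in (0, 1).
#' @param ta,rh,ws Air temperature (degC), relative humidity (%), wind
#'   speed (m/s) during the flight.
#' @param n_accessions Accessions cycled through the plants.
#' @return A `scene_config` list.
#' @export
scene_config <- function(plots = 4,
                         treatments = c("control", "control", "salt", "salt"),
                         plant_rows = 15, plant_cols = 20,
                         spacing_m = 0.30, plot_gap_m = 0.30, margin_m = 0.15,
                         gsd_tir = 0.015, gsd_rgb = 0.005,
                         radius_mean_m = 0.09, radius_sd_m = 0.012,
                         soil_offset = 18,
                         dtp_mean = c(control = 2.5, salt = 4.2),
                         dtp_sd = c(control = 1.0, salt = 1.2),
                         sunlit_offset = 0.4, shaded_offset = -0.4,
                         sunlit_fraction = 0.5,
                         senesced_offset = 12,
                         tag_fraction = 0.005, tag_offset = 5,
                         senescence_fraction = c(control = 0.02, salt = 0.08),
                         declining_fraction = c(control = 0.03, salt = 0.10),
                         declining_shift = 1.5,
                         edge_soil_weight = 0.6,
                         noise_refl = 0.02, noise_temp = 0.3,
                         swath_offset_sd = 1.0,
                         frame_rows = 48, frame_cols = 64,
                         forward_overlap = 0.93, sidelap = 0.60,
                         ta = 31, rh = 25, ws = 2.5,
                         n_accessions = 200) {
  cfg <- as.list(environment())
  if (length(cfg$treatments) != cfg$plots) stop("one treatment per plot required")
  if (!all(cfg$treatments %in% c("control", "salt"))) {
    stop("treatments must be 'control' or 'salt'")
  }
  if (cfg$gsd_tir <= 0 || cfg$gsd_rgb <= 0) stop("GSDs must be positive")
  ratio <- cfg$gsd_tir / cfg$gsd_rgb
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("gsd_rgb must divide gsd_tir for aligned nesting")
  }
  for (f in c("forward_overlap", "sidelap")) {
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1) stop(f, " must lie in (0, 1)")
  }
  if (cfg$noise_refl < 0 || cfg$noise_temp < 0) stop("noise sds must be >= 0")
  bad <- c(cfg$senescence_fraction, cfg$declining_fraction, cfg$tag_fraction,
           cfg$sunlit_fraction)
  if (any(bad < 0 | bad > 1)) stop("fractions must lie in [0, 1]")
  if (2 * (cfg$radius_mean_m + 3 * cfg$radius_sd_m + cfg$gsd_tir) >
      cfg$spacing_m) {
    stop("infeasible layout: plants would overlap at this spacing")
  }
  class(cfg) <- "scene_config"
  cfg
}

# Deterministic scene layout + per-plant draws + noise-free rendering on the
# thermal grid. Everything downstream (noisy rasters, flight frames) reuses
# this truth.
render_scene_truth <- function(config, seed) {
  with_local_seed(seed, {
    gsd <- config$gsd_tir
    plot_w <- config$plant_cols * config$spacing_m
    plot_h <- config$plant_rows * config$spacing_m
    width_m <- config$plots * plot_w + (config$plots - 1) * config$plot_gap_m +
      2 * config$margin_m
    height_m <- plot_h + 2 * config$margin_m
    nr <- as.integer(round(height_m / gsd))
    nc <- as.integer(round(width_m / gsd))

    # per-plant table
    n_per_plot <- config$plant_rows * config$plant_cols
    plants <- do.call(rbind, lapply(seq_len(config$plots), function(p) {
      idx <- seq_len(n_per_plot)
      ri <- (idx - 1) %/% config$plant_cols + 1
      ci <- (idx - 1) %% config$plant_cols + 1
      x0 <- config$margin_m + (p - 1) * (plot_w + config$plot_gap_m)
      data.frame(plot_id = paste0(substr(config$treatments[p], 1, 1), p),
                 treatment = config$treatments[p],
                 x_m = x0 + (ci - 0.5) * config$spacing_m,
                 y_m = config$margin_m + (ri - 0.5) * config$spacing_m,
                 stringsAsFactors = FALSE)
    }))
    n <- nrow(plants)
    plants$plant_id <- seq_len(n)
    plants$accession_id <- paste0("ACC", (plants$plant_id - 1) %% config$n_accessions + 1)
    plants$radius_m <- pmin(pmax(stats::rnorm(n, config$radius_mean_m,
                                              config$radius_sd_m),
                                 0.5 * config$radius_mean_m),
                            config$spacing_m / 2 - gsd)
    plants$senesced <- stats::runif(n) <
      config$senescence_fraction[plants$treatment]
    plants$declining <- !plants$senesced & stats::runif(n) <
      config$declining_fraction[plants$treatment]
    mu <- config$dtp_mean[plants$treatment]
    sg <- config$dtp_sd[plants$treatment]
    plants$true_dtp <- stats::rnorm(n, mu, sg) +
      ifelse(plants$declining, config$declining_shift, 0)
    plants$true_dtp[plants$senesced] <- NA_real_

    class_map <- matrix(TRUTH_CODES[["soil"]], nr, nc)
    labels <- matrix(0L, nr, nc)
    illum <- matrix(NA_integer_, nr, nc)  # 1 sunlit, 0 shaded over live canopy
    temp_true <- matrix(config$ta + config$soil_offset, nr, nc)

    for (i in seq_len(n)) {
      r0 <- plants$y_m[i] / gsd + 0.5
      c0 <- plants$x_m[i] / gsd + 0.5
      rad_px <- plants$radius_m[i] / gsd
      rr <- max(1L, floor(r0 - rad_px - 2)):min(nr, ceiling(r0 + rad_px + 2))
      cc <- max(1L, floor(c0 - rad_px - 2)):min(nc, ceiling(c0 + rad_px + 2))
      dist <- sqrt(outer((rr - r0)^2, (cc - c0)^2, "+"))
      canopy <- dist <= rad_px
      ring <- dist > rad_px & dist <= rad_px + 1
      sub_lab <- labels[rr, cc]
      sub_lab[canopy | ring] <- plants$plant_id[i]
      labels[rr, cc] <- sub_lab
      sub_cls <- class_map[rr, cc]
      sub_tmp <- temp_true[rr, cc]
      if (plants$senesced[i]) {
        sub_cls[canopy] <- TRUTH_CODES[["senesced"]]
        sub_cls[ring] <- TRUTH_CODES[["senesced"]]
        sub_tmp[canopy | ring] <- config$ta + config$senesced_offset
      } else {
        sub_cls[canopy] <- TRUTH_CODES[["vegetation"]]
        sub_cls[ring] <- TRUTH_CODES[["edge"]]
        npx <- sum(canopy)
        sun <- stats::runif(npx) < config$sunlit_fraction
        sub_ill <- illum[rr, cc]
        sub_ill[canopy] <- as.integer(sun)
        illum[rr, cc] <- sub_ill
        base <- config$ta + plants$true_dtp[i]
        sub_tmp[canopy] <- base + ifelse(sun, config$sunlit_offset,
                                         config$shaded_offset)
        sub_tmp[ring] <- config$edge_soil_weight *
          (config$ta + config$soil_offset) +
          (1 - config$edge_soil_weight) * base
        # white tag pixels inside the canopy
        n_tag <- max(1L, round(config$tag_fraction * npx))
        tag_at <- sample(which(canopy), n_tag)
        sub_cls[tag_at] <- TRUTH_CODES[["tag"]]
        sub_ill[tag_at] <- NA_integer_
        illum[rr, cc] <- sub_ill
        sub_tmp[tag_at] <- config$ta + config$tag_offset
      }
      class_map[rr, cc] <- sub_cls
      temp_true[rr, cc] <- sub_tmp
    }

    plants <- plants[, c("plant_id", "plot_id", "treatment", "accession_id",
                         "x_m", "y_m", "radius_m", "true_dtp", "senesced",
                         "declining")]
    list(class_map = class_map, labels = labels, illum = illum,
         temp_true = temp_true, plants = plants, dim = c(nr, nc),
         ta = config$ta, config = config, seed = seed)
  })
}

# Class-conditional base reflectance (red, green, blue); blue for live
# canopy is illumination-dependent and handled separately.
scene_reflectance_bases <- function() {
  rbind(soil = c(0.35, 0.30, 0.20),
        vegetation = c(0.12, 0.25, NA),
        edge = c(0.235, 0.275, 0.16),
        tag = c(0.90, 0.90, 0.90),
        senesced = c(0.30, 0.26, 0.15))
}

#' Generate a full synthetic scene
#'
#' Produces the co-registered rasters and records the analysis pipeline
#' consumes -- an RGB reflectance orthomosaic at the fine GSD, a thermal
#' orthomosaic at the coarse GSD, plant delineations (disc plus mixed edge
#' ring), and a minute weather series -- together with the generative
#' ground truth. The RGB grid nests exactly in the thermal grid so
#' nearest-neighbor resampling picks the center fine pixel of each thermal
#' pixel. The same seed reproduces the outputs bit-exactly.
#'
#' @param config A [scene_config()].
#' @param seed Integer seed.
#' @return List: `rgb` ([reflectance_grid()]), `temp`
#'   ([temperature_grid()]), `delins` ([plant_delineations()]), `weather`
#'   ([weather_series()]), `truth` (class map, illumination, noise-free
#'   temperature, per-plant table, config, seed).
#' @export
generate_scene <- function(config = scene_config(), seed = 1L) {
  truth <- render_scene_truth(config, seed)
  with_local_seed(seed + 1000L, {
    nr <- truth$dim[1]; nc <- truth$dim[2]
    # thermal orthomosaic: truth + sensor noise
    tv <- truth$temp_true +
      stats::rnorm(nr * nc, 0, config$noise_temp)
    temp <- temperature_grid(matrix(tv, nr, nc), georef(0, 0, config$gsd_tir))

    # RGB at the fine grid: upsample class/illumination, add reflectance noise
    f <- as.integer(round(config$gsd_tir / config$gsd_rgb))
    up <- function(m) m[rep(seq_len(nr), each = f), rep(seq_len(nc), each = f)]
    cls_f <- up(truth$class_map)
    ill_f <- up(truth$illum)
    bases <- scene_reflectance_bases()
    code_row <- match(cls_f, TRUTH_CODES)  # maps code to base-table row
    nrf <- nr * f; ncf <- nc * f
    rgb <- array(NA_real_, c(nrf, ncf, 3))
    for (b in 1:3) {
      v <- bases[code_row, b]
      if (b == 3L) {
        live <- cls_f == TRUTH_CODES[["vegetation"]]
        v[live] <- ifelse(ill_f[live] == 1L, 0.12, 0.05)
      }
      v <- v + stats::rnorm(length(v), 0, config$noise_refl)
      rgb[, , b] <- matrix(pmin(pmax(v, 0), 1), nrf, ncf)
    }
    rgb_georef <- georef(-(f - 1) / 2 * config$gsd_rgb,
                         (f - 1) / 2 * config$gsd_rgb, config$gsd_rgb)
    rgb <- reflectance_grid(rgb, rgb_georef)

    delins <- plant_delineations(
      truth$labels,
      truth$plants[, c("plant_id", "plot_id", "treatment", "accession_id")])

    t0 <- as.POSIXct("2017-12-20 11:30:00", tz = "UTC")
    wx <- weather_series(data.frame(
      timestamp = t0 + 60 * (0:59),
      ta_c = config$ta + stats::rnorm(60, 0, 0.02),
      rh_pct = pmin(pmax(config$rh + stats::rnorm(60, 0, 0.2), 0), 100),
      ws_ms = pmax(config$ws + stats::rnorm(60, 0, 0.1), 0)))

    list(rgb = rgb, temp = temp, delins = delins, weather = wx, truth = truth)
  })
}

#' Generate a synthetic thermal flight (swath frames with drift)
#'
#' Tiles the noise-free scene with overlapping thermal frames arranged in
#' flight lines: frames within a swath share one injected additive drift
#' offset (the first swath is the anchor at 0 degC) and each frame carries
#' independent pixel noise. Feeding the stacks through
#' [average_swath_overlap()], [chain_normalize_swaths()] and
#' [assemble_mosaic()] should recover the scene and the offsets.
#'
#' @param config A [scene_config()].
#' @param seed Integer seed (the scene truth uses the same derivation as
#'   [generate_scene()], so flight and scene agree).
#' @param offsets Optional numeric vector of per-swath offsets to inject
#'   (first should be 0); drawn Normal(0, `swath_offset_sd`) otherwise.
#' @param noise_temp Override of the per-frame pixel noise sd, degC.
#' @return List: `stacks` (list of [swath_stack()]), `offsets` (injected,
#'   degC), `truth` (scene truth), `georef`.
#' @export
generate_flight <- function(config = scene_config(), seed = 1L,
                            offsets = NULL, noise_temp = config$noise_temp) {
  truth <- render_scene_truth(config, seed)
  with_local_seed(seed + 2000L, {
    nr <- truth$dim[1]; nc <- truth$dim[2]
    fr <- min(config$frame_rows, nr)
    fc <- min(config$frame_cols, nc)
    row_step <- max(1L, as.integer(round(fr * (1 - config$forward_overlap))))
    col_step <- max(1L, as.integer(round(fc * (1 - config$sidelap))))
    row_offs <- unique(c(seq(0L, nr - fr, by = row_step), nr - fr))
    col_offs <- unique(c(seq(0L, nc - fc, by = col_step), nc - fc))
    n_swaths <- length(col_offs)
    if (is.null(offsets)) {
      offsets <- c(0, stats::rnorm(n_swaths - 1, 0, config$swath_offset_sd))
    }
    if (length(offsets) != n_swaths) {
      stop(sprintf("need %d per-swath offsets, got %d", n_swaths,
                   length(offsets)))
    }
    stacks <- vector("list", n_swaths)
    for (s in seq_len(n_swaths)) {
      frames <- vector("list", length(row_offs))
      for (k in seq_along(row_offs)) {
        ri <- (row_offs[k] + 1L):(row_offs[k] + fr)
        ci <- (col_offs[s] + 1L):(col_offs[s] + fc)
        v <- truth$temp_true[ri, ci] + offsets[s]
        if (noise_temp > 0) v <- v + stats::rnorm(fr * fc, 0, noise_temp)
        frames[[k]] <- swath_frame(v, row_offs[k], col_offs[s],
                                   acquisition_index = k)
      }
      stacks[[s]] <- swath_stack(frames, c(nr, nc), swath_index = s)
    }
    list(stacks = stacks, offsets = offsets, truth = truth,
         georef = georef(0, 0, config$gsd_tir))
  })
}

#' Per-plant ground-truth table
#'
#' Flattens the scene truth into a table suitable for joining against
#' pipeline outputs by `plant_id`.
#'
#' @param truth The `truth` element of [generate_scene()].
#' @return Data frame: `plant_id`, `plot_id`, `treatment`, `accession_id`,
#'   `true_dtp`, `senesced`, `declining`.
#' @export
truth_report <- function(truth) {
  truth$plants[, c("plant_id", "plot_id", "treatment", "accession_id",
                   "true_dtp", "senesced", "declining")]
}
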