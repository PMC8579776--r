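# Canopy-air temperature deviation and the crop water stress index under
# three baseline schemes: empirical (VPD regression), theoretical (energy
# balance lower limit), and simplified statistical (scene-derived).

#' Canopy-air temperature deviation
#'
#' `dtp = tp - ta`, the raw thermal stress signal: transpiring canopies sit
#' below air temperature or only slightly above; stomatal closure raises it.
#'
#' @param tp Plant temperature, degC.
#' @param ta Air temperature, degC.
#' @return Temperature deviation, degC.
#' @export
dtp <- function(tp, ta) {
  if (any(!is.finite(tp)) || any(!is.finite(ta))) stop("inputs must be finite")
  tp - ta
}

#' Baseline pair for the crop water stress index
#'
#' @param dt_ll Lower limit (fully transpiring canopy), degC.
#' @param dt_ul Upper limit (transpiration halted), degC. Must exceed
#'   `dt_ll`.
#' @param method One of `"statistical"`, `"empirical"`, `"theoretical"`.
#' @return List of class `cwsi_baselines`.
#' @export
cwsi_baselines <- function(dt_ll, dt_ul,
                           method = c("statistical", "empirical", "theoretical")) {
  method <- match.arg(method)
  if (!is.finite(dt_ll) || !is.finite(dt_ul)) stop("baselines must be finite")
  if (dt_ul <= dt_ll) stop("invalid baselines: dt_ul must exceed dt_ll")
  structure(list(dt_ll = dt_ll, dt_ul = dt_ul, method = method),
            class = "cwsi_baselines")
}

#' Crop water stress index
#'
#' Positions the observed canopy-air deviation between the transpiring
#' lower limit and the non-transpiring upper limit:
#' \deqn{CWSI = \frac{dT_p - dT_{LL}}{dT_{UL} - dT_{LL}}}
#' The value is deliberately *not* clipped to \[0, 1\]: values below zero
#' mark canopies cooler than the lower baseline, values above one canopies
#' hotter than the non-transpiring limit.
#'
#' @param dtp_c Canopy-air deviation, degC (vectorized).
#' @param baselines A [cwsi_baselines()] object.
#' @return Unitless index.
#' @export
cwsi <- function(dtp_c, baselines) {
  stopifnot(inherits(baselines, "cwsi_baselines"))
  (dtp_c - baselines$dt_ll) / (baselines$dt_ul - baselines$dt_ll)
}

#' Simplified statistical baselines from the scene itself
#'
#' The lower limit is anchored on the coolest plants present: the mean of
#' the lowest 5% (by count, `m = ceiling(0.05 n)`) of plant mean
#' temperatures in the control plots, expressed as a deviation from air
#' temperature. The upper limit is the empirical non-transpiring ceiling
#' `ta + upper_offset` (9 degC by default), expressed as a deviation. Only
#' air temperature is needed beyond the imagery, but the scene must contain
#' both stressed and non-stressed plants.
#'
#' @param control_tp Mean plant temperatures of retained control plants,
#'   degC.
#' @param ta Flight-mean air temperature, degC.
#' @param upper_offset Upper-limit offset above `ta`, degC (default 9).
#' @param lower_fraction Fraction of coolest control plants defining the
#'   lower limit (default 0.05).
#' @return A [cwsi_baselines()] with `method = "statistical"`.
#' @export
statistical_baselines <- function(control_tp, ta, upper_offset = 9,
                                  lower_fraction = 0.05) {
  control_tp <- control_tp[is.finite(control_tp)]
  n <- length(control_tp)
  if (!n) stop("no retained control plants to anchor the lower baseline")
  m <- ceiling(lower_fraction * n)
  dt_ll <- mean(sort(control_tp)[seq_len(m)]) - ta
  if (dt_ll >= upper_offset) {
    stop("invalid baselines: coolest control plants reach the upper limit")
  }
  cwsi_baselines(dt_ll, upper_offset, method = "statistical")
}

#' Empirical (VPD-regression) lower limit
#'
#' The non-water-stressed baseline relates the canopy-air deviation of
#' fully transpiring plants linearly to vapor pressure deficit:
#' `dt_ll = intercept + slope * vpd`. Crop-specific intercept and slope
#' must be supplied (they come from season-long observations of unstressed
#' plants; none are bundled).
#'
#' @param vpd Vapor pressure deficit, kPa (>= 0).
#' @param intercept Intercept, degC.
#' @param slope Slope, degC per kPa (typically negative).
#' @return Lower limit, degC.
#' @export
empirical_lower_limit <- function(vpd, intercept, slope) {
  if (any(vpd < 0)) stop("vpd must be non-negative")
  if (!is.finite(intercept) || !is.finite(slope)) stop("parameters must be finite")
  intercept + slope * vpd
}

#' Theoretical (energy-balance) lower limit
#'
#' Energy-balance lower limit of the canopy-air deviation for a fully
#' transpiring canopy, in the standard aerodynamic form:
#' \deqn{dT_{LL} = \frac{r_a R_n}{C} \cdot \frac{\gamma}{\Delta + \gamma}
#'   - \frac{VPD}{\Delta + \gamma}}
#' with aerodynamic resistance `r_a`, net radiation `Rn`, volumetric heat
#' capacity of air `C`, psychrometric constant `gamma` and saturation-curve
#' slope `delta`. The matching theoretical upper limit needs aerodynamic
#' resistance under zero transpiration and is error-prone; the pipeline
#' instead pairs this lower limit with the empirical `ta + 9` ceiling, and
#' output metadata flags the expression as the package's documented form of
#' the energy-balance baseline.
#'
#' @param vpd Vapor pressure deficit, kPa.
#' @param rn Net radiation, W m^-2.
#' @param ra Aerodynamic resistance, s m^-1.
#' @param gamma Psychrometric constant, kPa degC^-1 (default 0.067).
#' @param delta Slope of the saturation vapor pressure curve at air
#'   temperature, kPa degC^-1 (see [svp_slope()]).
#' @param heat_capacity Volumetric heat capacity of air, J m^-3 degC^-1
#'   (default 1208).
#' @return Lower limit, degC.
#' @export
theoretical_lower_limit <- function(vpd, rn, ra, gamma = 0.067, delta,
                                    heat_capacity = 1208) {
  if (delta + gamma <= 0) stop("delta + gamma must be positive")
  if (ra <= 0 || heat_capacity <= 0) stop("ra and heat_capacity must be positive")
  (ra * rn / heat_capacity) * (gamma / (delta + gamma)) - vpd / (delta + gamma)
}

#' Per-plant stress indices
#'
#' Joins the per-plant temperature table with the flight weather and
#' computes `dtp` and the crop water stress index under the simplified
#' statistical scheme (always) and under the empirical and theoretical
#' schemes when their parameters are supplied.
#'
#' @param plants Per-plant table from [plant_temperatures()] (needs
#'   `mean_c`, `treatment`, `retained`).
#' @param ta Flight-mean air temperature, degC.
#' @param vpd Flight-mean VPD, kPa (needed for empirical/theoretical
#'   schemes).
#' @param upper_offset Non-transpiring ceiling above `ta`, degC (default 9).
#' @param empirical Optional list `(intercept, slope)` for the empirical
#'   scheme.
#' @param theoretical Optional list `(rn, ra, gamma, heat_capacity)` for the
#'   energy-balance scheme (`delta` derived from `ta` via [svp_slope()]
#'   unless supplied).
#' @param tp_stat Plant temperature statistic feeding the indices,
#'   `"mean"` (default) or `"median"`.
#' @return List: `records` (the table with `dtp_c`, `cwsi_s`, and `cwsi_e` /
#'   `cwsi_t` when enabled; non-retained plants get `NA`), `baselines`
#'   (named list of the [cwsi_baselines()] used), `notes` (character).
#' @export
stress_records <- function(plants, ta, vpd = NULL, upper_offset = 9,
                           empirical = NULL, theoretical = NULL,
                           tp_stat = c("mean", "median")) {
  tp_stat <- match.arg(tp_stat)
  tp <- if (tp_stat == "mean") plants$mean_c else plants$median_c
  use <- plants$retained & is.finite(tp)
  out <- plants
  out$tp_c <- tp
  out$dtp_c <- ifelse(use, tp - ta, NA_real_)
  notes <- character()
  ctrl <- tp[use & plants$treatment == "control"]
  bl <- list(statistical = statistical_baselines(ctrl, ta, upper_offset))
  out$cwsi_s <- ifelse(use, cwsi(out$dtp_c, bl$statistical), NA_real_)
  if (!is.null(empirical)) {
    if (is.null(vpd)) stop("empirical scheme needs the flight VPD")
    ll <- empirical_lower_limit(vpd, empirical$intercept, empirical$slope)
    bl$empirical <- cwsi_baselines(ll, upper_offset, method = "empirical")
    out$cwsi_e <- ifelse(use, cwsi(out$dtp_c, bl$empirical), NA_real_)
  } else {
    notes <- c(notes, "empirical baseline parameters not supplied; cwsi_e disabled")
  }
  if (!is.null(theoretical)) {
    if (is.null(vpd)) stop("theoretical scheme needs the flight VPD")
    delta <- if (!is.null(theoretical$delta)) theoretical$delta else svp_slope(ta)
    ll <- theoretical_lower_limit(
      vpd, rn = theoretical$rn, ra = theoretical$ra,
      gamma = if (is.null(theoretical$gamma)) 0.067 else theoretical$gamma,
      delta = delta,
      heat_capacity = if (is.null(theoretical$heat_capacity)) 1208
                      else theoretical$heat_capacity)
    bl$theoretical <- cwsi_baselines(ll, upper_offset, method = "theoretical")
    out$cwsi_t <- ifelse(use, cwsi(out$dtp_c, bl$theoretical), NA_real_)
  } else {
    notes <- c(notes, "theoretical baseline parameters not supplied; cwsi_t disabled")
  }
  list(records = out, baselines = bl, notes = notes)
}
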