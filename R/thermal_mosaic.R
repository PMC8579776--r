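# Thermal swath processing: radiometric calibration of raw frames, within-
# swath overlap averaging, between-swath additive drift normalization, and
# mosaic assembly. Frames are assumed already geo-placed on a common mosaic
# grid (photogrammetry is upstream); placement is an integer row/col offset.

#' Construct a swath frame
#'
#' One thermal frame placed on the mosaic grid. `row_off`/`col_off` are
#' 0-based offsets of the frame's top-left pixel on the mosaic.
#'
#' @param values Numeric matrix: calibrated temperature (degC) or raw sensor
#'   counts before [apply_ambient_calibration()].
#' @param row_off,col_off 0-based placement offsets on the mosaic grid.
#' @param acquisition_index Ordinal of the frame within its swath.
#' @return An object of class `swath_frame`.
#' @export
swath_frame <- function(values, row_off, col_off, acquisition_index = 1L) {
  stopifnot(is.matrix(values), row_off >= 0, col_off >= 0)
  structure(list(values = values, row_off = as.integer(row_off),
                 col_off = as.integer(col_off),
                 acquisition_index = as.integer(acquisition_index)),
            class = "swath_frame")
}

#' Construct a swath stack
#'
#' The ordered frames of one flight line. Consecutive frames are expected to
#' overlap heavily (forward overlap around 93% in a typical survey).
#'
#' @param frames List of [swath_frame()] objects, acquisition order.
#' @param mosaic_dim Integer `c(nrow, ncol)` of the common mosaic grid.
#' @param swath_index Ordinal of the swath within the flight.
#' @return An object of class `swath_stack`.
#' @export
swath_stack <- function(frames, mosaic_dim, swath_index = 1L) {
  if (!length(frames)) stop("a swath stack needs at least one frame")
  idx <- vapply(frames, function(f) f$acquisition_index, integer(1))
  if (any(diff(idx) <= 0)) stop("acquisition_index must be strictly increasing")
  d1 <- dim(frames[[1]]$values)
  for (f in frames) {
    if (!identical(dim(f$values), d1)) stop("frame dimensions differ within the swath")
    if (f$row_off + d1[1] > mosaic_dim[1] || f$col_off + d1[2] > mosaic_dim[2]) {
      stop("frame placement exceeds mosaic bounds")
    }
  }
  structure(list(frames = frames, mosaic_dim = as.integer(mosaic_dim),
                 swath_index = as.integer(swath_index)),
            class = "swath_stack")
}

#' Apply an ambient-temperature-dependent radiometric calibration
#'
#' Converts raw sensor counts to temperature per pixel with a supplied
#' per-pixel linear model `T(p) = c0(p) + c1(p) * raw(p) + c2(p) * ta_mean`.
#' The intercept map absorbs vignetting and fixed-pattern non-uniformity;
#' the ambient term removes the microbolometer's dependence on the air
#' temperature during the flight.
#'
#' @param raw_frame A [swath_frame()] of raw counts.
#' @param coeffs List with matrices `c0` (degC), `c1` (degC/count), `c2`
#'   (dimensionless), each congruent with the frame.
#' @param ta_mean Mean air temperature during the flight, degC.
#' @return A [swath_frame()] of calibrated temperatures.
#' @export
apply_ambient_calibration <- function(raw_frame, coeffs, ta_mean) {
  d <- dim(raw_frame$values)
  for (nm in c("c0", "c1", "c2")) {
    m <- coeffs[[nm]]
    if (is.null(m) || !identical(dim(m), d)) {
      stop("calibration coefficient '", nm, "' is missing or not congruent with the frame")
    }
  }
  if (!is.finite(ta_mean)) stop("ta_mean must be finite")
  swath_frame(coeffs$c0 + coeffs$c1 * raw_frame$values + coeffs$c2 * ta_mean,
              raw_frame$row_off, raw_frame$col_off, raw_frame$acquisition_index)
}

#' Average overlapping frames of one swath
#'
#' Because consecutive frames of a flight line are acquired near-
#' simultaneously, every mosaic pixel covered by several frames is set to
#' the arithmetic mean of all covering frame values; this suppresses
#' frame-to-frame sensor noise. Pixels covered by no frame are `NA`.
#'
#' @param stack A [swath_stack()].
#' @return A mosaic-sized numeric matrix (one swath strip), `NA` outside
#'   coverage.
#' @export
average_swath_overlap <- function(stack) {
  if (!inherits(stack, "swath_stack")) stop("stack must be a swath_stack")
  nr <- stack$mosaic_dim[1]; nc <- stack$mosaic_dim[2]
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0L, nr, nc)
  for (f in stack$frames) {
    d <- dim(f$values)
    ri <- (f$row_off + 1L):(f$row_off + d[1])
    ci <- (f$col_off + 1L):(f$col_off + d[2])
    v <- f$values
    ok <- !is.na(v)
    v[!ok] <- 0
    acc[ri, ci] <- acc[ri, ci] + v
    cnt[ri, ci] <- cnt[ri, ci] + ok
  }
  out <- acc / cnt
  out[cnt == 0L] <- NA
  out
}

#' Chain-normalize neighboring swath strips
#'
#' Uncooled thermal sensors drift over the minutes of a survey, so adjacent
#' flight lines show additive temperature offsets. Assuming the true scene
#' temperature difference in the sidelap overlap of neighboring swaths is
#' zero, each strip is shifted to agree with its (already corrected)
#' predecessor: the first strip anchors the chain; for strip i >= 2 the
#' offset is the mean (or median) of `strip_i - corrected_strip_(i-1)` over
#' shared valid pixels, and is subtracted from strip i.
#'
#' @param strips List of mosaic-sized strip matrices ([average_swath_overlap()]
#'   output), in flight order.
#' @param stat Overlap-difference statistic, `"mean"` (default) or `"median"`.
#' @return List with `strips` (corrected matrices) and `offsets` (numeric,
#'   cumulative correction applied to each strip; first is 0).
#' @export
chain_normalize_swaths <- function(strips, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (!length(strips)) stop("no strips to normalize")
  f <- if (stat == "mean") mean else stats::median
  offsets <- numeric(length(strips))
  out <- strips
  for (i in seq_along(strips)[-1]) {
    ov <- !is.na(out[[i - 1]]) & !is.na(strips[[i]])
    if (!any(ov)) {
      stop(sprintf("no overlap between swaths %d and %d: normalization chain broken",
                   i - 1, i))
    }
    offsets[i] <- f(strips[[i]][ov] - out[[i - 1]][ov])
    out[[i]] <- strips[[i]] - offsets[i]
  }
  list(strips = out, offsets = offsets)
}

#' Assemble corrected swath strips into a thermal orthomosaic
#'
#' Non-overlapping pixels are copied; sidelap pixels are averaged across the
#' contributing strips; pixels covered by no strip stay nodata.
#'
#' @param strips List of corrected strip matrices sharing the mosaic grid.
#' @param georef A [georef()] for the mosaic grid.
#' @return A [temperature_grid()].
#' @export
assemble_mosaic <- function(strips, georef = thermopheno::georef()) {
  if (!length(strips)) stop("no strips to assemble")
  d <- dim(strips[[1]])
  acc <- matrix(0, d[1], d[2])
  cnt <- matrix(0L, d[1], d[2])
  for (s in strips) {
    if (!identical(dim(s), d)) stop("strips do not share the mosaic grid")
    ok <- !is.na(s)
    s[!ok] <- 0
    acc <- acc + s
    cnt <- cnt + ok
  }
  v <- acc / cnt
  v[cnt == 0L] <- NA
  temperature_grid(v, georef)
}

#' Build a thermal orthomosaic from swath stacks
#'
#' Convenience wrapper running the full mosaic stage: per-swath overlap
#' averaging, between-swath chain normalization, and assembly.
#'
#' @param stacks List of [swath_stack()] objects in flight order.
#' @param georef A [georef()] for the mosaic grid.
#' @param stat Offset statistic passed to [chain_normalize_swaths()].
#' @return List with `mosaic` (a [temperature_grid()]) and `offsets`
#'   (per-swath corrections, degC).
#' @export
build_thermal_mosaic <- function(stacks, georef = thermopheno::georef(),
                                 stat = "mean") {
  strips <- lapply(stacks, average_swath_overlap)
  norm <- chain_normalize_swaths(strips, stat = stat)
  list(mosaic = assemble_mosaic(norm$strips, georef), offsets = norm$offsets)
}
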