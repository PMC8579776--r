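# Raster containers: plain matrices/arrays plus a pixel-center georeference.
# Row 1 is the northern edge; x grows with column, y shrinks with row.

#' Create a georeference
#'
#' A georeference anchors a raster grid to map coordinates. `origin_x` and
#' `origin_y` are the map coordinates of the *center* of the top-left pixel
#' (row 1, column 1); `gsd` is the ground sample distance in meters. Columns
#' advance east (+x), rows advance south (-y).
#'
#' @param origin_x,origin_y Map coordinates (m) of the center of pixel (1, 1).
#' @param gsd Ground sample distance in meters; must be positive.
#' @return A list of class `georef`.
#' @export
georef <- function(origin_x = 0, origin_y = 0, gsd = 0.015) {
  if (!is.finite(gsd) || gsd <= 0) stop("gsd must be a positive finite number")
  structure(list(origin_x = origin_x, origin_y = origin_y, gsd = gsd),
            class = "georef")
}

#' Single-band surface-temperature raster
#'
#' Wraps a numeric matrix of surface temperatures in degrees Celsius. Missing
#' coverage is stored as `NA` internally; the on-disk nodata marker is -9999.
#'
#' @param values Numeric matrix, degrees C; `NA` marks nodata.
#' @param georef A [georef()] object.
#' @return An object of class `temperature_grid`.
#' @export
temperature_grid <- function(values, georef = thermopheno::georef()) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (any(is.infinite(values))) stop("temperature values must be finite or NA")
  structure(list(values = values, georef = georef), class = "temperature_grid")
}

#' Three-band (red, green, blue) reflectance raster
#'
#' @param values Numeric array `[rows, cols, 3]` with bands in red, green,
#'   blue order; values in `[0, 1]` or `NA` for nodata.
#' @param georef A [georef()] object.
#' @return An object of class `reflectance_grid`.
#' @export
reflectance_grid <- function(values, georef = thermopheno::georef(gsd = 0.005)) {
  if (!is.array(values) || length(dim(values)) != 3L || dim(values)[3] != 3L) {
    stop("values must be a [rows, cols, 3] array")
  }
  rng <- range(values, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1)) {
    stop("reflectance values must lie in [0, 1] (or NA)")
  }
  structure(list(values = values, georef = georef), class = "reflectance_grid")
}

#' Single-band vegetation-index raster
#'
#' Holds the green-red vegetation index, GRVI = (green - red)/(green + red),
#' which is bounded in \[-1, 1\] wherever defined.
#'
#' @param values Numeric matrix in `[-1, 1]`, `NA` for nodata.
#' @param georef A [georef()] object.
#' @return An object of class `index_grid`.
#' @export
index_grid <- function(values, georef = thermopheno::georef()) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  ok <- values[is.finite(values)]
  if (length(ok) && (min(ok) < -1 - 1e-12 || max(ok) > 1 + 1e-12)) {
    stop("index values must lie in [-1, 1]")
  }
  structure(list(values = values, georef = georef), class = "index_grid")
}

#' @export
dim.temperature_grid <- function(x) dim(x$values)
#' @export
dim.reflectance_grid <- function(x) dim(x$values)
#' @export
dim.index_grid <- function(x) dim(x$values)

#' @export
print.temperature_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("temperature_grid: %d x %d px, gsd %.4g m, %d nodata px\n",
              d[1], d[2], x$georef$gsd, sum(is.na(x$values))))
  invisible(x)
}

#' @export
print.reflectance_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("reflectance_grid: %d x %d px x 3 bands, gsd %.4g m\n",
              d[1], d[2], x$georef$gsd))
  invisible(x)
}

# Map coordinates of every pixel center along one axis.
pixel_centers_x <- function(g, ncol) g$origin_x + (seq_len(ncol) - 1) * g$gsd
pixel_centers_y <- function(g, nrow) g$origin_y - (seq_len(nrow) - 1) * g$gsd

NODATA <- -9999

write_georef_sidecar <- function(georef, path, extra = list()) {
  meta <- c(list(origin_x = georef$origin_x, origin_y = georef$origin_y,
                 gsd = georef$gsd, nodata = NODATA,
                 convention = "pixel-center, row 1 north"), extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
}

read_georef_sidecar <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  list(georef = georef(meta$origin_x, meta$origin_y, meta$gsd), meta = meta)
}

# The tiff package stores samples scaled to [0, 1]; physical values are
# written through an affine encoding (value = stored * scale + offset)
# recorded in the sidecar. Nodata is stored as 0; valid data occupy
# [0.5, 1], so the two never collide.
write_raster_tiff <- function(values, path, georef, extra = list()) {
  fin <- is.finite(values)
  vmin <- if (any(fin)) min(values[fin]) else 0
  vmax <- if (any(fin)) max(values[fin]) else 1
  scale <- if (vmax > vmin) 2 * (vmax - vmin) else 1
  offset <- vmin - 0.5 * scale
  enc <- pmin(pmax((values - offset) / scale, 0), 1)
  enc[!fin] <- 0
  tiff::writeTIFF(enc, path, bits.per.sample = 32, reduce = FALSE)
  write_georef_sidecar(georef, path,
                       c(list(scale = scale, offset = offset), extra))
  invisible(path)
}

read_raster_tiff <- function(path) {
  enc <- tiff::readTIFF(path)
  sc <- read_georef_sidecar(path)
  v <- enc * sc$meta$scale + sc$meta$offset
  v[enc < 0.25] <- NA
  list(values = v, georef = sc$georef, meta = sc$meta)
}

#' Write a temperature grid to disk
#'
#' Writes a single-band 32-bit TIFF in degrees C with a JSON sidecar
#' (`<path>.json`) holding the georeference and the affine value encoding;
#' nodata pixels are preserved.
#'
#' @param grid A [temperature_grid()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_temperature_tiff <- function(grid, path) {
  stopifnot(inherits(grid, "temperature_grid"))
  write_raster_tiff(grid$values, path, grid$georef, list(units = "degC"))
}

#' Read a temperature grid written by [write_temperature_tiff()]
#'
#' @param path TIFF path (a `<path>.json` sidecar must exist).
#' @return A [temperature_grid()].
#' @export
read_temperature_tiff <- function(path) {
  r <- read_raster_tiff(path)
  v <- r$values
  if (length(dim(v)) == 3L) v <- v[, , 1]
  temperature_grid(v, r$georef)
}

#' Write a reflectance grid to disk
#'
#' Writes a 3-band TIFF (red, green, blue reflectance) with a JSON
#' georeference sidecar.
#'
#' @param grid A [reflectance_grid()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_reflectance_tiff <- function(grid, path) {
  stopifnot(inherits(grid, "reflectance_grid"))
  write_raster_tiff(grid$values, path, grid$georef,
                    list(bands = c("red", "green", "blue")))
}

#' Read a reflectance grid written by [write_reflectance_tiff()]
#'
#' @param path TIFF path (a `<path>.json` sidecar must exist).
#' @return A [reflectance_grid()].
#' @export
read_reflectance_tiff <- function(path) {
  r <- read_raster_tiff(path)
  # the affine encoding can overshoot [0, 1] by float rounding
  v <- pmin(pmax(r$values, 0), 1)
  reflectance_grid(v, r$georef)
}

# Congruence check used by grid-to-grid operations.
check_congruent <- function(a, b, what = "grids") {
  da <- dim(a$values); db <- dim(b$values)
  if (da[1] != db[1] || da[2] != db[2]) {
    stop(sprintf("%s are not congruent: %dx%d vs %dx%d",
                 what, da[1], da[2], db[1], db[2]))
  }
  invisible(TRUE)
}
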