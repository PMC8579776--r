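# Per-plant temperature retrieval: delineations, zonal statistics over the
# vegetation mask, and the sparse/dead-plant retention rule.

#' Construct plant delineations
#'
#' Plant extents come from an object-based segmentation of the RGB
#' orthomosaic (performed upstream) and are represented as an integer label
#' raster on the thermal grid (0 = no plant, otherwise the plant id) plus an
#' attribute table.
#'
#' @param labels Integer matrix on the thermal grid; 0 outside plants.
#' @param attrs Data frame with columns `plant_id`, `plot_id`, `treatment`
#'   (`"control"` or `"salt"`), `accession_id`.
#' @return Object of class `plant_delineations`.
#' @export
plant_delineations <- function(labels, attrs) {
  stopifnot(is.matrix(labels))
  need <- c("plant_id", "plot_id", "treatment", "accession_id")
  miss <- setdiff(need, names(attrs))
  if (length(miss)) stop("attrs missing columns: ", paste(miss, collapse = ", "))
  ids <- setdiff(unique(as.vector(labels)), 0L)
  unknown <- setdiff(ids, attrs$plant_id)
  if (length(unknown)) {
    stop("label raster contains plant ids absent from attrs: ",
         paste(utils::head(unknown), collapse = ", "))
  }
  if (!all(attrs$treatment %in% c("control", "salt"))) {
    stop("treatment must be 'control' or 'salt'")
  }
  structure(list(labels = labels, attrs = attrs), class = "plant_delineations")
}

#' Read delineations from a label TIFF and attribute CSV
#'
#' @param label_path Single-band integer TIFF written with the package's
#'   sidecar convention (ids as float values).
#' @param attrs_path CSV with `plant_id`, `plot_id`, `treatment`,
#'   `accession_id`.
#' @return A [plant_delineations()] object.
#' @export
read_delineations <- function(label_path, attrs_path) {
  r <- read_raster_tiff(label_path)
  v <- r$values
  if (length(dim(v)) == 3L) v <- v[, , 1]
  v[is.na(v)] <- 0
  labels <- matrix(as.integer(round(v)), nrow(v), ncol(v))
  attrs <- utils::read.csv(attrs_path, stringsAsFactors = FALSE)
  plant_delineations(labels, attrs)
}

#' Write delineations (label TIFF + attribute CSV)
#'
#' @param delins A [plant_delineations()] object.
#' @param label_path,attrs_path Output paths.
#' @param georef Georeference for the label raster sidecar.
#' @return `label_path`, invisibly.
#' @export
write_delineations <- function(delins, label_path, attrs_path,
                               georef = thermopheno::georef()) {
  write_raster_tiff(delins$labels / 1, label_path, georef,
                    list(content = "plant labels"))
  utils::write.csv(delins$attrs, attrs_path, row.names = FALSE)
  invisible(label_path)
}

#' Rasterize polygon delineations (GeoJSON) onto a grid
#'
#' Reads a GeoJSON FeatureCollection of plant polygons (properties
#' `plant_id`, `plot_id`, `treatment`, `accession_id`) and burns each
#' polygon into an integer label raster using an even-odd point-in-polygon
#' test on pixel centers.
#'
#' @param path GeoJSON file.
#' @param georef Target grid [georef()].
#' @param dim Integer `c(nrow, ncol)` of the target grid.
#' @return A [plant_delineations()] object.
#' @export
read_delineations_geojson <- function(path, georef, dim) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  labels <- matrix(0L, dim[1], dim[2])
  xs <- pixel_centers_x(georef, dim[2])
  ys <- pixel_centers_y(georef, dim[1])
  rows <- lapply(gj$features, function(ft) {
    pr <- ft$properties
    ring <- ft$geometry$coordinates[[1]]
    px <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    py <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    # restrict the scan to the polygon's bounding box
    ci <- which(xs >= min(px) - georef$gsd & xs <= max(px) + georef$gsd)
    ri <- which(ys >= min(py) - georef$gsd & ys <= max(py) + georef$gsd)
    for (r in ri) for (cc in ci) {
      if (point_in_polygon(xs[cc], ys[r], px, py)) {
        labels[r, cc] <<- as.integer(pr$plant_id)
      }
    }
    data.frame(plant_id = as.integer(pr$plant_id),
               plot_id = as.character(pr$plot_id),
               treatment = as.character(pr$treatment),
               accession_id = as.character(pr$accession_id),
               stringsAsFactors = FALSE)
  })
  plant_delineations(labels, do.call(rbind, rows))
}

# Even-odd ray casting; vertices px/py (closed or open ring).
point_in_polygon <- function(x, y, px, py) {
  n <- length(px)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((py[i] > y) != (py[j] > y)) {
      xint <- px[i] + (y - py[i]) / (py[j] - py[i]) * (px[j] - px[i])
      if (x < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Zonal temperature statistics for one plant
#'
#' Descriptive statistics of surface temperature over the pixels of one
#' delineation that carry the `vegetation` class in the mask: minimum,
#' maximum, mean, median, standard deviation and pixel count. An empty
#' vegetation set yields `NA` statistics and `retained = FALSE`.
#'
#' @param pix Integer matrix or two-column row/col index of the plant's
#'   delineation pixels, or a logical matrix selecting them.
#' @param class_map Integer class-code matrix from [vegetation_mask()].
#' @param temp A [temperature_grid()] congruent with `class_map`.
#' @param sd_type `"population"` (divide by n, the raster-zonal default) or
#'   `"sample"`.
#' @return One-row data frame: `min_c`, `max_c`, `mean_c`, `median_c`,
#'   `sd_c`, `pixel_count`, `original_count`, `nodata_only`.
#' @export
zonal_stats <- function(pix, class_map, temp,
                        sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (is.logical(pix)) pix <- which(pix, arr.ind = TRUE)
  if (!nrow(pix)) stop("empty delineation")
  d <- dim(class_map)
  if (any(pix[, 1] < 1 | pix[, 1] > d[1] | pix[, 2] < 1 | pix[, 2] > d[2])) {
    stop("delineation extends outside the raster")
  }
  cls <- class_map[pix]
  tv <- temp$values[pix]
  veg <- cls == CLASS_CODES[["vegetation"]] & !is.na(tv)
  vals <- tv[veg]
  n <- length(vals)
  if (n == 0L) {
    return(data.frame(min_c = NA_real_, max_c = NA_real_, mean_c = NA_real_,
                      median_c = NA_real_, sd_c = NA_real_, pixel_count = 0L,
                      original_count = nrow(pix),
                      nodata_only = all(is.na(tv))))
  }
  sdv <- if (n == 1L) 0 else {
    s <- stats::sd(vals)
    if (sd_type == "population") s * sqrt((n - 1) / n) else s
  }
  data.frame(min_c = min(vals), max_c = max(vals), mean_c = mean(vals),
             median_c = stats::median(vals), sd_c = sdv, pixel_count = n,
             original_count = nrow(pix), nodata_only = FALSE)
}

#' Sparse/dead-plant retention rule
#'
#' A plant whose final vegetation mask keeps fewer than `min_fraction` of
#' its delineated pixels is assumed dead or too sparse for reliable
#' temperature retrieval and is dropped from further analysis. The boundary
#' is retained: exactly `min_fraction` passes.
#'
#' @param pixel_count Vegetation pixels surviving the mask.
#' @param original_count Pixels in the original delineation (> 0).
#' @param min_fraction Minimum retained fraction (default 0.10).
#' @return Logical: keep the plant?
#' @export
retention_filter <- function(pixel_count, original_count, min_fraction = 0.10) {
  if (any(original_count <= 0)) stop("original_count must be positive")
  pixel_count >= min_fraction * original_count
}

#' Per-plant temperature table over a whole scene
#'
#' Runs tag removal, zonal statistics and the retention rule for every
#' delineated plant and returns one row per plant.
#'
#' @param delins A [plant_delineations()] object (labels on the thermal grid).
#' @param rgb A [reflectance_grid()] resampled to the thermal grid.
#' @param temp A [temperature_grid()].
#' @param ta Flight-mean air temperature, degC.
#' @param grvi_threshold GRVI decision boundary (default 0).
#' @param max_offset Vegetation temperature ceiling above `ta` (default 9).
#' @param tag_percentile Per-plant blue percentile for tag removal
#'   (default 99.5).
#' @param min_fraction Retention threshold (default 0.10).
#' @param sd_type Standard-deviation convention for [zonal_stats()].
#' @return List: `plants` (data frame, one row per plant with ids,
#'   statistics, `retained`, `reason`), `class_map` (integer matrix with tag
#'   pixels marked), `grvi` (the [index_grid()]).
#' @export
plant_temperatures <- function(delins, rgb, temp, ta,
                               grvi_threshold = 0, max_offset = 9,
                               tag_percentile = 99.5, min_fraction = 0.10,
                               sd_type = "population") {
  check_congruent(list(values = delins$labels), temp, "labels and temperature")
  grvi <- compute_grvi(rgb)
  class_map <- vegetation_mask(grvi, temp, ta, max_offset = max_offset,
                               grvi_threshold = grvi_threshold)
  blue <- rgb$values[, , 3]
  attrs <- delins$attrs
  # pixel lists per plant from the label raster
  lab_v <- as.vector(delins$labels)
  inplant <- which(lab_v != 0L)
  by_plant <- split(inplant, lab_v[inplant])
  nrow_g <- nrow(delins$labels)
  rows <- vector("list", nrow(attrs))
  for (i in seq_len(nrow(attrs))) {
    id <- attrs$plant_id[i]
    lin <- by_plant[[as.character(id)]]
    if (is.null(lin)) {
      rows[[i]] <- data.frame(min_c = NA_real_, max_c = NA_real_,
                              mean_c = NA_real_, median_c = NA_real_,
                              sd_c = NA_real_, pixel_count = 0L,
                              original_count = 0L, nodata_only = FALSE,
                              retained = FALSE, reason = "no_delineation")
      next
    }
    pix <- cbind((lin - 1L) %% nrow_g + 1L, (lin - 1L) %/% nrow_g + 1L)
    keep <- remove_tag_pixels(blue[pix], percentile = tag_percentile)
    tag_pix <- pix[!keep, , drop = FALSE]
    if (nrow(tag_pix)) class_map[tag_pix] <- CLASS_CODES[["tag"]]
    st <- zonal_stats(pix[keep, , drop = FALSE], class_map, temp,
                      sd_type = sd_type)
    st$original_count <- nrow(pix)  # retention is relative to the full delineation
    retained <- !st$nodata_only && st$pixel_count > 0 &&
      retention_filter(st$pixel_count, st$original_count, min_fraction)
    st$retained <- retained
    st$reason <- if (retained) "ok" else if (st$nodata_only) "nodata" else "sparse"
    rows[[i]] <- st
  }
  plants <- cbind(attrs, do.call(rbind, rows))
  rownames(plants) <- NULL
  list(plants = plants, class_map = class_map, grvi = grvi)
}
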