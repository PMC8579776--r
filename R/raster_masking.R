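# Vegetation/background separation on the thermal grid: nearest-neighbor
# resampling of RGB, GRVI, white-tag removal, GRVI thresholding (fixed or
# 2-means), the Ta+9 degC mixed-pixel ceiling, and sunlit/shaded splitting.

# Integer codes used in class maps.
CLASS_CODES <- c(nodata = 0L, background = 1L, vegetation = 2L, tag = 3L,
                 overtemp = 4L)

#' Pixel class codes
#'
#' Integer coding of the per-pixel classes written to class-map rasters:
#' 0 nodata, 1 background (soil / non-photosynthetic), 2 vegetation,
#' 3 tag, 4 overtemp (positive GRVI but warmer than the vegetation ceiling).
#'
#' @return Named integer vector.
#' @export
pixel_class_codes <- function() CLASS_CODES

#' Nearest-neighbor resampling onto a target grid
#'
#' Each target pixel takes the value of the source pixel whose center is
#' nearest to the target pixel center; target pixels falling outside the
#' source extent become nodata. Used to bring the fine RGB orthomosaic onto
#' the coarser thermal grid so both can be indexed per thermal pixel.
#'
#' @param fine A [reflectance_grid()] (the finer source).
#' @param target_georef A [georef()] of the target (thermal) grid.
#' @param target_dim Integer `c(nrow, ncol)` of the target grid.
#' @return A [reflectance_grid()] on the target grid.
#' @export
resample_nearest <- function(fine, target_georef, target_dim) {
  sv <- fine$values
  sg <- fine$georef
  nr <- target_dim[1]; nc <- target_dim[2]
  tx <- pixel_centers_x(target_georef, nc)
  ty <- pixel_centers_y(target_georef, nr)
  # nearest source index per target center
  sc <- round((tx - sg$origin_x) / sg$gsd) + 1
  sr <- round((sg$origin_y - ty) / sg$gsd) + 1
  cok <- sc >= 1 & sc <= dim(sv)[2]
  rok <- sr >= 1 & sr <= dim(sv)[1]
  if (!any(cok) || !any(rok)) stop("target grid is disjoint from the source extent")
  out <- array(NA_real_, c(nr, nc, 3))
  for (b in 1:3) {
    band <- sv[, , b]
    block <- matrix(NA_real_, nr, nc)
    block[rok, cok] <- band[sr[rok], sc[cok]]
    out[, , b] <- block
  }
  reflectance_grid(out, target_georef)
}

#' Green-red vegetation index
#'
#' `GRVI = (green - red) / (green + red)`. Photosynthetic vegetation has
#' positive GRVI; sandy soil and senesced material sit near or below zero.
#' Pixels where `green + red = 0` (or either band is nodata) are nodata.
#'
#' @param rgb A [reflectance_grid()].
#' @return An [index_grid()] on the same grid.
#' @export
compute_grvi <- function(rgb) {
  d <- dim(rgb$values)
  g <- matrix(rgb$values[, , 2], d[1], d[2])
  r <- matrix(rgb$values[, , 1], d[1], d[2])
  s <- g + r
  v <- (g - r) / s
  v[!is.na(s) & s == 0] <- NA
  index_grid(v, rgb$georef)
}

#' Remove white-tag pixels from a plant's pixel set
#'
#' Field plants carry white identification tags that are much brighter in
#' blue than foliage. Within each delineated plant, pixels whose blue
#' reflectance strictly exceeds the plant's `percentile`-th percentile
#' (type-7 linear-interpolation order statistic) are flagged as tag pixels
#' and excluded from temperature retrieval.
#'
#' @param blue Numeric vector of blue reflectance for the plant's pixels.
#' @param percentile Percentile cut, default 99.5.
#' @return Logical vector, `TRUE` where the pixel is kept (not a tag).
#' @export
remove_tag_pixels <- function(blue, percentile = 99.5) {
  if (!length(blue)) stop("empty pixel set")
  thr <- stats::quantile(blue, percentile / 100, na.rm = TRUE, names = FALSE,
                         type = 7)
  is.na(blue) | blue <= thr
}

#' Exact 1-D k-means by sorted-split enumeration
#'
#' In one dimension, optimal k-means clusters are contiguous in sorted
#' order; for `k = 2` the global optimum is found by scanning all n-1
#' splits of the sorted values and minimizing the within-cluster sum of
#' squares. Serves as the exact reference for the iterative clustering.
#'
#' @param x Numeric vector with at least 2 distinct values.
#' @return List: `split` (last index of the low cluster in sorted order),
#'   `centers` (low, high), `wss` (optimal within-cluster sum of squares),
#'   `assignment` (1 = low, 2 = high, in the order of `x`).
#' @export
kmeans_1d_exact <- function(x) {
  x <- as.numeric(x)
  if (length(unique(x)) < 2) stop("need at least 2 distinct values")
  o <- order(x)
  s <- x[o]
  n <- length(s)
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  i <- seq_len(n - 1)
  # within-cluster SS of {1..i} and {i+1..n} via prefix sums
  w_lo <- cs2[i] - cs[i]^2 / i
  w_hi <- (cs2[n] - cs2[i]) - (cs[n] - cs[i])^2 / (n - i)
  wss <- w_lo + w_hi
  best <- which.min(wss)
  assign_sorted <- rep(2L, n)
  assign_sorted[seq_len(best)] <- 1L
  assignment <- integer(n)
  assignment[o] <- assign_sorted
  list(split = best,
       centers = c(cs[best] / best, (cs[n] - cs[best]) / (n - best)),
       wss = wss[best],
       assignment = assignment)
}

#' GRVI vegetation/background threshold by 2-cluster k-means
#'
#' Clusters the GRVI values found inside plant delineations into two groups
#' (vegetation vs soil background) and returns the decision boundary: the
#' midpoint between the largest GRVI of the low cluster and the smallest
#' GRVI of the high cluster. Values above the boundary are classed
#' vegetation. The boundary can go negative in scenes with much senesced
#' material.
#'
#' @param grvi Numeric vector of GRVI values inside plant delineations.
#' @param seed Integer seed controlling the restarts of the iterative
#'   clustering.
#' @param method `"iterative"` (default; 10 restarts, 300 iterations, via
#'   [stats::kmeans()]) or `"exact"` (sorted-split global optimum).
#' @return List: `threshold`, `centers` (sorted), `wss`, `method`.
#' @export
kmeans_grvi_threshold <- function(grvi, seed = 1L, method = c("iterative", "exact")) {
  method <- match.arg(method)
  grvi <- grvi[is.finite(grvi)]
  if (length(unique(grvi)) < 2) stop("degenerate input: all GRVI values identical")
  if (method == "exact") {
    fit <- kmeans_1d_exact(grvi)
    lo_max <- max(grvi[fit$assignment == 1L])
    hi_min <- min(grvi[fit$assignment == 2L])
    return(list(threshold = (lo_max + hi_min) / 2, centers = fit$centers,
                wss = fit$wss, method = "exact"))
  }
  km <- with_local_seed(seed, stats::kmeans(grvi, centers = 2, nstart = 10,
                                            iter.max = 300))
  lo <- which.min(km$centers)
  lo_max <- max(grvi[km$cluster == lo])
  hi_min <- min(grvi[km$cluster != lo])
  list(threshold = (lo_max + hi_min) / 2,
       centers = sort(as.numeric(km$centers)),
       wss = sum(km$withinss), method = "iterative")
}

#' Final vegetation mask: GRVI threshold plus air-temperature ceiling
#'
#' A pixel is vegetation iff its GRVI strictly exceeds `grvi_threshold`
#' (default 0, the fixed threshold suited to multi-temporal comparison) and
#' its temperature does not exceed `ta + max_offset`. Positive-GRVI pixels
#' strictly warmer than the ceiling are mixed soil/canopy pixels or
#' misclassifications and are labeled `overtemp`; GRVI at or below the
#' threshold is `background`; nodata in either raster propagates.
#'
#' @param grvi An [index_grid()].
#' @param temp A congruent [temperature_grid()].
#' @param ta Flight-mean air temperature, degC.
#' @param max_offset Vegetation ceiling above `ta`, degC (default 9).
#' @param grvi_threshold Vegetation requires GRVI strictly above this
#'   (default 0; pass a [kmeans_grvi_threshold()] result for the adaptive
#'   variant).
#' @return Integer matrix of class codes (see [pixel_class_codes()]).
#' @export
vegetation_mask <- function(grvi, temp, ta, max_offset = 9, grvi_threshold = 0) {
  check_congruent(grvi, temp, "GRVI and temperature grids")
  g <- grvi$values
  t <- temp$values
  out <- matrix(CLASS_CODES[["nodata"]], nrow(g), ncol(g))
  known <- !is.na(g) & !is.na(t)
  out[known & g <= grvi_threshold] <- CLASS_CODES[["background"]]
  veg <- known & g > grvi_threshold
  out[veg & t > ta + max_offset] <- CLASS_CODES[["overtemp"]]
  out[veg & t <= ta + max_offset] <- CLASS_CODES[["vegetation"]]
  out
}

#' Split vegetation pixels into sunlit and shaded by blue reflectance
#'
#' Clusters the blue reflectance of vegetation pixels into `k` groups
#' (default 5). The cluster with the lowest center collects the darkest
#' (shaded) pixels; its maximum blue value is the threshold above which
#' vegetation is labeled sunlit.
#'
#' @param blue Numeric vector of blue reflectance over vegetation pixels.
#' @param k Number of clusters (default 5).
#' @param seed Integer seed for the clustering restarts.
#' @return List: `threshold`, `sunlit` (logical, same order as `blue`),
#'   `centers` (sorted).
#' @export
sunlit_shaded_split <- function(blue, k = 5, seed = 1L) {
  blue <- as.numeric(blue)
  ok <- is.finite(blue)
  if (length(unique(blue[ok])) < k) {
    stop("degenerate input: fewer than k distinct blue values")
  }
  km <- with_local_seed(seed, stats::kmeans(blue[ok], centers = k, nstart = 10,
                                            iter.max = 300))
  first <- which.min(km$centers)
  thr <- max(blue[ok][km$cluster == first])
  sunlit <- rep(NA, length(blue))
  sunlit[ok] <- blue[ok] > thr
  list(threshold = thr, sunlit = sunlit, centers = sort(as.numeric(km$centers)))
}

#' Elbow choice of the number of clusters
#'
#' Runs k-means for k = 1..`k_max`, records the within-cluster sum of
#' squares (inertia) curve, and returns the k of maximal curvature: the
#' largest second difference of log-inertia. The log scale makes the
#' criterion invariant to the units of the data; on the raw scale the
#' roughly geometric decay of inertia would always place the sharpest bend
#' at k = 2 regardless of structure.
#'
#' @param values Numeric vector to cluster.
#' @param k_max Largest k to try (default 10).
#' @param seed Integer seed.
#' @return List: `k` (chosen), `inertia` (length `k_max`).
#' @export
elbow_optimal_k <- function(values, k_max = 10, seed = 1L) {
  values <- values[is.finite(values)]
  if (length(unique(values)) <= k_max) {
    stop("degenerate input: need more distinct values than k_max")
  }
  inertia <- numeric(k_max)
  inertia[1] <- sum((values - mean(values))^2)
  for (k in 2:k_max) {
    km <- with_local_seed(seed + k, stats::kmeans(values, centers = k,
                                                  nstart = 10, iter.max = 300))
    inertia[k] <- sum(km$withinss)
  }
  if (k_max < 3) return(list(k = k_max, inertia = inertia))
  li <- log(inertia + 1e-12 * inertia[1])
  ks <- 2:(k_max - 1)
  curv <- li[ks - 1] - 2 * li[ks] + li[ks + 1]
  list(k = ks[which.max(curv)], inertia = inertia)
}

# Run an expression under a temporary RNG seed, restoring global RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
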