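# Shared fixtures: compact trial configurations and small oracles.

# A 60-plant trial (4 plots of 3 x 5) that renders in well under a second.
small_scene_config <- function(...) {
  scene_config(plant_rows = 3, plant_cols = 5, ...)
}

# Same layout with all stochastic pixel/reflectance noise switched off.
noise_free_config <- function(...) {
  small_scene_config(noise_refl = 0, noise_temp = 0, ...)
}

# Pixel-level F1 of predicted vegetation vs the generator truth.
vegetation_f1 <- function(pred_class_map, truth_class_map) {
  pred <- pred_class_map == pixel_class_codes()[["vegetation"]]
  truth <- truth_class_map == truth_class_codes()[["vegetation"]]
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

# Brute-force within-cluster sum of squares for a 1-D two-way split, by
# scanning every split of the sorted values with plain loops.
brute_force_two_means_wss <- function(x) {
  s <- sort(x)
  n <- length(s)
  best <- Inf
  for (i in 1:(n - 1)) {
    lo <- s[1:i]; hi <- s[(i + 1):n]
    w <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (w < best) best <- w
  }
  best
}
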