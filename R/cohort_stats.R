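# Treatment-level comparisons: two-sample t-tests, percentage differences,
# proportions above a stress threshold, and the dead-vs-healthy early-
# detection contrast.

#' Two-sample treatment comparison
#'
#' Independent two-sample t-test of a thermal index between control and
#' salt-treated cohorts (pooled across plots per treatment). Equal-variance
#' (Student) by default; Welch available. Also reports per-arm means and
#' medians and the percentage difference relative to the control mean.
#'
#' @param control,salt Numeric index values per retained plant in each arm
#'   (n >= 2 each).
#' @param alpha Significance level (default 0.01).
#' @param equal_variance Pooled-variance Student test if `TRUE` (default),
#'   Welch otherwise.
#' @param variable Label carried into the output row.
#' @return One-row data frame: `variable`, `n_control`, `n_salt`,
#'   `mean_control`, `mean_salt`, `median_control`, `median_salt`,
#'   `t_stat`, `p_value`, `significant`, `percent_difference`.
#' @export
treatment_ttest <- function(control, salt, alpha = 0.01,
                            equal_variance = TRUE, variable = "dtp_c") {
  control <- control[is.finite(control)]
  salt <- salt[is.finite(salt)]
  if (length(control) < 2 || length(salt) < 2) {
    stop("each arm needs at least 2 finite values")
  }
  tt <- stats::t.test(salt, control, var.equal = equal_variance)
  mc <- mean(control); ms <- mean(salt)
  data.frame(variable = variable,
             n_control = length(control), n_salt = length(salt),
             mean_control = mc, mean_salt = ms,
             median_control = stats::median(control),
             median_salt = stats::median(salt),
             t_stat = unname(tt$statistic), p_value = tt$p.value,
             significant = tt$p.value < alpha,
             percent_difference = if (mc != 0) percent_difference(mc, ms)
                                  else NA_real_,
             stringsAsFactors = FALSE)
}

#' Percentage difference of the treated arm relative to control
#'
#' `100 * (salt_mean - control_mean) / control_mean`.
#'
#' @param control_mean,salt_mean Arm means (control non-zero).
#' @return Percentage.
#' @export
percent_difference <- function(control_mean, salt_mean) {
  if (any(control_mean == 0)) stop("control mean of zero: percentage undefined")
  100 * (salt_mean - control_mean) / control_mean
}

#' Proportion of plants above a stress threshold
#'
#' Share of values strictly exceeding `threshold`, as a percentage. A crop
#' water stress index around 0.35 separates stressed from unstressed
#' tomato plants in the trial the defaults emulate.
#'
#' @param values Numeric vector (non-empty after removing non-finite).
#' @param threshold Strict cut (default 0.35).
#' @return Percentage in `[0, 100]`.
#' @export
proportion_above <- function(values, threshold = 0.35) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values")
  100 * sum(values > threshold) / length(values)
}

#' Early-detection contrast between later-dead and healthy plants
#'
#' Given stress-index records from an *early* flight and a later condition
#' assignment (plants observed dead or healthy weeks afterwards), reports
#' per-group sample size and median index for the four groups
#' control/salt x healthy/dead. Higher early medians in the later-dead
#' groups indicate the index flagged stress before it was visible.
#'
#' @param records Data frame with `plant_id`, `treatment`, and the index
#'   column named by `variable`.
#' @param assignment Data frame with `plant_id` and `condition`
#'   (`"healthy"` or `"dead"`).
#' @param variable Index column (default `"cwsi_s"`).
#' @return Data frame, one row per group: `treatment`, `condition`, `n`,
#'   `median_value`.
#' @export
condition_group_contrast <- function(records, assignment, variable = "cwsi_s") {
  if (!all(assignment$condition %in% c("healthy", "dead"))) {
    stop("condition must be 'healthy' or 'dead'")
  }
  m <- merge(records, assignment, by = "plant_id")
  grid <- expand.grid(treatment = c("control", "salt"),
                      condition = c("healthy", "dead"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    v <- m[[variable]][m$treatment == grid$treatment[i] &
                         m$condition == grid$condition[i]]
    v <- v[is.finite(v)]
    data.frame(treatment = grid$treatment[i], condition = grid$condition[i],
               n = length(v),
               median_value = if (length(v)) stats::median(v) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Treatment comparison table over several index columns
#'
#' Runs [treatment_ttest()] for each requested index column of a per-plant
#' stress-record table, using retained plants only.
#'
#' @param records Per-plant table from [stress_records()] (needs
#'   `treatment`, `retained`, and the index columns).
#' @param variables Columns to compare (defaults to `dtp_c` plus whichever
#'   CWSI columns are present).
#' @param alpha,equal_variance Passed to [treatment_ttest()].
#' @return Data frame, one row per variable.
#' @export
compare_treatments <- function(records, variables = NULL, alpha = 0.01,
                               equal_variance = TRUE) {
  if (is.null(variables)) {
    variables <- intersect(c("dtp_c", "cwsi_s", "cwsi_e", "cwsi_t"),
                           names(records))
  }
  keep <- records$retained
  rows <- lapply(variables, function(v) {
    treatment_ttest(records[[v]][keep & records$treatment == "control"],
                    records[[v]][keep & records$treatment == "salt"],
                    alpha = alpha, equal_variance = equal_variance,
                    variable = v)
  })
  do.call(rbind, rows)
}
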