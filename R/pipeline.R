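#' Flatten encoding results into the classification table
#'
#' @param results List of [classify_unit()] results.
#' @return Data frame with columns `unit_id`, `class_variable`,
#'   `direction`, `sign`, `best_lag_s`, `r`, `p` (one row per unit; the
#'   per-variable p of the class variable).
#' @export
classification_table <- function(results) {
  do.call(rbind, lapply(results, function(res) {
    cv <- res$class_variable
    p <- if (cv == "uncorrelated") NA_real_
         else res$table$p[res$table$variable == cv]
    data.frame(unit_id = res$unit_id, class_variable = cv,
               direction = if (cv == "uncorrelated") ""
                           else variable_direction(cv),
               sign = res$sign, best_lag_s = res$class_lag_s,
               r = res$class_r, p = p, stringsAsFactors = FALSE)
  }))
}

#' Analyze a session end to end
#'
#' Builds the kinematic set from tracking, bins each unit's spikes on the
#' same grid, classifies every unit by the two-step lag-optimized
#' cross-correlation, and assembles the population tables and tests.
#'
#' @param bundle A [session_bundle()].
#' @param bin_width Analysis bin width (s, default 0.030).
#' @param alpha Per-variable significance level (default 0.05).
#' @param max_lag_s Lag search half-width (s, default 0.5).
#' @param smoothing_window_bins Position smoothing window (default 3).
#' @param camera_mirrored_x Flip x before analysis (default FALSE).
#' @param min_bins Minimum jointly valid bins per correlation.
#' @param null `"pearson"` or `"shuffle"` (see [classify_unit()]).
#' @param cell_rule A [cell_class_rule()] for DA/non-DA annotation.
#' @param verbose Log per-unit progress to stderr.
#' @return List of class `session_analysis`: `results` (per-unit
#'   [classify_unit()] objects), `classifications` (data frame),
#'   `class_table` ([tabulate_classes()]), `population` (list with
#'   `lateralization`, `class_rate_anova`, `lag_asymmetry`, `counts`),
#'   `kinset`, `cell_types`.
#' @export
analyze_session <- function(bundle, bin_width = 0.030, alpha = 0.05,
                            max_lag_s = 0.5, smoothing_window_bins = 3,
                            camera_mirrored_x = FALSE, min_bins = 100,
                            null = "pearson",
                            cell_rule = cell_class_rule(),
                            verbose = FALSE) {
  stopifnot(inherits(bundle, "session_bundle"))
  kin <- build_kinematics(bundle$tracking, bin_width, smoothing_window_bins,
                          camera_mirrored_x)
  results <- lapply(bundle$units, function(u) {
    if (verbose) message("classifying unit ", u$unit_id)
    rate <- bin_rate(u, kin$grid_t, bin_width)
    classify_unit(rate, kin, alpha = alpha, max_lag_s = max_lag_s,
                  min_bins = min_bins, null = null)
  })
  classifications <- classification_table(results)
  ct <- tabulate_classes(results, bundle$units)
  pop <- list(counts = ct$counts,
              n_classified = ct$n_classified,
              n_uncorrelated = ct$n_uncorrelated,
              n_positive = ct$n_positive, n_negative = ct$n_negative)
  pop$lateralization <- tryCatch(lateralization_test(ct),
                                 error = function(e) conditionMessage(e))
  pop$class_rate_anova <- tryCatch(
    class_rate_anova(results, bundle$units, "direction"),
    error = function(e) conditionMessage(e))
  pop$lag_asymmetry <- lag_asymmetry_test(results)
  if (ct$n_classified == 0L) pop$note <- "no classified units"
  cell_types <- tryCatch({
    rates <- vapply(bundle$units, `[[`, numeric(1), "mean_rate")
    fwhm <- vapply(bundle$units, `[[`, numeric(1), "spike_width_fwhm")
    suppressWarnings(classify_cell_type(rates, fwhm, cell_rule))
  }, error = function(e) NULL)
  structure(list(results = results, classifications = classifications,
                 class_table = ct, population = pop, kinset = kin,
                 cell_types = cell_types),
            class = "session_analysis")
}

#' @export
print.session_analysis <- function(x, ...) {
  cat(sprintf("<session_analysis> %d units: %d classified, %d uncorrelated\n",
              nrow(x$classifications), x$class_table$n_classified,
              x$class_table$n_uncorrelated))
  print(x$class_table$counts)
  invisible(x)
}

#' Score classification against generator ground truth
#'
#' Compares recovered classes, signs and lags with the planted tuning of a
#' synthetic cohort. Scoring covers units whose planted target is one of
#' the eight kinematic components (position-coding GABA pseudo-units and
#' uncoupled units are excluded; for an all-uncoupled cohort the
#' accuracies are NA with a flag).
#'
#' @param classifications Data frame from [classification_table()] (or a
#'   `session_analysis`).
#' @param ground_truth Data frame from [generate_cohort()] (columns
#'   `unit_id`, `target`, `sign`, `lag_bins`).
#' @param bin_width Analysis bin width (s), to convert lags to bins.
#' @return List of class `recovery_score`: `n_units`, `n_scored`,
#'   `class_accuracy`, `sign_accuracy`, `lag_errors_bins` (per correctly
#'   classified unit), `median_lag_error_bins`, `flag`.
#' @export
recovery_score <- function(classifications, ground_truth,
                           bin_width = 0.030) {
  if (inherits(classifications, "session_analysis"))
    classifications <- classifications$classifications
  gt <- as.data.frame(ground_truth)
  m <- merge(classifications, gt, by = "unit_id")
  coupled <- m$target %in% kinematic_components()
  if (!any(coupled))
    return(structure(list(n_units = nrow(m), n_scored = 0L,
                          class_accuracy = NA_real_,
                          sign_accuracy = NA_real_,
                          lag_errors_bins = integer(0),
                          median_lag_error_bins = NA_real_,
                          flag = "no coupled units"),
                     class = "recovery_score"))
  mc <- m[coupled, ]
  class_ok <- mc$class_variable == mc$target
  planted_sign <- ifelse(mc$sign.y > 0, "positive", "negative")
  sign_ok <- mc$sign.x == planted_sign
  lag_err <- round(mc$best_lag_s[class_ok] / bin_width) -
    mc$lag_bins[class_ok]
  structure(list(n_units = nrow(m), n_scored = nrow(mc),
                 class_accuracy = mean(class_ok),
                 sign_accuracy = mean(sign_ok),
                 lag_errors_bins = lag_err,
                 median_lag_error_bins = stats::median(lag_err),
                 flag = "ok"),
            class = "recovery_score")
}

#' @export
print.recovery_score <- function(x, ...) {
  cat(sprintf(paste0("<recovery_score> %d/%d scored: class %.1f%%, ",
                     "sign %.1f%%, median |lag error| %s bins\n"),
              x$n_scored, x$n_units, 100 * x$class_accuracy,
              100 * x$sign_accuracy,
              format(x$median_lag_error_bins)))
  invisible(x)
}
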