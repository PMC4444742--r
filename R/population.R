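#' Tabulate unit classifications
#'
#' Builds the population class table: counts by quantity (velocity /
#' acceleration) x direction (up / down / left / right), counts of
#' positively vs negatively correlated units, the number of uncorrelated
#' units, and per-hemisphere counts of horizontally tuned units (used for
#' the lateralization test). Units without a hemisphere are counted under
#' `"unknown"` and excluded from lateralization.
#'
#' @param results List of [classify_unit()] results.
#' @param units List of matching [unit_recording()] objects (same ids), for
#'   hemisphere and rate metadata; optional.
#' @return An object of class `class_table`: `counts` (2 x 4 matrix),
#'   `n_uncorrelated`, `n_positive`, `n_negative`, `n_classified`, and
#'   `hemisphere` (a list with one hemisphere x {left,right}-preference
#'   table per quantity).
#' @export
tabulate_classes <- function(results, units = NULL) {
  dirs <- c("up", "down", "left", "right")
  counts <- matrix(0L, nrow = 2, ncol = 4,
                   dimnames = list(c("velocity", "acceleration"), dirs))
  n_unc <- 0L; n_pos <- 0L; n_neg <- 0L
  hemi <- lapply(c(velocity = "velocity", acceleration = "acceleration"),
                 function(q) matrix(0L, 2, 2,
                   dimnames = list(hemisphere = c("left", "right"),
                                   preferred = c("left", "right"))))
  hemis <- if (!is.null(units))
    stats::setNames(vapply(units, `[[`, character(1), "hemisphere"),
                    vapply(units, `[[`, character(1), "unit_id"))
  else character(0)
  for (res in results) {
    cv <- res$class_variable
    if (cv == "uncorrelated") { n_unc <- n_unc + 1L; next }
    q <- variable_quantity(cv); d <- variable_direction(cv)
    counts[q, d] <- counts[q, d] + 1L
    if (res$sign == "positive") n_pos <- n_pos + 1L else n_neg <- n_neg + 1L
    if (d %in% c("left", "right")) {
      h <- hemis[res$unit_id]
      if (!is.na(h) && h %in% c("left", "right"))
        hemi[[q]][h, d] <- hemi[[q]][h, d] + 1L
    }
  }
  structure(list(counts = counts, n_uncorrelated = n_unc,
                 n_positive = n_pos, n_negative = n_neg,
                 n_classified = n_pos + n_neg, hemisphere = hemi),
            class = "class_table")
}

#' @export
print.class_table <- function(x, ...) {
  cat("<class_table>\n")
  print(x$counts)
  cat(sprintf("classified %d (%d positive, %d negative), uncorrelated %d\n",
              x$n_classified, x$n_positive, x$n_negative, x$n_uncorrelated))
  invisible(x)
}

#' Pearson chi-square test for a 2x2 table
#'
#' Without continuity correction by default, matching the style of the
#' reported population statistics; Yates correction is available behind the
#' `correct` flag.
#'
#' @param tab 2x2 matrix of non-negative counts with all marginals > 0.
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return List: `chi2`, `df` (1), `p`.
#' @export
chi_square_2x2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("chi_square_2x2: 2x2 table required")
  if (any(tab < 0)) stop("chi_square_2x2: counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi_square_2x2: zero marginal")
  # asymptotic p by construction (matching the reported statistics); the
  # small-expected-count warning is therefore not informative here
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Lateralization of horizontally tuned units
#'
#' Tests, separately for velocity- and acceleration-classified units,
#' whether the preferred horizontal direction (left vs right) is
#' independent of the recording hemisphere. Contralateral organisation
#' (left nigra over-representing rightward units and vice versa) shows up
#' as a significant 2x2 chi-square.
#'
#' @param class_table A [tabulate_classes()] result.
#' @param correct Yates correction flag passed to [chi_square_2x2()].
#' @return Named list (`velocity`, `acceleration`); each element is either
#'   the [chi_square_2x2()] result plus the table, or the string
#'   `"insufficient"` when a marginal is empty.
#' @export
lateralization_test <- function(class_table, correct = FALSE) {
  stopifnot(inherits(class_table, "class_table"))
  lapply(class_table$hemisphere, function(tab) {
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      return("insufficient")
    c(chi_square_2x2(tab, correct = correct), list(table = tab))
  })
}

#' One-way ANOVA of firing rate across functional classes
#'
#' Compares mean firing rates across unit classes, either grouped by
#' preferred direction (4 groups) or by the class x sign combination (up to
#' 8 groups).
#'
#' @param results List of [classify_unit()] results.
#' @param units List of matching [unit_recording()] objects (for
#'   `mean_rate`).
#' @param grouping `"direction"` or `"class_sign"`.
#' @return List: `F`, `df1`, `df2`, `p`, `groups` (group sizes).
#' @export
class_rate_anova <- function(results, units,
                             grouping = c("direction", "class_sign")) {
  grouping <- match.arg(grouping)
  rates <- stats::setNames(vapply(units, `[[`, numeric(1), "mean_rate"),
                           vapply(units, `[[`, character(1), "unit_id"))
  grp <- character(0); val <- numeric(0)
  for (res in results) {
    if (res$class_variable == "uncorrelated") next
    g <- switch(grouping,
                direction = variable_direction(res$class_variable),
                class_sign = paste(res$class_variable, res$sign, sep = ":"))
    r <- rates[res$unit_id]
    if (is.na(r)) next
    grp <- c(grp, g); val <- c(val, unname(r))
  }
  tabn <- table(grp)
  if (length(tabn) < 2L || sum(tabn >= 2L) < 2L)
    stop("class_rate_anova: need >= 2 groups with >= 2 units")
  # degenerate (zero-residual) inputs are handled by the zero-SS
  # convention below, so the perfect-fit warning carries no information
  fit <- suppressWarnings(stats::anova(stats::lm(val ~ factor(grp))))
  f <- fit$`F value`[1]; p <- fit$`Pr(>F)`[1]
  # zero between-group variation is F = 0 even when the residual is also
  # zero (degenerate identical-groups input)
  if (fit$`Sum Sq`[1] <= 1e-12 * max(1, sum(fit$`Sum Sq`))) { f <- 0; p <- 1 }
  list(F = f, df1 = fit$Df[1], df2 = fit$Df[2], p = p, groups = tabn)
}

#' Lag asymmetry between positively and negatively correlated units
#'
#' Negatively correlated (pause-like) units lag movement by more than
#' positively correlated (burst-like) units. Reports the mean and SEM of
#' the class lag per sign and a Welch t-test between the two groups.
#'
#' @param results List of [classify_unit()] results.
#' @param absolute Use |lag| (default TRUE).
#' @return List: `summary` (data.frame sign/n/mean_lag_s/sem_lag_s), `t`,
#'   `df`, `p`, `flag` (`"ok"`, `"degenerate"` or `"insufficient"`).
#' @export
lag_asymmetry_test <- function(results, absolute = TRUE) {
  sgn <- vapply(results, `[[`, character(1), "sign")
  lag <- vapply(results, `[[`, numeric(1), "class_lag_s")
  keep <- sgn %in% c("positive", "negative") & !is.na(lag)
  sgn <- sgn[keep]; lag <- lag[keep]
  if (absolute) lag <- abs(lag)
  sm <- do.call(rbind, lapply(c("positive", "negative"), function(s) {
    v <- lag[sgn == s]
    data.frame(sign = s, n = length(v),
               mean_lag_s = if (length(v)) mean(v) else NA_real_,
               sem_lag_s = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                           else NA_real_)
  }))
  if (any(sm$n < 2L))
    return(list(summary = sm, t = NA_real_, df = NA_real_, p = NA_real_,
                flag = "insufficient"))
  a <- lag[sgn == "positive"]; b <- lag[sgn == "negative"]
  w <- welch_or_flag(a, b)
  list(summary = sm, t = w$t, df = w$df, p = w$p,
       flag = if (w$degenerate) "degenerate" else "ok")
}

#' Valence comparison of correlation signs
#'
#' Chi-square test (2x2, no continuity correction) of whether the
#' proportion of positively vs negatively correlated units differs between
#' appetitive (sucrose) and aversive (air puff) sessions.
#'
#' @param results_appetitive,results_aversive Lists of [classify_unit()]
#'   results from the two session types.
#' @return [chi_square_2x2()] result plus the underlying table.
#' @export
valence_test <- function(results_appetitive, results_aversive) {
  count_signs <- function(results) {
    s <- vapply(results, `[[`, character(1), "sign")
    c(positive = sum(s == "positive"), negative = sum(s == "negative"))
  }
  tab <- rbind(appetitive = count_signs(results_appetitive),
               aversive = count_signs(results_aversive))
  c(chi_square_2x2(tab), list(table = tab))
}

#' Two-way ANOVA of stimulation-evoked kinematics
#'
#' Fixed-effects two-way ANOVA (genotype, stimulation frequency, and their
#' interaction) on session-level summaries of the movement evoked by
#' optogenetic stimulation trains.
#'
#' @param df Data frame with columns `genotype`, `frequency` and the
#'   response columns named in `responses` (session-level summaries, e.g.
#'   from averaging [stim_kinematics()] over a session's trains).
#' @param responses Character vector of response column names.
#' @return Named list (one per response); each element is a data.frame with
#'   rows genotype / frequency / interaction and columns `F`, `df1`, `df2`,
#'   `p`.
#' @export
stim_anova <- function(df, responses = c("peak_speed", "distance")) {
  df <- as.data.frame(df)
  if (length(unique(df$genotype)) < 2L || length(unique(df$frequency)) < 2L)
    stop("stim_anova: need >= 2 levels per factor")
  lapply(stats::setNames(responses, responses), function(resp) {
    fit <- suppressWarnings(stats::anova(stats::lm(
      df[[resp]] ~ factor(df$genotype) * factor(df$frequency))))
    f <- fit$`F value`[1:3]; p <- fit$`Pr(>F)`[1:3]
    zero <- fit$`Sum Sq`[1:3] <= 1e-12 * max(1, sum(fit$`Sum Sq`))
    f[zero] <- 0; p[zero] <- 1
    data.frame(term = c("genotype", "frequency", "interaction"),
               F = f, df1 = fit$Df[1:3], df2 = fit$Df[4],
               p = p, row.names = NULL)
  })
}
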