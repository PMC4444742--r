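rate_vec <- function(rate) {
  if (inherits(rate, "rate_series")) rate$rate else as.numeric(rate)
}

#' Evaluate and restore RNG state around a seeded computation
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Find the lag maximizing the rate/kinematics correlation
#'
#' Step one of the two-step encoding analysis: over integer lags
#' `l in [-L, +L]` bins, computes the Pearson correlation between
#' `rate[t]` and `kin[t + l*bin_width]` on the jointly valid overlap and
#' returns the lag maximizing `|r|`. Positive lag means the kinematic
#' signal follows the neural signal (the neuron leads the movement).
#'
#' Ties in `|r|` (within 1e-12, which also absorbs floating-point ties on
#' degenerate collinear signals) are broken toward the smallest `|l|`, then
#' toward the negative (neural-leading... see Details) member.
#'
#' @details The tie-break preference for negative `l` at equal `|l|` makes
#' the output deterministic; with the sign convention above a negative lag
#' means the movement precedes the neural signal, so ties at symmetric lags
#' resolve to the earlier-movement member only when `|r|` is exactly equal.
#'
#' @param rate A [bin_rate()] result or numeric vector on the grid.
#' @param kin Numeric kinematic series on the same grid.
#' @param bin_width Bin width (s).
#' @param max_lag_s Half-width of the symmetric lag search window (s);
#'   default 0.5 (observed neural-kinematic lags are tens to ~160 ms).
#' @param mask Logical vector of valid bins (TRUE = usable), or NULL.
#' @param min_bins Minimum jointly valid bins required (default 100).
#' @return List: `lag_s`, `r` (signed r at the best lag), `n` (overlap
#'   size there), `lags_s`, `r_by_lag` (the full scan), and `undefined`
#'   (TRUE when every lag had zero variance on its overlap).
#' @export
best_lag <- function(rate, kin, bin_width = 0.030, max_lag_s = 0.5,
                     mask = NULL, min_bins = 100) {
  r <- rate_vec(rate)
  kin <- as.numeric(kin)
  n <- length(r)
  if (length(kin) != n) stop("best_lag: rate and kin must share the grid")
  L <- round(max_lag_s / bin_width)
  if (L < 1) stop("best_lag: max_lag_s must cover at least one bin")
  valid <- if (is.null(mask)) rep(TRUE, n) else as.logical(mask)
  valid <- valid & is.finite(r) & is.finite(kin)
  if (sum(valid) < min_bins)
    stop(sprintf("best_lag: %d jointly valid bins < required %d",
                 sum(valid), min_bins))
  lags <- -L:L
  rs <- rep(NA_real_, length(lags))
  ns <- integer(length(lags))
  for (j in seq_along(lags)) {
    l <- lags[j]
    i <- max(1L, 1L - l):min(n, n - l)
    ok <- valid[i] & valid[i + l]
    a <- r[i][ok]; b <- kin[i + l][ok]
    ns[j] <- length(a)
    if (length(a) >= 3L && stats::sd(a) > 0 && stats::sd(b) > 0)
      rs[j] <- stats::cor(a, b)
  }
  if (all(is.na(rs)))
    return(list(lag_s = NA_real_, r = NA_real_, n = NA_integer_,
                lags_s = lags * bin_width, r_by_lag = rs, undefined = TRUE))
  amax <- max(abs(rs), na.rm = TRUE)
  cand <- which(!is.na(rs) & abs(rs) >= amax - 1e-12)
  cand <- cand[order(abs(lags[cand]), lags[cand])]
  j <- cand[1L]
  list(lag_s = lags[j] * bin_width, r = rs[j], n = ns[j],
       lags_s = lags * bin_width, r_by_lag = rs, undefined = FALSE)
}

#' Pearson correlation between lag-aligned series
#'
#' Step two of the encoding analysis: shifts the kinematic series by the
#' chosen lag, then computes the Pearson r on the jointly valid overlap and
#' a two-sided p-value from the t transform with n - 2 degrees of freedom.
#'
#' @inheritParams best_lag
#' @param lag_s Lag in seconds (a multiple of `bin_width`; positive =
#'   kinematics follows the neural signal).
#' @return List: `r`, `p`, `n`, `df`.
#' @export
shifted_pearson <- function(rate, kin, lag_s, bin_width = 0.030, mask = NULL) {
  r <- rate_vec(rate)
  kin <- as.numeric(kin)
  n <- length(r)
  if (length(kin) != n) stop("shifted_pearson: series must share the grid")
  l <- as.integer(round(lag_s / bin_width))
  valid <- if (is.null(mask)) rep(TRUE, n) else as.logical(mask)
  valid <- valid & is.finite(r) & is.finite(kin)
  i <- max(1L, 1L - l):min(n, n - l)
  ok <- valid[i] & valid[i + l]
  a <- r[i][ok]; b <- kin[i + l][ok]
  m <- length(a)
  if (m < 3L) stop("shifted_pearson: fewer than 3 overlapping valid bins")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, p = NA_real_, n = m, df = m - 2L))
  rv <- stats::cor(a, b)
  if (abs(rv) >= 1) {
    p <- 0
  } else {
    tstat <- rv * sqrt((m - 2) / (1 - rv^2))
    p <- 2 * stats::pt(-abs(tstat), df = m - 2)
  }
  list(r = rv, p = p, n = m, df = m - 2L)
}

#' Circular-shift null distribution of the best-lag |r|
#'
#' Optional honest-inference alternative to the parametric Pearson p:
#' circularly shifts the rate series by random offsets (preserving its
#' autocorrelation), re-runs the best-lag scan, and collects max |r|.
#'
#' @inheritParams best_lag
#' @param n_shuffles Number of circular shifts (default 500).
#' @param seed RNG seed.
#' @return Numeric vector of null max-|r| values, length `n_shuffles`.
#' @export
circular_shift_null <- function(rate, kin, bin_width = 0.030, max_lag_s = 0.5,
                                mask = NULL, min_bins = 100,
                                n_shuffles = 500, seed = 1) {
  r <- rate_vec(rate)
  n <- length(r)
  with_seed(seed, {
    offs <- sample.int(n - 1L, n_shuffles, replace = TRUE)
    vapply(offs, function(o) {
      shifted <- c(r[(o + 1L):n], r[1:o])
      bl <- best_lag(shifted, kin, bin_width, max_lag_s, mask, min_bins)
      if (bl$undefined) NA_real_ else abs(bl$r)
    }, numeric(1))
  })
}

variable_direction <- function(v) sub("^(vel|acc)_", "", v)
variable_quantity <- function(v)
  ifelse(grepl("^vel_", v), "velocity", "acceleration")
opposite_component <- function(v) {
  swaps <- c(up = "down", down = "up", left = "right", right = "left")
  paste0(sub("_.*$", "", v), "_", swaps[variable_direction(v)])
}

#' Classify a unit by its strongest significant kinematic correlate
#'
#' Runs [best_lag()] then [shifted_pearson()] for the unit's rate against
#' each of the eight rectified components over the entire session
#' (inter-trial intervals included, so the correlation is not driven by
#' event-locked structure alone). The unit's class is the component with
#' the largest |r| among those with p below `alpha`; `"uncorrelated"` if
#' none. The sign of the class correlation distinguishes burst-like
#' (positive) from pause-like (negative) units.
#'
#' @param rate A [bin_rate()] result aligned with `kinset`.
#' @param kinset A [build_kinematics()] result.
#' @param alpha Per-variable significance level (default 0.05; no
#'   multiple-comparison correction across the 8 variables, by design).
#' @param max_lag_s Lag search half-width (s).
#' @param extra_mask Optional additional logical mask ANDed with the
#'   kinematic mask (e.g. a peri-event mask from [peri_event_mask()]).
#' @param min_bins Minimum jointly valid bins.
#' @param null `"pearson"` (parametric p, the default) or `"shuffle"`
#'   (circular-shift permutation p).
#' @param n_shuffles,seed Used when `null = "shuffle"`.
#' @return An object of class `encoding_result`: `unit_id`, `table`
#'   (data.frame: variable, best_lag_s, r, p, n), `class_variable`,
#'   `sign` (`"positive"`, `"negative"` or `"none"`), `class_r`,
#'   `class_lag_s`, `alpha`.
#' @export
classify_unit <- function(rate, kinset, alpha = 0.05, max_lag_s = 0.5,
                          extra_mask = NULL, min_bins = 100,
                          null = c("pearson", "shuffle"),
                          n_shuffles = 1000, seed = 1) {
  null <- match.arg(null)
  stopifnot(inherits(kinset, "kinematic_set"), alpha > 0, alpha < 1)
  mask <- kinset$mask
  if (!is.null(extra_mask)) mask <- mask & extra_mask
  vars <- kinematic_components()
  rows <- lapply(vars, function(v) {
    kin <- kinset$components[[v]]
    bl <- best_lag(rate, kin, kinset$bin_width, max_lag_s, mask, min_bins)
    if (bl$undefined)
      return(data.frame(variable = v, best_lag_s = NA_real_, r = NA_real_,
                        p = NA_real_, n = NA_integer_))
    sp <- shifted_pearson(rate, kin, bl$lag_s, kinset$bin_width, mask)
    p <- sp$p
    if (null == "shuffle") {
      nul <- circular_shift_null(rate, kin, kinset$bin_width, max_lag_s,
                                 mask, min_bins, n_shuffles, seed)
      p <- (1 + sum(nul >= abs(sp$r), na.rm = TRUE)) / (1 + sum(!is.na(nul)))
    }
    data.frame(variable = v, best_lag_s = bl$lag_s, r = sp$r, p = p,
               n = sp$n)
  })
  tab <- do.call(rbind, rows)
  tab$r_aligned <- NA_real_
  sig <- !is.na(tab$p) & tab$p < alpha
  if (any(sig)) {
    cand <- tab[sig, ]
    best <- cand[order(-abs(cand$r)), ][1L, ]
    class_variable <- best$variable
    class_r <- best$r
    class_lag_s <- best$best_lag_s
    sgn <- if (class_r > 0) "positive" else "negative"
    # every variable's correlation at the unit's operative lag, for
    # same-shift comparisons across directions (opponency)
    tab$r_aligned <- vapply(vars, function(v) {
      sp <- tryCatch(shifted_pearson(rate, kinset$components[[v]],
                                     class_lag_s, kinset$bin_width, mask),
                     error = function(e) list(r = NA_real_))
      sp$r
    }, numeric(1))
  } else {
    class_variable <- "uncorrelated"
    class_r <- NA_real_
    class_lag_s <- NA_real_
    sgn <- "none"
  }
  structure(list(unit_id = if (inherits(rate, "rate_series")) rate$unit_id
                   else "unit",
                 table = tab, class_variable = class_variable, sign = sgn,
                 class_r = class_r, class_lag_s = class_lag_s,
                 alpha = alpha),
            class = "encoding_result")
}

#' @export
print.encoding_result <- function(x, ...) {
  cat(sprintf("<encoding_result> %s: %s", x$unit_id, x$class_variable))
  if (x$class_variable != "uncorrelated")
    cat(sprintf(" (%s, r = %.3f, lag = %+.0f ms)", x$sign, x$class_r,
                1000 * x$class_lag_s))
  cat("\n")
  invisible(x)
}

#' Direction opponency of a classified unit
#'
#' A unit coupled to movement in one direction typically shows the opposite
#' sign of correlation with movement in the opposite direction along the
#' same axis: the two rectified halves of an axis are never jointly active,
#' so their covariance, at a common shift, is negative. For the axis
#' containing the unit's class variable the two directions are therefore
#' compared at the unit's operative (class) lag, using the aligned
#' correlations stored by [classify_unit()]; letting each direction pick
#' its own best-|r| lag instead can legitimately pick up the later
#' return movement and is not the sign comparison intended here. For the
#' remaining axes the per-variable best-lag records are compared and the
#' preferred direction is the one with the larger |r|.
#'
#' @param result An [classify_unit()] result.
#' @return Data frame with columns `quantity`, `axis`, `preferred`,
#'   `r_preferred`, `r_opposite`, `opponent` (logical), `aligned` (TRUE
#'   when the comparison used the class lag for both directions),
#'   `defined` (FALSE when either correlation was undefined, e.g. a
#'   direction never visited).
#' @export
opponency <- function(result) {
  stopifnot(inherits(result, "encoding_result"))
  tab <- result$table
  cv <- result$class_variable
  pairs <- expand.grid(quantity = c("vel", "acc"),
                       axis = c("vertical", "horizontal"),
                       stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    q <- pairs$quantity[i]
    dirs <- if (pairs$axis[i] == "vertical") c("up", "down")
            else c("left", "right")
    v <- paste0(q, "_", dirs)
    aligned <- cv %in% v
    if (aligned) {
      pref_var <- cv
      opp_var <- v[v != cv]
      rp <- result$class_r
      ro <- tab$r_aligned[tab$variable == opp_var]
    } else {
      r1 <- tab$r[tab$variable == v[1]]; r2 <- tab$r[tab$variable == v[2]]
      swap <- !is.na(r1) && !is.na(r2) && abs(r2) > abs(r1)
      pref_var <- if (swap) v[2] else v[1]
      rp <- if (swap) r2 else r1
      ro <- if (swap) r1 else r2
    }
    defined <- !is.na(rp) && !is.na(ro)
    data.frame(quantity = ifelse(q == "vel", "velocity", "acceleration"),
               axis = pairs$axis[i], preferred = variable_direction(pref_var),
               r_preferred = rp, r_opposite = ro,
               opponent = if (defined) rp * ro < 0 else NA,
               aligned = aligned, defined = defined)
  })
  do.call(rbind, out)
}

#' Test the derivative relationship between GABA and DA units
#'
#' Nigral GABAergic output neurons carry position-like signals while DA
#' neurons carry velocity-like signals; for a matched pair the
#' (time-)derivative of the GABA rate should be a mirror image of the DA
#' rate. This takes the central-difference derivative of the GABA rate,
#' scans lags against the DA rate, and returns the peak correlation
#' (expected negative for mirror-image pairs) with its lag.
#'
#' @param gaba_rate,da_rate [bin_rate()] results on a common grid.
#' @inheritParams best_lag
#' @param smooth_sigma_bins Gaussian smoothing (sd in bins) applied to both
#'   rates before differentiation. Default 0 (raw rates, preserving the
#'   exact antiderivative identity); for Poisson spike trains binned at
#'   30 ms the central-difference derivative is dominated by counting
#'   noise, and a few bins of smoothing (e.g. 3) are needed for the
#'   relationship to be visible.
#' @return List: `peak_r`, `lag_s`, `p`, `n`.
#' @export
gaba_da_derivative_test <- function(gaba_rate, da_rate, bin_width = 0.030,
                                    max_lag_s = 0.5, mask = NULL,
                                    min_bins = 100, smooth_sigma_bins = 0) {
  g <- rate_vec(gaba_rate)
  if (inherits(gaba_rate, "rate_series")) bin_width <- gaba_rate$bin_width
  if (smooth_sigma_bins > 0) {
    g <- gaussian_smooth(g, smooth_sigma_bins)
    da_rate <- gaussian_smooth(rate_vec(da_rate), smooth_sigma_bins)
  }
  deriv <- differentiate(g, dt = bin_width)
  # the first/last bins use one-sided stencils (a different estimator);
  # exclude them from the correlation
  dmask <- if (is.null(mask)) rep(TRUE, length(deriv)) else propagate_mask(mask)
  dmask[c(1L, length(dmask))] <- FALSE
  bl <- best_lag(da_rate, deriv, bin_width, max_lag_s, dmask, min_bins)
  if (bl$undefined)
    return(list(peak_r = NA_real_, lag_s = NA_real_, p = NA_real_,
                n = NA_integer_))
  sp <- shifted_pearson(da_rate, deriv, bl$lag_s, bin_width, dmask)
  list(peak_r = sp$r, lag_s = bl$lag_s, p = sp$p, n = sp$n)
}

#' Peri-event analysis mask
#'
#' TRUE for grid bins within a window around any cue or outcome; used to
#' check that session-wide classification agrees with classification
#' restricted to the trial periods.
#'
#' @param grid_t Analysis grid (s).
#' @param events A [session_events()].
#' @param pre_s,post_s Window half-extents before/after each event (s).
#' @return Logical vector over `grid_t`.
#' @export
peri_event_mask <- function(grid_t, events, pre_s = 1, post_s = 1) {
  m <- rep(FALSE, length(grid_t))
  for (e in c(events$cue_onsets, events$outcome_times))
    m[grid_t >= e - pre_s & grid_t <= e + post_s] <- TRUE
  m
}
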