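#' Bin spikes into a firing-rate series
#'
#' Counts spikes in half-open bins `[t_i, t_i + bin_width)` anchored at the
#' kinematic grid instants and divides by the bin width, giving rate in Hz.
#' Spikes outside the grid span are dropped; the dropped count is attached.
#'
#' @param unit A [unit_recording()] (or a numeric vector of spike times).
#' @param grid_t Uniform grid of bin left edges (s), e.g. from a
#'   [build_kinematics()] result.
#' @param bin_width Bin width in seconds.
#' @return An object of class `rate_series`: `grid_t`, `rate` (Hz),
#'   `unit_id`, `bin_width`, `n_dropped`.
#' @export
bin_rate <- function(unit, grid_t, bin_width = 0.030) {
  spikes <- if (inherits(unit, "unit_recording")) unit$spike_times
            else sort(as.numeric(unit))
  uid <- if (inherits(unit, "unit_recording")) unit$unit_id else "unit"
  n <- length(grid_t)
  if (n >= 2L) {
    d <- diff(grid_t)
    if (max(d) - min(d) > 1e-9 * bin_width)
      stop("bin_rate: grid must be uniform")
  }
  edges <- c(grid_t, grid_t[n] + bin_width)
  idx <- findInterval(spikes, edges)        # [edges[i], edges[i+1]) -> i
  inside <- idx >= 1L & idx <= n & spikes < edges[n + 1L]
  counts <- tabulate(idx[inside], nbins = n)
  structure(list(grid_t = grid_t, rate = counts / bin_width, unit_id = uid,
                 bin_width = bin_width, n_dropped = sum(!inside)),
            class = "rate_series")
}

#' Optional Gaussian smoothing of a rate series
#'
#' Convolves the binned rate with a centered Gaussian kernel (sd in bins,
#' truncated at 4 sd, renormalized). The default analysis uses raw binned
#' rates; smoothing is exposed for exploration.
#'
#' @param rate_series A [bin_rate()] result.
#' @param sigma_bins Kernel sd in bins; 0 returns the input unchanged.
#' @return A `rate_series` with smoothed `rate`.
#' @export
smooth_rate <- function(rate_series, sigma_bins = 0) {
  if (sigma_bins <= 0) return(rate_series)
  rate_series$rate <- gaussian_smooth(rate_series$rate, sigma_bins)
  rate_series
}

gaussian_smooth <- function(r, sigma_bins) {
  half <- ceiling(4 * sigma_bins)
  k <- stats::dnorm(-half:half, sd = sigma_bins)
  k <- k / sum(k)
  n <- length(r)
  # pad with edge values so the kernel is defined everywhere
  padded <- c(rep(r[1], half), r, rep(r[n], half))
  sm <- stats::filter(padded, k, sides = 2)
  as.numeric(sm[(half + 1L):(half + n)])
}

#' Cell-class rule for putative dopaminergic units
#'
#' Dopaminergic (DA) neurons in the substantia nigra pars compacta are
#' distinguished from GABAergic neurons by lower firing rates and wider
#' spike waveforms. The numeric boundaries are configuration, not ground
#' truth: defaults of 12 Hz and 0.5 ms FWHM are consistent with typical SNc
#' criteria.
#'
#' @param rate_max_da Maximum mean rate (Hz) for a DA call (default 12).
#' @param fwhm_min_da Minimum spike FWHM (ms) for a DA call (default 0.5).
#' @return An object of class `cell_class_rule`.
#' @export
cell_class_rule <- function(rate_max_da = 12, fwhm_min_da = 0.5) {
  stopifnot(rate_max_da > 0, fwhm_min_da > 0)
  structure(list(rate_max_da = rate_max_da, fwhm_min_da = fwhm_min_da),
            class = "cell_class_rule")
}

#' Classify units as putative DA vs non-DA
#'
#' A unit is called DA iff its mean rate is at or below `rate_max_da` AND
#' its spike FWHM is at or above `fwhm_min_da`; otherwise non-DA. A missing
#' FWHM yields `"unknown"` with a warning (such units are excluded from
#' class-dependent analyses).
#'
#' @param mean_rate Numeric vector of mean rates (Hz).
#' @param fwhm Numeric vector of spike widths (ms); NA allowed.
#' @param rule A [cell_class_rule()].
#' @return Character vector: `"DA"`, `"nonDA"` or `"unknown"`.
#' @export
classify_cell_type <- function(mean_rate, fwhm, rule = cell_class_rule()) {
  stopifnot(inherits(rule, "cell_class_rule"))
  out <- ifelse(mean_rate <= rule$rate_max_da & fwhm >= rule$fwhm_min_da,
                "DA", "nonDA")
  if (any(is.na(fwhm))) {
    warning("classify_cell_type: missing fwhm -> class 'unknown'")
    out[is.na(fwhm)] <- "unknown"
  }
  out
}

welch_or_flag <- function(a, b) {
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
    return(list(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0,
                degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Compare DA vs non-DA populations on rate and spike width
#'
#' Welch two-sample t-tests of mean firing rate and spike FWHM between the
#' putative DA and non-DA groups.
#'
#' @param units List of [unit_recording()] objects with `putative_class`
#'   set (or classifiable via `rule`).
#' @param rule Optional [cell_class_rule()] used to (re)classify from
#'   metadata when `putative_class` is `"unknown"`.
#' @return Data frame with rows `mean_rate` and `fwhm`: group means,
#'   Welch t, df, two-sided p, and a `degenerate` flag (TRUE when both
#'   groups had zero variance; p is then 0 or 1 by convention).
#' @export
compare_cell_classes <- function(units, rule = cell_class_rule()) {
  rates <- vapply(units, `[[`, numeric(1), "mean_rate")
  fwhm <- vapply(units, `[[`, numeric(1), "spike_width_fwhm")
  cls <- vapply(units, `[[`, character(1), "putative_class")
  unk <- cls == "unknown" & !is.na(fwhm)
  if (any(unk)) cls[unk] <- classify_cell_type(rates[unk], fwhm[unk], rule)
  da <- cls == "DA"; non <- cls %in% c("GABA", "nonDA")
  if (sum(da) < 2L || sum(non) < 2L)
    stop("compare_cell_classes: need >= 2 units per class")
  res <- list(mean_rate = welch_or_flag(rates[da], rates[non]),
              fwhm = welch_or_flag(fwhm[da], fwhm[non]))
  data.frame(variable = names(res),
             mean_da = c(mean(rates[da]), mean(fwhm[da])),
             mean_nonda = c(mean(rates[non]), mean(fwhm[non])),
             t = vapply(res, `[[`, numeric(1), "t"),
             df = vapply(res, `[[`, numeric(1), "df"),
             p = vapply(res, `[[`, numeric(1), "p"),
             degenerate = vapply(res, `[[`, logical(1), "degenerate"),
             row.names = NULL)
}
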