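#' Names of the eight rectified kinematic components
#'
#' The x and y velocity and acceleration series are each split into their
#' positive and negative halves, yielding eight non-negative directional
#' variables: velocity and acceleration in the up, down, left and right
#' directions.
#'
#' @return Character vector of length 8.
#' @export
kinematic_components <- function() {
  c("vel_up", "vel_down", "vel_left", "vel_right",
    "acc_up", "acc_down", "acc_left", "acc_right")
}

#' Resample tracking onto a uniform analysis grid
#'
#' Linear interpolation of x and y at the grid instants
#' `t0 + k * bin_width`. Grid bins falling inside tracking dropouts (gaps
#' longer than 3 nominal frame intervals, see [tracking_gaps()]) are marked
#' invalid in the mask rather than interpolated across.
#'
#' @param tracking A [tracking_series()].
#' @param bin_width Grid bin width in seconds (default 0.030).
#' @return List with `grid_t`, `x`, `y`, `mask` (TRUE = valid) and
#'   `bin_width`.
#' @export
resample_to_grid <- function(tracking, bin_width = 0.030) {
  stopifnot(inherits(tracking, "tracking_series"))
  if (bin_width <= 0) stop("resample_to_grid: bin_width > 0 required")
  span <- range(tracking$t)
  if (bin_width > diff(span))
    stop("resample_to_grid: bin_width larger than session duration")
  n <- floor(diff(span) / bin_width) + 1L
  grid_t <- span[1] + (seq_len(n) - 1L) * bin_width
  x <- stats::approx(tracking$t, tracking$x, xout = grid_t, rule = 2)$y
  y <- stats::approx(tracking$t, tracking$y, xout = grid_t, rule = 2)$y
  mask <- rep(TRUE, n)
  gaps <- tracking_gaps(tracking)
  if (nrow(gaps) > 0) {
    for (g in seq_len(nrow(gaps)))
      mask[grid_t > gaps[g, 1] & grid_t < gaps[g, 2]] <- FALSE
  }
  list(grid_t = grid_t, x = x, y = y, mask = mask, bin_width = bin_width)
}

#' Differentiate a uniformly sampled series
#'
#' Central difference `(s[i+1] - s[i-1]) / (2 * dt)` at interior points and
#' one-sided differences at the two edges. The central scheme has zero phase
#' shift, so it does not bias the lag estimates computed downstream.
#'
#' @param series Numeric vector sampled on a uniform grid.
#' @param grid_t The grid (checked for uniformity), or `NULL` if `dt` given.
#' @param dt Grid spacing in seconds (ignored when `grid_t` supplied).
#' @return Numeric vector of the derivative, same length.
#' @export
differentiate <- function(series, grid_t = NULL, dt = NULL) {
  n <- length(series)
  if (n < 3L) stop("differentiate: at least 3 samples required")
  if (!is.null(grid_t)) {
    d <- diff(grid_t)
    if (max(d) - min(d) > 1e-9 * stats::median(d))
      stop("differentiate: non-uniform grid")
    dt <- stats::median(d)
  }
  if (is.null(dt) || dt <= 0) stop("differentiate: need dt > 0 or grid_t")
  out <- numeric(n)
  out[2:(n - 1L)] <- (series[3:n] - series[1:(n - 2L)]) / (2 * dt)
  out[1L] <- (series[2L] - series[1L]) / dt
  out[n] <- (series[n] - series[n - 1L]) / dt
  out
}

# mask for a central-difference output: a bin is valid only if the stencil
# bins it touches are valid
propagate_mask <- function(mask) {
  n <- length(mask)
  out <- mask
  out[2:(n - 1L)] <- mask[2:(n - 1L)] & mask[1:(n - 2L)] & mask[3:n]
  out[1L] <- mask[1L] & mask[2L]
  out[n] <- mask[n] & mask[n - 1L]
  out
}

#' Split velocity and acceleration into rectified directional components
#'
#' `vel_right = max(vx, 0)`, `vel_left = max(-vx, 0)`, `vel_up = max(vy, 0)`,
#' `vel_down = max(-vy, 0)`, and the same pattern for acceleration. The two
#' halves of an axis are mutually exclusive (their product is zero in every
#' bin) and reconstruct the signed series exactly
#' (`vel_right - vel_left == vx`).
#'
#' @param vx,vy,ax,ay Aligned numeric series (mm/s and mm/s^2).
#' @return Named list of the 8 non-negative component series (see
#'   [kinematic_components()]).
#' @export
decompose_components <- function(vx, vy, ax, ay) {
  list(vel_up    = pmax(vy, 0), vel_down  = pmax(-vy, 0),
       vel_left  = pmax(-vx, 0), vel_right = pmax(vx, 0),
       acc_up    = pmax(ay, 0), acc_down  = pmax(-ay, 0),
       acc_left  = pmax(-ax, 0), acc_right = pmax(ax, 0))
}

moving_average <- function(x, w) {
  if (w <= 1L) return(x)
  if (w %% 2L == 0L) stop("smoothing window must be odd")
  sm <- stats::filter(x, rep(1 / w, w), sides = 2)
  sm <- as.numeric(sm)
  # keep raw values at the edges where the centered window does not fit
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

#' Build the full kinematic set from tracking
#'
#' Resamples tracking to the analysis grid, optionally smooths position with
#' a short centered moving average, differentiates (central differences) to
#' velocity, differentiates velocity to acceleration, and rectifies into the
#' eight directional components.
#'
#' @param tracking A [tracking_series()].
#' @param bin_width Analysis bin width in seconds (default 0.030).
#' @param smoothing_window_bins Odd moving-average window applied to x and y
#'   before differentiation (default 3; 1 disables). Centered, so zero phase.
#' @param camera_mirrored_x If TRUE, negate x first (swaps left and right
#'   components exactly; up/down untouched).
#' @return An object of class `kinematic_set`: `grid_t`, `x`, `y`, `vx`,
#'   `vy`, `ax`, `ay`, `components` (list of 8), `mask` (valid bins for
#'   correlation; dropout bins and their difference-stencil neighbors are
#'   FALSE), `bin_width`.
#' @export
build_kinematics <- function(tracking, bin_width = 0.030,
                             smoothing_window_bins = 3,
                             camera_mirrored_x = FALSE) {
  # center coordinates on the first sample before any arithmetic: velocity
  # and acceleration are then computed from position differences only, so
  # a constant shift of the whole trajectory cannot leak into them
  x0 <- tracking$x[1]; y0 <- tracking$y[1]
  tracking$x <- tracking$x - x0
  tracking$y <- tracking$y - y0
  g <- resample_to_grid(tracking, bin_width)
  x <- if (camera_mirrored_x) -g$x else g$x
  y <- g$y
  x <- moving_average(x, smoothing_window_bins)
  y <- moving_average(y, smoothing_window_bins)
  vx <- differentiate(x, dt = bin_width)
  vy <- differentiate(y, dt = bin_width)
  # acceleration as the first difference of the velocity series (this and
  # the direct second difference of position differ only at mask edges)
  ax <- differentiate(vx, dt = bin_width)
  ay <- differentiate(vy, dt = bin_width)
  vmask <- propagate_mask(g$mask)
  amask <- propagate_mask(vmask)
  x <- x + (if (camera_mirrored_x) -x0 else x0)
  y <- y + y0
  structure(list(grid_t = g$grid_t, x = x, y = y, vx = vx, vy = vy,
                 ax = ax, ay = ay,
                 components = decompose_components(vx, vy, ax, ay),
                 mask = amask, bin_width = bin_width),
            class = "kinematic_set")
}

#' @export
print.kinematic_set <- function(x, ...) {
  cat(sprintf("<kinematic_set> %d bins of %g ms, %d valid (%.1f%%)\n",
              length(x$grid_t), 1000 * x$bin_width, sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' Movement metrics for optogenetic stimulation trains
#'
#' For each train, distance is the Euclidean displacement between the head
#' (LED) position at train onset and at train termination; the speed series
#' is the derivative of the instantaneous distance from the onset location,
#' and peak speed is its maximum over the train.
#'
#' @param tracking A [tracking_series()].
#' @param stim_trains Data frame with columns `onset`, `offset`,
#'   `frequency_hz` (as in [session_events()]).
#' @param bin_width Sampling step for the within-train distance series (s).
#' @return Data frame with one row per train: `onset`, `offset`,
#'   `frequency_hz`, `distance` (mm), `peak_speed` (mm/s); the per-train
#'   speed series are attached as the list column `speed_series`.
#' @export
stim_kinematics <- function(tracking, stim_trains, bin_width = 0.030) {
  stopifnot(inherits(tracking, "tracking_series"))
  span <- range(tracking$t)
  n <- nrow(stim_trains)
  out <- stim_trains[, c("onset", "offset", "frequency_hz"), drop = FALSE]
  out$distance <- numeric(n)
  out$peak_speed <- numeric(n)
  speed_series <- vector("list", n)
  for (i in seq_len(n)) {
    on <- stim_trains$onset[i]; off <- stim_trains$offset[i]
    if (on < span[1] || off > span[2])
      stop("stim_kinematics: train outside tracking span")
    # uniform grid covering the train inclusive of its termination (the
    # distance is defined at the end of the train)
    tt <- seq(on, off, length.out = max(3L, round((off - on) / bin_width) + 1L))
    px <- stats::approx(tracking$t, tracking$x, xout = tt)$y
    py <- stats::approx(tracking$t, tracking$y, xout = tt)$y
    d <- sqrt((px - px[1])^2 + (py - py[1])^2)
    out$distance[i] <- d[length(d)]
    sp <- differentiate(d, dt = tt[2] - tt[1])
    speed_series[[i]] <- sp
    out$peak_speed[i] <- max(sp)
  }
  out$speed_series <- speed_series
  out
}
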