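#' Parameters of the cascade velocity-position control model
#'
#' The generator's trajectory model is a two-level negative-feedback
#' cascade per axis. The upper (velocity) controller compares a velocity
#' reference with the sensed velocity; the error, scaled by a
#' multiplicative dopamine-like gain, drives a leaky integrator whose state
#' is the position reference handed to the lower loop. The lower (position)
#' controller produces velocity proportional to the position error. The
#' integrator leak pulls the position reference back toward a home
#' coordinate, so movements are self-terminating and the trajectory returns
#' to its starting point after each bout.
#'
#' @param da_gain Dimensionless gain on the velocity error (>= 0). Zero
#'   gain produces no movement; larger gain produces faster movement.
#' @param integrator_leak Leak rate of the integrator (1/s, >= 0).
#' @param position_gain Proportional gain of the position loop (1/s, > 0).
#' @param dt Simulation step (s).
#' @param sensor_noise_sd SD of Gaussian noise on the sensed velocity
#'   (mm/s).
#' @param opponent_split If TRUE, the velocity error is phase-split into a
#'   direct (positive half) and indirect (negative half) channel, recorded
#'   per step; the two channels sum to the raw error exactly.
#' @return An object of class `control_model_params`.
#' @export
control_model_params <- function(da_gain = 1, integrator_leak = 0.5,
                                 position_gain = 8, dt = 0.005,
                                 sensor_noise_sd = 0,
                                 opponent_split = FALSE) {
  stopifnot(da_gain >= 0, integrator_leak >= 0, position_gain > 0, dt > 0,
            sensor_noise_sd >= 0)
  if (position_gain * dt >= 2)
    stop("control_model_params: unstable (position_gain * dt must be < 2)")
  structure(list(da_gain = da_gain, integrator_leak = integrator_leak,
                 position_gain = position_gain, dt = dt,
                 sensor_noise_sd = sensor_noise_sd,
                 opponent_split = opponent_split),
            class = "control_model_params")
}

simulate_axis <- function(params, v_ref, home, p0, p_ref0, noise) {
  n <- length(v_ref)
  g <- params$da_gain; lam <- params$integrator_leak
  kp <- params$position_gain; dt <- params$dt
  pos <- numeric(n); pref <- numeric(n); vel <- numeric(n); err <- numeric(n)
  p <- p0; pr <- p_ref0; vs <- 0
  for (k in seq_len(n)) {
    e <- g * (v_ref[k] - vs)
    pr <- pr + dt * (e - lam * (pr - home))
    v <- kp * (pr - p)
    p <- p + dt * v
    vs <- v + noise[k]
    err[k] <- e; pref[k] <- pr; vel[k] <- v; pos[k] <- p
  }
  list(pos = pos, p_ref = pref, v = vel, err = err)
}

#' Simulate a trajectory with the cascade control model
#'
#' Discrete-time loop per axis, at step `dt`:
#' `error = da_gain * (v_ref - v_sensed)`;
#' `p_ref <- p_ref + dt * (error - integrator_leak * (p_ref - home))`;
#' `v = position_gain * (p_ref - p)`; `p <- p + dt * v`;
#' `v_sensed = v + noise`. Returns the position trace as a
#' [tracking_series()] sampled at the camera frame rate, plus the dense
#' internal state traces for ground-truth coupling of synthetic units.
#'
#' @param params A [control_model_params()].
#' @param v_ref Velocity reference: numeric matrix with columns x, y (mm/s)
#'   on the dense grid, or a single numeric vector (treated as the x axis,
#'   y reference zero).
#' @param duration Session duration (s); defaults to
#'   `nrow(v_ref) * params$dt`.
#' @param home Home coordinates (mm), length 2.
#' @param p0 Initial position; default `home`.
#' @param p_ref0 Initial position reference; default `p0`.
#' @param frame_rate Tracking sampling rate (Hz, default 30).
#' @param seed RNG seed for the sensor noise (only drawn when
#'   `sensor_noise_sd > 0`).
#' @return An object of class `control_sim`: `t_dense`, `pos` (n x 2),
#'   `p_ref`, `v`, `err` (each n x 2), optional `direct`/`indirect`
#'   channel matrices, `tracking` ([tracking_series()]), `params`.
#' @export
simulate_control_trajectory <- function(params, v_ref, duration = NULL,
                                        home = c(0, 0), p0 = home,
                                        p_ref0 = p0, frame_rate = 30,
                                        seed = 1) {
  stopifnot(inherits(params, "control_model_params"))
  if (is.null(dim(v_ref))) v_ref <- cbind(x = v_ref, y = 0)
  n <- nrow(v_ref)
  if (!is.null(duration)) {
    n <- max(2L, as.integer(round(duration / params$dt)))
    if (nrow(v_ref) < n)
      v_ref <- rbind(v_ref, matrix(0, n - nrow(v_ref), 2))
    v_ref <- v_ref[seq_len(n), , drop = FALSE]
  }
  noise <- if (params$sensor_noise_sd > 0)
    with_seed(seed, matrix(stats::rnorm(2L * n, sd = params$sensor_noise_sd),
                           ncol = 2))
  else matrix(0, n, 2)
  ax <- simulate_axis(params, v_ref[, 1], home[1], p0[1], p_ref0[1],
                      noise[, 1])
  ay <- simulate_axis(params, v_ref[, 2], home[2], p0[2], p_ref0[2],
                      noise[, 2])
  t_dense <- c(0, seq_len(n) * params$dt)
  pos <- rbind(p0, cbind(ax$pos, ay$pos))
  out <- list(t_dense = t_dense, pos = unname(pos),
              p_ref = unname(rbind(p_ref0, cbind(ax$p_ref, ay$p_ref))),
              v = rbind(0, cbind(ax$v, ay$v)),
              err = rbind(0, cbind(ax$err, ay$err)),
              params = params)
  if (params$opponent_split) {
    out$direct <- pmax(out$err, 0)
    out$indirect <- pmin(out$err, 0)
  }
  tf <- seq(0, t_dense[length(t_dense)], by = 1 / frame_rate)
  out$tracking <- tracking_series(
    tf,
    stats::approx(t_dense, out$pos[, 1], xout = tf)$y,
    stats::approx(t_dense, out$pos[, 2], xout = tf)$y,
    frame_rate_nominal = frame_rate)
  class(out) <- "control_sim"
  out
}

#' Raised-cosine velocity-reference pulse
#'
#' Smooth, compactly supported bump used for movement-bout references:
#' `amplitude * (1 - cos(2*pi*(t - onset)/duration)) / 2` inside
#' `[onset, onset + duration]`, zero outside. Twice differentiable, so the
#' resulting acceleration components are well-behaved.
#'
#' @param t Numeric vector of times (s).
#' @param onset Pulse onset (s).
#' @param duration Pulse duration (s).
#' @param amplitude Peak amplitude (mm/s).
#' @return Numeric vector over `t`.
#' @export
raised_cosine_pulse <- function(t, onset, duration, amplitude) {
  u <- (t - onset) / duration
  ifelse(u >= 0 & u <= 1, amplitude * 0.5 * (1 - cos(2 * pi * u)), 0)
}
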