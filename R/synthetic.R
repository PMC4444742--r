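#' Task specification for synthetic sessions
#'
#' Encodes the trace-conditioning task structure the generator emulates: a
#' brief tone, an outcome about 2 s after tone offset, long variable
#' inter-trial intervals with spontaneous movements, and movement bouts
#' locked to cue and outcome.
#'
#' @param n_trials Number of trials (default 60).
#' @param tone_duration Tone duration (s, default 0.1).
#' @param outcome_delay Range (s) of the outcome delay after tone offset
#'   (default c(1.9, 2.1), i.e. ~2 s).
#' @param iti_range Inter-trial-interval range (s, default c(20, 50)).
#' @param outcome_schedule `"sucrose"`, `"airpuff"`, `"AB"` (sucrose block
#'   then airpuff block) or `"ABAB"` (alternating quarter blocks).
#' @param bout_amplitude Peak velocity-reference amplitude for spontaneous
#'   bouts (mm/s).
#' @param cue_amplitude,outcome_amplitude Peak reference amplitudes for the
#'   cue- and outcome-locked bouts (mm/s).
#' @param bout_duration Reference pulse duration (s).
#' @param spontaneous_bout_rate Rate of spontaneous ITI bouts (1/s;
#'   default 0.08, about 5 bouts per minute — unrestrained mice move
#'   frequently between trials, and most of the session is ITI).
#' @param direction_jitter_sd SD (radians) of the Gaussian jitter applied
#'   to each cue/outcome bout direction (default 0.5), reflecting
#'   trial-to-trial variability of the movement path to and from the
#'   spout.
#' @param amplitude_jitter Range of the multiplicative amplitude jitter on
#'   event-locked bouts (default c(0.7, 1.3)).
#' @param reaction_delay Delay from event to movement onset (s).
#' @param fast If TRUE, a reduced profile for quick runs: 10 trials with
#'   5-10 s ITIs (overrides `n_trials` and `iti_range`).
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(n_trials = 60, tone_duration = 0.1,
                      outcome_delay = c(1.9, 2.1), iti_range = c(20, 50),
                      outcome_schedule = "sucrose", bout_amplitude = 50,
                      cue_amplitude = 60, outcome_amplitude = 80,
                      bout_duration = 0.5, spontaneous_bout_rate = 0.08,
                      direction_jitter_sd = 0.5,
                      amplitude_jitter = c(0.7, 1.3),
                      reaction_delay = 0.1, fast = FALSE) {
  if (fast) { n_trials <- 10; iti_range <- c(5, 10) }
  stopifnot(n_trials >= 1, tone_duration > 0, all(outcome_delay > 0),
            diff(outcome_delay) >= 0, all(iti_range > 0),
            iti_range[1] <= iti_range[2], bout_duration > 0,
            spontaneous_bout_rate >= 0)
  if (!outcome_schedule %in% c("sucrose", "airpuff", "AB", "ABAB"))
    stop("task_spec: unknown outcome_schedule")
  structure(list(n_trials = n_trials, tone_duration = tone_duration,
                 outcome_delay = outcome_delay, iti_range = iti_range,
                 outcome_schedule = outcome_schedule,
                 bout_amplitude = bout_amplitude,
                 cue_amplitude = cue_amplitude,
                 outcome_amplitude = outcome_amplitude,
                 bout_duration = bout_duration,
                 spontaneous_bout_rate = spontaneous_bout_rate,
                 direction_jitter_sd = direction_jitter_sd,
                 amplitude_jitter = amplitude_jitter,
                 reaction_delay = reaction_delay),
            class = "task_spec")
}

outcome_schedule_vec <- function(schedule, n) {
  switch(schedule,
         sucrose = rep("sucrose", n),
         airpuff = rep("airpuff", n),
         AB = rep(c("sucrose", "airpuff"), c(ceiling(n / 2), floor(n / 2))),
         ABAB = rep(rep(c("sucrose", "airpuff"),
                        length.out = 4)[rep(1:4, each = ceiling(n / 4))][1:n]))
}

# ground-truth kinematics from the dense model state, sampled on the
# analysis grid (no smoothing: the model velocity is exact)
truth_kinematics <- function(sim, bin_width = 0.030) {
  dur <- sim$t_dense[length(sim$t_dense)]
  grid_t <- seq(0, dur, by = bin_width)
  vx <- stats::approx(sim$t_dense, sim$v[, 1], xout = grid_t)$y
  vy <- stats::approx(sim$t_dense, sim$v[, 2], xout = grid_t)$y
  x <- stats::approx(sim$t_dense, sim$pos[, 1], xout = grid_t)$y
  y <- stats::approx(sim$t_dense, sim$pos[, 2], xout = grid_t)$y
  ax <- differentiate(vx, dt = bin_width)
  ay <- differentiate(vy, dt = bin_width)
  structure(list(grid_t = grid_t, x = x, y = y, vx = vx, vy = vy,
                 ax = ax, ay = ay,
                 components = decompose_components(vx, vy, ax, ay),
                 mask = rep(TRUE, length(grid_t)), bin_width = bin_width),
            class = "kinematic_set")
}

#' Simulate a trial-structured behavioral session
#'
#' Draws trial events from the task spec, builds a velocity-reference
#' signal (cue- and outcome-locked raised-cosine bouts directed toward the
#' spout for sucrose and away from it for air puff, plus spontaneous
#' random-direction ITI bouts), feeds it through the cascade control model,
#' and returns tracking, events and the ground-truth kinematics.
#' Deterministic given the seed.
#'
#' @param task A [task_spec()].
#' @param params A [control_model_params()].
#' @param seed RNG seed.
#' @param spout Spout location (mm) relative to the home position.
#' @param bin_width Analysis bin width used for the ground-truth kinematic
#'   set (s).
#' @return List: `tracking` ([tracking_series()]), `events`
#'   ([session_events()]), `kinset_truth` ([build_kinematics()]-compatible
#'   ground truth from the model's internal velocity), `sim`
#'   (the `control_sim`), `task`, `params`, `spout`.
#' @export
simulate_task_session <- function(task = task_spec(),
                                  params = control_model_params(),
                                  seed = 1, spout = c(10, 25),
                                  bin_width = 0.030) {
  stopifnot(inherits(task, "task_spec"),
            inherits(params, "control_model_params"))
  with_seed(seed, {
    n <- task$n_trials
    itis <- stats::runif(n + 1, task$iti_range[1], task$iti_range[2])
    delays <- stats::runif(n, task$outcome_delay[1], task$outcome_delay[2])
    cue <- numeric(n); outc <- numeric(n)
    t0 <- itis[1]
    for (i in seq_len(n)) {
      cue[i] <- t0
      outc[i] <- cue[i] + task$tone_duration + delays[i]
      t0 <- outc[i] + itis[i + 1]
    }
    duration <- t0
    otype <- outcome_schedule_vec(task$outcome_schedule, n)

    nd <- as.integer(ceiling(duration / params$dt))
    td <- seq_len(nd) * params$dt
    vref <- matrix(0, nd, 2)
    theta_spout <- atan2(spout[2], spout[1])
    add_pulse <- function(onset, theta, amp) {
      p <- raised_cosine_pulse(td, onset, task$bout_duration, amp)
      vref[, 1] <<- vref[, 1] + p * cos(theta)
      vref[, 2] <<- vref[, 2] + p * sin(theta)
    }
    jit <- stats::rnorm(2 * n, 0, task$direction_jitter_sd)
    amp_j <- stats::runif(2 * n, task$amplitude_jitter[1],
                          task$amplitude_jitter[2])
    for (i in seq_len(n)) {
      add_pulse(cue[i] + task$reaction_delay, theta_spout + jit[2 * i - 1],
                task$cue_amplitude * amp_j[2 * i - 1])
      th_out <- if (otype[i] == "sucrose") theta_spout else theta_spout + pi
      add_pulse(outc[i] + task$reaction_delay, th_out + jit[2 * i],
                task$outcome_amplitude * amp_j[2 * i])
    }
    n_spont <- stats::rpois(1, task$spontaneous_bout_rate * duration)
    if (n_spont > 0) {
      on_s <- stats::runif(n_spont, 0, duration - task$bout_duration)
      th <- stats::runif(n_spont, 0, 2 * pi)
      am <- stats::runif(n_spont, 0.5, 1) * task$bout_amplitude
      for (j in seq_len(n_spont))
        add_pulse(on_s[j], th[j], am[j])
    }
    sim <- simulate_control_trajectory(params, vref, seed = seed + 7919L)
    events <- session_events(cue, outc, otype)
    list(tracking = sim$tracking, events = events,
         kinset_truth = truth_kinematics(sim, bin_width), sim = sim,
         task = task, params = params, spout = spout)
  })
}

#' Tuning specification for a synthetic unit
#'
#' @param unit_id Character id.
#' @param target One of the eight components ([kinematic_components()]),
#'   `"x"` or `"y"` (position coding), or `"none"` (uncoupled).
#' @param sign +1 or -1: direction of rate modulation.
#' @param baseline Baseline rate (Hz, >= 0).
#' @param gain Coupling gain (Hz per mm/s, per mm/s^2, or per mm).
#' @param lag_bins Non-negative integer; the unit's rate leads its target
#'   by this many analysis bins (so the recovered lag, with the convention
#'   that positive lag means kinematics follows the neural signal, equals
#'   `+lag_bins`).
#' @param hemisphere,cell_class Metadata passed to the generated unit.
#' @return An object of class `tuning_spec`.
#' @export
tuning_spec <- function(unit_id, target, sign = 1, baseline = 5, gain = 0.3,
                        lag_bins = 0, hemisphere = "unknown",
                        cell_class = "DA") {
  stopifnot(target %in% c(kinematic_components(), "x", "y", "none"),
            sign %in% c(-1, 1), baseline >= 0, gain >= 0,
            lag_bins >= 0, lag_bins == round(lag_bins))
  structure(list(unit_id = as.character(unit_id), target = target,
                 sign = sign, baseline = baseline, gain = gain,
                 lag_bins = as.integer(lag_bins), hemisphere = hemisphere,
                 cell_class = cell_class),
            class = "tuning_spec")
}

#' Gain giving a desired correlation for a Poisson tuned unit
#'
#' For a unit with intensity `baseline + gain * target` and Poisson bin
#' counts, the expected Pearson correlation between the binned rate and the
#' target is `g*sd(k) / sqrt(g^2 var(k) + mean(lambda)/bin_width)`.
#' Inverting gives the gain achieving a requested r; one fixed-point pass
#' accounts for the coupling's own contribution to the mean rate.
#'
#' @param target Target series on the analysis grid.
#' @param baseline Baseline rate (Hz).
#' @param r Desired correlation magnitude (0 < r < 1).
#' @param bin_width Bin width (s).
#' @param sign Coupling sign.
#' @return Gain (Hz per target unit).
#' @export
tuning_gain_for_r <- function(target, baseline, r, bin_width = 0.030,
                              sign = 1) {
  stopifnot(r > 0, r < 1)
  sdk <- stats::sd(target)
  if (sdk == 0) stop("tuning_gain_for_r: zero-variance target")
  lam <- baseline
  g <- 0
  for (it in 1:3) {
    g <- r / sqrt(1 - r^2) * sqrt(lam / bin_width) / sdk
    lam <- max(0.1, baseline + sign * g * mean(target))
  }
  g
}

#' Generate a Poisson unit tuned to a kinematic or position signal
#'
#' Intensity `lambda(t) = max(0, baseline + sign*gain*target(t +
#' lag_bins*bin_width))` evaluated per analysis bin (the rate leads its
#' target, as burst-like nigral units lead movement); spike counts are
#' Poisson per bin with timestamps placed uniformly within the bin, which
#' is exact under the later binning of the analysis. Metadata (spike width)
#' is drawn from class-conditional distributions: DA-like units wide
#' (~1.1 ms FWHM), GABA-like units narrow (~0.3 ms).
#'
#' @param spec A [tuning_spec()].
#' @param kinset A `kinematic_set` (typically the ground-truth set from
#'   [simulate_task_session()]).
#' @param seed RNG seed.
#' @return A [unit_recording()].
#' @export
generate_unit <- function(spec, kinset, seed = 1) {
  stopifnot(inherits(spec, "tuning_spec"), inherits(kinset, "kinematic_set"))
  n <- length(kinset$grid_t)
  dt <- kinset$bin_width
  target <- switch(spec$target,
                   x = kinset$x, y = kinset$y,
                   none = rep(0, n),
                   kinset$components[[spec$target]])
  if (is.null(target)) stop("generate_unit: target series missing")
  lag <- spec$lag_bins
  shifted <- if (lag > 0) c(target[(lag + 1L):n], rep(target[n], lag))
             else target
  lambda <- pmax(0, spec$baseline + spec$sign * spec$gain * shifted)
  with_seed(seed, {
    counts <- stats::rpois(n, lambda * dt)
    idx <- rep.int(seq_len(n), counts)
    spikes <- kinset$grid_t[idx] + stats::runif(length(idx)) * dt
    fwhm <- if (spec$cell_class == "DA")
      max(0.7, stats::rnorm(1, 1.1, 0.12))
    else max(0.15, stats::rnorm(1, 0.30, 0.04))
    unit_recording(spec$unit_id, sort(spikes),
                   hemisphere = spec$hemisphere,
                   mean_rate = length(spikes) / (n * dt),
                   spike_width_fwhm = fwhm,
                   putative_class = spec$cell_class)
  })
}

default_class_mix <- function() {
  # per-cell composition of the classified population (velocity 66 /
  # acceleration 31 of 97 classified units)
  c(vel_up = 18, vel_down = 19, vel_left = 13, vel_right = 16,
    acc_up = 9, acc_down = 13, acc_left = 4, acc_right = 5) / 97
}

#' Draw the categorical composition of a synthetic cohort
#'
#' The assignment layer of [generate_cohort()], exposed separately because
#' the population-level tests (lateralization chi-square calibration) only
#' depend on it: class per the mix, an uncorrelated fraction, sign (78%
#' positive / 22% negative among coupled units), planted lags (0-1 bins for
#' positive units, 5 bins for negative units, mirroring the short positive
#' and long negative lags seen in recordings), and hemisphere assigned
#' contralateral to the preferred horizontal direction with probability
#' `contralateral_bias` (vertically tuned and uncoupled units get a random
#' hemisphere).
#'
#' @param n_units Number of units.
#' @param class_mix Named probabilities over the 8 components (default:
#'   the recorded-population composition template).
#' @param p_uncorrelated Probability of an uncoupled unit (default 9/106).
#' @param p_positive Probability of positive sign (default 0.78).
#' @param contralateral_bias Probability that a horizontally tuned unit
#'   sits in the hemisphere contralateral to its preferred direction
#'   (0.5 = no lateralization).
#' @param seed RNG seed.
#' @return Data frame: `unit_id`, `target`, `sign`, `lag_bins`,
#'   `hemisphere`.
#' @export
draw_cohort_specs <- function(n_units, class_mix = default_class_mix(),
                              p_uncorrelated = 9 / 106, p_positive = 0.78,
                              contralateral_bias = 0.75, seed = 1) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-8)
  with_seed(seed, {
    coupled <- stats::runif(n_units) >= p_uncorrelated
    target <- ifelse(coupled,
                     sample(names(class_mix), n_units, replace = TRUE,
                            prob = class_mix),
                     "none")
    sign <- ifelse(stats::runif(n_units) < p_positive, 1, -1)
    sign[!coupled] <- 1
    lag_bins <- ifelse(sign > 0, sample(0:1, n_units, replace = TRUE), 5L)
    lag_bins[!coupled] <- 0L
    dirs <- variable_direction(target)
    contra <- stats::runif(n_units) < contralateral_bias
    hemisphere <- ifelse(
      dirs == "left", ifelse(contra, "right", "left"),
      ifelse(dirs == "right", ifelse(contra, "left", "right"),
             sample(c("left", "right"), n_units, replace = TRUE)))
    data.frame(unit_id = sprintf("u%03d", seq_len(n_units)),
               target = target, sign = sign, lag_bins = as.integer(lag_bins),
               hemisphere = hemisphere, stringsAsFactors = FALSE)
  })
}

#' Generate a full synthetic cohort session with ground truth
#'
#' Simulates one task session, draws a cohort composition, calibrates each
#' unit's gain so its expected rate-kinematics correlation falls in
#' `r_range`, generates Poisson spike trains, and (optionally) appends
#' matched GABA/DA pseudo-unit pairs sharing the trajectory (GABA coding
#' -y position at a high baseline, DA coding upward velocity) for the
#' derivative-relationship test.
#'
#' @param n_units Number of DA-like cohort units.
#' @param task,params,seed,spout As in [simulate_task_session()].
#' @param class_mix,p_uncorrelated,p_positive,contralateral_bias Passed to
#'   [draw_cohort_specs()].
#' @param r_range Range of per-unit target correlations (default
#'   c(0.35, 0.55)).
#' @param baseline_positive,baseline_negative Baseline rates (Hz) for
#'   positive- and negative-sign units (negative units get a higher
#'   baseline so their intensity rarely floors at zero).
#' @param n_gaba_pairs Number of appended GABA/DA pairs (default 2).
#' @param bin_width Analysis bin width (s).
#' @return List: `bundle` ([session_bundle()]), `ground_truth` (data frame
#'   with unit ids, targets, signs, lags, gains, baselines and a
#'   `pair` column marking GABA/DA partners), `kinset_truth`, `session`
#'   (the [simulate_task_session()] output).
#' @export
generate_cohort <- function(n_units = 100, task = task_spec(fast = TRUE),
                            params = control_model_params(), seed = 1,
                            spout = c(10, 25),
                            class_mix = default_class_mix(),
                            p_uncorrelated = 9 / 106, p_positive = 0.78,
                            contralateral_bias = 0.75,
                            r_range = c(0.35, 0.55),
                            baseline_positive = 5, baseline_negative = 10,
                            n_gaba_pairs = 2, bin_width = 0.030) {
  sess <- simulate_task_session(task, params, seed = seed, spout = spout,
                                bin_width = bin_width)
  kin <- sess$kinset_truth
  specs <- draw_cohort_specs(n_units, class_mix, p_uncorrelated, p_positive,
                             contralateral_bias, seed = seed + 1L)
  rs <- with_seed(seed + 2L, stats::runif(n_units, r_range[1], r_range[2]))
  units <- vector("list", 0)
  gt <- specs
  gt$baseline <- ifelse(specs$sign > 0, baseline_positive, baseline_negative)
  gt$gain <- 0
  gt$cell_class <- "DA"
  gt$pair <- NA_character_
  for (i in seq_len(n_units)) {
    sp <- specs[i, ]
    gain <- 0
    if (sp$target != "none") {
      target <- kin$components[[sp$target]]
      gain <- tuning_gain_for_r(target, gt$baseline[i], rs[i], bin_width,
                                sp$sign)
    }
    gt$gain[i] <- gain
    ts <- tuning_spec(sp$unit_id, sp$target, sp$sign, gt$baseline[i], gain,
                      sp$lag_bins, sp$hemisphere, "DA")
    units[[length(units) + 1L]] <- generate_unit(ts, kin, seed = seed + 10L + i)
  }
  if (n_gaba_pairs > 0) {
    for (j in seq_len(n_gaba_pairs)) {
      gid <- sprintf("gaba%02d", j); did <- sprintf("daPair%02d", j)
      g_gain <- tuning_gain_for_r(kin$y, 25, 0.6, bin_width, -1)
      d_gain <- tuning_gain_for_r(kin$components$vel_up, 5, 0.5, bin_width, 1)
      gspec <- tuning_spec(gid, "y", -1, 25, g_gain, 0, "unknown", "GABA")
      dspec <- tuning_spec(did, "vel_up", 1, 5, d_gain, 0, "unknown", "DA")
      units[[length(units) + 1L]] <- generate_unit(gspec, kin,
                                                   seed = seed + 5000L + j)
      units[[length(units) + 1L]] <- generate_unit(dspec, kin,
                                                   seed = seed + 6000L + j)
      gt <- rbind(gt,
        data.frame(unit_id = c(gid, did), target = c("y", "vel_up"),
                   sign = c(-1, 1), lag_bins = 0L,
                   hemisphere = "unknown", baseline = c(25, 5),
                   gain = c(g_gain, d_gain), cell_class = c("GABA", "DA"),
                   pair = sprintf("pair%02d", j), stringsAsFactors = FALSE))
    }
  }
  bundle <- session_bundle(sess$tracking, sess$events, units,
                           provenance = list(generator = "generate_cohort",
                                             seed = seed,
                                             n_units = n_units))
  list(bundle = bundle, ground_truth = gt, kinset_truth = kin,
       session = sess)
}

#' Generate an optogenetic stimulation session
#'
#' Stimulation trains of ~1 s at the configured frequencies with 9-12 s
#' inter-train intervals. In ChR2-expressing sessions each train adds a
#' random-direction velocity-reference pulse of amplitude `effect_size`;
#' control sessions receive the light schedule but no drive. Spontaneous
#' bouts occur in both genotypes, providing natural movement variability.
#'
#' @param genotype `"chr2"` or `"control"`.
#' @param effect_size Peak reference amplitude added per train (mm/s).
#' @param frequencies Stimulation frequencies (Hz), cycled across trains.
#' @param n_trains Number of trains.
#' @param train_duration Train duration (s, default 1).
#' @param iti_range Inter-train interval range (s, default c(9, 12)).
#' @param params A [control_model_params()].
#' @param spontaneous_bout_rate,bout_amplitude,bout_duration Spontaneous
#'   movement parameters as in [task_spec()].
#' @param seed RNG seed.
#' @return List: `tracking`, `stim_trains` (data frame onset/offset/
#'   frequency_hz), `genotype`, `events` ([session_events()] with the
#'   trains and no trials).
#' @export
generate_stim_session <- function(genotype = c("chr2", "control"),
                                  effect_size = 15,
                                  frequencies = c(11, 15, 25),
                                  n_trains = 12, train_duration = 1,
                                  iti_range = c(9, 12),
                                  params = control_model_params(),
                                  spontaneous_bout_rate = 0.04,
                                  bout_amplitude = 50, bout_duration = 0.5,
                                  seed = 1) {
  genotype <- match.arg(genotype)
  stopifnot(length(frequencies) >= 1, n_trains >= 1)
  with_seed(seed, {
    itis <- stats::runif(n_trains + 1, iti_range[1], iti_range[2])
    onsets <- cumsum(itis)[seq_len(n_trains)]
    offsets <- onsets + train_duration
    freqs <- rep(frequencies, length.out = n_trains)
    duration <- offsets[n_trains] + itis[n_trains + 1]
    nd <- as.integer(ceiling(duration / params$dt))
    td <- seq_len(nd) * params$dt
    vref <- matrix(0, nd, 2)
    add <- function(onset, dur, dir_unit, amp) {
      p <- raised_cosine_pulse(td, onset, dur, amp)
      vref[, 1] <<- vref[, 1] + p * dir_unit[1]
      vref[, 2] <<- vref[, 2] + p * dir_unit[2]
    }
    if (genotype == "chr2" && effect_size > 0) {
      th <- stats::runif(n_trains, 0, 2 * pi)
      for (i in seq_len(n_trains))
        add(onsets[i], train_duration, c(cos(th[i]), sin(th[i])),
            effect_size)
    } else {
      # keep the RNG stream aligned across genotypes
      stats::runif(n_trains, 0, 2 * pi)
    }
    n_spont <- stats::rpois(1, spontaneous_bout_rate * duration)
    if (n_spont > 0) {
      on_s <- stats::runif(n_spont, 0, duration - bout_duration)
      ths <- stats::runif(n_spont, 0, 2 * pi)
      ams <- stats::runif(n_spont, 0.5, 1) * bout_amplitude
      for (j in seq_len(n_spont))
        add(on_s[j], bout_duration, c(cos(ths[j]), sin(ths[j])), ams[j])
    }
    sim <- simulate_control_trajectory(params, vref, seed = seed + 7919L)
    trains <- data.frame(onset = onsets, offset = offsets,
                         frequency_hz = freqs)
    list(tracking = sim$tracking, stim_trains = trains, genotype = genotype,
         events = session_events(numeric(0), numeric(0), character(0),
                                 stim_trains = trains))
  })
}

#' Session-level stimulation summaries for ANOVA calibration
#'
#' Lightweight generator of the session-summary layer consumed by
#' [stim_anova()]: per session one peak-speed and one distance value, drawn
#' from Gaussians with an additive genotype effect. Used for type-I-error
#' and power calibration of the two-way ANOVA at replicate counts where
#' full trajectory simulation would be wasteful (the ANOVA only ever sees
#' this layer).
#'
#' @param n_per_cell Sessions per genotype x frequency cell.
#' @param frequencies Frequency levels (Hz).
#' @param effect_speed,effect_distance Additive ChR2 effect on peak speed
#'   (mm/s) and distance (mm); 0 = null.
#' @param mu_speed,sd_speed,mu_distance,sd_distance Baseline distribution of
#'   the session summaries. Session-level SDs are small (default 1.2)
#'   because each summary averages over a session's many trains.
#' @param seed RNG seed.
#' @return Data frame: `genotype`, `frequency`, `peak_speed`, `distance`.
#' @export
simulate_stim_summaries <- function(n_per_cell = 4,
                                    frequencies = c(11, 15, 25),
                                    effect_speed = 0, effect_distance = 0,
                                    mu_speed = 20, sd_speed = 1.2,
                                    mu_distance = 10, sd_distance = 1.2,
                                    seed = 1) {
  with_seed(seed, {
    df <- expand.grid(rep = seq_len(n_per_cell),
                      genotype = c("control", "chr2"),
                      frequency = frequencies, stringsAsFactors = FALSE)
    chr2 <- df$genotype == "chr2"
    n <- nrow(df)
    df$peak_speed <- stats::rnorm(n, mu_speed, sd_speed) +
      ifelse(chr2, effect_speed, 0)
    df$distance <- stats::rnorm(n, mu_distance, sd_distance) +
      ifelse(chr2, effect_distance, 0)
    df$rep <- NULL
    df
  })
}
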