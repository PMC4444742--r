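#' Construct a tracking series
#'
#' A `tracking_series` is the raw behavioral record: timestamped 2D head
#' position, as extracted from video tracking of a head-mounted LED. Times
#' are in seconds from session start; coordinates are in mm, with x
#' increasing rightward and y increasing upward in the animal's frame.
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param x,y Numeric vectors of positions in mm, same length as `t`.
#' @param frame_rate_nominal Nominal camera frame rate in Hz (default 30).
#'   Used to detect tracking dropouts: gaps longer than 3 nominal frame
#'   intervals are masked out of downstream analyses.
#' @return An object of class `tracking_series`.
#' @export
tracking_series <- function(t, x, y, frame_rate_nominal = 30) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  if (length(t) < 2L) stop("tracking_series: length >= 2 required")
  if (length(x) != length(t) || length(y) != length(t))
    stop("tracking_series: t, x, y must have equal length")
  if (any(!is.finite(t))) stop("tracking_series: t must be finite")
  if (any(diff(t) <= 0)) stop("tracking_series: t strictly increasing")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("tracking_series: x, y must be finite")
  if (!is.numeric(frame_rate_nominal) || frame_rate_nominal <= 0)
    stop("tracking_series: frame_rate_nominal must be > 0")
  structure(list(t = t, x = x, y = y,
                 frame_rate_nominal = frame_rate_nominal),
            class = "tracking_series")
}

#' @export
print.tracking_series <- function(x, ...) {
  cat(sprintf("<tracking_series> %d frames, %.1f s, nominal %g fps\n",
              length(x$t), diff(range(x$t)), x$frame_rate_nominal))
  invisible(x)
}

#' Tracking dropout intervals
#'
#' Returns intervals between consecutive tracking samples whose spacing
#' exceeds `gap_factor` nominal frame intervals. Bins falling inside these
#' intervals are excluded from all downstream correlation analyses rather
#' than interpolated across.
#'
#' @param tracking A [tracking_series()].
#' @param gap_factor Multiplier on the nominal frame interval (default 3).
#' @return A two-column matrix (start, end) in seconds; zero rows if none.
#' @export
tracking_gaps <- function(tracking, gap_factor = 3) {
  stopifnot(inherits(tracking, "tracking_series"))
  dt_nom <- 1 / tracking$frame_rate_nominal
  d <- diff(tracking$t)
  i <- which(d > gap_factor * dt_nom)
  if (length(i) == 0L)
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  cbind(start = tracking$t[i], end = tracking$t[i + 1L])
}

#' Construct session events
#'
#' Trial structure of the trace-conditioning task: per trial a brief tone
#' (cue) followed, after a trace interval, by an outcome (sucrose reward or
#' aversive air puff), plus optional optogenetic stimulation trains.
#'
#' @param cue_onsets Numeric vector of cue onset times (s).
#' @param outcome_times Numeric vector of outcome delivery times (s), one
#'   per trial, each later than its cue onset.
#' @param outcome_type Character vector, `"sucrose"` or `"airpuff"`, one per
#'   trial (recycled if length 1).
#' @param stim_trains Optional data.frame with columns `onset`, `offset`,
#'   `frequency_hz` describing non-overlapping stimulation trains; `NULL`
#'   or zero rows if none.
#' @return An object of class `session_events`.
#' @export
session_events <- function(cue_onsets, outcome_times, outcome_type = "sucrose",
                           stim_trains = NULL) {
  cue_onsets <- as.numeric(cue_onsets)
  outcome_times <- as.numeric(outcome_times)
  if (length(cue_onsets) != length(outcome_times))
    stop("session_events: one outcome per cue required")
  if (length(outcome_type) == 1L)
    outcome_type <- rep(outcome_type, length(cue_onsets))
  if (length(outcome_type) != length(cue_onsets))
    stop("session_events: outcome_type length mismatch")
  if (!all(outcome_type %in% c("sucrose", "airpuff")))
    stop("session_events: outcome_type must be 'sucrose' or 'airpuff'")
  if (any(outcome_times <= cue_onsets))
    stop("session_events: each outcome_time > its paired cue_onset")
  if (is.null(stim_trains)) {
    stim_trains <- data.frame(onset = numeric(0), offset = numeric(0),
                              frequency_hz = numeric(0))
  } else {
    stim_trains <- as.data.frame(stim_trains)
    need <- c("onset", "offset", "frequency_hz")
    if (!all(need %in% names(stim_trains)))
      stop("session_events: stim_trains needs columns onset, offset, frequency_hz")
    stim_trains <- stim_trains[need]
    if (nrow(stim_trains) > 0) {
      if (any(stim_trains$offset <= stim_trains$onset))
        stop("session_events: train offset must exceed onset")
      o <- order(stim_trains$onset)
      stim_trains <- stim_trains[o, , drop = FALSE]
      if (nrow(stim_trains) > 1 &&
          any(stim_trains$onset[-1] < stim_trains$offset[-nrow(stim_trains)]))
        stop("session_events: stim trains must be non-overlapping")
      rownames(stim_trains) <- NULL
    }
  }
  structure(list(cue_onsets = cue_onsets, outcome_times = outcome_times,
                 outcome_type = outcome_type, stim_trains = stim_trains),
            class = "session_events")
}

#' Construct a unit recording
#'
#' Spike timestamps and metadata for one isolated single unit. The putative
#' cell class (dopaminergic vs GABAergic) is carried as metadata; see
#' [classify_cell_type()] for the rate/spike-width rule.
#'
#' @param unit_id Character id.
#' @param spike_times Numeric vector of spike times (s), non-negative;
#'   sorted internally.
#' @param hemisphere `"left"`, `"right"` or `"unknown"`.
#' @param mean_rate Mean firing rate (Hz); if `NULL`, computed from
#'   `spike_times` and `span` when `span` is given.
#' @param spike_width_fwhm Spike width at half maximum (ms), or `NA`.
#' @param putative_class `"DA"`, `"GABA"` or `"unknown"`.
#' @param span Optional session span (s) used to compute `mean_rate`.
#' @return An object of class `unit_recording`.
#' @export
unit_recording <- function(unit_id, spike_times, hemisphere = "unknown",
                           mean_rate = NULL, spike_width_fwhm = NA_real_,
                           putative_class = "unknown", span = NULL) {
  spike_times <- sort(as.numeric(spike_times))
  if (length(spike_times) && any(spike_times < 0))
    stop("unit_recording: spike_times must be non-negative")
  if (!hemisphere %in% c("left", "right", "unknown"))
    stop("unit_recording: hemisphere must be left/right/unknown")
  if (!putative_class %in% c("DA", "GABA", "unknown"))
    stop("unit_recording: putative_class must be DA/GABA/unknown")
  if (is.null(mean_rate)) {
    mean_rate <- if (!is.null(span) && span > 0) length(spike_times) / span
                 else NA_real_
  }
  if (!is.na(mean_rate) && mean_rate < 0)
    stop("unit_recording: mean_rate must be >= 0")
  if (!is.na(spike_width_fwhm) && spike_width_fwhm <= 0)
    stop("unit_recording: spike_width_fwhm must be > 0 when present")
  structure(list(unit_id = as.character(unit_id), spike_times = spike_times,
                 hemisphere = hemisphere, mean_rate = mean_rate,
                 spike_width_fwhm = spike_width_fwhm,
                 putative_class = putative_class),
            class = "unit_recording")
}

#' Construct a session bundle
#'
#' One recording session: tracking, trial events, and the units recorded in
#' it, plus free-form provenance metadata (seed and generator parameters for
#' synthetic sessions).
#'
#' @param tracking A [tracking_series()].
#' @param events A [session_events()].
#' @param units List of [unit_recording()] objects.
#' @param provenance Named list of free-form metadata.
#' @param spike_tolerance Slack (s) allowed for spikes just outside the
#'   tracking span (default 0.5).
#' @return An object of class `session_bundle`.
#' @export
session_bundle <- function(tracking, events, units = list(),
                           provenance = list(), spike_tolerance = 0.5) {
  stopifnot(inherits(tracking, "tracking_series"),
            inherits(events, "session_events"))
  span <- range(tracking$t)
  ev <- c(events$cue_onsets, events$outcome_times,
          events$stim_trains$onset, events$stim_trains$offset)
  if (length(ev) && (any(ev < span[1]) || any(ev > span[2])))
    stop("session_bundle: all event times within tracking time span")
  for (u in units) {
    stopifnot(inherits(u, "unit_recording"))
    if (length(u$spike_times) &&
        (u$spike_times[1] < span[1] - spike_tolerance ||
         u$spike_times[length(u$spike_times)] > span[2] + spike_tolerance))
      stop(sprintf("session_bundle: unit %s has spikes outside tracking span",
                   u$unit_id))
  }
  names(units) <- vapply(units, `[[`, character(1), "unit_id")
  structure(list(tracking = tracking, events = events, units = units,
                 provenance = provenance),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle> %d trials, %d units, %.1f s of tracking\n",
              length(x$events$cue_onsets), length(x$units),
              diff(range(x$tracking$t))))
  invisible(x)
}

fmt_num <- function(v) sprintf("%.9f", v)

#' Write a session bundle to a directory
#'
#' Plain-text layout: `tracking.csv` (t,x,y), `events.csv`
#' (trial,cue_onset,outcome_time,outcome_type), `stim.csv`
#' (onset,offset,frequency_hz; only when trains exist),
#' `units/<unit_id>.csv` (spike_time) and `units/meta.json`. Numbers are
#' formatted with 9 decimal places so output is byte-stable and round-trips
#' within 1e-9.
#'
#' @param bundle A [session_bundle()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(bundle, dir) {
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(file.path(dir, "units"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("write_session: cannot create ", dir)

  tr <- bundle$tracking
  writeLines(c("t,x,y",
               paste(fmt_num(tr$t), fmt_num(tr$x), fmt_num(tr$y), sep = ",")),
             file.path(dir, "tracking.csv"))

  ev <- bundle$events
  writeLines(c("trial,cue_onset,outcome_time,outcome_type",
               paste(seq_along(ev$cue_onsets), fmt_num(ev$cue_onsets),
                     fmt_num(ev$outcome_times), ev$outcome_type, sep = ",")),
             file.path(dir, "events.csv"))

  if (nrow(ev$stim_trains) > 0) {
    st <- ev$stim_trains
    writeLines(c("onset,offset,frequency_hz",
                 paste(fmt_num(st$onset), fmt_num(st$offset),
                       fmt_num(st$frequency_hz), sep = ",")),
               file.path(dir, "stim.csv"))
  }

  meta <- list(frame_rate_nominal = tr$frame_rate_nominal,
               provenance = bundle$provenance,
               units = lapply(bundle$units, function(u)
                 list(hemisphere = u$hemisphere, mean_rate = u$mean_rate,
                      fwhm_ms = u$spike_width_fwhm,
                      putative_class = u$putative_class)))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null", na = "null"),
             file.path(dir, "units", "meta.json"))
  for (u in bundle$units) {
    writeLines(c("spike_time", fmt_num(u$spike_times)),
               file.path(dir, "units", paste0(u$unit_id, ".csv")))
  }
  invisible(dir)
}

read_csv_checked <- function(path, cols) {
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop(sprintf("parse error in %s: %s", path, conditionMessage(e))))
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("parse error in %s: missing columns %s", path,
                 paste(missing, collapse = ", ")))
  for (cc in cols) {
    if (cc %in% c("outcome_type")) next
    if (nrow(df) == 0L) { df[[cc]] <- numeric(0); next }
    if (!is.numeric(df[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cc]]))))[1]
      stop(sprintf("parse error in %s line %d: non-numeric value in column %s",
                   path, if (is.na(bad)) -1L else bad + 1L, cc))
    }
  }
  df
}

#' Read a session bundle from a directory
#'
#' Inverse of [write_session()]; validates every invariant of the data
#' model (monotone timestamps, paired events inside the tracking span,
#' sorted spikes) and fails with an error naming the file or invariant.
#'
#' @param dir Directory produced by [write_session()] or conforming to its
#'   layout.
#' @param camera_mirrored_x If `TRUE`, flip the x coordinate at load (for
#'   data recorded with a camera facing the animal, whose image left/right
#'   is the mirror of the animal's left/right).
#' @return A [session_bundle()].
#' @export
read_session <- function(dir, camera_mirrored_x = FALSE) {
  tp <- file.path(dir, "tracking.csv")
  if (!file.exists(tp)) stop("read_session: missing ", tp)
  trd <- read_csv_checked(tp, c("t", "x", "y"))

  meta_path <- file.path(dir, "units", "meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::fromJSON(meta_path, simplifyVector = FALSE) else list()
  fr <- if (!is.null(meta$frame_rate_nominal)) meta$frame_rate_nominal else 30

  x <- if (camera_mirrored_x) -trd$x else trd$x
  tracking <- tracking_series(trd$t, x, trd$y, frame_rate_nominal = fr)

  evd <- read_csv_checked(file.path(dir, "events.csv"),
                          c("trial", "cue_onset", "outcome_time", "outcome_type"))
  sp <- file.path(dir, "stim.csv")
  stim <- if (file.exists(sp))
    read_csv_checked(sp, c("onset", "offset", "frequency_hz")) else NULL
  events <- session_events(evd$cue_onset, evd$outcome_time, evd$outcome_type,
                           stim_trains = stim)

  unit_files <- list.files(file.path(dir, "units"), pattern = "\\.csv$",
                           full.names = TRUE)
  units <- lapply(unit_files, function(f) {
    uid <- sub("\\.csv$", "", basename(f))
    sd <- read_csv_checked(f, "spike_time")
    m <- meta$units[[uid]]
    unit_recording(uid, sd$spike_time,
                   hemisphere = if (!is.null(m$hemisphere)) m$hemisphere else "unknown",
                   mean_rate = if (!is.null(m$mean_rate)) m$mean_rate else NULL,
                   spike_width_fwhm = if (!is.null(m$fwhm_ms) && !is.na(m$fwhm_ms))
                     m$fwhm_ms else NA_real_,
                   putative_class = if (!is.null(m$putative_class)) m$putative_class
                     else "unknown",
                   span = diff(range(trd$t)))
  })
  session_bundle(tracking, events, units,
                 provenance = if (!is.null(meta$provenance)) meta$provenance
                   else list())
}

#' Write analysis reports
#'
#' Writes `classifications.csv` (one row per unit: its class variable,
#' direction, correlation sign, best lag, r and p) and `population.json`
#' (the population tables and test statistics).
#'
#' @param classifications Data frame as returned by [classification_table()].
#' @param population Named list of population statistics (from
#'   [analyze_session()] or assembled manually).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(classifications, population, dir) {
  if (is.null(classifications) || nrow(classifications) == 0L)
    stop("write_report: results non-empty required")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- classifications
  num <- vapply(df, is.numeric, logical(1))
  rows <- do.call(paste, c(lapply(seq_along(df), function(j)
    if (num[j]) ifelse(is.na(df[[j]]), "NA", sprintf("%.9g", df[[j]]))
    else as.character(df[[j]])), sep = ","))
  writeLines(c(paste(names(df), collapse = ","), rows),
             file.path(dir, "classifications.csv"))
  if (all(classifications$class_variable == "uncorrelated"))
    population <- c(population, list(note = "no classified units"))
  writeLines(jsonlite::toJSON(population, auto_unbox = TRUE, pretty = TRUE,
                              digits = 10, na = "null", null = "null",
                              force = TRUE),
             file.path(dir, "population.json"))
  invisible(dir)
}
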