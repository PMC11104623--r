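#' Construct a gaze-sample stream for one trial
#'
#' A gaze stream is a uniformly sampled (default 1000 Hz, i.e. 1 ms period)
#' record of eye position for a single trial, together with the trial's event
#' timestamps. Time is in milliseconds, position in degrees of visual angle
#' relative to the fixation cross.
#'
#' @param t numeric vector of sample times, ms, strictly increasing and
#'   uniformly spaced with no gaps.
#' @param x,y numeric vectors of gaze position, deg.
#' @param fixation_off_t time of fixation-cross offset (the go signal), ms.
#' @param feedback_onset_t optional time of feedback onset, ms.
#' @return An object of class `gaze_stream`.
#' @export
gaze_stream <- function(t, x, y, fixation_off_t = t[1],
                        feedback_onset_t = NULL) {
  if (length(t) < 2L || length(x) != length(t) || length(y) != length(t)) {
    stop("`t`, `x`, `y` must have equal length >= 2", call. = FALSE)
  }
  dt <- diff(t)
  if (any(dt <= 0)) stop("`t` must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-9) {
    stop("gaze stream has non-uniform sampling (missing samples?)",
         call. = FALSE)
  }
  structure(list(t = t, x = x, y = y, dt = dt[1],
                 fixation_off_t = fixation_off_t,
                 feedback_onset_t = feedback_onset_t),
            class = "gaze_stream")
}

#' @export
print.gaze_stream <- function(x, ...) {
  cat(sprintf("Gaze stream: %d samples at %.0f Hz, t = [%g, %g] ms\n",
              length(x$t), 1000 / x$dt, x$t[1], x$t[length(x$t)]))
  cat("  fixation-cross offset at", x$fixation_off_t, "ms\n")
  invisible(x)
}

#' Per-sample gaze speed
#'
#' Speed in deg/s by a two-point backward difference (causal, matching the
#' online setting); the first sample gets speed 0. An optional centred
#' moving-average smoother can be applied afterwards.
#'
#' @param stream a [gaze_stream()].
#' @param smooth_window odd integer; 1 (default) disables smoothing.
#' @return Numeric vector of speeds, deg/s, same length as the stream.
#' @export
estimate_velocity <- function(stream, smooth_window = 1L) {
  stopifnot(inherits(stream, "gaze_stream"))
  if (length(stream$t) < 3L) {
    stop("stream too short: need at least 3 samples", call. = FALSE)
  }
  step <- sqrt(diff(stream$x)^2 + diff(stream$y)^2)
  speed <- c(0, step / (stream$dt / 1000))
  if (smooth_window > 1L) {
    if (smooth_window %% 2L == 0L) {
      stop("`smooth_window` must be odd", call. = FALSE)
    }
    k <- rep(1 / smooth_window, smooth_window)
    sm <- stats::filter(speed, k, sides = 2)
    speed <- ifelse(is.na(sm), speed, as.numeric(sm))
  }
  speed
}

#' Online saccade-onset trigger
#'
#' The simulated system's trigger: the first sample at which gaze speed
#' exceeds `v_threshold` (100 deg/s) *and* the eye has travelled at least
#' `travel_threshold` (3 deg) from the fixation cross. Returns the trigger
#' time, or `NA` if the criterion is never met. Note this is the system
#' trigger, not a precise estimate of kinematic onset: the travel criterion
#' intentionally delays it past the start of the movement (see
#' [parse_trial()] for onset timing of recorded events).
#'
#' @param stream a [gaze_stream()].
#' @param fixation c(x, y) of the fixation cross, deg.
#' @param v_threshold speed criterion, deg/s.
#' @param travel_threshold distance-from-fixation criterion, deg.
#' @param from earliest time (ms) considered; defaults to fixation-cross
#'   offset.
#' @return Trigger time in ms, or `NA_real_`.
#' @export
detect_onset_online <- function(stream, fixation = c(0, 0),
                                v_threshold = 100, travel_threshold = 3,
                                from = stream$fixation_off_t) {
  stopifnot(inherits(stream, "gaze_stream"))
  speed <- estimate_velocity(stream)
  dist <- sqrt((stream$x - fixation[1])^2 + (stream$y - fixation[2])^2)
  ok <- stream$t >= from & speed > v_threshold & dist >= travel_threshold
  k <- which(ok)[1]
  if (is.na(k)) NA_real_ else stream$t[k]
}

#' Online saccade-offset detection and endpoint
#'
#' The saccade ends at the earliest sample after `after` at which the mean
#' gaze speed over the last three samples falls below `v_threshold`
#' (30 deg/s); the endpoint is the last of those three samples.
#'
#' @param stream a [gaze_stream()].
#' @param after onset time in ms; only samples strictly later are considered.
#' @param v_threshold exit speed criterion, deg/s.
#' @return A list with `offset_t` (ms) and `endpoint` (list with `x`, `y`).
#' @export
detect_offset_online <- function(stream, after, v_threshold = 30) {
  stopifnot(inherits(stream, "gaze_stream"))
  speed <- estimate_velocity(stream)
  n <- length(speed)
  if (n < 3L) stop("stream too short: need at least 3 samples", call. = FALSE)
  m3 <- (speed + c(0, speed[-n]) + c(0, 0, speed[-c(n - 1, n)])) / 3
  ok <- seq_len(n) >= 3L & stream$t > after & m3 < v_threshold
  k <- which(ok)[1]
  if (is.na(k)) {
    stop("unterminated saccade: offset criterion never met", call. = FALSE)
  }
  list(offset_t = stream$t[k],
       endpoint = list(x = stream$x[k], y = stream$y[k]))
}

#' Parse a trial's gaze stream into saccade events
#'
#' Offline event parser used for analysis (and, with its defaults, matching
#' the simulated system's criteria). A saccade is found where speed exceeds
#' `v_onset` (100 deg/s); its onset is then backdated to the first sample of
#' the velocity rise (the sample after speed last dropped below
#' `v_baseline`), the usual offline convention, so onset times track the
#' kinematic movement start rather than the threshold crossing. Offset
#' follows the three-sample rule of [detect_offset_online()].
#' The first saccade after fixation-cross
#' offset is the primary saccade; later saccades starting within
#' `secondary_window` ms of the primary offset are secondary; still later
#' ones are labelled `"other"`. Validity flags follow [filter_primary()] and
#' [filter_secondary()].
#'
#' @param stream a [gaze_stream()].
#' @param v_onset onset speed criterion, deg/s.
#' @param v_baseline baseline speed (deg/s) used to backdate the onset.
#' @param v_offset offset (exit) speed criterion, deg/s.
#' @param secondary_window latency window (ms after primary offset) within
#'   which a saccade counts as secondary.
#' @param refractory minimum gap (ms) after an offset before a new onset is
#'   accepted.
#' @return A data frame of class `saccade_events`, one row per saccade:
#'   `onset_t`, `offset_t`, `duration`, `amplitude`, `end_x`, `end_y`,
#'   `latency`, `order` ("primary"/"secondary"/"other") and `valid`.
#'   Zero rows (with attribute `flagged = TRUE`) when no primary saccade is
#'   found.
#' @export
parse_trial <- function(stream, v_onset = 100, v_baseline = 10,
                        v_offset = 30, secondary_window = c(100, 500),
                        refractory = 10) {
  stopifnot(inherits(stream, "gaze_stream"))
  speed <- estimate_velocity(stream)
  n <- length(speed)
  m3 <- (speed + c(0, speed[-n]) + c(0, 0, speed[-c(n - 1, n)])) / 3
  start_k <- which(stream$t >= stream$fixation_off_t)[1]
  events <- list()
  k <- max(start_k, 2L)
  while (!is.na(k) && k <= n) {
    rel <- which(speed[k:n] > v_onset)[1]
    if (is.na(rel)) break
    cross_k <- k + rel - 1L
    # backdate onset to the start of the velocity rise
    on_k <- cross_k
    while (on_k > k && speed[on_k - 1L] > v_baseline) on_k <- on_k - 1L
    off_rel <- which(seq_len(n) > cross_k & seq_len(n) >= 3L & m3 < v_offset)
    if (length(off_rel) == 0L) break # unterminated: drop trailing movement
    off_k <- off_rel[1]
    # movement start position = sample before the onset
    s_k <- max(on_k - 1L, 1L)
    events[[length(events) + 1L]] <- data.frame(
      onset_t = stream$t[on_k],
      offset_t = stream$t[off_k],
      start_x = stream$x[s_k], start_y = stream$y[s_k],
      end_x = stream$x[off_k], end_y = stream$y[off_k]
    )
    k <- off_k + max(1L, as.integer(round(refractory / stream$dt)))
  }
  if (length(events) == 0L) {
    out <- data.frame(onset_t = numeric(0), offset_t = numeric(0),
                      duration = numeric(0), amplitude = numeric(0),
                      start_x = numeric(0), start_y = numeric(0),
                      end_x = numeric(0), end_y = numeric(0),
                      latency = numeric(0), order = character(0),
                      valid = logical(0))
    class(out) <- c("saccade_events", "data.frame")
    attr(out, "flagged") <- TRUE
    return(out)
  }
  ev <- do.call(rbind, events)
  ev$duration <- ev$offset_t - ev$onset_t
  ev$amplitude <- sqrt((ev$end_x - ev$start_x)^2 + (ev$end_y - ev$start_y)^2)
  ev$order <- "other"
  ev$order[1] <- "primary"
  ev$latency <- NA_real_
  ev$latency[1] <- ev$onset_t[1] - stream$fixation_off_t
  if (nrow(ev) > 1L) {
    lat2 <- ev$onset_t[-1] - ev$offset_t[1]
    ev$latency[-1] <- lat2
    ev$order[-1][lat2 <= secondary_window[2]] <- "secondary"
  }
  ev$valid <- FALSE
  ev$valid[1] <- filter_primary(ev[1, , drop = FALSE])
  sec <- ev$order == "secondary"
  if (any(sec)) ev$valid[sec] <- filter_secondary(ev[sec, , drop = FALSE])
  out <- ev[, c("onset_t", "offset_t", "duration", "amplitude",
                "start_x", "start_y", "end_x", "end_y",
                "latency", "order", "valid")]
  class(out) <- c("saccade_events", "data.frame")
  attr(out, "flagged") <- FALSE
  out
}

#' Validity filters for primary and secondary saccades
#'
#' A primary saccade is valid when its amplitude lies between 3.5 and 10.5
#' deg of visual angle (inclusive), its duration is under 100 ms (strict)
#' and its latency exceeds 100 ms (strict). A secondary saccade is valid
#' when its amplitude is under 5 deg (strict), its duration under 100 ms
#' (strict) and its latency (relative to the primary offset) lies in
#' \[100, 500\] ms (inclusive).
#'
#' @param e a data frame with columns `amplitude`, `duration`, `latency`
#'   (e.g. rows of [parse_trial()] output).
#' @return Logical vector of validity flags.
#' @export
filter_primary <- function(e) {
  e$amplitude >= 3.5 & e$amplitude <= 10.5 & e$duration < 100 &
    e$latency > 100
}

#' @rdname filter_primary
#' @export
filter_secondary <- function(e) {
  e$amplitude < 5 & e$duration < 100 & e$latency >= 100 & e$latency <= 500
}
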