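#' Saccade kinematic parameters for the synthetic generator
#'
#' The generator produces minimum-jerk saccade trajectories whose duration
#' follows the main-sequence relationship
#' `duration_ms = duration_slope * amplitude_deg + duration_intercept`
#' (defaults 2.2 and 21, standard main-sequence values for human saccades;
#' the recorded eyes of a real experiment are emulated, not reproduced).
#' Endpoint scatter is isotropic Gaussian (`endpoint_sd`, deg); aim
#' direction scatter is Gaussian on the clock angle (`angle_sd`, arc deg).
#' A sinusoidal bow of coefficient `bow` (deg, counterclockwise positive)
#' curves the trajectory; `gain` scales the planned amplitude (primary
#' saccades typically undershoot slightly). Primary latency is lognormal
#' with median `latency_median` ms (plus `latency_early_boost` ms during the
#' early learning phase, where saccade initiation slows while the feedback
#' contingency is being worked out); secondary-saccade latency is uniform on
#' `secondary_latency_range` ms after the primary offset. `feedback_delay`
#' emulates the detection-to-display delay of the interface (ms).
#'
#' @param duration_slope,duration_intercept main-sequence coefficients.
#' @param endpoint_sd,angle_sd,bow,gain kinematic noise/shape parameters.
#' @param latency_median,latency_sdlog,latency_early_boost latency model.
#' @param secondary_latency_range length-2 numeric, ms.
#' @param feedback_delay ms between detected saccade offset and feedback.
#' @return Object of class `kinematic_params`.
#' @export
kinematic_params <- function(duration_slope = 2.2, duration_intercept = 21,
                             endpoint_sd = 0.5, angle_sd = 5, bow = 0.15,
                             gain = 0.9,
                             latency_median = 350, latency_sdlog = 0.15,
                             latency_early_boost = 60,
                             secondary_latency_range = c(150, 350),
                             feedback_delay = 19) {
  stopifnot(endpoint_sd >= 0, angle_sd >= 0, gain > 0,
            duration_slope * 3.5 + duration_intercept > 0)
  structure(list(duration_slope = duration_slope,
                 duration_intercept = duration_intercept,
                 endpoint_sd = endpoint_sd, angle_sd = angle_sd,
                 bow = bow, gain = gain,
                 latency_median = latency_median,
                 latency_sdlog = latency_sdlog,
                 latency_early_boost = latency_early_boost,
                 secondary_latency_range = secondary_latency_range,
                 feedback_delay = feedback_delay),
            class = "kinematic_params")
}

#' Learner state for the simulated participant
#'
#' The learner carries an aim offset: the arc-deg angle (clockwise positive,
#' relative to the intended object) at which it aims its primary saccade.
#' 0 means aiming at the intended object; -45 means aiming at the optimal
#' point that cancels a +45 clockwise distortion. Two illustrative learning
#' modes are provided (the package makes no claim that either is what human
#' participants do):
#'
#' * `error_based` (suits motor feedback): the aim offset is corrected by a
#'   fraction `eta` of the signed angular error of the feedback dot relative
#'   to the intended object, the classic error-driven adaptation rule.
#' * `reward_based` (suits action feedback): win-stay/lose-shift; after a
#'   decoding error the aim offset is perturbed by a draw from a zero-mean
#'   Gaussian exploration kernel (`explore_sd` arc deg); after a success the
#'   offset is kept and the kernel width is multiplied by `explore_shrink`.
#'
#' `delay` trials pass before learning engages (the participant has not yet
#' connected feedback to behaviour); drawing it per participant staggers
#' convergence times across a cohort. `memory` and `savings` implement
#' cross-session savings: at the first feedback trial of a session with a
#' stored memory trace, the aim offset jumps to `savings * memory` and the
#' learning rate is multiplied by `relearn_boost`.
#'
#' @param mode `"error_based"` or `"reward_based"`.
#' @param eta learning rate in \[0, 1\] (error_based).
#' @param explore_sd,explore_shrink exploration kernel (reward_based).
#' @param aim_offset initial aim offset, arc deg in (-180, 180].
#' @param delay number of feedback trials before learning engages.
#' @param memory stored aim offset from a previous session (`NA` = none).
#' @param savings fraction of the memory trace retrieved, in \[0, 1\].
#' @param relearn_boost learning-rate multiplier applied on retrieval.
#' @return Object of class `learner_state`.
#' @export
learner_state <- function(mode = c("error_based", "reward_based"),
                          eta = 0.15, explore_sd = 20, explore_shrink = 0.9,
                          aim_offset = 0, delay = 0, memory = NA_real_,
                          savings = 0, relearn_boost = 2) {
  mode <- match.arg(mode)
  stopifnot(eta >= 0, eta <= 1, explore_sd >= 0, savings >= 0, savings <= 1)
  structure(list(mode = mode, eta = eta, explore_sd = explore_sd,
                 explore_shrink = explore_shrink,
                 aim_offset = wrap_angle(aim_offset),
                 delay = as.integer(delay),
                 memory = memory, savings = savings,
                 relearn_boost = relearn_boost, retrieved = FALSE),
            class = "learner_state")
}

#' Update the learner from one trial's feedback
#'
#' Applies one trial of learning (see [learner_state()] for the rules).
#' While the learner's engagement delay has not elapsed, the state is
#' returned unchanged except for the delay countdown. When no object was
#' decoded ("too far"), the motor-feedback dot is absent, so the
#' error-based learner receives no error vector and does not update; the
#' reward-based learner treats it as an unsuccessful trial.
#'
#' @param state a [learner_state()].
#' @param feedback one row of [render_feedback()] output.
#' @param outcome the matching row of [evaluate_trial()] output.
#' @param scene the [build_scene()] geometry.
#' @return The updated `learner_state`.
#' @export
learner_update <- function(state, feedback, outcome, scene) {
  stopifnot(inherits(state, "learner_state"))
  if (state$delay > 0L) {
    state$delay <- state$delay - 1L
    return(state)
  }
  intended_clock <- scene$object_clock_angle[outcome$intended_object]
  if (state$mode == "error_based") {
    if (feedback$feedback_kind == "dot") {
      err <- signed_angle(feedback$feedback_x, feedback$feedback_y,
                          intended_clock)
      state$aim_offset <- wrap_angle(state$aim_offset - state$eta * err)
    } else if (feedback$feedback_kind == "color") {
      # error-based learning from action feedback: the only error signal is
      # the angular offset of the decoded object from the intended one
      err <- wrap_angle(
        scene$object_clock_angle[outcome$decoded_object] - intended_clock)
      state$aim_offset <- wrap_angle(state$aim_offset - state$eta * err)
    }
    return(state)
  }
  # reward_based
  success <- !outcome$too_far && !isTRUE(outcome$decoding_error)
  if (success) {
    state$explore_sd <- max(2, state$explore_sd * state$explore_shrink)
  } else {
    state$aim_offset <- wrap_angle(state$aim_offset +
                                     rnorm(1, 0, state$explore_sd))
  }
  state
}

#' Generate one minimum-jerk saccade sampled at 1000 Hz
#'
#' Returns the movement trajectory (1 ms steps) together with the ground
#' truth the event detector can be validated against. The landing point is
#' the aim point plus isotropic Gaussian endpoint noise; duration follows
#' the main sequence; a sinusoidal bow of coefficient `bow` (deg) is added
#' perpendicular to the chord, positive = counterclockwise, so the
#' area-based curvature index of the trajectory is approximately
#' `2 * bow / pi`.
#'
#' @param start,aim numeric length-2 vectors `c(x, y)`, deg.
#' @param params a [kinematic_params()].
#' @param bow overrides `params$bow` when not `NULL`.
#' @return List with `t` (ms, 0-based), `x`, `y`, `duration` (ms),
#'   `landing` (c(x, y)), `amplitude` (planned, deg).
#' @export
generate_saccade <- function(start, aim, params = kinematic_params(),
                             bow = NULL) {
  amp <- sqrt(sum((aim - start)^2))
  if (!is.finite(amp) || amp <= 0) {
    stop("non-positive saccade amplitude", call. = FALSE)
  }
  if (is.null(bow)) bow <- params$bow
  dur <- max(10L, as.integer(round(params$duration_slope * amp +
                                     params$duration_intercept)))
  landing <- aim + rnorm(2, 0, params$endpoint_sd)
  tau <- (0:dur) / dur
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  chord <- landing - start
  len <- sqrt(sum(chord^2))
  perp <- c(-chord[2], chord[1]) / len # left of movement = counterclockwise
  bowing <- bow * sin(pi * tau)
  list(t = 0:dur,
       x = start[1] + s * chord[1] + bowing * perp[1],
       y = start[2] + s * chord[2] + bowing * perp[2],
       duration = dur,
       landing = landing,
       amplitude = amp)
}

#' Simulate one recording session of the gaze interface
#'
#' Runs the trial loop of one session: fixation (500-1000 ms uniform), go
#' signal, primary saccade toward the learner's current aim point, and, on
#' feedback trials, online endpoint detection, endpoint distortion,
#' decoding, feedback rendering and the learner update. Circle-off trials
#' (the pre/post baseline blocks) skip distortion, decoding, feedback and
#' learning. A corrective secondary saccade toward the learner's current
#' goal follows the primary after 150-350 ms.
#'
#' Two fidelity levels are available. `"stream"` synthesises the full
#' 1000 Hz gaze stream per trial and pushes it through the online detector
#' and the offline parser, so latencies, amplitudes, durations, curvature
#' and validity flags come from the detector just as they would for real
#' data. `"endpoint"` skips stream synthesis and uses the generator's
#' landing points directly (no curvature; detector-independent), which is
#' orders of magnitude faster and is meant for large cohort simulations
#' where only endpoint-derived quantities matter.
#'
#' @param layout a [session_layout()].
#' @param learner a [learner_state()].
#' @param params a [kinematic_params()].
#' @param scene a [build_scene()].
#' @param fidelity `"stream"` or `"endpoint"`.
#' @param keep_streams logical; keep the raw gaze streams (stream fidelity
#'   only; memory-heavy).
#' @param intended_seq optional integer vector of intended objects per
#'   trial; drawn uniformly when `NULL`.
#' @param participant,session,order_label identifiers copied into the trial
#'   table.
#' @return List of class `gaze_session`: `trials` (data frame), `learner`
#'   (final state), `streams` (list of [gaze_stream()] or `NULL`).
#' @export
simulate_session <- function(layout = session_layout(),
                             learner = learner_state(),
                             params = kinematic_params(),
                             scene = build_scene(),
                             fidelity = c("stream", "endpoint"),
                             keep_streams = FALSE,
                             intended_seq = NULL,
                             participant = 1L, session = 1L,
                             order_label = "motor-first") {
  fidelity <- match.arg(fidelity)
  n_tot <- layout$n_total
  if (is.null(intended_seq)) {
    intended_seq <- sample.int(scene$n_objects, n_tot, replace = TRUE)
  }
  phase <- assign_phase(seq_len(n_tot), layout)
  streams <- if (keep_streams && fidelity == "stream") vector("list", n_tot)
  # preallocated columns (the trial loop is the hot path of cohort runs)
  num <- function() rep(NA_real_, n_tot)
  C <- list(aim_offset = num(), latency = num(), amplitude = num(),
            duration = num(), end_x = num(), end_y = num(),
            curvature = num(), valid_primary = rep(NA, n_tot),
            sec_end_x = num(), sec_end_y = num(),
            n_valid_secondary = rep(NA_integer_, n_tot),
            true_onset = num(), true_offset = num(),
            true_land_x = num(), true_land_y = num(),
            dist_x = num(), dist_y = num(),
            decoded = rep(NA_integer_, n_tot),
            too_far = rep(NA, n_tot), decoding_error = rep(NA, n_tot),
            feedback_kind = rep(NA_character_, n_tot),
            feedback_x = num(), feedback_y = num(),
            colored_object = rep(NA_integer_, n_tot))
  is_fb_all <- seq_len(n_tot) > layout$n_pre &
    seq_len(n_tot) <= layout$n_pre + layout$n_feedback
  res_fields <- c("latency", "amplitude", "duration", "end_x", "end_y",
                  "curvature", "valid_primary", "sec_end_x", "sec_end_y",
                  "n_valid_secondary", "true_onset", "true_offset",
                  "true_land_x", "true_land_y")
  for (tr in seq_len(n_tot)) {
    is_fb <- is_fb_all[tr]
    intended <- intended_seq[tr]
    intended_clock <- scene$object_clock_angle[intended]
    if (is_fb && !learner$retrieved && !is.na(learner$memory)) {
      learner$aim_offset <- wrap_angle(learner$savings * learner$memory)
      learner$eta <- min(1, learner$eta *
                           (1 + learner$savings * (learner$relearn_boost - 1)))
      learner$retrieved <- TRUE
    }
    med <- params$latency_median +
      if (phase[tr] == "early") params$latency_early_boost else 0
    latency_true <- rlnorm(1, log(med), params$latency_sdlog)
    aim_clock <- intended_clock + learner$aim_offset +
      rnorm(1, 0, params$angle_sd)
    aim <- unlist(clock_to_xy(aim_clock, scene$object_radius * params$gain))
    goal <- unlist(clock_to_xy(intended_clock + learner$aim_offset,
                               scene$object_radius))
    if (fidelity == "stream") {
      res <- simulate_trial_stream(aim, goal, latency_true, params)
      if (keep_streams) streams[[tr]] <- res$stream
    } else {
      res <- simulate_trial_endpoint(aim, goal, latency_true, params)
    }
    for (f in res_fields) C[[f]][tr] <- res[[f]]
    if (is_fb && !is.na(res$end_x)) {
      dp <- apply_distortion(res$end_x, res$end_y, scene)
      decoded <- decode_object(dp$x, dp$y, scene)
      too_far <- is.na(decoded)
      derr <- if (too_far) NA else decoded != intended
      fb_kind <- if (too_far) "message" else
        if (layout$feedback == "motor") "dot" else "color"
      C$dist_x[tr] <- dp$x; C$dist_y[tr] <- dp$y
      C$decoded[tr] <- decoded
      C$too_far[tr] <- too_far
      C$decoding_error[tr] <- derr
      C$feedback_kind[tr] <- fb_kind
      if (fb_kind == "dot") {
        C$feedback_x[tr] <- dp$x; C$feedback_y[tr] <- dp$y
      }
      if (fb_kind == "color") C$colored_object[tr] <- decoded
      feedback <- list(feedback_kind = fb_kind,
                       feedback_x = dp$x, feedback_y = dp$y,
                       colored_object = if (fb_kind == "color") decoded
                                        else NA_integer_)
      outcome <- list(decoded_object = decoded, intended_object = intended,
                      too_far = too_far, decoding_error = derr)
      learner <- learner_update(learner, feedback, outcome, scene)
    }
    C$aim_offset[tr] <- learner$aim_offset
  }
  learner$memory <- learner$aim_offset
  trials <- data.frame(
    participant = participant, session = session, order = order_label,
    feedback = layout$feedback, trial = seq_len(n_tot),
    trial_type = ifelse(is_fb_all, "feedback", "circle_off"),
    phase = as.character(phase), intended = intended_seq, C
  )
  out <- list(trials = trials, learner = learner,
              streams = streams, layout = layout)
  class(out) <- "gaze_session"
  out
}

# Full-fidelity single trial: synthesise the 1 kHz stream, run the online
# detector (system role) and the offline parser (analysis role).
simulate_trial_stream <- function(aim, goal, latency_true, params) {
  fix_dur <- round(runif(1, 500, 1000))
  t_move <- fix_dur + round(latency_true)
  sac <- generate_saccade(c(0, 0), aim, params)
  land <- sac$landing
  sec_lat <- round(runif(1, params$secondary_latency_range[1],
                         params$secondary_latency_range[2]))
  sec_amp <- sqrt(sum((goal - land)^2))
  do_sec <- sec_amp > 0.2
  sec <- if (do_sec) generate_saccade(land, goal, params, bow = 0)
  pre <- t_move # samples 0..t_move-1 at fixation
  xs <- c(rep(0, pre), sac$x)
  ys <- c(rep(0, pre), sac$y)
  hold1 <- sec_lat
  xs <- c(xs, rep(land[1], hold1))
  ys <- c(ys, rep(land[2], hold1))
  if (do_sec) {
    xs <- c(xs, sec$x[-1], rep(sec$landing[1], 200))
    ys <- c(ys, sec$y[-1], rep(sec$landing[2], 200))
  } else {
    xs <- c(xs, rep(land[1], 200))
    ys <- c(ys, rep(land[2], 200))
  }
  stream <- gaze_stream(seq_along(xs) - 1, xs, ys, fixation_off_t = fix_dur)
  ev <- parse_trial(stream)
  prim <- ev[ev$order == "primary", , drop = FALSE]
  sec_ev <- ev[ev$order == "secondary" & ev$valid, , drop = FALSE]
  out <- list(true_onset = t_move, true_offset = t_move + sac$duration,
              true_land_x = land[1], true_land_y = land[2])
  if (nrow(prim) == 0L) {
    out <- c(out, list(latency = NA_real_, amplitude = NA_real_,
                       duration = NA_real_, end_x = NA_real_,
                       end_y = NA_real_, curvature = NA_real_,
                       valid_primary = FALSE, sec_end_x = NA_real_,
                       sec_end_y = NA_real_, n_valid_secondary = 0L,
                       stream = stream))
    return(out)
  }
  ii <- which(stream$t >= prim$onset_t[1] & stream$t <= prim$offset_t[1])
  curv <- if (length(ii) >= 2 &&
              (stream$x[ii[1]] != stream$x[ii[length(ii)]] ||
               stream$y[ii[1]] != stream$y[ii[length(ii)]])) {
    curvature_index(stream$x[ii], stream$y[ii])
  } else NA_real_
  c(out, list(
    latency = prim$latency[1], amplitude = prim$amplitude[1],
    duration = prim$duration[1], end_x = prim$end_x[1],
    end_y = prim$end_y[1], curvature = curv,
    valid_primary = prim$valid[1],
    sec_end_x = if (nrow(sec_ev)) sec_ev$end_x[1] else NA_real_,
    sec_end_y = if (nrow(sec_ev)) sec_ev$end_y[1] else NA_real_,
    n_valid_secondary = nrow(sec_ev),
    stream = stream))
}

# Fast single trial: analytic endpoints, no stream synthesis or detection.
simulate_trial_endpoint <- function(aim, goal, latency_true, params) {
  amp <- sqrt(sum(aim^2))
  dur <- max(10, round(params$duration_slope * amp +
                         params$duration_intercept))
  land <- aim + rnorm(2, 0, params$endpoint_sd)
  sec_land <- goal + rnorm(2, 0, params$endpoint_sd)
  amp_real <- sqrt(sum(land^2))
  list(latency = latency_true, amplitude = amp_real, duration = dur,
       end_x = land[1], end_y = land[2], curvature = NA_real_,
       valid_primary = amp_real >= 3.5 && amp_real <= 10.5 &&
         dur < 100 && latency_true > 100,
       sec_end_x = sec_land[1], sec_end_y = sec_land[2],
       n_valid_secondary = NA_integer_,
       true_onset = NA_real_, true_offset = NA_real_,
       true_land_x = land[1], true_land_y = land[2])
}

#' @export
print.gaze_session <- function(x, ...) {
  tt <- x$trials
  cat(sprintf("Simulated session: %d trials (%s feedback), participant %s\n",
              nrow(tt), x$layout$feedback, tt$participant[1]))
  fb <- tt[tt$trial_type == "feedback", ]
  ok <- mean(!is.na(fb$decoded) & fb$decoded == fb$intended)
  cat(sprintf("  valid decoding rate over feedback trials: %.3f\n", ok))
  cat(sprintf("  final aim offset: %.1f arc deg\n",
              x$learner$aim_offset))
  invisible(x)
}

#' Simulate a two-session cohort with counterbalanced feedback order
#'
#' Every participant completes one session with motor feedback and one with
#' action feedback; half the cohort (the first `n/2` participants) receives
#' motor feedback first. Session 2 starts with a neutral aim (baseline
#' behaviour is unaffected by prior learning) and retrieves the stored aim
#' offset, scaled by `savings`, at the first feedback trial; the engagement
#' delay of session 2 shrinks by the same factor. Per-participant engagement
#' delays drawn from `delay_range` stagger convergence across the cohort.
#'
#' @param n_participants cohort size (even, so order is counterbalanced).
#' @param savings fraction of the learned aim offset retrieved in session 2.
#' @param mode learner mode for all participants (see [learner_state()]).
#' @param eta learning rate.
#' @param delay_range integer range of engagement delays (feedback trials).
#' @param layout_args list of arguments for [session_layout()] shared by
#'   both sessions (feedback type is set per session).
#' @param params a [kinematic_params()].
#' @param scene a [build_scene()].
#' @param fidelity `"endpoint"` (fast, default) or `"stream"`.
#' @param seed optional integer seed (RNG state restored afterwards).
#' @return Object of class `gaze_cohort`: list with `trials` (one data
#'   frame for the whole cohort), `scene`, `config`.
#' @examples
#' coh <- simulate_experiment(n_participants = 4, seed = 1)
#' table(coh$trials$phase, coh$trials$session)
#' @export
simulate_experiment <- function(n_participants = 22, savings = 0.8,
                                mode = "error_based", eta = 0.15,
                                delay_range = c(10, 80),
                                layout_args = list(),
                                params = kinematic_params(),
                                scene = build_scene(),
                                fidelity = "endpoint",
                                seed = NULL) {
  stopifnot(n_participants >= 2)
  with_seed(seed, {
    all_rows <- vector("list", n_participants)
    half <- ceiling(n_participants / 2)
    for (p in seq_len(n_participants)) {
      motor_first <- p <= half
      order_label <- if (motor_first) "motor-first" else "action-first"
      fb1 <- if (motor_first) "motor" else "action"
      fb2 <- if (motor_first) "action" else "motor"
      lay1 <- do.call(session_layout, c(layout_args, list(feedback = fb1)))
      lay2 <- do.call(session_layout, c(layout_args, list(feedback = fb2)))
      delay1 <- sample(delay_range[1]:delay_range[2], 1)
      ln1 <- learner_state(mode = mode, eta = eta, delay = delay1)
      s1 <- simulate_session(lay1, ln1, params, scene, fidelity = fidelity,
                             participant = p, session = 1L,
                             order_label = order_label)
      delay2 <- round((1 - savings) * sample(delay_range[1]:delay_range[2], 1))
      ln2 <- learner_state(mode = mode, eta = eta, delay = delay2,
                           memory = s1$learner$memory, savings = savings)
      s2 <- simulate_session(lay2, ln2, params, scene, fidelity = fidelity,
                             participant = p, session = 2L,
                             order_label = order_label)
      all_rows[[p]] <- rbind(s1$trials, s2$trials)
    }
    out <- list(trials = do.call(rbind, all_rows), scene = scene,
                config = list(n_participants = n_participants,
                              savings = savings, mode = mode, eta = eta,
                              delay_range = delay_range,
                              fidelity = fidelity, seed = seed))
    class(out) <- "gaze_cohort"
    out
  })
}

#' @export
print.gaze_cohort <- function(x, ...) {
  tt <- x$trials
  cat(sprintf("Simulated cohort: %d participants, %d trials (%s fidelity)\n",
              length(unique(tt$participant)), nrow(tt),
              x$config$fidelity))
  fb <- tt[tt$trial_type == "feedback", ]
  by_s <- tapply(!is.na(fb$decoded) & fb$decoded == fb$intended,
                 fb$session, mean)
  cat("  valid decoding rate by session:",
      paste(sprintf("S%s %.3f", names(by_s), by_s), collapse = ", "), "\n")
  invisible(x)
}

#' Estimate the error-based learning rate from simulated sessions
#'
#' Fits the geometric decay of the cohort-mean angle to the optimal point
#' over feedback trials, `angle_t = A * rho^t`, by nonlinear least squares;
#' the learning rate estimate is `1 - rho`. Intended for parameter-recovery
#' checks on error-based cohorts whose learners engage immediately
#' (`delay_range = c(0, 0)`); engagement delays would flatten the early
#' decay and bias the fit.
#'
#' Only motor-feedback sessions enter the fit by default: under action
#' feedback the error signal is quantised to object positions, so the
#' error-based rule's effective rate differs from its nominal `eta`.
#'
#' @param trials a cohort trial table (see [simulate_experiment()]).
#' @param scene the matching [build_scene()].
#' @param session which session to use.
#' @param feedback which feedback condition to use.
#' @param n_trials number of leading feedback trials used in the fit.
#' @return List with `eta` (estimate), `rho`, `A`.
#' @export
estimate_learning_rate <- function(trials, scene = build_scene(),
                                   session = 1, feedback = "motor",
                                   n_trials = 100) {
  fb <- trials[trials$trial_type == "feedback" &
                 trials$session == session &
                 trials$feedback == feedback, ]
  ang <- signed_angle(fb$end_x, fb$end_y,
                      scene$object_clock_angle[fb$intended])
  a_opt <- wrap_angle(ang + scene$distortion)
  key <- interaction(fb$participant, drop = TRUE)
  tn <- stats::ave(fb$trial, key, FUN = seq_along)
  keep <- tn <= n_trials
  mean_a <- tapply(a_opt[keep], tn[keep], mean)
  tt <- as.numeric(names(mean_a))
  fit <- try(nls(y ~ A * rho^t,
                 data = data.frame(y = as.numeric(mean_a), t = tt),
                 start = list(A = scene$distortion, rho = 0.9),
                 control = list(warnOnly = TRUE)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    # log-linear fallback on positive means
    pos <- mean_a > 0.5
    cf <- stats::lm(log(mean_a[pos]) ~ tt[pos])$coefficients
    return(list(eta = 1 - exp(cf[2]), rho = exp(cf[2]), A = exp(cf[1])))
  }
  cf <- coef(fit)
  list(eta = unname(1 - cf["rho"]), rho = unname(cf["rho"]),
       A = unname(cf["A"]))
}
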