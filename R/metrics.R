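#' Signed angle of a screen point relative to a reference clock angle
#'
#' The clock angle of the point minus the reference, wrapped into
#' `(-180, 180]`, clockwise positive. With the intended object as reference
#' this is the "angle to intended"; with the optimal point (45 arc deg
#' counterclockwise of the intended object, i.e. reference - 45) as
#' reference it is the "angle to optimal", so
#' `angle_to_optimal = wrap_angle(angle_to_intended + 45)` always holds.
#'
#' @param x,y screen coordinates of the endpoint (deg), vectorised.
#' @param reference_clock_angle reference clock angle, arc deg.
#' @return Signed angles in arc deg, clockwise positive, in `(-180, 180]`.
#' @examples
#' p <- clock_to_xy(45, 7)
#' signed_angle(p$x, p$y, 90)   # -45: endpoint at the optimal point of the
#'                              # object at 3 o'clock
#' @export
signed_angle <- function(x, y, reference_clock_angle) {
  if (any(x == 0 & y == 0)) {
    stop("undefined angle: endpoint at the fixation cross", call. = FALSE)
  }
  wrap_angle(clock_angle(x, y) - reference_clock_angle)
}

#' Area-based saccade curvature index
#'
#' The trajectory is translated so its start is at the origin and rotated so
#' it becomes a rightward saccade (endpoint on the positive x axis); the
#' rotated vertical coordinate is then the deviation from the straight line
#' between start and end, with counterclockwise deviation positive and
#' clockwise deviation negative. The deviation is resampled to `n_steps`
#' (default 24) equally spaced time steps by linear interpolation and the
#' signed area under it over normalised time in \[0, 1\] is returned
#' (trapezoidal rule), in deg x normalised time.
#'
#' @param x,y ordered trajectory samples (deg), at least two distinct points,
#'   start != end.
#' @param n_steps number of resampling steps.
#' @return Signed curvature index (numeric scalar); 0 for a straight
#'   trajectory, sign flips under mirroring.
#' @export
curvature_index <- function(x, y, n_steps = 24) {
  n <- length(x)
  if (n < 2L || length(y) != n) {
    stop("need at least 2 trajectory points", call. = FALSE)
  }
  dx <- x[n] - x[1]
  dy <- y[n] - y[1]
  if (dx == 0 && dy == 0) {
    stop("degenerate trajectory: start equals end", call. = FALSE)
  }
  phi <- atan2(dy, dx)
  # rotate by -phi: endpoint lands on +x, ccw deviation maps to +y
  yr <- -sin(phi) * (x - x[1]) + cos(phi) * (y - y[1])
  s <- seq(0, 1, length.out = n)
  s_out <- seq(0, 1, length.out = n_steps)
  y24 <- approx(s, yr, xout = s_out)$y
  ds <- 1 / (n_steps - 1)
  sum((y24[-n_steps] + y24[-1]) / 2) * ds
}

#' Session layout of one recording session
#'
#' A session consists of `n_pre` baseline circle-off trials (objects vanish
#' at saccade onset, no feedback), `n_feedback` feedback trials, and
#' `n_post` final circle-off trials. Defaults are 20 / 200 / 20.
#'
#' @param n_pre,n_feedback,n_post positive trial counts.
#' @param feedback feedback condition, `"motor"` or `"action"`.
#' @param early_n,late_n sizes of the early and late learning-phase windows
#'   (first and last feedback trials).
#' @return An object of class `session_layout`.
#' @export
session_layout <- function(n_pre = 20, n_feedback = 200, n_post = 20,
                           feedback = c("motor", "action"),
                           early_n = 20, late_n = 20) {
  feedback <- match.arg(feedback)
  stopifnot(n_pre >= 1, n_feedback >= 1, n_post >= 1,
            early_n + late_n <= n_feedback)
  structure(list(n_pre = as.integer(n_pre),
                 n_feedback = as.integer(n_feedback),
                 n_post = as.integer(n_post),
                 n_total = as.integer(n_pre + n_feedback + n_post),
                 feedback = feedback,
                 early_n = as.integer(early_n),
                 late_n = as.integer(late_n)),
            class = "session_layout")
}

#' Assign learning-phase labels to trial indices
#'
#' `pre` and `post` are the circle-off blocks; `early` and `late` are the
#' first and last `early_n`/`late_n` feedback trials; feedback trials in
#' between are labelled `mid` so the labels partition the session.
#'
#' @param trial_index 1-based absolute trial index within the session.
#' @param layout a [session_layout()].
#' @return Factor with levels `pre`, `early`, `mid`, `late`, `post`.
#' @examples
#' lay <- session_layout()
#' assign_phase(c(5, 23, 120, 220, 230), lay)
#' @export
assign_phase <- function(trial_index, layout) {
  stopifnot(inherits(layout, "session_layout"))
  if (any(trial_index < 1 | trial_index > layout$n_total)) {
    stop("trial index outside the session", call. = FALSE)
  }
  fb <- trial_index - layout$n_pre # feedback trial number, 1..n_feedback
  lab <- ifelse(trial_index <= layout$n_pre, "pre",
         ifelse(trial_index > layout$n_pre + layout$n_feedback, "post",
         ifelse(fb <= layout$early_n, "early",
         ifelse(fb > layout$n_feedback - layout$late_n, "late", "mid"))))
  factor(lab, levels = c("pre", "early", "mid", "late", "post"))
}

#' Per-trial valid-decoding outcome table
#'
#' Extracts, from a cohort trial table (see [simulate_experiment()]), the
#' per-trial binary valid-decoding series of the feedback trials together
#' with the condition covariates, in the tidy form a downstream trend model
#' (e.g. a binomial mixed model) expects. The trial number is centred within
#' the feedback phase.
#'
#' @param trials a trial-table data frame with columns `participant`,
#'   `session`, `feedback`, `order`, `trial_type`, `trial`, `phase`,
#'   `decoded`, `intended`.
#' @return Data frame with columns `participant`, `session`, `feedback`,
#'   `order`, `phase`, `trial` (1-based feedback trial number), `trial_c`
#'   (centred) and `outcome` (1 = intended object decoded).
#' @export
decoding_outcome_table <- function(trials) {
  need <- c("participant", "session", "feedback", "order", "trial_type",
            "trial", "phase", "decoded", "intended")
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("trial table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  fb <- trials[trials$trial_type == "feedback", , drop = FALSE]
  # feedback trial number within participant x session
  key <- interaction(fb$participant, fb$session, drop = TRUE)
  fb <- fb[order(key, fb$trial), , drop = FALSE]
  tn <- stats::ave(fb$trial, key, FUN = seq_along)
  out <- data.frame(
    participant = fb$participant,
    session = fb$session,
    feedback = fb$feedback,
    order = fb$order,
    phase = fb$phase,
    trial = tn,
    trial_c = tn - stats::ave(tn, key, FUN = function(z) mean(range(z))),
    outcome = as.integer(!is.na(fb$decoded) & fb$decoded == fb$intended)
  )
  rownames(out) <- NULL
  out
}
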