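# Shared fixtures and independent oracles for the test suite.

# Independent brute-force decoder: loops over objects and checks the
# clockwise angular distance and the radius explicitly (no wedge arithmetic).
decode_brute <- function(x, y, scene) {
  vapply(seq_along(x), function(i) {
    r <- sqrt(x[i]^2 + y[i]^2)
    if (r > scene$area_outer_radius) return(NA_integer_)
    theta <- (atan2(x[i], y[i]) * 180 / pi) %% 360
    for (k in seq_len(scene$n_objects)) {
      d <- theta - scene$object_clock_angle[k]
      d <- ((d + 180) %% 360) - 180
      if (d >= -scene$area_half_width && d < scene$area_half_width) {
        return(k)
      }
    }
    NA_integer_
  }, integer(1))
}

# A stationary-fixation stream with one generated saccade embedded after
# `pre` ms, plus `post` ms of fixation at the landing point.
saccade_stream <- function(sac, pre = 60, post = 99, fixation_off_t = 0) {
  gaze_stream(0:(pre + sac$duration + post),
              c(rep(0, pre), sac$x, rep(sac$landing[1], post)),
              c(rep(0, pre), sac$y, rep(sac$landing[2], post)),
              fixation_off_t = fixation_off_t)
}

# Deterministic analytic trajectory: straight chord from `from` to `to`
# with a sinusoidal perpendicular bow; `side` = +1 bows counterclockwise
# (left of movement direction), -1 clockwise.
bowed_path <- function(from, to, c_bow, side = 1, n = 200) {
  s <- seq(0, 1, length.out = n)
  chord <- to - from
  len <- sqrt(sum(chord^2))
  perp <- side * c(-chord[2], chord[1]) / len
  list(x = from[1] + s * chord[1] + c_bow * sin(pi * s) * perp[1],
       y = from[2] + s * chord[2] + c_bow * sin(pi * s) * perp[2])
}

# Small balanced mixed-design fixture: 2 between groups x `n_per_group`
# participants each, 2 x 2 within design, with optional injected effects.
mixed_fixture <- function(phase_shift = 0, noise_sd = 0, seed = 1,
                          n_per_group = 2) {
  set.seed(seed)
  d <- expand.grid(participant = seq_len(2 * n_per_group),
                   feedback = c("motor", "action"),
                   phase = c("early", "late"),
                   stringsAsFactors = FALSE)
  d$order <- ifelse(d$participant <= n_per_group, "motor-first",
                    "action-first")
  subj_int <- rnorm(2 * n_per_group, 0, 0.3)
  d$y <- rnorm(nrow(d), 0, noise_sd) +
    ifelse(d$phase == "late", phase_shift, 0) +
    subj_int[d$participant]
  d
}
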