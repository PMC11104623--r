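test_that("generated saccades follow the main sequence and land on aim", {
  kin <- kinematic_params(endpoint_sd = 0, bow = 0)
  sac <- generate_saccade(c(0, 0), c(7, 0), kin)
  expect_equal(sac$duration, round(2.2 * 7 + 21)) # 36 ms
  expect_equal(sac$landing, c(7, 0))
  expect_equal(c(sac$x[length(sac$x)], sac$y[length(sac$y)]), c(7, 0))
  expect_equal(c(sac$x[1], sac$y[1]), c(0, 0))
  expect_error(generate_saccade(c(1, 1), c(1, 1), kin), "amplitude")
  # the bow coefficient maps onto the curvature index as 2c/pi
  sac_b <- generate_saccade(c(0, 0), c(0, 7), kin, bow = 0.4)
  expect_equal(curvature_index(sac_b$x, sac_b$y), 2 * 0.4 / pi,
               tolerance = 3e-3)
})

test_that("error-based learner corrects by eta times the feedback error", {
  sc <- build_scene()
  run_motor_trial <- function(state, intended = 3L) {
    aim <- unlist(clock_to_xy(sc$object_clock_angle[intended] +
                                state$aim_offset, 7))
    dp <- apply_distortion(aim[1], aim[2], sc)
    dec <- decode_object(dp$x, dp$y, sc)
    out <- evaluate_trial(dec, intended, dp$x, dp$y)
    fb <- render_feedback(out, "motor", sc)
    learner_update(state, fb[1, ], out[1, ], sc)
  }
  # full correction in a single trial at eta = 1
  s1 <- run_motor_trial(learner_state(eta = 1))
  expect_equal(s1$aim_offset, -45)
  # geometric decay of the residual at eta = 0.3 (noise-free recursion)
  st <- learner_state(eta = 0.3)
  res <- numeric(6)
  for (i in 1:6) {
    st <- run_motor_trial(st)
    res[i] <- st$aim_offset + 45
  }
  expect_equal(res, 45 * 0.7^(1:6), tolerance = 1e-10)
})

test_that("reward-based learner is win-stay lose-shift", {
  sc <- build_scene()
  conv <- learner_state(mode = "reward_based", aim_offset = -45,
                        explore_sd = 20)
  out_ok <- list(decoded_object = 3L, intended_object = 3L, too_far = FALSE,
                 decoding_error = FALSE)
  fb <- list(feedback_kind = "color", feedback_x = NA, feedback_y = NA,
             colored_object = 3L)
  set.seed(20)
  s <- learner_update(conv, fb, out_ok, sc)
  expect_equal(s$aim_offset, -45) # success: stay
  expect_lt(s$explore_sd, 20)     # and shrink exploration
  out_bad <- list(decoded_object = 4L, intended_object = 3L, too_far = FALSE,
                  decoding_error = TRUE)
  s2 <- learner_update(conv, fb, out_bad, sc)
  expect_false(s2$aim_offset == -45) # failure: shift
})

test_that("learner delay postpones updates", {
  sc <- build_scene()
  st <- learner_state(eta = 1, delay = 2)
  out <- list(decoded_object = 4L, intended_object = 3L, too_far = FALSE,
              decoding_error = TRUE)
  p <- clock_to_xy(135, 7)
  fb <- list(feedback_kind = "dot", feedback_x = p$x, feedback_y = p$y,
             colored_object = NA_integer_)
  st <- learner_update(st, fb, out, sc)
  expect_equal(st$aim_offset, 0)
  st <- learner_update(st, fb, out, sc)
  expect_equal(st$aim_offset, 0)
  st <- learner_update(st, fb, out, sc)
  expect_equal(st$aim_offset, -45) # delay elapsed: full correction
})

test_that("a zero-noise non-learner gets every feedback trial decoded wrong", {
  set.seed(21)
  lay <- session_layout(n_pre = 5, n_feedback = 40, n_post = 5)
  kin <- kinematic_params(endpoint_sd = 0, angle_sd = 0, gain = 1)
  s <- simulate_session(lay, learner_state(eta = 0), kin,
                        fidelity = "endpoint")
  fb <- s$trials[s$trials$trial_type == "feedback", ]
  expect_true(all(fb$decoding_error))
  # the distortion forces the clockwise neighbour
  expect_equal(fb$decoded, fb$intended %% 8 + 1L)
  # circle-off trials have no feedback and no decoding
  co <- s$trials[s$trials$trial_type == "circle_off", ]
  expect_true(all(is.na(co$decoded)))
  expect_true(all(is.na(co$feedback_kind)))
})

test_that("a converged learner decodes the intended object", {
  set.seed(22)
  lay <- session_layout(n_pre = 5, n_feedback = 40, n_post = 5)
  kin <- kinematic_params(angle_sd = 5)
  s <- simulate_session(lay, learner_state(aim_offset = -45, eta = 0.15),
                        kin, fidelity = "endpoint")
  fb <- s$trials[s$trials$trial_type == "feedback", ]
  expect_gt(mean(!fb$decoding_error), 0.9)
})

test_that("stream-fidelity sessions yield mostly valid primary saccades", {
  set.seed(23)
  s <- simulate_session(session_layout(), learner_state(delay = 20),
                        kinematic_params(), fidelity = "stream")
  expect_equal(nrow(s$trials), 240)
  expect_gte(mean(s$trials$valid_primary, na.rm = TRUE), 0.95)
  # detected endpoints track the generator's true landing points
  d <- sqrt((s$trials$end_x - s$trials$true_land_x)^2 +
              (s$trials$end_y - s$trials$true_land_y)^2)
  expect_lt(median(d, na.rm = TRUE), 0.1)
  # angle discrepancy between detected and true endpoints
  sc <- build_scene()
  ic <- sc$object_clock_angle[s$trials$intended]
  ok <- !is.na(s$trials$end_x)
  a_det <- signed_angle(s$trials$end_x[ok], s$trials$end_y[ok], ic[ok])
  a_true <- signed_angle(s$trials$true_land_x[ok], s$trials$true_land_y[ok],
                         ic[ok])
  expect_lt(median(abs(a_det - a_true)), 1)
})

test_that("cohort simulation is deterministic and counterbalanced", {
  lay <- list(n_pre = 3, n_feedback = 20, n_post = 3, early_n = 5,
              late_n = 5)
  c1 <- simulate_experiment(n_participants = 4, layout_args = lay, seed = 24)
  c2 <- simulate_experiment(n_participants = 4, layout_args = lay, seed = 24)
  expect_identical(c1$trials, c2$trials)
  ord <- unique(c1$trials[, c("participant", "order")])
  expect_equal(sum(ord$order == "motor-first"), 2)
  # each participant sees both feedback types, in the assigned order
  fb1 <- unique(c1$trials[c1$trials$session == 1,
                          c("participant", "feedback")])
  expect_equal(fb1$feedback[order(fb1$participant)],
               c("motor", "motor", "action", "action"))
  # session 2 pre-phase aim is neutral regardless of savings
  pre2 <- c1$trials[c1$trials$session == 2 & c1$trials$phase == "pre", ]
  expect_true(all(pre2$aim_offset == 0))
})

test_that("savings reinstates the learned aim at the first feedback trial", {
  lay <- list(n_pre = 3, n_feedback = 30, n_post = 3, early_n = 5,
              late_n = 5)
  coh <- simulate_experiment(n_participants = 2, savings = 1,
                             delay_range = c(0, 0), layout_args = lay,
                             seed = 25)
  s2 <- coh$trials[coh$trials$session == 2, ]
  first_fb <- s2[s2$trial_type == "feedback", ][1, ]
  expect_lt(abs(first_fb$aim_offset + 45), 10)
})

test_that("learning rate is recovered from motor-feedback sessions", {
  coh <- simulate_experiment(n_participants = 12, savings = 0,
                             delay_range = c(0, 0), seed = 26)
  est <- estimate_learning_rate(coh$trials)
  expect_lt(abs(est$eta - 0.15) / 0.15, 0.2)
})
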