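test_that("gaze streams validate sampling regularity", {
  expect_s3_class(gaze_stream(0:10, rep(0, 11), rep(0, 11)), "gaze_stream")
  expect_error(gaze_stream(c(0, 1, 3), rep(0, 3), rep(0, 3)), "non-uniform")
  expect_error(gaze_stream(c(0, 0, 1), rep(0, 3), rep(0, 3)), "increasing")
  expect_error(gaze_stream(0:3, rep(0, 2), rep(0, 4)), "equal length")
})

test_that("speed estimation is exact for simple motions", {
  st <- gaze_stream(0:50, rep(1, 51), rep(-2, 51))
  expect_equal(estimate_velocity(st), rep(0, 51))
  st2 <- gaze_stream(0:50, 0.1 * (0:50), rep(0, 51)) # 0.1 deg/ms
  expect_equal(estimate_velocity(st2), c(0, rep(100, 50)))
  expect_error(estimate_velocity(gaze_stream(0:1, 0:1, 0:1)), "3 samples")
})

test_that("minimum-jerk peak speed matches the analytic profile", {
  kin <- kinematic_params(endpoint_sd = 0, bow = 0)
  sac <- generate_saccade(c(0, 0), c(7, 0), kin)
  st <- saccade_stream(sac)
  peak_est <- max(estimate_velocity(st))
  peak_true <- 1.875 * 7 / (sac$duration / 1000)
  expect_lt(abs(peak_est - peak_true) / peak_true, 0.02)
})

test_that("online onset trigger requires both speed and travel", {
  # slow drift at 50 deg/s never triggers
  st <- gaze_stream(0:200, 0.05 * (0:200), rep(0, 201))
  expect_true(is.na(detect_onset_online(st)))
  # instantaneous 2.5-deg step fails the travel criterion
  st2 <- gaze_stream(0:100, c(rep(0, 50), rep(2.5, 51)), rep(0, 101))
  expect_true(is.na(detect_onset_online(st2)))
  # a real 7-deg saccade triggers once the eye is 3 deg out
  set.seed(1)
  sac <- generate_saccade(c(0, 0), c(7, 0),
                          kinematic_params(endpoint_sd = 0))
  st3 <- saccade_stream(sac, pre = 60)
  trig <- detect_onset_online(st3)
  expect_false(is.na(trig))
  k <- which(st3$t == trig)
  expect_gte(sqrt(st3$x[k]^2 + st3$y[k]^2), 3)
  expect_gt(max(estimate_velocity(st3)[k]), 100)
})

test_that("online offset uses the three-sample rule and reports the endpoint", {
  set.seed(2)
  sac <- generate_saccade(c(0, 0), c(0, -7),
                          kinematic_params(endpoint_sd = 0))
  st <- saccade_stream(sac, pre = 60)
  off <- detect_offset_online(st, after = detect_onset_online(st))
  expect_lte(abs(off$offset_t - (60 + sac$duration)), 3)
  expect_lt(sqrt((off$endpoint$x - sac$landing[1])^2 +
                   (off$endpoint$y - sac$landing[2])^2), 0.25)
  # constant fast motion never terminates
  st2 <- gaze_stream(0:300, 0.2 * (0:300), rep(0, 301))
  expect_error(detect_offset_online(st2, after = 0), "unterminated")
})

test_that("trial parsing labels primary and secondary saccades", {
  set.seed(3)
  kin <- kinematic_params(endpoint_sd = 0, bow = 0)
  prim <- generate_saccade(c(0, 0), c(7, 0), kin)
  make_trial <- function(sec_lat) {
    sec <- generate_saccade(prim$landing, prim$landing + c(0, 2), kin)
    xs <- c(rep(0, 200), prim$x, rep(prim$landing[1], sec_lat),
            sec$x[-1], rep(sec$landing[1], 120))
    ys <- c(rep(0, 200), prim$y, rep(prim$landing[2], sec_lat),
            sec$y[-1], rep(sec$landing[2], 120))
    gaze_stream(seq_along(xs) - 1, xs, ys, fixation_off_t = 50)
  }
  ev <- parse_trial(make_trial(200))
  expect_equal(ev$order, c("primary", "secondary"))
  expect_equal(ev$latency[1], ev$onset_t[1] - 50)
  expect_lt(abs(ev$latency[2] - 200), 6)
  expect_true(ev$valid[1])
  expect_true(ev$valid[2])
  # a corrective at 600 ms is not a secondary saccade
  ev2 <- parse_trial(make_trial(600))
  expect_equal(ev2$order, c("primary", "other"))
  # no eye movement: flagged, no events
  still <- gaze_stream(0:500, rep(0, 501), rep(0, 501))
  ev3 <- parse_trial(still)
  expect_equal(nrow(ev3), 0)
  expect_true(attr(ev3, "flagged"))
})

test_that("onset/offset recovery stays within tolerance across random saccades", {
  set.seed(4)
  kin <- kinematic_params()
  n <- 200
  err_on <- err_off <- err_pt <- numeric(n)
  for (i in seq_len(n)) {
    A <- runif(1, 3.5, 10.5)
    aim <- unlist(clock_to_xy(runif(1, 0, 360), A))
    sac <- generate_saccade(c(0, 0), aim, kin)
    st <- saccade_stream(sac, pre = 60)
    p <- parse_trial(st)
    p <- p[p$order == "primary", ]
    err_on[i] <- abs(p$onset_t[1] - 60)
    err_off[i] <- abs(p$offset_t[1] - (60 + sac$duration))
    err_pt[i] <- sqrt((p$end_x[1] - sac$landing[1])^2 +
                        (p$end_y[1] - sac$landing[2])^2)
  }
  expect_lte(max(err_on), 6)
  expect_lte(max(err_off), 6)
  expect_lte(max(err_pt), 0.3)
  # context metric reported by the suite: online-vs-true endpoint deviation
  expect_lt(median(err_pt), 0.1)
})

test_that("validity filters implement the amplitude/duration/latency rules", {
  ev <- data.frame(amplitude = c(7, 3.4, 3.5, 10.5, 10.6, 7, 7),
                   duration = c(45, 45, 45, 45, 45, 100, 99),
                   latency = c(300, 300, 300, 300, 300, 300, 100))
  expect_equal(filter_primary(ev),
               c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE))
  ev2 <- data.frame(amplitude = c(1.2, 5, 4.9, 2, 2, 2),
                    duration = c(30, 30, 30, 100, 30, 30),
                    latency = c(250, 250, 500, 250, 90, 501))
  expect_equal(filter_secondary(ev2),
               c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  # pure predicates: same event, same flag
  expect_identical(filter_primary(ev), filter_primary(ev))
})
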