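test_that("signed angles use the clockwise-positive convention", {
  sc <- build_scene()
  p <- clock_to_xy(90, 7)
  expect_equal(signed_angle(p$x, p$y, 90), 0)
  # endpoint at the intended object, referenced to its optimal point: +45
  expect_equal(signed_angle(p$x, p$y, 90 - 45), 45)
  # endpoint at the optimal point, referenced to the intended object: -45
  q <- clock_to_xy(45, 7)
  expect_equal(signed_angle(q$x, q$y, 90), -45)
  expect_error(signed_angle(0, 0, 10), "undefined")
  # result lies in (-180, 180]
  expect_equal(signed_angle(clock_to_xy(271, 5)$x, clock_to_xy(271, 5)$y, 90),
               -179)
})

test_that("angle to optimal leads angle to intended by the distortion", {
  sc <- build_scene()
  set.seed(11)
  th <- runif(200, 0, 360); r <- runif(200, 1, 9)
  p <- clock_to_xy(th, r)
  ref <- sample(sc$object_clock_angle, 200, replace = TRUE)
  a_int <- signed_angle(p$x, p$y, ref)
  a_opt <- signed_angle(p$x, p$y, ref - sc$distortion)
  expect_equal((a_opt - a_int) %% 360, rep(45, 200))
})

test_that("curvature index is zero for straight saccades and signed by side", {
  for (th in c(0, 37, 90, 213)) {
    p <- clock_to_xy(th, seq(0, 7, length.out = 50))
    expect_equal(curvature_index(p$x, p$y), 0, tolerance = 1e-12)
  }
  # analytic bow: area under c * sin(pi s) is 2c/pi
  for (c_bow in c(0.2, 0.5)) {
    tr <- bowed_path(c(0, 0), c(6, 3), c_bow, side = 1)
    expect_equal(curvature_index(tr$x, tr$y), 2 * c_bow / pi,
                 tolerance = 2e-3)
    mir <- bowed_path(c(0, 0), c(6, 3), c_bow, side = -1)
    expect_equal(curvature_index(mir$x, mir$y),
                 -curvature_index(tr$x, tr$y), tolerance = 1e-12)
  }
  expect_error(curvature_index(c(1, 1), c(2, 2)), "degenerate")
  expect_error(curvature_index(1, 2), "2 trajectory points")
})

test_that("curvature is invariant to rotation, translation and time rescaling", {
  tr <- bowed_path(c(0, 0), c(7, 0), 0.4, n = 120)
  v0 <- curvature_index(tr$x, tr$y)
  a <- 77 * pi / 180
  xr <- cos(a) * tr$x - sin(a) * tr$y + 3
  yr <- sin(a) * tr$x + cos(a) * tr$y - 1.5
  expect_equal(curvature_index(xr, yr), v0, tolerance = 1e-10)
  # uniform time rescaling = resampling the same path more densely
  tr2 <- bowed_path(c(0, 0), c(7, 0), 0.4, n = 480)
  expect_equal(curvature_index(tr2$x, tr2$y), v0, tolerance = 1e-3)
})

test_that("curvature signs match the distractor and forward-model scenarios", {
  sc <- build_scene()
  start <- c(0, 0)
  optimal <- unlist(clock_to_xy(45, 7))   # aiming here selects the triangle
  intended_dir <- unlist(clock_to_xy(90, 7)) / 7
  # distractor effect: trajectory pushed away from the intended object,
  # i.e. deviating counterclockwise -> positive index
  away <- bowed_path(start, optimal, 0.6, side = 1)
  expect_gt(curvature_index(away$x, away$y), 0)
  # forward-model adaptation: saccade starts out toward the intended object
  # and is corrected toward the optimal point -> clockwise, negative index
  s <- seq(0, 1, length.out = 150)
  blend <- (1 - s) * outer(s, intended_dir * 7) + s * outer(s, optimal)
  expect_lt(curvature_index(blend[, 1], blend[, 2]), 0)
})

test_that("phase assignment partitions the session with the block layout", {
  lay <- session_layout()
  ph <- assign_phase(1:240, lay)
  expect_equal(as.character(ph[c(5, 21, 23, 120, 201, 220, 221, 240)]),
               c("pre", "early", "early", "mid", "late", "late", "post",
                 "post"))
  expect_equal(sum(ph == "pre"), 20)
  expect_equal(sum(ph == "post"), 20)
  expect_equal(sum(ph == "early"), 20)
  expect_equal(sum(ph == "late"), 20)
  expect_false(any(is.na(ph)))
  expect_error(assign_phase(241, lay), "outside")
  expect_error(assign_phase(0, lay), "outside")
  # window sizes are configurable
  lay2 <- session_layout(early_n = 10, late_n = 30)
  expect_equal(sum(assign_phase(1:240, lay2) == "early"), 10)
  expect_equal(sum(assign_phase(1:240, lay2) == "late"), 30)
})

test_that("decoding outcome table centres trials and codes outcomes", {
  tr <- data.frame(participant = 1L, session = 1L, feedback = "motor",
                   order = "motor-first",
                   trial_type = c("circle_off", rep("feedback", 6),
                                  "circle_off"),
                   trial = 1:8, phase = "mid",
                   decoded = c(NA, 1L, 2L, NA, 3L, 3L, 1L, NA),
                   intended = c(1L, 1L, 2L, 3L, 1L, 3L, 1L, 2L))
  ot <- decoding_outcome_table(tr)
  expect_equal(nrow(ot), 6)
  expect_equal(ot$outcome, c(1L, 1L, 0L, 0L, 1L, 1L))
  expect_equal(ot$trial, 1:6)
  expect_equal(mean(ot$trial_c), 0)
  expect_error(decoding_outcome_table(tr[, -3]), "lacks")
})
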