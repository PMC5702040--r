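test_that("headings follow compass convention on the 20 s grid", {
  tt <- seq(0, 600, by = 1)
  north <- tibble::tibble(time_s = tt, x_m = 0, y_m = tt, depth_m = 0)
  east <- tibble::tibble(time_s = tt, x_m = tt, y_m = 0, depth_m = 0)
  hn <- downsample_and_heading(north)
  he <- downsample_and_heading(east)
  expect_equal(nrow(hn), 31)                  # 31 grid positions from 601 points
  expect_equal(unique(hn$heading_deg), 0)
  expect_equal(unique(he$heading_deg), 90)
  expect_error(downsample_and_heading(north[1, ]), "two")
})

test_that("relative heading is the smallest absolute angular difference", {
  expect_equal(relative_heading(45, 45), 0)
  expect_equal(relative_heading(0, 180), 180)
  expect_equal(relative_heading(350, 10), 20)
  expect_equal(relative_heading(10, 350), 20)
  expect_true(all(relative_heading(runif(50, 0, 360), runif(50, 0, 360)) <= 180))
})

test_that("turn segmentation finds maximal same-sign runs", {
  t1 <- segment_turns(c(0, 30, 60, 30))
  expect_equal(nrow(t1), 2)
  expect_equal(t1$direction, c("cw", "ccw"))
  expect_equal(t1$magnitude_deg, c(60, 30))
  expect_equal(nrow(segment_turns(rep(77, 10))), 0)
  alt <- segment_turns(cumsum(c(0, rep(c(10, -10), 8))))
  expect_true(all(alt$magnitude_deg == 10))
  # wrap-around: 350 -> 10 is a +20 cw increment
  wrap <- segment_turns(c(350, 10, 30))
  expect_equal(nrow(wrap), 1)
  expect_equal(wrap$magnitude_deg, 40)
})

test_that("turn segmentation conserves total signed heading change", {
  set.seed(8)
  for (k in 1:20) {
    h <- cumsum(c(runif(1, 0, 360), rnorm(40, 0, 25)))
    turns <- segment_turns(h %% 360)
    signed <- sum(ifelse(turns$direction == "cw", 1, -1) * turns$magnitude_deg)
    total <- sum(sonarramp:::wrap180(diff(h %% 360)))
    expect_equal(signed, total, tolerance = 1e-9)
  }
})

test_that("candidate screening applies the 90 deg, session and away criteria", {
  turn <- tibble::tibble(start_s = 100, end_s = 140, direction = "cw",
                         magnitude_deg = 120)
  expect_true(as.logical(candidate_avoidance(turn, c(0, 600), c(30, 40, 50))))
  expect_false(as.logical(candidate_avoidance(turn, c(0, 600), c(140, 150, 160))))
  small <- dplyr::mutate(turn, magnitude_deg = 80)
  expect_false(as.logical(candidate_avoidance(small, c(0, 600), c(30, 40, 50))))
  outside <- dplyr::mutate(turn, end_s = 700)
  expect_false(as.logical(candidate_avoidance(outside, c(0, 600), c(30, 40, 50))))
  expect_warning(
    flag <- candidate_avoidance(turn, c(0, 600), numeric()), "empty")
  expect_false(as.logical(flag))
  # fewer than the minimum persistence steps cannot qualify
  expect_false(as.logical(candidate_avoidance(turn, c(0, 600), c(10, 20))))
})

test_that("the empirical p-value is the add-one tail proportion", {
  expect_equal(empirical_turn_p(90, c(10, 20, 30, 40)), 1 / 5)
  expect_equal(empirical_turn_p(5, c(10, 20, 30, 40)), 1)
  expect_equal(empirical_turn_p(25, c(10, 20, 30, 40)), 3 / 5)
  expect_error(empirical_turn_p(90, numeric()), "baseline")
})

test_that("the empirical p-value is non-increasing in turn magnitude", {
  set.seed(3)
  base <- abs(rnorm(200, 0, 30))
  mags <- seq(5, 180, by = 5)
  ps <- vapply(mags, empirical_turn_p, numeric(1),
               baseline_magnitudes_deg = base)
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("Bonferroni classification thresholds at alpha over n_tests", {
  cand <- tibble::tibble(start_s = c(10, 20), p_value = c(0.004, 0.02))
  out <- classify_avoidance(cand, n_tests = 10)
  expect_equal(out$alpha_corrected, rep(0.005, 2))
  expect_equal(out$is_avoidance, c(TRUE, FALSE))
  expect_equal(out$onset_s, c(10, 20))
  # monotone: a larger denominator can never produce more calls
  out2 <- classify_avoidance(cand, n_tests = 40)
  expect_true(sum(out2$is_avoidance) <= sum(out$is_avoidance))
  expect_error(classify_avoidance(cand, n_tests = 0), "positive")
  expect_error(classify_avoidance(cand, n_tests = 1), "at least")
})

test_that("feeding state follows the 10-min-before-to-onset window rule", {
  expect_equal(assign_feeding_state(-300, c(0, 600))$state, "feeding")
  expect_equal(assign_feeding_state(400, c(0, 600), onset_s = 200)$state,
               "non_feeding")
  expect_equal(assign_feeding_state(numeric(), c(0, 600))$state, "non_feeding")
  expect_equal(assign_feeding_state(-700, c(0, 600))$state, "non_feeding")
  expect_equal(assign_feeding_state(150, c(0, 600), onset_s = 200)$state,
               "feeding")
})

test_that("injected responses are recovered against a sigma-30 baseline null", {
  n_ok <- 0; n <- 60
  for (s in 1:n) {
    set.seed(s + 5000)
    base <- sigma30_baseline_turns()
    tr <- generate_baseline_track(duration_s = 1800, seed = s,
                                  start_time_s = -600)
    onset <- 240
    h_pre <- tr$heading_deg[which(tr$time_s >= onset)[1] - 1]
    turn <- sample(c(-1, 1), 1) * runif(1, 120, 170)
    course <- ((h_pre + turn) %% 360 - runif(1, 20, 80)) %% 360
    tr2 <- inject_avoidance(tr, onset, turn, speed_mps = 1.3, until_s = 600)
    calls <- suppressWarnings(
      detect_avoidance(tr2, course, c(0, 600), baseline_turns = base))
    hit <- nrow(calls) > 0 && any(
      calls$is_avoidance & calls$start_s <= onset & calls$end_s >= onset - 20 &
        calls$magnitude_deg >= abs(turn) - 20)
    n_ok <- n_ok + hit
  }
  expect_gte(n_ok / n, 0.95)
})

test_that("null experiments rarely yield avoidance calls", {
  hits <- c()
  for (s in 1:40) {
    calls <- suppressWarnings(detect_experiment(make_experiment(seed = 700 + s)))
    per_sess <- dplyr::summarise(
      dplyr::group_by(calls, session_start_s),
      a = any(is_avoidance), .groups = "drop")
    hits <- c(hits, per_sess$a)
  }
  # point check at module scale; the binomial-CI check runs at larger n in
  # the acceptance suite
  expect_lte(mean(hits), 0.10)
})

test_that("experiment-level detection uses the experiment-wide test count", {
  exp <- make_experiment(seed = 31, respond = c(TRUE, TRUE))
  calls <- suppressWarnings(detect_experiment(exp))
  expect_true(all(calls$n_tests == calls$n_tests[1]))
  cand <- calls[!is.na(calls$magnitude_deg), ]
  expect_gte(calls$n_tests[1], nrow(cand))
  expect_true(all(c("Control", "RampUp1", "RampUp2") %in% calls$session_type))
  expect_true(all(calls$feeding_state %in% c("feeding", "non_feeding")))
})
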