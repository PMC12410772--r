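test_that("force-threshold stance detection matches a direct scan", {
  # frames (1-based): values above 20 N at frames 3..6
  f <- c(0, 10, 25, 400, 300, 25, 10, 0)
  ev <- detect_stance_from_force(f, threshold = 20, rate = 120,
                                 min_stance_s = 0)
  expect_identical(ev$ic, 3L)
  expect_identical(ev$to, 7L)
  expect_identical(nrow(detect_stance_from_force(rep(0, 100))), 0L)
  # incomplete stances touching the series ends are dropped
  f2 <- c(100, 100, 0, 0, 100, 100, 100, 0, 0, 100)
  ev2 <- detect_stance_from_force(f2, rate = 120, min_stance_s = 0)
  expect_identical(ev2$ic, 5L)
  expect_identical(ev2$to, 8L)
})

test_that("force-detected events agree with generator truth on clean data", {
  s <- fx_clean_tm()
  fz_n <- s$prepped$force_imu$fz_bw * s$raw$bodyweight_n / 100
  ev <- detect_stance_from_force(fz_n, rate = 120)
  tr <- s$truth
  expect_identical(nrow(ev), length(tr$ic))
  expect_true(all(abs(ev$ic - tr$ic) <= 1))
  expect_true(all(abs(ev$to - tr$to) <= 1))
})

test_that("window extension pads 29 frames and flags clipping", {
  # stance frames 41..91 -> window 12..120 (0.242 s of context per side)
  ev <- tibble::tibble(ic = 41L, to = 92L)
  w <- extend_window(ev, n_frames = 200L)
  expect_identical(w$window_start, 12L)
  expect_identical(w$window_end, 120L)
  expect_false(w$clipped)
  w2 <- extend_window(tibble::tibble(ic = 11L, to = 52L), n_frames = 200L)
  expect_identical(w2$window_start, 1L)
  expect_identical(w2$window_end, 80L)
  expect_true(w2$clipped)
  # 29 frames at 120 Hz is the documented 0.242 s swing pad
  expect_equal(29 / 120, 0.242, tolerance = 0.002)
})

test_that("sub-sequence slicing yields L - 21 windows with mid-point targets", {
  x <- seq_len(100)
  ss <- make_subsequences(x, length = 22L, hop = 1L)
  expect_identical(nrow(ss), 79L)
  expect_identical(ss$t_m, 12:90)
  expect_identical(ss$x[[1]], 1:22)
  one <- make_subsequences(seq_len(22), length = 22L)
  expect_identical(nrow(one), 1L)
  expect_identical(one$t_m, 12L) # 0-based index 11
  expect_error(make_subsequences(seq_len(21)), "too short")
})

test_that("stitching mid-points reproduces targets on covered frames", {
  y <- sin(seq_len(100) / 7) * 20
  ss <- make_subsequences(y, length = 22L, hop = 1L)
  preds <- vapply(seq_len(nrow(ss)), function(i) ss$x[[i]][12L], numeric(1))
  wav <- stitch_predictions(ss$t_m, preds, 100L)
  expect_identical(which(!is.na(wav)), 12:90)
  expect_equal(wav[12:90], y[12:90], tolerance = 0)
  # hop 2: gaps filled by linear interpolation, edges still NA
  ss2 <- make_subsequences(y, length = 22L, hop = 2L)
  preds2 <- vapply(seq_len(nrow(ss2)), function(i) ss2$x[[i]][12L], numeric(1))
  wav2 <- stitch_predictions(ss2$t_m, preds2, 100L)
  expect_true(all(is.na(wav2[1:11])))
  expect_equal(wav2[13], (y[12] + y[14]) / 2)
})

test_that("round trip: detect, extend, slice, stitch reproduces the target", {
  s <- fx_clean_tm()
  fy <- s$prepped$force_imu$fy_bw
  fz_n <- s$prepped$force_imu$fz_bw * s$raw$bodyweight_n / 100
  ev <- detect_stance_from_force(fz_n, rate = 120)
  win <- extend_window(ev, n_frames = length(fy))
  win <- win[!win$clipped, ]
  for (i in sample(nrow(win), 5)) {
    seg <- fy[win$window_start[i]:win$window_end[i]]
    ss <- make_subsequences(seg, length = 22L, hop = 1L,
                            offset = win$window_start[i])
    preds <- vapply(seq_len(nrow(ss)), function(j) ss$x[[j]][12L], numeric(1))
    wav <- stitch_predictions(ss$t_m, preds, length(fy))
    covered <- which(!is.na(wav))
    expect_identical(wav[covered], fy[covered])
  }
})

test_that("the swing rule finds toe off and initial contact", {
  wav <- c(rep(15, 30), rep(0, 20), rep(-10, 30))
  ev <- detect_gait_events_from_prediction(wav, swing_rule(min_stance_s = 0),
                                           rate = 120)
  # single swing run over frames 31..50: toe off at its start, initial
  # contact just after its end; no complete stance between two swings
  expect_identical(nrow(ev), 0L)
  sw <- attr(ev, "swings")
  expect_identical(sw$to, 31L)
  expect_identical(sw$ic, 51L)
  # flanked by swings: one stance between them
  wav2 <- c(rep(0, 20), rep(15, 25), rep(0, 20))
  ev2 <- detect_gait_events_from_prediction(wav2,
                                            swing_rule(min_stance_s = 0.1),
                                            rate = 120)
  expect_identical(ev2$ic, 21L)
  expect_identical(ev2$to, 46L)
  # constant zero: one long swing, no stances
  expect_identical(
    nrow(detect_gait_events_from_prediction(rep(0, 100), swing_rule())), 0L)
  # a 4-frame quiet dip inside stance is not a swing
  dip <- c(rep(0, 20), rep(15, 10), rep(0.1, 4), rep(15, 10), rep(0, 20))
  evd <- detect_gait_events_from_prediction(dip, swing_rule(min_stance_s = 0),
                                            rate = 120)
  expect_identical(nrow(evd), 1L)
  expect_identical(evd$ic, 21L)
  expect_identical(evd$to, 45L)
})

test_that("swing detection matches the exhaustive oracle on synthetic truth", {
  pr <- noise_free_runner(17)
  ss <- generate_session(pr, setting_shift("TM"), clean_config(40))
  y <- session_truth(ss)$grf_bw
  got <- detect_gait_events_from_prediction(y, swing_rule(), rate = 120)
  ora <- oracle_swing_events(y)
  expect_identical(got$ic, ora$ic)
  expect_identical(got$to, ora$to)
})

test_that("prediction-derived events recover generator truth within 2 frames", {
  pr <- noise_free_runner(23)
  ss <- generate_session(pr, setting_shift("TM"), clean_config(40))
  tr <- session_truth(ss)
  got <- detect_gait_events_from_prediction(tr$grf_bw, swing_rule(),
                                            rate = 120)
  # interior stances (the first/last lack a flanking swing by construction)
  m <- nrow(got)
  expect_gte(m, length(tr$ic) - 2)
  match_ic <- vapply(got$ic, function(p) min(abs(tr$ic - p)), numeric(1))
  match_to <- vapply(got$to, function(p) min(abs(tr$to - p)), numeric(1))
  expect_true(all(match_ic <= 2))
  expect_true(all(match_to <= 2))
  # same number of stances as the force threshold finds
  ps <- prep_session(ss)
  fz_n <- ps$force_imu$fz_bw * ss$bodyweight_n / 100
  ev_force <- detect_stance_from_force(fz_n, rate = 120)
  expect_lte(abs(nrow(ev_force) - m), 2)
})

test_that("event RMSE measures constructed shifts exactly", {
  ref <- new_ev <- tibble::tibble(ic = seq(100L, 2000L, by = 85L),
                                  to = seq(130L, 2030L, by = 85L))
  same <- event_rmse(ref, ref, rate = 120)
  expect_equal(same$ic_rmse_s, 0)
  expect_equal(same$to_rmse_s, 0)
  shifted <- tibble::tibble(ic = ref$ic + 6L, to = ref$to + 6L)
  sh <- event_rmse(shifted, ref, rate = 120)
  expect_equal(sh$ic_rmse_s, 0.05)
  expect_equal(sh$to_rmse_s, 0.05)
  expect_error(event_rmse(tibble::tibble(ic = integer(), to = integer()),
                          ref),
               "no predicted events")
})
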