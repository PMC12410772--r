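test_that("zero-phase Butterworth filter has unit DC gain and zero phase", {
  x <- rep(3.7, 200)
  expect_equal(butter_filter(x, 50, 120), x, tolerance = 1e-9)
  # a time-symmetric pulse stays time-symmetric
  t <- seq(-1, 1, length.out = 241)
  pulse <- exp(-(t / 0.1)^2)
  y <- butter_filter(pulse, 20, 120)
  expect_equal(y, rev(y), tolerance = 1e-7)
})

test_that("the filter attenuates above-cutoff power by at least 90 percent", {
  set.seed(11)
  x <- rnorm(4096)
  y <- butter_filter(x, 50, 120)
  spec_x <- Mod(fft(x))^2
  spec_y <- Mod(fft(y))^2
  freqs <- (seq_along(x) - 1) / length(x) * 120
  hi <- freqs > 50 & freqs < 60
  expect_lt(sum(spec_y[hi]) / sum(spec_x[hi]), 0.10)
})

test_that("filtering commutes with time reversal", {
  set.seed(4)
  x <- cumsum(rnorm(300))
  expect_equal(butter_filter(rev(x), 30, 120), rev(butter_filter(x, 30, 120)),
               tolerance = 1e-6)
})

test_that("filter preconditions are enforced", {
  expect_error(butter_filter(rnorm(40), 50, 120), "too short")
  expect_error(butter_filter(rnorm(200), 60, 120), "Nyquist")
})

test_that("force resampling is exact for constants, ramps and band-limited tones", {
  tf <- seq(0, 1, by = 1 / 2000)
  ti <- seq(0, 1, by = 1 / 120)
  expect_equal(resample_force_to_imu(tf, rep(5, length(tf)), ti),
               rep(5, length(ti)))
  expect_equal(resample_force_to_imu(tf, 3 * tf, ti), 3 * ti,
               tolerance = 1e-12)
  tone <- sin(2 * pi * 10 * tf)
  got <- resample_force_to_imu(tf, tone, ti)
  expect_equal(got, sin(2 * pi * 10 * ti), tolerance = 1e-6)
})

test_that("percent bodyweight conversion is exact", {
  expect_equal(force_to_percent_bw(735, 735), 100)
  expect_equal(force_to_percent_bw(0, 735), 0)
  expect_equal(force_to_percent_bw(490.3325, mass_kg = 100), 50)
  expect_error(force_to_percent_bw(10), "bodyweight_n or mass_kg")
})

test_that("sagittal angle extraction recovers static and ramp motions", {
  rate <- 120
  n <- 600
  # static sensor, gravity along the reference axis
  th0 <- extract_sagittal_angle(rep(0, n), rep(9.80665, n), rep(0, n), rate)
  expect_equal(th0, rep(0, n), tolerance = 1e-9)
  # pure rotation at a constant rate: ramp matching the integrated gyro
  omega <- 30 # deg/s
  t <- (seq_len(n) - 1) / rate
  theta <- omega * t
  acc_x <- 9.80665 * sin(theta * pi / 180)
  acc_z <- 9.80665 * cos(theta * pi / 180)
  th <- extract_sagittal_angle(acc_x, acc_z, rep(omega, n), rate)
  gyro_integrated <- theta
  expect_lt(max(abs(th - gyro_integrated)), 0.5)
})

test_that("sagittal angle extraction tracks the generator's angle", {
  s <- fx_clean_tm()
  imu <- s$raw$imu
  th <- extract_sagittal_angle(imu$shank_acc_x, imu$shank_acc_z,
                               imu$shank_gyro_y, rate = 120)
  truth <- imu$shank_angle # noise-free session: channel equals truth + offset
  offset <- noise_free_runner(3)$style_offsets$angle_offset[["shank_angle"]]
  rmse <- sqrt(mean((th - (truth - offset))^2))
  expect_lt(rmse, 1)
})

test_that("degenerate gravity estimates are rejected", {
  expect_error(extract_sagittal_angle(rep(0, 100), rep(0, 100), rep(0, 100),
                                      120),
               "degenerate")
})

test_that("cross-correlation sync finds constructed lags", {
  set.seed(2)
  base <- sin(seq(0, 20 * pi, length.out = 1200)) +
    0.3 * sin(seq(0, 63 * pi, length.out = 1200))
  expect_identical(sync_by_cross_correlation(base, base), 0L)
  delayed <- c(rep(base[1], 12), head(base, -12))
  expect_identical(sync_by_cross_correlation(base, delayed), 12L)
  # noisy delays stay within one frame (Monte Carlo over 100 seeds, SNR 10)
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    noisy <- delayed + rnorm(length(delayed), 0, sd(base) / sqrt(10))
    abs(sync_by_cross_correlation(base, noisy) - 12L) <= 1L
  }, logical(1))
  expect_true(all(hits))
})

test_that("grouped min-max normalisation follows the affine contract", {
  df <- tibble::tibble(a1 = c(-2, 0, 2, 4))
  spec <- fit_normalization(df, groups = list(g = "a1"))
  got <- apply_normalization(df, spec)
  expect_equal(got$a1, c(0, 1 / 3, 2 / 3, 1))
  # shared group: 2:1 peak ratio preserved after normalisation
  df2 <- tibble::tibble(x = c(0, 4, 0, -4), y = c(0, 2, 0, -2))
  sp2 <- fit_normalization(df2, groups = list(g = c("x", "y")))
  nn <- apply_normalization(df2, sp2)
  expect_equal(max(nn$x) - min(nn$x), 2 * (max(nn$y) - min(nn$y)))
  # out-of-range values are not clipped
  test_df <- tibble::tibble(a1 = c(-5, 10))
  mapped <- apply_normalization(test_df, spec)
  expect_lt(mapped$a1[1], 0)
  expect_gt(mapped$a1[2], 1)
  # degenerate group errors
  expect_error(fit_normalization(tibble::tibble(a1 = rep(1, 4)),
                                 groups = list(g = "a1")),
               "degenerate")
})

test_that("fitted normalisation maps train extrema to exactly 0 and 1", {
  imu <- fx_clean_tm()$prepped$imu
  spec <- fit_normalization(imu)
  nn <- apply_normalization(imu, spec)
  for (i in seq_len(nrow(spec))) {
    vals <- unlist(nn[spec$channels[[i]]], use.names = FALSE)
    expect_equal(min(vals), 0)
    expect_equal(max(vals), 1)
  }
  # one group per (sensor, modality), one per angle
  expect_setequal(spec$group,
                  c(paste0(rep(c("pelvis", "thigh", "shank", "foot"), each = 2),
                           "_", c("acc", "gyro")),
                    paste0(c("thigh", "shank", "foot"), "_angle")))
})

test_that("norm specs survive a JSON round trip", {
  imu <- fx_clean_tm()$prepped$imu
  spec <- fit_normalization(imu)
  path <- withr::local_tempfile(fileext = ".json")
  write_norm_spec(spec, path)
  back <- read_norm_spec(path)
  expect_equal(back$min, spec$min)
  expect_equal(back$max, spec$max)
  expect_identical(back$channels, spec$channels)
})

test_that("conditioning a noise-free session leaves stance timing unchanged", {
  s <- fx_clean_tm()
  raw_fz <- resample_force_to_imu(s$raw$force$time_s, s$raw$force$fz_n,
                                  s$raw$imu$time_s)
  ev_raw <- detect_stance_from_force(raw_fz, rate = 120)
  fz_filt <- butter_filter(raw_fz, 50, 120)
  ev_filt <- detect_stance_from_force(fz_filt, rate = 120)
  expect_identical(nrow(ev_raw), nrow(ev_filt))
  expect_true(all(abs(ev_raw$ic - ev_filt$ic) <= 1))
  expect_true(all(abs(ev_raw$to - ev_filt$to) <= 1))
})
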