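test_that("impulses integrate constant and zero stances exactly", {
  # constant -10 %BW over 0.1 s (13 frames = 12 intervals at 120 Hz)
  wav <- c(rep(0, 5), rep(-10, 13), rep(0, 5))
  ev <- tibble::tibble(ic = 6L, to = 19L)
  imp <- compute_impulses(wav, ev, rate = 120)
  expect_equal(imp$braking_impulse, -1.0)
  expect_equal(imp$propulsion_impulse, 0)
  zero <- compute_impulses(rep(0, 50), tibble::tibble(ic = 10L, to = 30L),
                           rate = 120)
  expect_equal(zero$braking_impulse, 0)
  expect_equal(zero$propulsion_impulse, 0)
})

test_that("impulses match analytic half-sine integrals within 1 percent", {
  rate <- 120
  for (A in c(5, 12.5, 20, 30)) {
    for (dur in c(0.05, 0.075, 0.1, 0.15, 0.2)) {
      n <- round(dur * rate)
      lobe <- A * sin(pi * (0:n) / n)
      wav <- c(rep(0, 10), lobe, rep(0, 10))
      ev <- tibble::tibble(ic = 11L, to = 11L + n + 1L)
      imp <- compute_impulses(wav, ev, rate = rate)
      expect_equal(imp$propulsion_impulse, 2 * A * dur / pi,
                   tolerance = 0.01)
      neg <- compute_impulses(-wav, ev, rate = rate)
      expect_equal(neg$braking_impulse, -2 * A * dur / pi, tolerance = 0.01)
    }
  }
})

test_that("impulse computation decomposes by sign", {
  set.seed(5)
  wav <- rnorm(200, 0, 10)
  ev <- tibble::tibble(ic = c(20L, 100L), to = c(60L, 150L))
  full <- compute_impulses(wav, ev, rate = 120)
  pos <- compute_impulses(pmax(wav, 0), ev, rate = 120)
  neg <- compute_impulses(pmin(wav, 0), ev, rate = 120)
  expect_equal(full$braking_impulse, neg$braking_impulse)
  expect_equal(full$propulsion_impulse, pos$propulsion_impulse)
  expect_true(all(full$braking_impulse <= 0))
  expect_true(all(full$propulsion_impulse >= 0))
})

test_that("speed binning keeps only bins with enough members", {
  pts <- tibble::tibble(
    stance_id = 1:5, ic = 1L, to = 2L,
    braking_impulse = -1, propulsion_impulse = 1,
    speed = c(2.05, 2.05, 2.05, 2.61, 2.61), source = "force_plate")
  bins <- bin_by_speed(pts)
  expect_identical(nrow(bins), 1L)
  expect_equal(bins$bin_left, 2.0)
  expect_identical(bins$n, 3L)
  expect_equal(attr(bins, "discarded")$bin_left, 2.6)
  # speed exactly 4.5 is outside every half-open bin
  pts45 <- dplyr::mutate(pts, speed = 4.5)
  expect_identical(nrow(bin_by_speed(pts45)), 0L)
  # empty input gives an empty binning
  expect_identical(nrow(bin_by_speed(pts[0, ])), 0L)
})

test_that("the weighted fit is exact on a line and matches a brute-force oracle", {
  mk_bins <- function(df) {
    df$stance_id <- seq_len(nrow(df)); df$ic <- 1L; df$to <- 2L
    df$braking_impulse <- -df$y; df$propulsion_impulse <- df$y
    df$source <- "force_plate"
    bin_by_speed(df, min_members = 1L)
  }
  line <- tibble::tibble(speed = rep(c(2.05, 3.05, 4.05), each = 3) +
                           rep(c(-0.02, 0, 0.02), 3))
  line$y <- 1 + 2 * (line$speed - 2.05) # slope 2 against speed
  fit <- weighted_linear_fit(mk_bins(line), "propulsion_impulse")
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$intercept, 1 - 2 * 2.05, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_error(weighted_linear_fit(mk_bins(line)[1, ], "propulsion_impulse"),
               "at least 2")

  # randomized heteroscedastic sets against direct minimisation of the
  # weighted squared loss
  for (s in 1:100) {
    set.seed(s)
    df <- tibble::tibble(
      speed = rep(seq(2.02, 4.38, length.out = 5), each = 4) +
        runif(20, 0, 0.05),
      y = rnorm(20, sd = rep(runif(5, 0.1, 2), each = 4)) +
        0.8 * rep(seq(2.02, 4.38, length.out = 5), each = 4))
    bins <- mk_bins(df)
    fit <- weighted_linear_fit(bins, "propulsion_impulse")
    obs <- purrr::map_dfr(seq_len(nrow(bins)), function(i) {
      mem <- bins$members[[i]]
      v <- var(mem$propulsion_impulse)
      if (!is.finite(v) || v < 1e-8) v <- 1e-8
      tibble::tibble(x = mem$speed, y = mem$propulsion_impulse, w = 1 / v)
    })
    # centred, weight-normalised parametrisation keeps the quadratic
    # well-conditioned for the numerical minimiser; restart once to polish
    xc <- mean(obs$x)
    wn <- obs$w / sum(obs$w)
    loss <- function(p) sum(wn * (obs$y - p[1] - p[2] * (obs$x - xc))^2)
    opt <- optim(c(0, 0), loss, method = "BFGS",
                 control = list(reltol = 1e-15, maxit = 2000))
    opt <- optim(opt$par, loss, method = "BFGS",
                 control = list(reltol = 1e-15, maxit = 2000))
    expect_lt(abs(fit$intercept - (opt$par[1] - opt$par[2] * xc)), 1e-6)
    expect_lt(abs(fit$slope - opt$par[2]), 1e-6)
  }
})

test_that("equal weights reduce the weighted fit to ordinary least squares", {
  # identical within-bin residual patterns give every bin the same variance,
  # hence identical inverse-variance weights
  centers <- c(2.15, 2.85, 3.55, 4.25)
  resid <- c(-0.3, 0.05, 0.25)
  df <- tibble::tibble(speed = rep(centers, each = 3),
                       y = 0.4 + 0.6 * rep(centers, each = 3) +
                         rep(resid, times = 4))
  df$stance_id <- seq_len(nrow(df)); df$ic <- 1L; df$to <- 2L
  df$propulsion_impulse <- df$y; df$braking_impulse <- -df$y
  df$source <- "force_plate"
  bins <- bin_by_speed(df)
  wfit <- weighted_linear_fit(bins, "propulsion_impulse")
  ols <- lm(y ~ speed, data = df)
  expect_equal(wfit$intercept, unname(coef(ols)[1]), tolerance = 1e-9)
  expect_equal(wfit$slope, unname(coef(ols)[2]), tolerance = 1e-9)
  expect_equal(wfit$r_squared, summary(ols)$r.squared, tolerance = 1e-9)
})

test_that("fit comparison evaluates lines on the 25-point speed grid", {
  f1 <- structure(list(slope = 0.5, intercept = 0.2, r_squared = 1,
                       weighted = TRUE, metric = "propulsion_impulse",
                       n_bins = 5L, n_obs = 50L), class = "impulse_fit")
  expect_equal(compare_fits(f1, f1)$rmse, 0)
  f2 <- f1; f2$intercept <- f1$intercept + 0.1
  expect_equal(compare_fits(f1, f2)$rmse, 0.1)
  f3 <- f1; f3$slope <- f1$slope + 0.1
  grid <- seq(2.05, 4.45, by = 0.1)
  expect_length(grid, 25L)
  expect_equal(compare_fits(f1, f3)$rmse, 0.1 * sqrt(mean(grid^2)))
})

test_that("an oracle estimator validates nearly perfectly on synthetic data", {
  pr <- noise_free_runner(31)
  cfg <- sim_config(seed = 13L, duration = 60, speed_jitter_sd = 0.05,
                    amp_jitter_sd = 0.03)
  cfg$speed_schedule <- tibble::tibble(t_start = c(0, 15, 30, 45),
                                       speed = c(2.6, 3.1, 3.6, 2.9))
  ss <- generate_session(pr, setting_shift("OG"), cfg)
  tr <- session_truth(ss)
  ev <- tibble::tibble(ic = tr$ic, to = tr$to)
  ref_pts <- compute_impulses(tr$grf_bw, ev, rate = 120,
                              speed = ss$speed$speed_mps)
  # oracle prediction = truth: detect stances from the waveform itself
  pev <- detect_gait_events_from_prediction(tr$grf_bw, swing_rule(), 120)
  pred_pts <- compute_impulses(tr$grf_bw, pev, rate = 120,
                               speed = ss$speed$speed_mps,
                               source = "prediction")
  for (metric in c("braking_impulse", "propulsion_impulse")) {
    rf <- weighted_linear_fit(bin_by_speed(ref_pts), metric)
    pf <- weighted_linear_fit(bin_by_speed(pred_pts), metric)
    cmp <- compare_fits(rf, pf)
    expect_lt(cmp$rmse, sd(ref_pts[[metric]]))
  }
})

test_that("validation fails loudly when no bins survive", {
  est <- fx_tiny_estimator()
  pts <- tibble::tibble(stance_id = 1:2, ic = 1L, to = 2L,
                        braking_impulse = -1, propulsion_impulse = 1,
                        speed = c(2.2, 2.2), source = "force_plate")
  expect_error(validate_setting(list(m = est), list(), pts),
               "\\[2, 4.5\\)")
})
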