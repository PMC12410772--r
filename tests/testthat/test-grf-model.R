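test_that("channel subsets match the sensor layout", {
  expect_length(select_channels("all"), 27L)   # 4 x 6 inertial + 3 angles
  expect_length(select_channels("foot"), 7L)
  expect_length(select_channels("shank"), 7L)
  expect_length(select_channels("thigh"), 7L)
  expect_length(select_channels("pelvis"), 6L) # no pelvis sagittal angle
  expect_error(select_channels("wrist"))
})

test_that("analytic gradients agree with finite differences", {
  set.seed(42)
  C <- 3L; T <- 8L; N <- 4L
  p <- runkinetics:::init_lstm_params(C, 4L, c(5L, 4L))
  X <- array(rnorm(C * T * N), dim = c(C, T, N))
  y <- rnorm(N)
  lg <- runkinetics:::cpp_lstm_loss_grad(p, X, y, 3L, 1.0)
  h <- 1e-5
  for (nm in names(p)) {
    pick <- sample(length(p[[nm]]), min(4L, length(p[[nm]])))
    for (j in pick) {
      pp <- p
      pp[[nm]][j] <- pp[[nm]][j] + h
      up <- runkinetics:::cpp_lstm_loss_grad(pp, X, y, 3L, 1.0)$loss
      pp[[nm]][j] <- pp[[nm]][j] - 2 * h
      dn <- runkinetics:::cpp_lstm_loss_grad(pp, X, y, 3L, 1.0)$loss
      fd <- (up - dn) / (2 * h)
      expect_lt(abs(fd - lg$grad[[nm]][j]),
                1e-4 * max(1, abs(fd)))
    }
  }
})

test_that("the read-out is bidirectional at the mid-point", {
  set.seed(1)
  C <- 5L; T <- 22L; tm0 <- 11L
  p <- runkinetics:::init_lstm_params(C, 8L, c(12L, 8L))
  X <- array(rnorm(C * T), dim = c(C, T, 1L))
  y0 <- runkinetics:::cpp_lstm_predict(p, X, tm0)
  # permuting frames after the mid-point must change the prediction
  Xp <- X
  Xp[, c(14L, 20L), 1L] <- X[, c(20L, 14L), 1L]
  expect_false(isTRUE(all.equal(
    runkinetics:::cpp_lstm_predict(p, Xp, tm0), y0)))
  # and frames before it too (the forward direction reads them)
  Xq <- X
  Xq[, c(2L, 9L), 1L] <- X[, c(9L, 2L), 1L]
  expect_false(isTRUE(all.equal(
    runkinetics:::cpp_lstm_predict(p, Xq, tm0), y0)))
  # replacing frames with identical copies changes nothing
  Xsame <- X
  Xsame[, 14L, 1L] <- X[, 14L, 1L]
  expect_identical(runkinetics:::cpp_lstm_predict(p, Xsame, tm0), y0)
})

test_that("generalized training enforces its preconditions", {
  pool <- fx_tiny_pool()
  one_runner <- pool[pool$runner_id == pool$runner_id[1], ]
  expect_error(train_generalized(one_runner), "at least 2 runners")
  expect_error(train_generalized(pool[0, ]), "empty")
  expect_error(
    train_generalized(pool, channels = c("foot_acc_x", "nonexistent")),
    "channel mismatch")
})

test_that("training is deterministic given a seed and learns on synthetic data", {
  pool <- fx_tiny_pool()
  cfg <- train_config("generalized", epochs = 2, subseq_stride = 6, seed = 7)
  spec <- model_spec(hidden = 12L, dense = c(24L, 12L))
  est1 <- fx_tiny_estimator()
  est2 <- train_generalized(pool, cfg = cfg, spec = spec)
  expect_identical(est1$history, est2$history)
  expect_identical(est1$params, est2$params)
  # validation loss decreases from the first epoch to the best epoch
  expect_lt(min(est2$history$val_loss), est2$history$val_loss[1] + 1e-12)
})

test_that("waveform prediction is deterministic and beats the zero predictor", {
  est <- fx_tiny_estimator()
  s <- fx_clean_tm()
  w1 <- predict_waveform(est, s$prepped)
  w2 <- predict_waveform(est, s$prepped)
  expect_identical(w1, w2)
  expect_true(all(is.na(w1[1:11])))
  fz_n <- s$prepped$force_imu$fz_bw * s$raw$bodyweight_n / 100
  ev <- detect_stance_from_force(fz_n, rate = 120)
  rmse <- stance_rmse(w1, s$prepped$force_imu$fy_bw, ev)
  zero <- stance_rmse(rep(0, length(w1)), s$prepped$force_imu$fy_bw, ev)
  expect_lt(rmse, zero)
  expect_error(predict_waveform(est, s$prepped$imu[1:10, ]), "shorter")
})

test_that("fine-tuning with zero epochs is the identity", {
  est <- fx_tiny_estimator()
  pool <- fx_tiny_pool()
  ft <- fine_tune(est, pool[1:2, ],
                  cfg = train_config("fine_tune", epochs = 0,
                                     subseq_stride = 6))
  expect_identical(ft$params, est$params)
  expect_identical(ft$provenance$k, 2L)
  expect_identical(ft$provenance$mode, "fine_tune")
})

test_that("fine-tuning updates every weight matrix and records provenance", {
  est <- fx_tiny_estimator()
  pool <- fx_tiny_pool()
  ft <- fine_tune(est, pool[1:4, ], pool[5:6, ],
                  cfg = train_config("fine_tune", epochs = 2,
                                     subseq_stride = 6, seed = 3))
  changed <- vapply(names(est$params), function(nm) {
    !isTRUE(all.equal(est$params[[nm]], ft$params[[nm]]))
  }, logical(1))
  expect_true(all(changed))
  expect_identical(ft$provenance$k, 4L)
  expect_identical(ft$provenance$source_setting, "TM-FP")
})

test_that("individual training starts fresh and requires data", {
  pool <- fx_tiny_pool()
  expect_error(train_individual(pool[0, ]), "empty")
  ind <- train_individual(pool[1:4, ], pool[5:6, ],
                          cfg = train_config("individual", epochs = 1,
                                             subseq_stride = 8),
                          spec = model_spec(hidden = 8L, dense = c(12L, 8L)))
  expect_identical(ind$provenance$mode, "individual")
  expect_identical(ind$provenance$k, 4L)
  expect_identical(glance(ind)$mode, "individual")
})

test_that("estimator bundles survive serialisation bit-exactly", {
  est <- fx_tiny_estimator()
  s <- fx_clean_tm()
  path <- withr::local_tempfile(fileext = ".rds")
  write_estimator(est, path)
  back <- read_estimator(path)
  expect_identical(predict_waveform(back, s$prepped),
                   predict_waveform(est, s$prepped))
  expect_identical(back$norm$min, est$norm$min)
  expect_identical(back$provenance, est$provenance)
})

test_that("tidiers expose the loss history and model summary", {
  est <- fx_tiny_estimator()
  td <- tidy(est)
  expect_named(td, c("epoch", "train_loss", "val_loss"))
  gl <- glance(est)
  expect_identical(gl$mode, "generalized")
  expect_identical(gl$n_channels, 27L)
})
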