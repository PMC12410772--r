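# Shared fixtures, built lazily and cached for the whole test run.

.fx <- new.env(parent = emptyenv())

fx <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# a runner profile with all sensor noise switched off
noise_free_runner <- function(seed) {
  pr <- generate_runner(seed)
  pr$noise_sd <- list(acc = 0, gyro = 0, angle = 0)
  pr
}

# deterministic config: no per-stride speed or amplitude jitter
clean_config <- function(duration = 30, seed = 1L, speeds = NULL) {
  cc <- sim_config(seed = seed, duration = duration,
                   speed_jitter_sd = 0, amp_jitter_sd = 0)
  if (!is.null(speeds)) {
    cc$speed_schedule <- tibble::tibble(
      t_start = seq(0, duration, length.out = length(speeds) + 1)[seq_along(speeds)],
      speed = speeds)
  }
  cc
}

# one noise-free treadmill session, conditioned, with windows
fx_clean_tm <- function() {
  fx("clean_tm", function() {
    ss <- generate_session(noise_free_runner(3), setting_shift("TM"),
                           clean_config(30))
    ps <- prep_session(ss)
    list(raw = ss, prepped = ps, windows = session_windows(ps),
         truth = session_truth(ss))
  })
}

# small two-runner treadmill window pool for quick trainings
fx_tiny_pool <- function() {
  fx("tiny_pool", function() {
    ws <- lapply(1:2, function(i) {
      pr <- generate_runner(i + 40L)
      pr$runner_id <- sprintf("R%03d", i)
      session_windows(prep_session(generate_session(
        pr, setting_shift("TM"), sim_config(seed = 9L, duration = 20))))
    })
    dplyr::bind_rows(ws)
  })
}

# a small trained estimator (reduced architecture for speed)
fx_tiny_estimator <- function() {
  fx("tiny_est", function() {
    pool <- fx_tiny_pool()
    train_generalized(
      pool,
      cfg = train_config("generalized", epochs = 2, subseq_stride = 6,
                         seed = 7),
      spec = model_spec(hidden = 12L, dense = c(24L, 12L)))
  })
}

# quick 3-runner experiment at reduced scale (shared by the engine tests
# and the determinism checks)
small_experiment <- function() {
  fx("small_experiment", function() {
    cfg <- sim_config(seed = 31L, duration = 25, n_runners = 3L)
    ds <- make_dataset(cfg, n_out = 0L)
    plan <- experiment_plan(
      configurations = c("GEN-TM", "FTN-OG", "IND-OG"),
      stride_counts = 2L, seeds = 1L,
      gen_cfg = train_config("generalized", epochs = 1, subseq_stride = 8),
      ftn_cfg = train_config("fine_tune", epochs = 1, subseq_stride = 8),
      ind_cfg = train_config("individual", epochs = 1, batch = 4,
                             subseq_stride = 8),
      val_stances = 2L,
      model = function(ch) model_spec(channels = ch, hidden = 8L,
                                      dense = c(12L, 8L)))
    list(ds = ds, plan = plan, res = run_experiment(ds, plan))
  })
}

# exhaustive reference implementation of the swing rule: scan every
# maximal qualifying run directly (independent of the rle-based path)
oracle_swing_events <- function(y, magnitude_max = 0.5, slope_max = 0.25,
                                min_run = 5L, rate = 120,
                                min_stance_s = 0.1) {
  n <- length(y)
  ok_mag <- function(i) !is.na(y[i]) && abs(y[i]) <= magnitude_max
  ok_step <- function(i) {
    !is.na(y[i]) && !is.na(y[i - 1L]) && abs(y[i] - y[i - 1L]) <= slope_max
  }
  runs <- list()
  i <- 1L
  while (i <= n) {
    if (ok_mag(i)) {
      j <- i
      while (j < n && ok_mag(j + 1L) && ok_step(j + 1L)) j <- j + 1L
      if (j - i + 1L >= min_run) runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(runs) < 2L) {
    return(tibble::tibble(ic = integer(), to = integer()))
  }
  ic <- integer(); to <- integer()
  for (k in seq_len(length(runs) - 1L)) {
    a <- runs[[k]][2L] + 1L
    b <- runs[[k + 1L]][1L]
    if (b - a >= max(1L, round(min_stance_s * rate)) &&
        !anyNA(y[a:(b - 1L)])) {
      ic <- c(ic, a); to <- c(to, b)
    }
  }
  tibble::tibble(ic = ic, to = to)
}
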