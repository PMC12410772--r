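# Experiment drivers: leave-one-runner-out cross validation over the four
# training configurations (GEN-TM, FTN-TM, FTN-OG, IND-OG), the
# fine-tuning stride-count sweep, and the single-sensor ablation, with
# stance-restricted RMSE as the error measure.
#
# Per held-out runner: the generalized model is trained on the other
# runners' treadmill windows; the runner's overground stances are split
# chronologically into split A (first half, fine-tuning pool) and split B
# (second half, test). Fine-tuning uses the chronologically first k stances
# of the pool and a fixed 4-stance validation set placed directly after the
# largest requested k, so every k shares the same validation stances and no
# test stance ever enters training (asserted via stance fingerprints).

#' Stance-restricted RMSE between waveforms
#'
#' RMSE pooled over the stance frames of `events` only, so trivially
#' correct swing-phase predictions (~0 %BW) cannot dilute the error.
#' Frames where the prediction is `NA` (outside sub-sequence coverage) are
#' excluded.
#'
#' @param predicted,truth AP-GRF waveforms, %BW.
#' @param events A `gait_events` tibble delimiting the stances.
#' @return RMSE in %BW.
#' @export
stance_rmse <- function(predicted, truth, events) {
  fr <- unlist(lapply(seq_len(nrow(events)),
                      function(i) events$ic[i]:(events$to[i] - 1L)))
  ok <- fr[!is.na(predicted[fr])]
  if (!length(ok)) return(NA_real_)
  sqrt(mean((predicted[ok] - truth[ok])^2))
}

#' Experiment plan
#'
#' @param configurations Subset of `c("GEN-TM", "FTN-TM", "FTN-OG",
#'   "IND-OG")`.
#' @param stride_counts Fine-tuning stride counts k.
#' @param sensor_sets Subset of `c("all", "foot", "shank", "thigh",
#'   "pelvis")`.
#' @param seeds Seeds for the stochastic fine-tuning / individual
#'   trainings; the generalized model is trained once per runner and
#'   sensor set with `gen_cfg$seed`.
#' @param gen_cfg,ftn_cfg,ind_cfg Training configurations per mode.
#' @param val_stances Fine-tuning validation set size.
#' @param val_anchor The validation stances are taken directly after this
#'   many stances of the pool (defaults to the largest stride count), so
#'   every k shares the same validation set — also across separate runs
#'   that sweep different stride counts.
#' @param runners Optional subset of runner ids to hold out.
#' @param model Function mapping a channel vector to a [model_spec()];
#'   defaults to the standard architecture (override to scale the network
#'   down, e.g. in quick checks).
#' @return An `experiment_plan`.
#' @export
experiment_plan <- function(configurations = c("GEN-TM", "FTN-TM", "FTN-OG",
                                               "IND-OG"),
                            stride_counts = 8L,
                            sensor_sets = "all",
                            seeds = 1L,
                            gen_cfg = train_config("generalized"),
                            ftn_cfg = train_config("fine_tune"),
                            ind_cfg = train_config("individual"),
                            val_stances = 4L,
                            val_anchor = NULL,
                            runners = NULL,
                            model = model_spec) {
  configurations <- match.arg(configurations,
                              c("GEN-TM", "FTN-TM", "FTN-OG", "IND-OG"),
                              several.ok = TRUE)
  if (!length(sensor_sets)) abort("empty sensor set list")
  sensor_sets <- match.arg(sensor_sets,
                           c("all", "foot", "shank", "thigh", "pelvis"),
                           several.ok = TRUE)
  stopifnot(all(stride_counts >= 1L), length(seeds) >= 1L)
  structure(list(configurations = configurations,
                 stride_counts = as.integer(stride_counts),
                 sensor_sets = sensor_sets, seeds = as.integer(seeds),
                 gen_cfg = gen_cfg, ftn_cfg = ftn_cfg, ind_cfg = ind_cfg,
                 val_stances = as.integer(val_stances),
                 val_anchor = if (!is.null(val_anchor)) as.integer(val_anchor),
                 runners = runners,
                 model = model),
            class = "experiment_plan")
}

# condition all force sessions of a dataset and extract their windows
prepare_runner_windows <- function(dataset) {
  man <- dataset$manifest
  runners <- unique(man$runner_id)
  out <- list()
  for (r in runners) {
    geti <- function(setting) man$session[man$runner_id == r &
                                            man$setting == setting]
    tm_i <- geti("TM-FP"); og_i <- geti("OG-FP")
    if (!length(tm_i) || !length(og_i)) next
    tm_s <- prep_session(dataset$sessions[[tm_i[1]]])
    og_s <- prep_session(dataset$sessions[[og_i[1]]])
    out[[r]] <- list(tm_windows = session_windows(tm_s),
                     og_session = og_s,
                     og_windows = session_windows(og_s))
  }
  out
}

# chronological split of a runner's overground stances
split_ab <- function(og_windows) {
  n <- nrow(og_windows)
  a <- og_windows[seq_len(n %/% 2L), , drop = FALSE]
  b <- og_windows[(n %/% 2L + 1L):n, , drop = FALSE]
  list(A = a, B = b)
}

# fine-tune pool: first k stances; validation: val_n stances directly
# after the largest requested k (shared across all k)
pool_and_val <- function(windows, k, k_max, val_n) {
  if (k > k_max) abort("k exceeds the largest planned stride count")
  if (nrow(windows) < k_max + val_n) {
    abort(sprintf("stance pool too small: need %d stances, have %d",
                  k_max + val_n, nrow(windows)))
  }
  list(train = windows[seq_len(k), , drop = FALSE],
       val = windows[(k_max + 1L):(k_max + val_n), , drop = FALSE])
}

assert_disjoint <- function(test_fp, train_fp, what) {
  overlap <- intersect(test_fp, train_fp)
  if (length(overlap)) {
    abort(sprintf("data leakage: %d test stances present in %s training data",
                  length(overlap), what))
  }
}

# predict over the slice covering the test stances and return the pooled
# stance RMSE plus the zero-predictor RMSE on the same frames
eval_on_split_b <- function(est, og_session, b_windows) {
  n <- nrow(og_session$imu)
  s0 <- max(1L, min(b_windows$stance_start) - 40L)
  s1 <- min(n, max(b_windows$stance_end) + 40L)
  wav <- predict_waveform(est, og_session$imu[s0:s1, , drop = FALSE])
  truth <- og_session$force_imu$fy_bw[s0:s1]
  ev <- new_gait_events(
    tibble::tibble(ic = b_windows$stance_start - s0 + 1L,
                   to = b_windows$stance_end + 1L - s0 + 1L),
    source = "force", rate = og_session$rate)
  list(rmse = stance_rmse(wav, truth, ev),
       zero = stance_rmse(rep(0, length(truth)), truth, ev))
}

#' Run the experiment matrix on a dataset
#'
#' The general engine behind [run_loocv()], [stride_sweep()] and
#' [sensor_ablation()]: for every held-out runner, sensor set, seed and
#' stride count it trains/fine-tunes the requested configurations and
#' reports the stance-restricted RMSE on the runner's overground split-B
#' stances, alongside the zero-predictor RMSE on the same frames.
#'
#' @param dataset A [make_dataset()] result.
#' @param plan An [experiment_plan()].
#' @param gen_cache Optional environment reusing generalized models across
#'   calls (keyed by runner and sensor set).
#' @return Tibble of result records.
#' @export
run_experiment <- function(dataset, plan = experiment_plan(),
                           gen_cache = NULL) {
  rw <- prepare_runner_windows(dataset)
  runners <- plan$runners %||% names(rw)
  k_max <- plan$val_anchor %||% max(plan$stride_counts)
  cache <- gen_cache %||% new.env(parent = emptyenv())
  rows <- list()
  for (r in runners) {
    info <- rw[[r]]
    ab <- split_ab(info$og_windows)
    test_fp <- ab$B$fingerprint
    for (sset in plan$sensor_sets) {
      channels <- select_channels(sset)
      need_gen <- any(c("GEN-TM", "FTN-TM", "FTN-OG") %in% plan$configurations)
      gen <- NULL
      if (need_gen) {
        key <- paste(r, sset, sep = "::")
        if (is.null(cache[[key]])) {
          others <- dplyr::bind_rows(
            purrr::map(setdiff(names(rw), r), function(q) rw[[q]]$tm_windows))
          cache[[key]] <- train_generalized(others, channels = channels,
                                            cfg = plan$gen_cfg,
                                            spec = plan$model(channels))
        }
        gen <- cache[[key]]
        assert_disjoint(test_fp, gen$provenance$fingerprints, "generalized")
      }
      if ("GEN-TM" %in% plan$configurations) {
        ev <- eval_on_split_b(gen, info$og_session, ab$B)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          runner_id = r, configuration = "GEN-TM", seed = plan$gen_cfg$seed,
          stride_count = NA_integer_, sensor_set = sset,
          stance_rmse_bw = ev$rmse, zero_rmse_bw = ev$zero,
          n_test_stances = nrow(ab$B))
      }
      for (seed in plan$seeds) {
        for (k in plan$stride_counts) {
          if ("FTN-TM" %in% plan$configurations) {
            pv <- pool_and_val(info$tm_windows, k, k_max, plan$val_stances)
            cfg <- plan$ftn_cfg; cfg$seed <- derive_seed(seed, k, 1L)
            est <- fine_tune(gen, pv$train, pv$val, cfg)
            assert_disjoint(test_fp, est$provenance$fingerprints, "FTN-TM")
            ev <- eval_on_split_b(est, info$og_session, ab$B)
            rows[[length(rows) + 1L]] <- tibble::tibble(
              runner_id = r, configuration = "FTN-TM", seed = seed,
              stride_count = k, sensor_set = sset,
              stance_rmse_bw = ev$rmse, zero_rmse_bw = ev$zero,
              n_test_stances = nrow(ab$B))
          }
          if ("FTN-OG" %in% plan$configurations) {
            pv <- pool_and_val(ab$A, k, k_max, plan$val_stances)
            cfg <- plan$ftn_cfg; cfg$seed <- derive_seed(seed, k, 2L)
            est <- fine_tune(gen, pv$train, pv$val, cfg)
            assert_disjoint(test_fp, est$provenance$fingerprints, "FTN-OG")
            ev <- eval_on_split_b(est, info$og_session, ab$B)
            rows[[length(rows) + 1L]] <- tibble::tibble(
              runner_id = r, configuration = "FTN-OG", seed = seed,
              stride_count = k, sensor_set = sset,
              stance_rmse_bw = ev$rmse, zero_rmse_bw = ev$zero,
              n_test_stances = nrow(ab$B))
          }
          if ("IND-OG" %in% plan$configurations) {
            pv <- pool_and_val(ab$A, k, k_max, plan$val_stances)
            cfg <- plan$ind_cfg; cfg$seed <- derive_seed(seed, k, 3L)
            est <- train_individual(pv$train, pv$val, channels = channels,
                                    cfg = cfg, spec = plan$model(channels))
            assert_disjoint(test_fp, est$provenance$fingerprints, "IND-OG")
            ev <- eval_on_split_b(est, info$og_session, ab$B)
            rows[[length(rows) + 1L]] <- tibble::tibble(
              runner_id = r, configuration = "IND-OG", seed = seed,
              stride_count = k, sensor_set = sset,
              stance_rmse_bw = ev$rmse, zero_rmse_bw = ev$zero,
              n_test_stances = nrow(ab$B))
          }
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Leave-one-runner-out cross validation
#'
#' Runs the four configurations (or the subset in `plan`) with one stride
#' count and one sensor set, holding out each runner in turn.
#'
#' @inheritParams run_experiment
#' @return Result tibble; aggregate with [summarize_results()].
#' @export
run_loocv <- function(dataset, plan = experiment_plan(), gen_cache = NULL) {
  if (length(plan$stride_counts) != 1L || length(plan$sensor_sets) != 1L) {
    abort("run_loocv expects one stride count and one sensor set; use stride_sweep() / sensor_ablation()")
  }
  run_experiment(dataset, plan, gen_cache)
}

#' Fine-tuning stride-count sweep
#'
#' Fine-tunes with each requested stride count k (treadmill and/or
#' overground source depending on `plan$configurations`), keeping the
#' 4-stance validation set fixed across k.
#'
#' @inheritParams run_experiment
#' @return Result tibble with one row per runner, seed, configuration, k.
#' @export
stride_sweep <- function(dataset,
                         plan = experiment_plan(
                           configurations = c("FTN-TM", "FTN-OG"),
                           stride_counts = c(2L, 4L, 8L, 14L, 20L)),
                         gen_cache = NULL) {
  run_experiment(dataset, plan, gen_cache)
}

#' Single-sensor ablation
#'
#' Retrains (and fine-tunes) per sensor set and reports the per-runner
#' error grid.
#'
#' @inheritParams run_experiment
#' @return Result tibble with one row per runner, configuration,
#'   sensor set.
#' @export
sensor_ablation <- function(dataset,
                            plan = experiment_plan(
                              configurations = c("GEN-TM", "FTN-OG"),
                              sensor_sets = c("all", "foot", "shank",
                                              "thigh", "pelvis")),
                            gen_cache = NULL) {
  run_experiment(dataset, plan, gen_cache)
}

#' Aggregate experiment results
#'
#' Mean and SD of the stance RMSE across runners (and seeds), by
#' configuration, stride count and sensor set.
#'
#' @param results A [run_experiment()] result tibble.
#' @return Summary tibble.
#' @export
summarize_results <- function(results) {
  dplyr::summarise(
    dplyr::group_by(results, .data$configuration, .data$stride_count,
                    .data$sensor_set),
    mean_rmse_bw = mean(.data$stance_rmse_bw),
    sd_rmse_bw = sd(.data$stance_rmse_bw),
    n = dplyr::n(), .groups = "drop")
}

#' Gait-event accuracy of prediction-derived events for one session
#'
#' Predicts the session waveform, detects gait events from the predictions
#' with the swing rule, and scores them against the force-derived events.
#'
#' @param estimator A `grf_estimator`.
#' @param session A conditioned session with force data.
#' @param rule Swing-detection rule.
#' @return List with `ic_rmse_s`, `to_rmse_s`, counts.
#' @export
evaluate_gait_events <- function(estimator, session, rule = swing_rule()) {
  wav <- predict_waveform(estimator, session)
  pred_ev <- detect_gait_events_from_prediction(wav, rule, session$rate)
  fz_n <- session$force_imu$fz_bw * session$bodyweight_n / 100
  ref_ev <- detect_stance_from_force(fz_n, rate = session$rate)
  event_rmse(pred_ev, ref_ev, rate = session$rate)
}
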