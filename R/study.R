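# End-to-end study driver: builds a synthetic multi-runner dataset, runs
# the leave-one-runner-out configuration comparison and the stride sweep,
# scores prediction-derived gait events, and validates the impulse-speed
# relationship on outdoor sessions without force truth. This is the single
# entry point behind the reproduction script and the heavier tests.

#' Run the full treadmill-to-overground transfer study on synthetic data
#'
#' Scaled-down re-enactment of the complete pipeline: a generalized model
#' is trained per held-out runner on the other runners' treadmill stances,
#' fine-tuned on the held-out runner's first `k_main` overground stances
#' (and, optionally, compared against the from-scratch individual model),
#' evaluated on the runner's held-back overground stances, swept over
#' fine-tuning stride counts, scored for prediction-derived gait-event
#' timing, and validated on outdoor sessions by comparing impulse-speed
#' lines against the force-plate reference.
#'
#' Every random draw (dataset, splits, initialisation, shuffling, dropout)
#' derives from `seed`.
#'
#' @param seed Master seed.
#' @param n_runners Number of synthetic runners.
#' @param n_out How many runners also get an outdoor session.
#' @param tm_duration,og_duration,out_duration Session lengths, s.
#' @param k_main Fine-tuning stride count for the main comparison.
#' @param sweep_counts Additional stride counts for the sweep.
#' @param seeds Training seeds for the stochastic fine-tune / individual
#'   comparisons.
#' @param gen_epochs,ftn_epochs,ind_epochs Epoch budgets per mode.
#' @param gen_stride,ftn_stride Training sub-sequence strides (inference is
#'   always hop 1).
#' @param include_ftn_tm Also run treadmill-source fine-tuning.
#' @param validate_out Run the outdoor impulse-speed validation.
#' @param n_event_runners Number of runners scored for gait-event RMSE.
#' @return List with `results`, `sweep`, `summary`, `events`, `validation`
#'   tibbles plus the `dataset`.
#' @export
run_transfer_study <- function(seed = 1L,
                               n_runners = 6L,
                               n_out = 5L,
                               tm_duration = 105,
                               og_duration = 60,
                               out_duration = 60,
                               k_main = 8L,
                               sweep_counts = c(2L, 20L),
                               seeds = 1:3,
                               gen_epochs = 4L,
                               ftn_epochs = 15L,
                               ind_epochs = 10L,
                               gen_stride = 4L,
                               ftn_stride = 2L,
                               include_ftn_tm = FALSE,
                               validate_out = TRUE,
                               n_event_runners = 2L) {
  cfg <- sim_config(seed = derive_seed(seed, 1L), n_runners = n_runners)
  dataset <- make_dataset(cfg, n_out = n_out,
                          durations = list(TM = tm_duration,
                                           OG = og_duration,
                                           OUT = out_duration))
  gen_cfg <- train_config("generalized", epochs = gen_epochs,
                          subseq_stride = gen_stride,
                          seed = derive_seed(seed, 2L))
  ftn_cfg <- train_config("fine_tune", epochs = ftn_epochs,
                          subseq_stride = ftn_stride)
  ind_cfg <- train_config("individual", epochs = ind_epochs,
                          subseq_stride = ftn_stride)
  k_max <- max(c(k_main, sweep_counts))
  cache <- new.env(parent = emptyenv())

  configs <- c("GEN-TM", if (include_ftn_tm) "FTN-TM", "FTN-OG", "IND-OG")
  main_plan <- experiment_plan(
    configurations = configs, stride_counts = as.integer(k_main),
    seeds = seeds, val_anchor = k_max,
    gen_cfg = gen_cfg, ftn_cfg = ftn_cfg, ind_cfg = ind_cfg)
  results <- run_experiment(dataset, main_plan, cache)

  sweep_plan <- experiment_plan(
    configurations = "FTN-OG",
    stride_counts = setdiff(as.integer(sweep_counts), k_main),
    seeds = seeds, val_anchor = k_max,
    gen_cfg = gen_cfg, ftn_cfg = ftn_cfg, ind_cfg = ind_cfg)
  sweep <- run_experiment(dataset, sweep_plan, cache)
  sweep <- dplyr::bind_rows(
    sweep, results[results$configuration == "FTN-OG", ])

  # prediction-derived gait events, scored on the first runners' OG data
  rw <- prepare_runner_windows(dataset)
  ev_rows <- purrr::map(head(names(rw), n_event_runners), function(r) {
    gen <- cache[[paste(r, "all", sep = "::")]]
    er <- evaluate_gait_events(gen, rw[[r]]$og_session)
    tibble::tibble(runner_id = r, ic_rmse_s = er$ic_rmse_s,
                   to_rmse_s = er$to_rmse_s, n_matched = er$n_matched,
                   n_unmatched = er$n_unmatched)
  })
  events <- dplyr::bind_rows(ev_rows)

  validation <- NULL
  if (validate_out && n_out > 0L) {
    man <- dataset$manifest
    out_runners <- unique(man$runner_id[man$setting == "OUT"])
    val_rows <- purrr::map(out_runners, function(r) {
      gen <- cache[[paste(r, "all", sep = "::")]]
      ab <- split_ab(rw[[r]]$og_windows)
      pv <- pool_and_val(ab$A, k_main, k_max, 4L)
      cfg_f <- ftn_cfg
      cfg_f$seed <- derive_seed(seeds[1L], k_main, 2L)
      ftn <- fine_tune(gen, pv$train, pv$val, cfg_f)
      out_i <- man$session[man$runner_id == r & man$setting == "OUT"]
      out_s <- prep_session(dataset$sessions[[out_i[1L]]])
      og_s <- rw[[r]]$og_session
      fz_n <- og_s$force_imu$fz_bw * og_s$bodyweight_n / 100
      ref_ev <- detect_stance_from_force(fz_n, rate = og_s$rate)
      ref_pts <- compute_impulses(og_s$force_imu$fy_bw, ref_ev,
                                  rate = og_s$rate,
                                  speed = og_s$speed$speed_mps)
      vs <- validate_setting(list(`GEN-TM` = gen, `FTN-OG` = ftn),
                             out_s, ref_pts)
      dplyr::mutate(vs$table, runner_id = r, .before = 1L)
    })
    validation <- dplyr::bind_rows(val_rows)
  }

  list(dataset = dataset, results = results, sweep = sweep,
       summary = summarize_results(dplyr::bind_rows(results, sweep)),
       events = events, validation = validation,
       settings = list(seed = seed, n_runners = n_runners,
                       gen_epochs = gen_epochs, ftn_epochs = ftn_epochs,
                       ind_epochs = ind_epochs, k_main = k_main,
                       sweep_counts = sweep_counts, seeds = seeds))
}
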