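# The AP-GRF regressor: a bidirectional LSTM reading 22-frame sensor
# sub-sequences and predicting the force at the mid-point frame, with three
# training modes (generalized, fine-tuning, individual) and channel-subset
# (single-sensor) support. The numerical core lives in src/lstm.cpp.

#' Model architecture specification
#'
#' Two bidirectional LSTM layers (64 units per direction each), dropout
#' after the second LSTM layer's mid-point read-out, then dense layers of
#' 128 and 64 ReLU units and a scalar output. The recurrent output is read
#' at the sub-sequence mid-point; targets are raw %BW (not normalised), so
#' the swing-phase target is exactly zero.
#'
#' @param channels Input channel names (see [select_channels()]).
#' @param hidden LSTM units per direction.
#' @param dense Sizes of the two dense layers.
#' @param dropout Dropout probability applied to the read-out features.
#' @param seq_len Sub-sequence length, frames.
#' @return A `grf_model_spec`.
#' @export
model_spec <- function(channels = select_channels("all"), hidden = 64L,
                       dense = c(128L, 64L), dropout = 0.2, seq_len = 22L) {
  stopifnot(length(dense) == 2L, hidden >= 1L, seq_len >= 2L)
  structure(list(channels = channels, hidden = as.integer(hidden),
                 dense = as.integer(dense), dropout = dropout,
                 seq_len = as.integer(seq_len),
                 t_m = as.integer(seq_len %/% 2L + 1L)),
            class = "grf_model_spec")
}

#' Channel subset for a sensor configuration
#'
#' Single-segment subsets contain that sensor's six inertial channels plus
#' its sagittal angle (seven channels; six for the pelvis, which has no
#' sagittal angle input); `"all"` is the full 27-channel set.
#'
#' @param segment One of `"all"`, `"foot"`, `"shank"`, `"thigh"`, `"pelvis"`.
#' @return Character vector of channel names.
#' @export
select_channels <- function(segment = c("all", "foot", "shank", "thigh",
                                        "pelvis")) {
  segment <- match.arg(segment)
  all_ch <- sensor_channels()
  if (segment == "all") return(all_ch)
  grep(paste0("^", segment, "_"), all_ch, value = TRUE)
}

#' Training configuration
#'
#' Defaults follow the training recipe: smooth-L1 loss, learning rate
#' 0.001, AdamW (weight decay 0.01); 40 epochs at batch 32 for generalized
#' training with a random 9:1 stance-level train:validation split; 15
#' epochs at batch 16 for fine-tuning with a 4-stance validation set; batch
#' 1 for from-scratch individual training.
#'
#' @param mode `"generalized"`, `"fine_tune"`, or `"individual"`.
#' @param epochs,batch,lr,weight_decay,beta,dropout Optimiser settings
#'   (`beta` is the smooth-L1 transition point).
#' @param val_frac Validation fraction of stances (generalized mode).
#' @param subseq_stride Hop between training sub-sequence starts; inference
#'   always uses hop 1. Values > 1 subsample the training set for speed and
#'   are recorded in provenance.
#' @param seed Integer seed controlling initialisation, the stance split,
#'   shuffling, and dropout.
#' @param pick_best Keep the epoch with the lowest validation loss rather
#'   than the final epoch.
#' @return A `train_config` list.
#' @export
train_config <- function(mode = c("generalized", "fine_tune", "individual"),
                         epochs = NULL, batch = NULL, lr = 0.001,
                         weight_decay = 0.01, beta = 1.0, dropout = 0.2,
                         val_frac = 0.1, subseq_stride = 1L, seed = 1L,
                         pick_best = TRUE) {
  mode <- match.arg(mode)
  defaults <- switch(mode,
    generalized = list(epochs = 40L, batch = 32L),
    fine_tune = list(epochs = 15L, batch = 16L),
    individual = list(epochs = 40L, batch = 1L)
  )
  structure(list(mode = mode,
                 epochs = as.integer(epochs %||% defaults$epochs),
                 batch = as.integer(batch %||% defaults$batch),
                 lr = lr, weight_decay = weight_decay, beta = beta,
                 dropout = dropout, val_frac = val_frac,
                 subseq_stride = as.integer(subseq_stride),
                 seed = as.integer(seed), pick_best = isTRUE(pick_best)),
            class = "train_config")
}

# torch-convention uniform init: LSTM weights U(-1/sqrt(H), 1/sqrt(H)),
# dense layers U(-1/sqrt(fan_in), 1/sqrt(fan_in))
init_lstm_params <- function(n_input, hidden, dense) {
  H <- hidden
  um <- function(r, c, k) matrix(runif(r * c, -k, k), r, c)
  kl <- 1 / sqrt(H)
  lstm <- function(cin) list(W = um(4 * H, cin, kl), U = um(4 * H, H, kl),
                             b = um(4 * H, 1, kl))
  l1f <- lstm(n_input); l1b <- lstm(n_input)
  l2f <- lstm(2 * H); l2b <- lstm(2 * H)
  p <- list(
    W1f = l1f$W, U1f = l1f$U, b1f = l1f$b,
    W1b = l1b$W, U1b = l1b$U, b1b = l1b$b,
    W2f = l2f$W, U2f = l2f$U, b2f = l2f$b,
    W2b = l2b$W, U2b = l2b$U, b2b = l2b$b,
    Wfc1 = um(dense[1], 2 * H, 1 / sqrt(2 * H)),
    bfc1 = um(dense[1], 1, 1 / sqrt(2 * H)),
    Wfc2 = um(dense[2], dense[1], 1 / sqrt(dense[1])),
    bfc2 = um(dense[2], 1, 1 / sqrt(dense[1])),
    Wout = um(1, dense[2], 1 / sqrt(dense[2])),
    bout = um(1, 1, 1 / sqrt(dense[2]))
  )
  p
}

#' Extract labelled stance windows from a conditioned session
#'
#' Detects stances with the 20 N vertical-force threshold, extends each by
#' `pad` frames of swing context, and attaches the per-frame AP-GRF target
#' in %BW along with the mean running speed over the stance. Clipped
#' windows (truncated at the series bounds) are excluded by default.
#'
#' @param session A session that has been through [prep_session()] and has
#'   force data.
#' @param pad Swing extension, frames.
#' @param keep_clipped Keep windows clipped at the series bounds.
#' @return Tibble of windows: identification columns, `input` (27 x W
#'   matrix list-column), `target` (%BW vector list-column), `stance_speed`,
#'   and a `fingerprint` string uniquely naming the stance.
#' @export
session_windows <- function(session, pad = 29L, keep_clipped = FALSE) {
  if (is.null(session$force_imu)) {
    abort("session has no frame-aligned force; run prep_session() on a session with force data")
  }
  fz_n <- session$force_imu$fz_bw * session$bodyweight_n / 100
  ev <- detect_stance_from_force(fz_n, threshold = 20, rate = session$rate)
  win <- extend_window(ev, n_frames = nrow(session$imu), pad = pad)
  if (!keep_clipped) win <- win[!win$clipped, , drop = FALSE]
  chs <- intersect(sensor_channels(), names(session$imu))
  M <- t(as.matrix(session$imu[chs]))
  tgt <- session$force_imu$fy_bw
  spd <- session$speed$speed_mps
  win$stance_id <- seq_len(nrow(win))
  win$runner_id <- session$runner_id
  win$setting <- session$setting
  win$input <- lapply(seq_len(nrow(win)), function(i) {
    M[, win$window_start[i]:win$window_end[i], drop = FALSE]
  })
  win$target <- lapply(seq_len(nrow(win)), function(i) {
    tgt[win$window_start[i]:win$window_end[i]]
  })
  win$stance_speed <- vapply(seq_len(nrow(win)), function(i) {
    mean(spd[win$stance_start[i]:win$stance_end[i]])
  }, numeric(1))
  win$fingerprint <- sprintf("%s|%s|%d", win$runner_id, win$setting,
                             win$stance_start)
  tibble::as_tibble(win)
}

# normalise one channels-by-frames matrix with a norm_spec
normalize_matrix <- function(M, spec) {
  for (i in seq_len(nrow(spec))) {
    chs <- intersect(spec$channels[[i]], rownames(M))
    if (length(chs)) {
      M[chs, ] <- (M[chs, ] - spec$min[i]) / (spec$max[i] - spec$min[i])
    }
  }
  M
}

# fit grouped min-max from the input matrices of a window set
fit_normalization_windows <- function(windows, channels) {
  big <- do.call(cbind, windows$input)
  df <- tibble::as_tibble(t(big[channels, , drop = FALSE]))
  fit_normalization(df)
}

# Build the sub-sequence tensor (C x seq_len x N) from a window set.
# Returns X, y, and the window id of every sample (for stance-level splits).
windows_to_arrays <- function(windows, channels, spec, seq_len = 22L,
                              stride = 1L, t_m = seq_len %/% 2L + 1L) {
  xs <- list(); ys <- list(); wid <- list()
  for (i in seq_len(nrow(windows))) {
    M <- normalize_matrix(windows$input[[i]], spec)[channels, , drop = FALSE]
    L <- ncol(M)
    if (L < seq_len) next
    starts <- seq.int(1L, L - seq_len + 1L, by = stride)
    Xi <- array(0, dim = c(length(channels), seq_len, length(starts)))
    for (tt in seq_len(seq_len)) {
      Xi[, tt, ] <- M[, starts + tt - 1L, drop = FALSE]
    }
    xs[[length(xs) + 1L]] <- Xi
    ys[[length(ys) + 1L]] <- windows$target[[i]][starts + t_m - 1L]
    wid[[length(wid) + 1L]] <- rep(i, length(starts))
  }
  if (!length(xs)) abort("no usable windows (all shorter than seq_len)")
  ns <- vapply(xs, function(a) dim(a)[3], numeric(1))
  X <- array(0, dim = c(length(channels), seq_len, sum(ns)))
  at <- 1L
  for (j in seq_along(xs)) {
    X[, , at:(at + ns[j] - 1L)] <- xs[[j]]
    at <- at + ns[j]
  }
  list(X = X, y = unlist(ys), window = unlist(wid))
}

new_estimator <- function(params, spec, norm, provenance, history) {
  structure(list(params = params, spec = spec, norm = norm,
                 provenance = provenance, history = history),
            class = "grf_estimator")
}

#' Train a generalized AP-GRF model
#'
#' Trains the bidirectional LSTM regressor on stance windows pooled from
#' several runners (at least two). Normalisation is fitted on the training
#' windows only; the stance-level 9:1 train:validation split, parameter
#' initialisation, shuffling and dropout are all governed by `cfg$seed`.
#'
#' @param windows A window tibble (see [session_windows()]) from two or
#'   more runners.
#' @param channels Input channels, e.g. [select_channels()].
#' @param cfg A [train_config()] (mode `"generalized"`).
#' @param spec Optional [model_spec()]; defaults to the standard
#'   architecture over `channels`.
#' @return A `grf_estimator`.
#' @export
train_generalized <- function(windows, channels = select_channels("all"),
                              cfg = train_config("generalized"),
                              spec = NULL) {
  if (nrow(windows) == 0L) abort("empty training set")
  if (length(unique(windows$runner_id)) < 2L) {
    abort("generalized training needs windows from at least 2 runners")
  }
  spec <- spec %||% model_spec(channels = channels)
  if (!all(channels %in% rownames(windows$input[[1]]))) {
    abort("channel mismatch: requested channels absent from window inputs")
  }
  norm <- fit_normalization_windows(windows, channels)
  arr <- windows_to_arrays(windows, channels, norm, spec$seq_len,
                           cfg$subseq_stride, spec$t_m)
  set.seed(cfg$seed)
  n_win <- max(arr$window)
  n_val <- max(1L, round(cfg$val_frac * n_win))
  val_win <- sample(n_win, n_val)
  val_idx <- which(arr$window %in% val_win)
  train_idx <- setdiff(seq_along(arr$y), val_idx)
  params <- init_lstm_params(length(channels), spec$hidden, spec$dense)
  fit <- cpp_lstm_train(params, arr$X, arr$y, train_idx, val_idx,
                        cfg$epochs, cfg$batch, cfg$lr, cfg$weight_decay,
                        cfg$beta, cfg$dropout, spec$t_m - 1L, cfg$pick_best)
  new_estimator(
    fit$params, spec, norm,
    provenance = list(mode = "generalized", config = unclass(cfg),
                      seed = cfg$seed,
                      n_stances = nrow(windows),
                      n_runners = length(unique(windows$runner_id)),
                      subseq_stride = cfg$subseq_stride,
                      fingerprints = windows$fingerprint),
    history = tibble::tibble(epoch = seq_len(cfg$epochs),
                             train_loss = fit$train_loss,
                             val_loss = fit$val_loss)
  )
}

#' Fine-tune a pre-trained estimator on one runner's stances
#'
#' Continues training all weights and biases of a pre-trained estimator on
#' a small individual stance set (15 epochs, batch 16 by default), keeping
#' the pre-trained normalisation so the inputs stay on the scale the
#' weights were learned under. With `cfg$epochs = 0` the estimator is
#' returned numerically unchanged.
#'
#' @param estimator A `grf_estimator` (usually from [train_generalized()]).
#' @param windows Fine-tuning stance windows (the `k` strides).
#' @param val_windows Validation stance windows (4 stances by convention).
#' @param cfg A [train_config()] (mode `"fine_tune"`).
#' @return A `grf_estimator` with updated weights; provenance records `k`
#'   and the source setting.
#' @export
fine_tune <- function(estimator, windows, val_windows = NULL,
                      cfg = train_config("fine_tune")) {
  stopifnot(inherits(estimator, "grf_estimator"))
  if (nrow(windows) == 0L) abort("empty fine-tuning set")
  spec <- estimator$spec
  all_w <- if (is.null(val_windows)) windows else
    dplyr::bind_rows(windows, val_windows)
  arr <- windows_to_arrays(all_w, spec$channels, estimator$norm,
                           spec$seq_len, cfg$subseq_stride, spec$t_m)
  n_tr <- nrow(windows)
  train_idx <- which(arr$window <= n_tr)
  val_idx <- which(arr$window > n_tr)
  set.seed(cfg$seed)
  fit <- cpp_lstm_train(estimator$params, arr$X, arr$y, train_idx, val_idx,
                        cfg$epochs, cfg$batch, cfg$lr, cfg$weight_decay,
                        cfg$beta, cfg$dropout, spec$t_m - 1L,
                        cfg$pick_best && length(val_idx) > 0L)
  new_estimator(
    fit$params, spec, estimator$norm,
    provenance = list(mode = "fine_tune", config = unclass(cfg),
                      seed = cfg$seed, k = n_tr,
                      source_setting = unique(windows$setting),
                      parent = estimator$provenance$mode,
                      fingerprints = c(windows$fingerprint,
                                       if (!is.null(val_windows))
                                         val_windows$fingerprint)),
    history = tibble::tibble(epoch = seq_len(cfg$epochs),
                             train_loss = fit$train_loss,
                             val_loss = fit$val_loss)
  )
}

#' Train an individual model from scratch
#'
#' Fresh initialisation, no pre-training; batch size 1 by default to suit
#' the small training set. Normalisation is fitted on the supplied training
#' windows.
#'
#' @inheritParams fine_tune
#' @param channels Input channels.
#' @param spec Optional [model_spec()].
#' @return A `grf_estimator` (provenance mode `"individual"`).
#' @export
train_individual <- function(windows, val_windows = NULL,
                             channels = select_channels("all"),
                             cfg = train_config("individual"), spec = NULL) {
  if (nrow(windows) == 0L) abort("empty training set")
  spec <- spec %||% model_spec(channels = channels)
  norm <- fit_normalization_windows(windows, channels)
  all_w <- if (is.null(val_windows)) windows else
    dplyr::bind_rows(windows, val_windows)
  arr <- windows_to_arrays(all_w, channels, norm, spec$seq_len,
                           cfg$subseq_stride, spec$t_m)
  n_tr <- nrow(windows)
  train_idx <- which(arr$window <= n_tr)
  val_idx <- which(arr$window > n_tr)
  set.seed(cfg$seed)
  params <- init_lstm_params(length(channels), spec$hidden, spec$dense)
  fit <- cpp_lstm_train(params, arr$X, arr$y, train_idx, val_idx,
                        cfg$epochs, cfg$batch, cfg$lr, cfg$weight_decay,
                        cfg$beta, cfg$dropout, spec$t_m - 1L,
                        cfg$pick_best && length(val_idx) > 0L)
  new_estimator(
    fit$params, spec, norm,
    provenance = list(mode = "individual", config = unclass(cfg),
                      seed = cfg$seed, k = n_tr,
                      source_setting = unique(windows$setting),
                      fingerprints = c(windows$fingerprint,
                                       if (!is.null(val_windows))
                                         val_windows$fingerprint)),
    history = tibble::tibble(epoch = seq_len(cfg$epochs),
                             train_loss = fit$train_loss,
                             val_loss = fit$val_loss)
  )
}

#' Predict a continuous AP-GRF waveform
#'
#' Applies the stored normalisation, slides a hop-1 window of
#' `spec$seq_len` frames over the whole session, predicts the mid-point of
#' every sub-sequence, and stitches the mid-points into a waveform. The
#' first and last few frames (outside any mid-point) are `NA`.
#'
#' @param estimator A `grf_estimator`.
#' @param session A conditioned session (only its IMU channels are used).
#' @return Numeric waveform, %BW, one value per frame.
#' @export
predict_waveform <- function(estimator, session) {
  stopifnot(inherits(estimator, "grf_estimator"))
  imu <- if (inherits(session, "sensor_session")) session$imu else session
  spec <- estimator$spec
  if (nrow(imu) < spec$seq_len) {
    abort(sprintf("session shorter than one sub-sequence (%d frames)",
                  spec$seq_len))
  }
  missing_ch <- setdiff(spec$channels, names(imu))
  if (length(missing_ch)) {
    abort(paste("session lacks model channels:",
                paste(missing_ch, collapse = ", ")))
  }
  M <- t(as.matrix(imu[spec$channels]))
  M <- normalize_matrix(M, estimator$norm)
  n <- ncol(M)
  N <- n - spec$seq_len + 1L
  X <- array(0, dim = c(nrow(M), spec$seq_len, N))
  for (tt in seq_len(spec$seq_len)) {
    X[, tt, ] <- M[, tt:(tt + N - 1L), drop = FALSE]
  }
  y <- cpp_lstm_predict(estimator$params, X, spec$t_m - 1L)
  stitch_predictions(seq_len(N) + spec$t_m - 1L, y, n)
}

#' Save / load an estimator bundle
#'
#' The bundle holds the weights, architecture spec, normalisation and
#' provenance; a load followed by prediction is bit-identical to the
#' original estimator.
#'
#' @param estimator A `grf_estimator`.
#' @param path File path.
#' @return `path` (write) or the estimator (read).
#' @export
write_estimator <- function(estimator, path) {
  stopifnot(inherits(estimator, "grf_estimator"))
  saveRDS(estimator, path)
  invisible(path)
}

#' @rdname write_estimator
#' @export
read_estimator <- function(path) {
  est <- readRDS(path)
  stopifnot(inherits(est, "grf_estimator"))
  est
}

#' @export
print.grf_estimator <- function(x, ...) {
  cat(sprintf("<grf_estimator> mode %s: %d channels, %d LSTM units/dir, best epoch %s\n",
              x$provenance$mode, length(x$spec$channels), x$spec$hidden,
              if (nrow(x$history)) which.min(x$history$val_loss) else NA))
  invisible(x)
}

#' @export
tidy.grf_estimator <- function(x, ...) {
  x$history
}

#' @export
glance.grf_estimator <- function(x, ...) {
  tibble::tibble(
    mode = x$provenance$mode,
    n_channels = length(x$spec$channels),
    hidden = x$spec$hidden,
    n_params = sum(vapply(x$params, length, numeric(1))),
    epochs = nrow(x$history),
    best_epoch = if (nrow(x$history)) which.min(x$history$val_loss) else NA_integer_,
    final_val_loss = if (nrow(x$history)) tail(x$history$val_loss, 1) else NA_real_,
    k = x$provenance$k %||% NA_integer_
  )
}
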