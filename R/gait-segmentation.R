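# Gait segmentation: force-threshold stance extraction with window
# extension for training, prediction-based swing/stance detection for
# continuous inference, sub-sequence construction and mid-point stitching.
#
# Frame indices are 1-based throughout: a stance occupies frames
# `ic .. to - 1`, with `to` the first frame after ground contact.

#' Detect stances from a vertical force series
#'
#' A stance is a maximal run of frames whose vertical force exceeds the
#' threshold (20 N by default). Initial contact is the first frame of the
#' run; toe off is the first frame after it. Runs touching either end of
#' the series (incomplete stances) and runs shorter than `min_stance_s` are
#' dropped.
#'
#' @param force_n Vertical force, N, one value per frame.
#' @param threshold Contact threshold, N.
#' @param rate Frame rate, Hz.
#' @param min_stance_s Minimum stance duration, s.
#' @return A `gait_events` tibble with columns `ic`, `to`; attributes
#'   `source = "force"` and `rate`.
#' @export
detect_stance_from_force <- function(force_n, threshold = 20, rate = 120,
                                     min_stance_s = 0.1) {
  on <- !is.na(force_n) & force_n > threshold
  events_from_mask(on, rate, min_stance_s, source = "force")
}

events_from_mask <- function(stance_mask, rate, min_stance_s, source) {
  r <- rle(stance_mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values &
    starts > 1L & ends < length(stance_mask) &
    r$lengths >= max(1L, round(min_stance_s * rate))
  ev <- tibble::tibble(ic = starts[keep], to = ends[keep] + 1L)
  new_gait_events(ev, source = source, rate = rate)
}

new_gait_events <- function(ev, source, rate) {
  stopifnot(all(ev$to > ev$ic))
  attr(ev, "source") <- source
  attr(ev, "rate") <- rate
  class(ev) <- c("gait_events", class(ev))
  ev
}

#' Extend stance windows by a fixed swing pad
#'
#' Every stance is extended by `pad` frames (29 by default, i.e. 0.242 s at
#' 120 Hz — the shortest swing phase the training data are assumed to
#' contain) on each side so that training windows include swing context.
#' Windows clipped at the series bounds are flagged.
#'
#' @param events A `gait_events` tibble.
#' @param n_frames Length of the underlying series.
#' @param pad Extension on each side, frames.
#' @return Tibble with `stance_start`, `stance_end` (last stance frame),
#'   `window_start`, `window_end`, `clipped`.
#' @export
extend_window <- function(events, n_frames, pad = 29L) {
  ws <- pmax(1L, events$ic - pad)
  we <- pmin(n_frames, events$to - 1L + pad)
  tibble::tibble(
    stance_start = events$ic,
    stance_end = events$to - 1L,
    window_start = ws,
    window_end = we,
    clipped = (events$ic - pad < 1L) | (events$to - 1L + pad > n_frames)
  )
}

#' Slice a series into overlapping fixed-length sub-sequences
#'
#' A series of `L` frames yields `L - length + 1` sub-sequences at hop 1,
#' each labelled by the global index of its mid-point frame `t_m` (local
#' position `length/2 + 1`, i.e. frame 12 of 22).
#'
#' @param x Numeric vector, or a channels-by-frames matrix.
#' @param length Sub-sequence length, frames.
#' @param hop Hop between consecutive sub-sequence starts, frames.
#' @param offset Global index of the first frame of `x` (so `t_m` can refer
#'   to positions in a longer series).
#' @return Tibble with `start`, `t_m`, and list-column `x` (each element a
#'   channels-by-`length` matrix, or a length-`length` vector).
#' @export
make_subsequences <- function(x, length = 22L, hop = 1L, offset = 1L) {
  L <- if (is.matrix(x)) ncol(x) else base::length(x)
  if (L < length) {
    abort(sprintf("series too short for sub-sequences: %d < %d", L, length))
  }
  mid <- length %/% 2L + 1L
  starts <- seq.int(1L, L - length + 1L, by = hop)
  slices <- lapply(starts, function(s) {
    if (is.matrix(x)) x[, s:(s + length - 1L), drop = FALSE]
    else x[s:(s + length - 1L)]
  })
  tibble::tibble(start = starts + offset - 1L,
                 t_m = starts + offset - 1L + mid - 1L,
                 x = slices)
}

#' Stitch mid-point predictions into a waveform
#'
#' Places every sub-sequence prediction at its mid-point frame. Frames not
#' covered by any mid-point (the first `mid - 1` and last `length - mid`
#' frames of the series, and any frames skipped by `hop > 1`) are `NA`;
#' interior gaps left by `hop > 1` are filled by linear interpolation.
#'
#' @param t_m Mid-point frame indices (global, 1-based).
#' @param y Predictions, one per `t_m`.
#' @param n_frames Length of the output waveform.
#' @return Numeric waveform with `NA` outside the covered range.
#' @export
stitch_predictions <- function(t_m, y, n_frames) {
  stopifnot(length(t_m) == length(y), all(t_m >= 1L), all(t_m <= n_frames))
  out <- rep(NA_real_, n_frames)
  out[t_m] <- y
  rng <- range(t_m)
  inside <- seq.int(rng[1L], rng[2L])
  gap <- inside[is.na(out[inside])]
  if (length(gap)) {
    out[gap] <- approx(t_m, y, xout = gap)$y
  }
  out
}

#' Swing-detection rule
#'
#' @param magnitude_max Magnitude bound, %BW.
#' @param slope_max First-difference bound, %BW per frame.
#' @param min_run Minimum number of consecutive qualifying frames.
#' @param min_stance_s Minimum stance duration between two swings, s.
#' @return A `swing_rule` list.
#' @export
swing_rule <- function(magnitude_max = 0.5, slope_max = 0.25, min_run = 5L,
                       min_stance_s = 0.1) {
  structure(list(magnitude_max = magnitude_max, slope_max = slope_max,
                 min_run = as.integer(min_run), min_stance_s = min_stance_s),
            class = "swing_rule")
}

#' Detect gait events from a predicted AP-GRF waveform
#'
#' A swing phase is a maximal run of at least `min_run` consecutive frames
#' whose predicted magnitude is at most `magnitude_max` (%BW) and whose
#' absolute frame-to-frame difference within the run is at most
#' `slope_max` (%BW per frame; the step into the run's first frame does
#' not count against it). Toe off is the first frame of a swing run;
#' initial contact is the frame after its last. Stances are the intervals
#' between consecutive swing runs (so both events are observed); `NA`
#' frames split candidate runs.
#'
#' @param waveform Predicted AP-GRF, %BW (may contain `NA` at the edges).
#' @param rule A [swing_rule()].
#' @param rate Frame rate, Hz.
#' @return A `gait_events` tibble (`source = "prediction"`).
#' @export
detect_gait_events_from_prediction <- function(waveform, rule = swing_rule(),
                                               rate = 120) {
  y <- waveform
  n <- length(y)
  quiet <- !is.na(y) & abs(y) <= rule$magnitude_max
  # split quiet stretches where the within-run slope bound is violated
  steep <- c(FALSE, is.na(diff(y)) | abs(diff(y)) > rule$slope_max)
  new_run <- quiet & (!c(FALSE, quiet[-n]) | steep)
  grp <- cumsum(new_run)
  grp[!quiet] <- 0L
  runs <- which(tabulate(grp) >= rule$min_run)
  starts <- vapply(runs, function(g) min(which(grp == g)), integer(1))
  ends <- vapply(runs, function(g) max(which(grp == g)), integer(1))
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  sw <- seq_along(starts)
  # every swing run contributes a toe off (its first frame) and an initial
  # contact (the frame after its last); complete stances pair consecutive
  # swings
  swings <- tibble::tibble(start = starts[sw], end = ends[sw],
                           to = starts[sw], ic = ends[sw] + 1L)
  if (nrow(swings) < 2L) {
    out <- new_gait_events(tibble::tibble(ic = integer(), to = integer()),
                           source = "prediction", rate = rate)
    attr(out, "swings") <- swings
    return(out)
  }
  ic <- swings$end[-nrow(swings)] + 1L
  to <- swings$start[-1L]
  keep <- (to - ic) >= max(1L, round(rule$min_stance_s * rate)) &
    vapply(seq_along(ic), function(i) !anyNA(y[ic[i]:(to[i] - 1L)]), logical(1))
  out <- new_gait_events(tibble::tibble(ic = ic[keep], to = to[keep]),
                         source = "prediction", rate = rate)
  attr(out, "swings") <- swings
  out
}

#' RMSE between predicted and reference gait events
#'
#' Each predicted event is matched to the nearest reference event of the
#' same type; matches farther than half the median reference stride period
#' are counted as unmatched and excluded from the RMSE.
#'
#' @param predicted,reference `gait_events` tibbles.
#' @param rate Frame rate, Hz.
#' @return List with `ic_rmse_s`, `to_rmse_s`, `n_matched`, `n_unmatched`.
#' @export
event_rmse <- function(predicted, reference, rate = 120) {
  if (nrow(predicted) == 0L) {
    abort("no predicted events: cannot compute event RMSE")
  }
  if (nrow(reference) == 0L) {
    abort("no reference events: cannot compute event RMSE")
  }
  half_stride <- if (nrow(reference) >= 2L) {
    median(diff(reference$ic)) / 2
  } else {
    Inf
  }
  one <- function(pred, ref) {
    d <- vapply(pred, function(p) min(abs(ref - p)), numeric(1))
    ok <- d <= half_stride
    list(rmse = if (any(ok)) sqrt(mean((d[ok] / rate)^2)) else NA_real_,
         matched = sum(ok), unmatched = sum(!ok))
  }
  ic <- one(predicted$ic, reference$ic)
  to <- one(predicted$to, reference$to)
  list(ic_rmse_s = ic$rmse, to_rmse_s = to$rmse,
       n_matched = ic$matched + to$matched,
       n_unmatched = ic$unmatched + to$unmatched)
}
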