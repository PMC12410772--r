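# Impulse-versus-speed validation: stance-level braking and propulsion
# impulses, 0.1 m/s speed bins over 2-4.5 m/s, inverse-variance weighted
# linear fits, and RMSE comparison between fitted lines. This is the
# mechanism for judging predictions where no force plates exist: a
# prediction whose impulse-speed line matches the force-plate line is
# behaving plausibly across speeds.

#' Stance-level braking and propulsion impulses
#'
#' Numerical integration (composite Simpson, trapezoidal fallback for very
#' short segments) of the negative (braking) and positive (propulsion)
#' portions of the AP-GRF over each stance. Signed convention:
#' `braking_impulse <= 0 <= propulsion_impulse`, both in %BW.s.
#'
#' @param waveform AP-GRF, %BW, one value per frame (NA frames outside the
#'   covered range are fine as long as stances are fully covered; stances
#'   containing NA are dropped).
#' @param events A `gait_events` tibble.
#' @param rate Frame rate, Hz.
#' @param speed Optional per-frame speed trace, m/s; the per-stance speed
#'   is its mean over the stance frames.
#' @param source Label recorded per point (`"force_plate"` or
#'   `"prediction"`).
#' @return Tibble of impulse points: `stance_id`, `ic`, `to`,
#'   `braking_impulse`, `propulsion_impulse`, `speed`, `source`.
#' @export
compute_impulses <- function(waveform, events, rate = 120, speed = NULL,
                             source = "force_plate") {
  rows <- purrr::map(seq_len(nrow(events)), function(i) {
    fr <- events$ic[i]:(events$to[i] - 1L)
    y <- waveform[fr]
    if (anyNA(y)) return(NULL)
    tibble::tibble(
      stance_id = i,
      ic = events$ic[i], to = events$to[i],
      braking_impulse = simpson_rate(pmin(y, 0), rate),
      propulsion_impulse = simpson_rate(pmax(y, 0), rate),
      speed = if (is.null(speed)) NA_real_ else mean(speed[fr]),
      source = source
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(stance_id = integer(), ic = integer(),
                          to = integer(), braking_impulse = numeric(),
                          propulsion_impulse = numeric(), speed = numeric(),
                          source = character())
  }
  out
}

#' Bin impulse points by speed
#'
#' 25 half-open bins of width 0.1 m/s spanning \[2.0, 4.5) m/s; bins with
#' fewer than `min_members` points are discarded (logged in the
#' `"discarded"` attribute), and points outside the range are ignored.
#'
#' @param points Impulse points from [compute_impulses()].
#' @param bin_width Bin width, m/s.
#' @param range Speed range covered by the bins.
#' @param min_members Minimum points per surviving bin.
#' @return Tibble of surviving bins: `bin_left`, `bin_mid`, `n`, and
#'   list-column `members`.
#' @export
bin_by_speed <- function(points, bin_width = 0.1, range = c(2, 4.5),
                         min_members = 3L) {
  if (nrow(points) == 0L) {
    out <- tibble::tibble(bin_left = numeric(), bin_mid = numeric(),
                          n = integer(), members = list())
    attr(out, "discarded") <- tibble::tibble(bin_left = numeric(), n = integer())
    return(out)
  }
  lefts <- seq(range[1], range[2] - bin_width / 2, by = bin_width)
  idx <- findInterval(points$speed, c(lefts, range[2]))
  inside <- idx >= 1L & idx <= length(lefts) & points$speed < range[2]
  pts <- points[inside, , drop = FALSE]
  idx <- idx[inside]
  rows <- purrr::map(seq_along(lefts), function(b) {
    mem <- pts[idx == b, , drop = FALSE]
    tibble::tibble(bin_left = lefts[b], bin_mid = lefts[b] + bin_width / 2,
                   n = nrow(mem), members = list(mem))
  })
  bins <- dplyr::bind_rows(rows)
  discarded <- bins[bins$n > 0L & bins$n < min_members, c("bin_left", "n")]
  out <- bins[bins$n >= min_members, , drop = FALSE]
  attr(out, "discarded") <- discarded
  out
}

#' Inverse-variance weighted linear fit of impulse on speed
#'
#' Regresses the individual stance impulses in the surviving bins on their
#' stance speeds, weighting every observation of bin i by
#' `w_i = 1 / var_i`, where `var_i` is the within-bin impulse variance
#' (floored at `var_floor` for degenerate bins). With all-equal weights the
#' fit reduces exactly to ordinary least squares.
#'
#' @param bins A [bin_by_speed()] result (at least 2 surviving bins).
#' @param metric `"braking_impulse"` or `"propulsion_impulse"`.
#' @param var_floor Variance floor for degenerate bins, (%BW.s)^2.
#' @return An `impulse_fit`: slope, intercept, weighted R^2, counts.
#' @export
weighted_linear_fit <- function(bins, metric = c("propulsion_impulse",
                                                 "braking_impulse"),
                                var_floor = 1e-8) {
  metric <- match.arg(metric)
  if (nrow(bins) < 2L) {
    abort(sprintf("need at least 2 surviving speed bins, got %d", nrow(bins)))
  }
  obs <- purrr::map_dfr(seq_len(nrow(bins)), function(i) {
    mem <- bins$members[[i]]
    v <- max(var(mem[[metric]]), var_floor)
    if (is.na(v)) v <- var_floor
    tibble::tibble(x = mem$speed, y = mem[[metric]], w = 1 / v)
  })
  fit <- lm(y ~ x, data = obs, weights = w)
  s <- summary(fit)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = s$r.squared,
                 weighted = TRUE, metric = metric,
                 n_bins = nrow(bins), n_obs = nrow(obs)),
            class = "impulse_fit")
}

#' @export
print.impulse_fit <- function(x, ...) {
  cat(sprintf("<impulse_fit> %s: slope %.3f %%BW.s per m/s, intercept %.3f, R^2 %.3f (%d bins, %d stances)\n",
              x$metric, x$slope, x$intercept, x$r_squared, x$n_bins, x$n_obs))
  invisible(x)
}

#' @export
tidy.impulse_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "speed"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.impulse_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, n_bins = x$n_bins, n_obs = x$n_obs,
                 metric = x$metric)
}

#' Compare two impulse-speed lines
#'
#' RMSE between the two fitted lines evaluated at the 25 bin-centre speeds
#' (2.05, 2.15, ..., 4.45 m/s by default).
#'
#' @param reference,candidate `impulse_fit` objects.
#' @param grid Speeds at which the lines are evaluated, m/s.
#' @return A `fit_comparison`: `rmse` (%BW.s) plus the evaluated lines.
#' @export
compare_fits <- function(reference, candidate,
                         grid = seq(2.05, 4.45, by = 0.1)) {
  stopifnot(inherits(reference, "impulse_fit"),
            inherits(candidate, "impulse_fit"))
  yr <- reference$intercept + reference$slope * grid
  yc <- candidate$intercept + candidate$slope * grid
  structure(list(rmse = sqrt(mean((yr - yc)^2)), grid = grid,
                 reference = yr, candidate = yc,
                 metric = candidate$metric),
            class = "fit_comparison")
}

#' @export
print.fit_comparison <- function(x, ...) {
  cat(sprintf("<fit_comparison> %s: line RMSE %.3f %%BW.s over %d grid points\n",
              x$metric, x$rmse, length(x$grid)))
  invisible(x)
}

#' Validate estimators on sessions without force plates
#'
#' For every estimator: predicts the AP-GRF waveform of each session,
#' detects stances from the predictions (swing rule), computes per-stance
#' braking and propulsion impulses with the session speed trace, pools the
#' points, bins them by speed and fits the weighted line, then compares it
#' with the force-plate reference line. The result mirrors a
#' per-setting report with fit RMSE and R^2 per metric and model.
#'
#' @param estimators Named list of `grf_estimator` objects.
#' @param sessions List of conditioned sessions (force truth not used).
#' @param reference_points Impulse points measured from force plates (with
#'   speeds), used for the reference fit.
#' @param rule Swing-detection rule.
#' @return List with `table` (tibble: model, metric, fit_rmse, r_squared,
#'   n_stances, n_bins) and `fits` (all fitted lines).
#' @export
validate_setting <- function(estimators, sessions, reference_points,
                             rule = swing_rule()) {
  if (inherits(sessions, "sensor_session")) sessions <- list(sessions)
  metrics <- c("braking_impulse", "propulsion_impulse")
  ref_bins <- bin_by_speed(reference_points)
  if (nrow(ref_bins) < 2L) {
    abort(sprintf(
      "no usable reference speed bins in [2, 4.5) m/s (only %d survive)",
      nrow(ref_bins)))
  }
  ref_fits <- lapply(metrics, function(m) weighted_linear_fit(ref_bins, m))
  names(ref_fits) <- metrics
  rows <- list(); fits <- list(reference = ref_fits)
  for (nm in names(estimators)) {
    pts <- purrr::map_dfr(sessions, function(ss) {
      wav <- predict_waveform(estimators[[nm]], ss)
      ev <- detect_gait_events_from_prediction(wav, rule, rate = ss$rate)
      compute_impulses(wav, ev, rate = ss$rate,
                       speed = ss$speed$speed_mps, source = "prediction")
    })
    bins <- bin_by_speed(pts)
    if (nrow(bins) < 2L) {
      abort(sprintf(
        "model '%s': fewer than 2 surviving speed bins in [2, 4.5) m/s", nm))
    }
    fits[[nm]] <- lapply(metrics, function(m) weighted_linear_fit(bins, m))
    names(fits[[nm]]) <- metrics
    for (m in metrics) {
      cmp <- compare_fits(ref_fits[[m]], fits[[nm]][[m]])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        model = nm, metric = sub("_impulse", "", m),
        fit_rmse = cmp$rmse, r_squared = fits[[nm]][[m]]$r_squared,
        n_stances = nrow(pts), n_bins = nrow(bins)
      )
    }
  }
  list(table = dplyr::bind_rows(rows), fits = fits)
}
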