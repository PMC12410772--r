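# Signal conditioning: zero-phase Butterworth filtering, force resampling,
# bodyweight scaling, grouped min-max normalisation, drift-corrected
# sagittal segment angles, and cross-correlation synchronisation.

#' Zero-phase low-pass Butterworth filter
#'
#' Fourth-order (by default) Butterworth low-pass applied forward and
#' backward (bidirectional), giving zero phase distortion and squared
#' magnitude response. The series is extended at both ends by odd
#' reflection over `3 * (order + 1)` samples before filtering and trimmed
#' afterwards, which suppresses start-up transients.
#'
#' @param x Numeric series.
#' @param cutoff_hz Cutoff frequency, Hz; must be below the Nyquist
#'   frequency `rate / 2`.
#' @param rate Sampling rate of `x`, Hz.
#' @param order Filter order (applied twice, so the effective attenuation
#'   is that of a filter of twice this order).
#' @return Filtered series, same length as `x`.
#' @export
butter_filter <- function(x, cutoff_hz, rate, order = 4L) {
  pad <- 3L * (order + 1L)
  if (length(x) <= 3L * pad) {
    abort(sprintf("series too short to filter: need > %d samples, got %d",
                  3L * pad, length(x)))
  }
  if (cutoff_hz <= 0 || cutoff_hz >= rate / 2) {
    abort("cutoff must lie strictly between 0 and the Nyquist frequency")
  }
  bf <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
  n <- length(x)
  front <- 2 * x[1L] - x[(pad + 1L):2L]
  back <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xx <- c(front, x, back)
  # single pass with steady-state initial conditions at the first padded
  # sample (unit DC gain: state = first value held forever)
  one_pass <- function(v) {
    signal::filter(bf$b, bf$a, v, init = rep(v[1L], order),
                   init.x = rep(v[1L], order))
  }
  y <- one_pass(xx)
  y <- rev(one_pass(rev(y)))
  as.numeric(y[(pad + 1L):(pad + n)])
}

#' Resample a force series onto the IMU frame grid
#'
#' Cubic-spline interpolation of an (already 50 Hz low-passed, hence
#' band-limited well below the 60 Hz IMU Nyquist) force series onto the
#' IMU timestamps. The spline reproduces constants and ramps exactly and
#' keeps the interpolation error of band-limited tones far below the
#' sensor noise floor, where linear interpolation from a 2 kHz grid would
#' leave a ~1e-4 relative ripple.
#'
#' @param force_time_s,force Time stamps (s) and values of the force series.
#' @param imu_time_s Target IMU timestamps (s).
#' @return Numeric vector of length `length(imu_time_s)`.
#' @export
resample_force_to_imu <- function(force_time_s, force, imu_time_s) {
  stopifnot(length(force_time_s) == length(force), length(force) >= 2L)
  out <- stats::spline(force_time_s, force, xout = imu_time_s,
                       method = "fmm")$y
  # clamp extrapolation beyond the measured range to the edge values
  out[imu_time_s < force_time_s[1L]] <- force[1L]
  nlast <- length(force_time_s)
  out[imu_time_s > force_time_s[nlast]] <- force[nlast]
  out
}

#' Express force as percent bodyweight
#'
#' @param force_n Force in newtons.
#' @param bodyweight_n Bodyweight in newtons; alternatively give `mass_kg`
#'   and bodyweight is `mass_kg * 9.80665`.
#' @param mass_kg Body mass in kg (used when `bodyweight_n` is missing).
#' @return Force in %BW.
#' @export
force_to_percent_bw <- function(force_n, bodyweight_n = NULL, mass_kg = NULL) {
  if (is.null(bodyweight_n)) {
    if (is.null(mass_kg)) abort("supply bodyweight_n or mass_kg")
    bodyweight_n <- mass_kg * 9.80665
  }
  stopifnot(bodyweight_n > 0)
  100 * force_n / bodyweight_n
}

#' Drift-corrected sagittal segment angle
#'
#' Complementary-filter fusion of the medio-lateral gyroscope channel with
#' the accelerometer inclination: the angle is propagated by trapezoidal
#' gyro integration and continuously pulled toward the gravity-referenced
#' inclination `atan2(acc_x, acc_z)`, which removes integration drift while
#' keeping the gyro's within-stride dynamics. Sensible for segments whose
#' motion is predominantly sagittal (thigh, shank, foot).
#'
#' @param acc_x,acc_z Accelerometer channels in the sagittal plane, m/s^2
#'   (`acc_z` along the segment's reference axis, so a static sensor with
#'   gravity on that axis reads 0 degrees).
#' @param gyro_ml Medio-lateral angular velocity, deg/s.
#' @param rate Sampling rate, Hz.
#' @param alpha Complementary-filter coefficient in (0, 1); higher trusts
#'   the gyro more (crossover `(1 - alpha) * rate / (2 * pi)` Hz).
#' @return Angle series in degrees.
#' @export
extract_sagittal_angle <- function(acc_x, acc_z, gyro_ml, rate,
                                   alpha = 0.998) {
  stopifnot(length(acc_x) == length(acc_z),
            length(acc_x) == length(gyro_ml), alpha > 0, alpha < 1)
  norm_acc <- sqrt(acc_x^2 + acc_z^2)
  sm <- pmin(length(acc_x), as.integer(rate))
  if (mean(norm_acc[seq_len(sm)]) < 1) {
    abort("gravity estimate degenerate: sagittal acceleration norm near zero")
  }
  theta_acc <- unwrap_deg(atan2(acc_x, acc_z) * 180 / pi)
  n <- length(acc_x)
  dt <- 1 / rate
  th <- numeric(n)
  th[1L] <- theta_acc[1L]
  for (i in 2:n) {
    gy <- (gyro_ml[i - 1L] + gyro_ml[i]) / 2
    th[i] <- alpha * (th[i - 1L] + gy * dt) + (1 - alpha) * theta_acc[i]
  }
  th
}

#' Synchronisation lag by cross-correlation
#'
#' Finds the integer lag (frames) that maximises the normalised
#' cross-correlation between a reference angle series and a second series.
#' A positive lag means the second series is delayed relative to the
#' reference, i.e. `series[i + lag]` lines up with `reference[i]`.
#'
#' @param reference,series Numeric series (equal rates).
#' @param max_lag Largest |lag| searched, frames.
#' @return Integer lag.
#' @export
sync_by_cross_correlation <- function(reference, series,
                                      max_lag = min(length(reference) %/% 4L, 240L)) {
  r <- reference - mean(reference)
  s <- series - mean(series)
  n <- min(length(r), length(s))
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(L) {
    if (L >= 0) {
      a <- r[1:(n - L)]; b <- s[(1 + L):n]
    } else {
      a <- r[(1 - L):n]; b <- s[1:(n + L)]
    }
    denom <- sqrt(sum(a^2) * sum(b^2))
    if (denom == 0) 0 else sum(a * b) / denom
  }, numeric(1))
  lags[which.max(cc)]
}

#' Fit grouped min-max normalisation
#'
#' Learns one `(min, max)` pair per channel group from training data only.
#' Tri-axial channels of one sensor share a group so that their relative
#' magnitudes are preserved; each sagittal angle forms its own group.
#'
#' @param imu Tibble (or data frame) of training-set channels.
#' @param groups Named list mapping group name to channel names; defaults to
#'   one group per (segment, modality) plus one per angle channel.
#' @return A `norm_spec` tibble with columns `group`, `channels` (list),
#'   `min`, `max`.
#' @export
fit_normalization <- function(imu, groups = NULL) {
  channels <- setdiff(names(imu), c("frame", "time_s"))
  groups <- groups %||% default_channel_groups(channels)
  rows <- purrr::imap(groups, function(chs, g) {
    chs <- intersect(chs, channels)
    if (!length(chs)) return(NULL)
    vals <- unlist(imu[chs], use.names = FALSE)
    lo <- min(vals); hi <- max(vals)
    if (!is.finite(lo) || !is.finite(hi) || hi <= lo) {
      abort(sprintf("degenerate normalisation group '%s' (max <= min)", g))
    }
    tibble::tibble(group = g, channels = list(chs), min = lo, max = hi)
  })
  spec <- dplyr::bind_rows(rows)
  class(spec) <- c("norm_spec", class(spec))
  spec
}

default_channel_groups <- function(channels) {
  groups <- list()
  for (seg in c("pelvis", "thigh", "shank", "foot")) {
    for (mod in c("acc", "gyro")) {
      nm <- paste0(seg, "_", mod)
      chs <- grep(paste0("^", nm, "_"), channels, value = TRUE)
      if (length(chs)) groups[[nm]] <- chs
    }
  }
  for (ch in grep("_angle$", channels, value = TRUE)) groups[[ch]] <- ch
  leftover <- setdiff(channels, unlist(groups))
  for (ch in leftover) groups[[ch]] <- ch
  groups
}

#' Apply a fitted normalisation
#'
#' Maps every channel by its group's affine transform
#' `(x - min) / (max - min)`. Values outside the training range map outside
#' `[0, 1]` (no clipping).
#'
#' @param imu Tibble of channels (extra columns such as `frame`, `time_s`
#'   pass through unchanged).
#' @param spec A [fit_normalization()] result.
#' @return Tibble of the same shape.
#' @export
apply_normalization <- function(imu, spec) {
  out <- imu
  for (i in seq_len(nrow(spec))) {
    rng <- spec$max[i] - spec$min[i]
    for (ch in spec$channels[[i]]) {
      if (ch %in% names(out)) out[[ch]] <- (out[[ch]] - spec$min[i]) / rng
    }
  }
  out
}

#' Condition a raw session
#'
#' Applies the standard conditioning chain: zero-phase 50 Hz low-pass on all
#' IMU channels, resampling of the force-plate series (if present) onto the
#' IMU frame grid, and conversion of forces to %BW. Adds a `force_imu`
#' tibble (`frame`, `fz_bw`, `fy_bw`) to the session.
#'
#' @param session A `sensor_session`.
#' @param cutoff_hz IMU low-pass cutoff, Hz.
#' @param filter_imu Set `FALSE` to skip IMU filtering.
#' @return The conditioned session.
#' @export
prep_session <- function(session, cutoff_hz = 50, filter_imu = TRUE) {
  stopifnot(inherits(session, "sensor_session"))
  out <- session
  if (filter_imu) {
    chs <- setdiff(names(out$imu), c("frame", "time_s"))
    for (ch in chs) {
      out$imu[[ch]] <- butter_filter(out$imu[[ch]], cutoff_hz, out$rate)
    }
  }
  if (!is.null(out$force)) {
    fz <- resample_force_to_imu(out$force$time_s, out$force$fz_n,
                                out$imu$time_s)
    fy <- resample_force_to_imu(out$force$time_s, out$force$fy_n,
                                out$imu$time_s)
    out$force_imu <- tibble::tibble(
      frame = out$imu$frame,
      fz_bw = force_to_percent_bw(fz, out$bodyweight_n),
      fy_bw = force_to_percent_bw(fy, out$bodyweight_n)
    )
  }
  out$conditioned <- TRUE
  out
}
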