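# Synthetic running-gait simulator.
#
# Generates multi-runner, multi-setting recordings of body-worn inertial
# sensors (pelvis, left thigh, shank, foot; tri-axial acceleration and
# angular velocity at 120 Hz, plus sagittal segment angles) together with
# ground-truth anterior-posterior ground reaction force (AP-GRF, %BW),
# vertical force, gait events, and per-stance running speed.
#
# The AP-GRF of every stance is a negative half-sine braking lobe over the
# first 45 % of stance followed by a positive half-sine propulsion lobe over
# the remainder. Lobe amplitudes scale linearly with running speed through
# runner-specific gains, so per-stance impulses are linear in speed by
# construction. Overground settings apply a multiplicative propulsion shift
# and a foot-angle offset at contact to the generated data, emulating the
# systematic treadmill-to-overground differences the estimation pipeline has
# to overcome. Inertial channels are smooth deterministic functions of gait
# phase (segment-angle sinusoids, their analytic derivatives, an impact
# transient at initial contact, and a late-stance push wavelet whose
# amplitude tracks the propulsion gain) plus i.i.d. Gaussian noise.

SEGMENTS <- c("pelvis", "thigh", "shank", "foot")
ANGLE_SEGMENTS <- c("thigh", "shank", "foot")
GRAVITY <- 9.80665

#' All 27 sensor channel names
#'
#' Four segments with tri-axial acceleration and angular velocity, plus
#' drift-corrected sagittal angles for thigh, shank, and foot.
#' @return Character vector of length 27.
#' @export
sensor_channels <- function() {
  inertial <- as.vector(vapply(
    SEGMENTS,
    function(s) paste0(s, "_", rep(c("acc", "gyro"), each = 3), "_",
                       rep(c("x", "y", "z"), 2)),
    character(6)
  ))
  c(inertial, paste0(ANGLE_SEGMENTS, "_angle"))
}

#' Draw a synthetic runner profile
#'
#' Deterministically draws the anthropometric and style parameters that
#' govern one runner's simulated gait: body mass, baseline cadence, duty
#' factor (stance fraction of the stride), the braking and propulsion gains
#' that scale AP-GRF lobe amplitudes with running speed (%BW per m/s), small
#' per-channel style offsets, and per-modality sensor noise levels.
#'
#' Parameter ranges follow a recreational-runner cohort: mass ~ N(72.8,
#' 14.2) kg clipped to \[50, 105\], cadence uniform in \[162, 182\]
#' steps/min, duty factor uniform in \[0.30, 0.40\].
#'
#' @param seed Integer seed; the same seed always yields the same profile.
#' @return A `runner_profile` list.
#' @export
generate_runner <- function(seed) {
  with_seed(derive_seed(seed, 11L), {
    profile <- list(
      runner_id = sprintf("R%03d", seed %% 1000L),
      seed = as.integer(seed),
      mass = rnorm_clip(1, 72.8, 14.2, 50, 105),
      cadence_base = runif(1, 162, 182),
      duty_factor = runif(1, 0.30, 0.40),
      braking_gain = rnorm_clip(1, 6.5, 0.8, 4.0, 9.0),
      propulsion_gain = rnorm_clip(1, 7.0, 0.8, 4.5, 9.5),
      style_offsets = list(
        motion_scale = setNames(exp(rnorm(27, 0, 0.08)), sensor_channels()),
        angle_offset = setNames(runif(3, -2, 2), paste0(ANGLE_SEGMENTS, "_angle")),
        phase = setNames(runif(4, -0.03, 0.03), SEGMENTS)
      ),
      noise_sd = list(
        acc = 0.25 * runif(1, 0.8, 1.2),
        gyro = 6.0 * runif(1, 0.8, 1.2),
        angle = 0.6 * runif(1, 0.8, 1.2)
      )
    )
    stopifnot(profile$mass > 0,
              profile$duty_factor >= 0.2, profile$duty_factor <= 0.45,
              profile$braking_gain > 0, profile$propulsion_gain > 0)
    structure(profile, class = "runner_profile")
  })
}

#' Setting-specific domain shift
#'
#' Treadmill (`"TM"`) is the identity. Overground (`"OG"`) applies a
#' multiplicative propulsion-amplitude shift and a foot-angle offset at
#' contact; outdoor (`"OUT"`) additionally injects extra sensor noise and
#' its force ground truth is withheld from the estimation pipeline (but
#' retained for testing). The shift acts on the generated force only — the
#' inertial signals carry the foot-angle change but not the propulsion
#' change, so a treadmill-trained model is systematically biased overground
#' until it is fine-tuned.
#'
#' @param setting One of `"TM"`, `"OG"`, `"OUT"`.
#' @param propulsion_shift Multiplicative factor on the propulsion lobe.
#' @param foot_angle_shift Degrees added to the foot angle.
#' @param extra_noise_sd Named list of additional noise (acc m/s^2,
#'   gyro deg/s, angle deg).
#' @return A `setting_shift` list.
#' @export
setting_shift <- function(setting = c("TM", "OG", "OUT"),
                          propulsion_shift = NULL,
                          foot_angle_shift = NULL,
                          extra_noise_sd = NULL) {
  setting <- match.arg(setting)
  defaults <- switch(setting,
    TM = list(propulsion_shift = 1.0, foot_angle_shift = 0,
              extra_noise_sd = list(acc = 0, gyro = 0, angle = 0)),
    OG = list(propulsion_shift = 1.2, foot_angle_shift = -5,
              extra_noise_sd = list(acc = 0, gyro = 0, angle = 0)),
    OUT = list(propulsion_shift = 1.2, foot_angle_shift = -5,
               extra_noise_sd = list(acc = 0.15, gyro = 3, angle = 0.3))
  )
  out <- list(
    setting = setting,
    propulsion_shift = propulsion_shift %||% defaults$propulsion_shift,
    foot_angle_shift = foot_angle_shift %||% defaults$foot_angle_shift,
    extra_noise_sd = extra_noise_sd %||% defaults$extra_noise_sd
  )
  if (setting == "TM" &&
      (out$propulsion_shift != 1 || out$foot_angle_shift != 0)) {
    abort("the treadmill setting shift must be the identity")
  }
  structure(out, class = "setting_shift")
}

#' Simulation configuration
#'
#' @param seed Integer master seed.
#' @param sample_rate IMU sampling rate, Hz.
#' @param duration Session length, s.
#' @param speed_schedule Tibble with columns `t_start` (s) and `speed`
#'   (m/s); piecewise-constant commanded speed. Defaults to five equal
#'   segments between 2.4 and 3.6 m/s.
#' @param n_runners Number of runners for [make_dataset()].
#' @param force_rate Force-plate sampling rate, Hz.
#' @param speed_jitter_sd Per-stride deviation from the commanded speed, m/s.
#' @param amp_jitter_sd Relative step-to-step variability of lobe amplitudes.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, sample_rate = 120, duration = 60,
                       speed_schedule = NULL, n_runners = 15L,
                       force_rate = 2000, speed_jitter_sd = 0.04,
                       amp_jitter_sd = 0.03) {
  stopifnot(sample_rate > 0, duration > 0, n_runners >= 1)
  if (is.null(speed_schedule)) {
    speeds <- c(3.0, 2.4, 3.6, 2.7, 3.3)
    speed_schedule <- tibble::tibble(
      t_start = seq(0, duration, length.out = 6)[1:5],
      speed = speeds
    )
  }
  stopifnot(all(speed_schedule$speed >= 2), all(speed_schedule$speed <= 4.5))
  structure(list(seed = as.integer(seed), sample_rate = sample_rate,
                 duration = duration, speed_schedule = speed_schedule,
                 n_runners = as.integer(n_runners), force_rate = force_rate,
                 speed_jitter_sd = speed_jitter_sd,
                 amp_jitter_sd = amp_jitter_sd),
            class = "sim_config")
}

# per-segment waveform constants: angle amplitude/phase/baseline (deg),
# impact and push amplitudes (m/s^2)
SEG_PAR <- list(
  pelvis = list(amp = 4,  phase = 0.0, base = 2,   imp = 1.2, push = 0.4),
  thigh  = list(amp = 20, phase = 0.3, base = 5,   imp = 2.0, push = 0.6),
  shank  = list(amp = 30, phase = 1.5, base = -10, imp = 3.5, push = 1.0),
  foot   = list(amp = 40, phase = 2.1, base = 8,   imp = 5.0, push = 1.2)
)

# zero-mean motion transients as functions of stride phase (0 = initial
# contact). The impact transient is a decaying oscillation; the push term is
# one full sine period over the propulsion part of stance (exactly zero
# mean), whose amplitude carries the runner's propulsion gain.
impact_wave <- function(phi) {
  exp(-phi / 0.02) * sin(2 * pi * phi / 0.025)
}
push_wave <- function(phi, duty) {
  lo <- 0.45 * duty
  w <- 0.55 * duty
  ifelse(phi >= lo & phi < lo + w, sin(2 * pi * (phi - lo) / w), 0)
}

#' Generate one synthetic sensor session
#'
#' Simulates a continuous run of `cfg$duration` seconds for one runner in
#' one setting. The returned session holds the 120 Hz IMU table (27
#' channels), a 2 kHz force-plate table (vertical and AP force in newtons;
#' omitted for the outdoor setting), a per-frame speed trace, and a hidden
#' `truth` element (AP-GRF in %BW on the IMU frame grid, initial-contact and
#' toe-off frames, per-stance speed) that the estimation pipeline never
#' reads but tests may.
#'
#' @param profile A [generate_runner()] profile.
#' @param shift A [setting_shift()].
#' @param cfg A [sim_config()].
#' @param session_seed Optional seed for this session's noise draws;
#'   defaults to a value derived from `cfg$seed`, the profile and setting.
#' @return A `sensor_session` object.
#' @export
generate_session <- function(profile, shift, cfg, session_seed = NULL) {
  stopifnot(inherits(profile, "runner_profile"),
            inherits(shift, "setting_shift"), inherits(cfg, "sim_config"))
  rate <- cfg$sample_rate
  t_stride <- 120 / profile$cadence_base        # stride period, s
  if (cfg$duration < t_stride + 0.3) {
    abort("duration too short for one full stride")
  }
  seed <- session_seed %||%
    derive_seed(cfg$seed, profile$seed, match(shift$setting, c("TM", "OG", "OUT")))

  with_seed(seed, {
    n <- as.integer(round(cfg$duration * rate))
    t <- (seq_len(n) - 1) / rate
    t0 <- 0.15                                   # first initial contact, s
    duty <- profile$duty_factor
    stance_dur <- duty * t_stride

    # stride timeline: complete strides only
    n_strides <- floor((cfg$duration - t0 - 0.05) / t_stride)
    ic_time <- t0 + (seq_len(n_strides) - 1) * t_stride
    to_time <- ic_time + stance_dur

    # per-stride speed: commanded schedule + small jitter, held per stride
    v_cmd <- piecewise_at(cfg$speed_schedule, ic_time + stance_dur / 2)
    v_str <- pmin(pmax(v_cmd + rnorm(n_strides, 0, cfg$speed_jitter_sd), 2), 4.5)
    amp_eps_b <- 1 + rnorm(n_strides, 0, cfg$amp_jitter_sd)
    amp_eps_p <- 1 + rnorm(n_strides, 0, cfg$amp_jitter_sd)
    a_brake <- profile$braking_gain * v_str * amp_eps_b
    a_prop <- profile$propulsion_gain * v_str * shift$propulsion_shift * amp_eps_p

    # map every frame to its stride and phase
    stride_of <- findInterval(t, ic_time)        # 0 before first IC
    phi <- rep(NA_real_, n)
    in_run <- stride_of >= 1L & stride_of <= n_strides
    phi[in_run] <- (t[in_run] - ic_time[stride_of[in_run]]) / t_stride
    phi[!in_run] <- ((t[!in_run] - t0) %% t_stride) / t_stride

    stride_idx <- pmin(pmax(stride_of, 1L), n_strides)
    v_frame <- v_str[stride_idx]
    sa <- 0.6 + v_frame * (0.4 / 3)              # speed-amplitude factor, 1 @ 3 m/s
    # kinematic amplitudes adapt smoothly over ~a third of a second, so the
    # segment angles stay continuous across commanded speed changes
    sa <- stats::filter(c(rep(sa[1], 20), sa, rep(sa[n], 20)),
                        rep(1 / 41, 41), sides = 2)[(21):(20 + n)]
    sa <- as.numeric(sa)

    ap_at <- function(tt) {
      s <- findInterval(tt, ic_time)
      ok <- s >= 1L & s <= n_strides
      out <- numeric(length(tt))
      ph <- (tt[ok] - ic_time[s[ok]]) / stance_dur
      st <- s[ok]
      y <- numeric(sum(ok))
      brk <- ph >= 0 & ph < 0.45
      prp <- ph >= 0.45 & ph < 1
      y[brk] <- -a_brake[st[brk]] * sin(pi * ph[brk] / 0.45)
      y[prp] <- a_prop[st[prp]] * sin(pi * (ph[prp] - 0.45) / 0.55)
      out[ok] <- y
      out
    }
    vz_at <- function(tt) {                      # vertical force, N
      s <- findInterval(tt, ic_time)
      ok <- s >= 1L & s <= n_strides
      out <- numeric(length(tt))
      ph <- (tt[ok] - ic_time[s[ok]]) / stance_dur
      inside <- ph >= 0 & ph < 1
      y <- numeric(sum(ok))
      y[inside] <- 2.4 * profile$mass * GRAVITY * sin(pi * ph[inside])
      out[ok] <- y
      out
    }

    grf_bw <- ap_at(t)                           # truth on the IMU grid, %BW

    # gait-event frames (1-based; frame i samples time (i-1)/rate).
    # IC = first frame at/after contact, TO = first frame at/after lift-off.
    ic_frame <- pmin(as.integer(ceiling(ic_time * rate - 1e-9)) + 1L, n)
    to_frame <- pmin(as.integer(ceiling(to_time * rate - 1e-9)) + 1L, n)

    # IMU channels
    ms <- profile$style_offsets$motion_scale
    imu <- tibble::tibble(frame = seq_len(n), time_s = t)
    angles <- list()
    for (seg in SEGMENTS) {
      pp <- SEG_PAR[[seg]]
      ph_seg <- 2 * pi * (phi + profile$style_offsets$phase[[seg]])
      theta <- pp$amp * sa * sin(ph_seg + pp$phase) + pp$base
      if (seg == "foot") theta <- theta + shift$foot_angle_shift
      # ML angular velocity as the sampled angle's central difference, so
      # the gyroscope is kinematically consistent with the angle it senses
      gyro_ml <- c(theta[2L] - theta[1L],
                   (theta[3:n] - theta[1:(n - 2L)]) / 2,
                   theta[n] - theta[n - 1L]) * rate
      imp <- pp$imp * (v_frame / 3) *
        (profile$braking_gain / 6.5) * impact_wave(phi)
      push <- pp$push * (v_frame / 3) *
        (profile$propulsion_gain / 7.0) * push_wave(phi, duty)
      th_rad <- theta * pi / 180
      nsd_acc <- profile$noise_sd$acc + shift$extra_noise_sd$acc
      nsd_gyro <- profile$noise_sd$gyro + shift$extra_noise_sd$gyro
      mot_x <- (imp + push) * ms[[paste0(seg, "_acc_x")]]
      mot_z <- 0.6 * imp * ms[[paste0(seg, "_acc_z")]]
      imu[[paste0(seg, "_acc_x")]] <-
        GRAVITY * sin(th_rad) + mot_x + rnorm(n, 0, nsd_acc)
      imu[[paste0(seg, "_acc_y")]] <-
        0.5 * sa * sin(2 * ph_seg + 0.7) * ms[[paste0(seg, "_acc_y")]] +
        rnorm(n, 0, nsd_acc)
      imu[[paste0(seg, "_acc_z")]] <-
        GRAVITY * cos(th_rad) + mot_z + rnorm(n, 0, nsd_acc)
      imu[[paste0(seg, "_gyro_x")]] <-
        0.25 * pp$amp * sa * sin(ph_seg + pp$phase + 0.9) * 2 * pi / t_stride *
        ms[[paste0(seg, "_gyro_x")]] + rnorm(n, 0, nsd_gyro)
      imu[[paste0(seg, "_gyro_y")]] <- gyro_ml + rnorm(n, 0, nsd_gyro)
      imu[[paste0(seg, "_gyro_z")]] <-
        0.2 * pp$amp * sa * sin(ph_seg + pp$phase - 0.6) * 2 * pi / t_stride *
        ms[[paste0(seg, "_gyro_z")]] + rnorm(n, 0, nsd_gyro)
      if (seg %in% ANGLE_SEGMENTS) {
        nsd_ang <- profile$noise_sd$angle + shift$extra_noise_sd$angle
        angles[[paste0(seg, "_angle")]] <- theta +
          profile$style_offsets$angle_offset[[paste0(seg, "_angle")]] +
          rnorm(n, 0, nsd_ang)
      }
    }
    for (nm in names(angles)) imu[[nm]] <- angles[[nm]]

    force <- NULL
    if (shift$setting %in% c("TM", "OG")) {
      tf <- seq(0, cfg$duration - 1 / cfg$force_rate, by = 1 / cfg$force_rate)
      bw_n <- profile$mass * GRAVITY
      force <- tibble::tibble(
        time_s = tf,
        fz_n = vz_at(tf),
        fy_n = ap_at(tf) / 100 * bw_n
      )
    }

    structure(list(
      runner_id = profile$runner_id,
      setting = switch(shift$setting, TM = "TM-FP", OG = "OG-FP", OUT = "OUT"),
      rate = rate,
      imu = imu,
      force = force,
      force_rate = cfg$force_rate,
      bodyweight_n = profile$mass * GRAVITY,
      speed = tibble::tibble(frame = seq_len(n), speed_mps = v_frame),
      truth = list(grf_bw = grf_bw, ic = ic_frame, to = to_frame,
                   stance_speed = v_str,
                   braking_amp = a_brake, propulsion_amp = a_prop,
                   stance_duration_s = stance_dur,
                   theta = NULL)
    ), class = "sensor_session")
  })
}

#' @export
print.sensor_session <- function(x, ...) {
  cat(sprintf("<sensor_session> runner %s, setting %s: %d frames @ %g Hz, %d stances, force %s\n",
              x$runner_id, x$setting, nrow(x$imu), x$rate,
              length(x$truth$ic), if (is.null(x$force)) "absent" else "present"))
  invisible(x)
}

#' Build a multi-runner, multi-setting dataset
#'
#' Mirrors the study design: every runner contributes a treadmill session
#' and an overground session with force ground truth; a subset additionally
#' contributes an outdoor session whose force truth is withheld from the
#' pipeline. Each setting uses its own piecewise-constant speed schedule
#' (treadmill and overground span roughly 2.4-3.8 m/s, outdoor 2.3-4.2 m/s).
#'
#' @param cfg A [sim_config()]; `cfg$n_runners` runners are drawn with seeds
#'   derived from `cfg$seed`.
#' @param n_out Number of runners (from the first) that also get an outdoor
#'   session.
#' @param og_shift,out_shift Setting shifts; defaults per [setting_shift()].
#' @param durations Optional named list overriding the session length (s)
#'   per setting, e.g. `list(TM = 105, OG = 60, OUT = 60)`.
#' @return A `gait_dataset`: list of sessions plus a manifest tibble.
#' @export
make_dataset <- function(cfg, n_out = min(5L, cfg$n_runners),
                         og_shift = setting_shift("OG"),
                         out_shift = setting_shift("OUT"),
                         durations = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  schedules <- list(
    TM = c(3.0, 2.4, 3.6, 2.7, 3.3),
    OG = c(2.8, 3.4, 2.5, 3.7, 3.1),
    OUT = c(2.5, 3.2, 3.9, 2.8, 3.5)
  )
  sched_cfg <- function(speeds, setting) {
    cc <- cfg
    dur <- (durations[[setting]] %||% cfg$duration)
    cc$duration <- dur
    cc$speed_schedule <- tibble::tibble(
      t_start = seq(0, dur, length.out = length(speeds) + 1)[seq_along(speeds)],
      speed = speeds
    )
    cc
  }
  tm_shift <- setting_shift("TM")
  sessions <- list()
  rows <- list()
  profiles <- list()
  for (i in seq_len(cfg$n_runners)) {
    prof <- generate_runner(derive_seed(cfg$seed, i, 7L) %% 100000L)
    prof$runner_id <- sprintf("R%03d", i)
    profiles[[i]] <- prof
    combos <- list(list(shift = tm_shift, sched = schedules$TM, tag = "TM"),
                   list(shift = og_shift, sched = schedules$OG, tag = "OG"))
    if (i <= n_out) {
      combos <- c(combos, list(list(shift = out_shift, sched = schedules$OUT,
                                    tag = "OUT")))
    }
    for (cb in combos) {
      ss <- generate_session(prof, cb$shift, sched_cfg(cb$sched, cb$tag))
      sessions[[length(sessions) + 1L]] <- ss
      rows[[length(rows) + 1L]] <- tibble::tibble(
        session = length(sessions),
        runner_id = prof$runner_id,
        setting = ss$setting,
        truth_available = ss$setting %in% c("TM-FP", "OG-FP"),
        n_frames = nrow(ss$imu),
        n_stances = length(ss$truth$ic)
      )
    }
  }
  structure(list(sessions = sessions,
                 manifest = dplyr::bind_rows(rows),
                 profiles = profiles,
                 config = cfg),
            class = "gait_dataset")
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat(sprintf("<gait_dataset> %d runners, %d sessions\n",
              length(unique(x$manifest$runner_id)), nrow(x$manifest)))
  print(x$manifest)
  invisible(x)
}

#' Leave-one-runner-out partition of a dataset
#'
#' @param dataset A [make_dataset()] result.
#' @return Tibble with one row per runner: `test_runner` and list-columns of
#'   session indices for the held-out runner and the remaining runners.
#' @export
loocv_partition <- function(dataset) {
  runners <- unique(dataset$manifest$runner_id)
  purrr::map_dfr(runners, function(r) {
    tibble::tibble(
      test_runner = r,
      test_sessions = list(which(dataset$manifest$runner_id == r)),
      train_sessions = list(which(dataset$manifest$runner_id != r))
    )
  })
}

# truth accessor used by tests and evaluation drivers (never by the
# estimation pipeline itself)
#' Ground-truth components of a synthetic session
#' @param session A `sensor_session`.
#' @return List with `grf_bw`, `ic`, `to`, `stance_speed`.
#' @export
session_truth <- function(session) {
  stopifnot(inherits(session, "sensor_session"))
  session$truth
}
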