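# Plain-text persistence of sessions and datasets: one directory per
# session holding imu.csv (one row per frame), force.csv (lab settings
# only), speed.csv, meta.json, and a truth.csv sidecar that the estimation
# pipeline never reads.

#' Write a session to a directory of CSV files
#'
#' @param session A `sensor_session`.
#' @param dir Target directory (created if needed).
#' @param write_truth Write the `truth.csv` / `truth_events.csv` sidecars
#'   (kept for testing; the estimation pipeline does not read them).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir, write_truth = TRUE) {
  stopifnot(inherits(session, "sensor_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(session$imu, file.path(dir, "imu.csv"), row.names = FALSE)
  if (!is.null(session$force)) {
    write.csv(session$force, file.path(dir, "force.csv"), row.names = FALSE)
  }
  write.csv(session$speed, file.path(dir, "speed.csv"), row.names = FALSE)
  meta <- list(runner_id = session$runner_id, setting = session$setting,
               rate = session$rate, force_rate = session$force_rate,
               bodyweight_n = session$bodyweight_n)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  if (write_truth && !is.null(session$truth)) {
    write.csv(tibble::tibble(frame = seq_along(session$truth$grf_bw),
                             grf_bw = session$truth$grf_bw),
              file.path(dir, "truth.csv"), row.names = FALSE)
    write.csv(tibble::tibble(ic = session$truth$ic, to = session$truth$to,
                             speed_mps = session$truth$stance_speed),
              file.path(dir, "truth_events.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir Session directory.
#' @param read_truth Also load the truth sidecars if present.
#' @return A `sensor_session`.
#' @export
read_session <- function(dir, read_truth = FALSE) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  imu <- tibble::as_tibble(read.csv(file.path(dir, "imu.csv")))
  force <- NULL
  if (file.exists(file.path(dir, "force.csv"))) {
    force <- tibble::as_tibble(read.csv(file.path(dir, "force.csv")))
  }
  speed <- tibble::as_tibble(read.csv(file.path(dir, "speed.csv")))
  truth <- NULL
  if (read_truth && file.exists(file.path(dir, "truth.csv"))) {
    tw <- read.csv(file.path(dir, "truth.csv"))
    te <- read.csv(file.path(dir, "truth_events.csv"))
    truth <- list(grf_bw = tw$grf_bw, ic = te$ic, to = te$to,
                  stance_speed = te$speed_mps)
  }
  structure(list(runner_id = meta$runner_id, setting = meta$setting,
                 rate = meta$rate, imu = imu, force = force,
                 force_rate = meta$force_rate,
                 bodyweight_n = meta$bodyweight_n, speed = speed,
                 truth = truth),
            class = "sensor_session")
}

#' Write a dataset (manifest + per-session directories)
#'
#' @param dataset A `gait_dataset`.
#' @param dir Target directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- dataset$manifest
  man$path <- sprintf("session_%03d", man$session)
  for (i in seq_len(nrow(man))) {
    write_session(dataset$sessions[[man$session[i]]],
                  file.path(dir, man$path[i]),
                  write_truth = man$truth_available[i])
  }
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' Serialise a normalisation spec to JSON
#' @param spec A `norm_spec`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_norm_spec <- function(spec, path) {
  jsonlite::write_json(
    lapply(seq_len(nrow(spec)), function(i) {
      list(group = spec$group[i], channels = spec$channels[[i]],
           min = spec$min[i], max = spec$max[i])
    }),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a normalisation spec from JSON
#' @param path File written by [write_norm_spec()].
#' @return A `norm_spec` tibble.
#' @export
read_norm_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  spec <- dplyr::bind_rows(lapply(raw, function(r) {
    tibble::tibble(group = r$group, channels = list(unlist(r$channels)),
                   min = r$min, max = r$max)
  }))
  class(spec) <- c("norm_spec", class(spec))
  spec
}
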