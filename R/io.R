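#' Write a trial table as a BIDS-style events file
#'
#' Tab-separated with a header row; missing values written as `"n/a"`.
#' Columns: `onset`, `duration`, `trial_type` (`"stim"`/`"null"`), `run`,
#' `level`, `intensity_mA`, `cue`, `detected`, `report`, `response_time`.
#'
#' @param trials Trial-table tibble.
#' @param path Output path (`.tsv`).
#' @return `path`, invisibly.
#' @export
write_events <- function(trials, path) {
  out <- tibble::tibble(
    onset = trials$onset,
    duration = trials$duration,
    trial_type = ifelse(trials$is_null, "null", "stim"),
    run = trials$run,
    level = trials$level,
    intensity_mA = trials$intensity,
    cue = trials$cue,
    detected = trials$detected,
    report = trials$report,
    response_time = trials$rt
  )
  fmt <- lapply(out, function(col) {
    s <- if (is.numeric(col)) {
      formatC(col, format = "g", digits = 15)
    } else {
      as.character(col)
    }
    s[is.na(col)] <- "n/a"
    s
  })
  mat <- do.call(cbind, fmt)
  utils::write.table(rbind(names(out), mat), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BIDS-style events file into a trial table
#'
#' Inverse of [write_events]; validates per-run onset monotonicity and
#' reports malformed rows with their line number.
#'
#' @param path Path to a `.tsv` events file.
#' @return Trial-table tibble (`run`, `trial`, `onset`, `duration`,
#'   `level`, `intensity`, `cue`, `is_null`, `detected`, `report`, `rt`).
#' @export
read_events <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE,
                           na.strings = "n/a", stringsAsFactors = FALSE)
  needed <- c("onset", "duration", "trial_type", "run", "level",
              "intensity_mA", "cue", "detected", "report", "response_time")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("events file missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(raw$onset) | !is.finite(raw$duration))
  if (length(bad)) {
    stop("malformed events row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)  # +1 for header
  }
  trials <- tibble::tibble(
    run = as.integer(raw$run),
    onset = raw$onset,
    duration = raw$duration,
    level = as.integer(raw$level),
    intensity = raw$intensity_mA,
    cue = raw$cue,
    is_null = raw$trial_type == "null",
    detected = as.integer(raw$detected),
    report = raw$report,
    rt = raw$response_time
  )
  trials <- trials |>
    dplyr::group_by(.data$run) |>
    dplyr::mutate(trial = dplyr::row_number()) |>
    dplyr::ungroup()
  non_mono <- trials |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(ok = !is.unsorted(.data$onset, strictly = TRUE),
                     .groups = "drop")
  if (any(!non_mono$ok)) {
    stop("onsets not strictly increasing in run(s) ",
         paste(non_mono$run[!non_mono$ok], collapse = ", "), call. = FALSE)
  }
  trials[, c("run", "trial", "onset", "duration", "level", "intensity",
             "cue", "is_null", "detected", "report", "rt")]
}

#' Write a 3-D volume as plain text with a JSON sidecar
#'
#' Text-only volume interchange: voxel values as one whitespace-separated
#' row per z-slice, and a `.json` sidecar recording dimensions, voxel size
#' and any provenance metadata.
#'
#' @param vol 3-D numeric array.
#' @param path Output path for the values (`.txt`); the sidecar is written
#'   next to it with extension `.json`.
#' @param voxel_size_mm Isotropic voxel size recorded in the sidecar.
#' @param meta Optional named list of extra metadata (seed, config hash...).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, voxel_size_mm = 3, meta = list()) {
  stopifnot(length(dim(vol)) == 3L)
  dm <- dim(vol)
  utils::write.table(matrix(aperm(vol, c(3L, 1L, 2L)), dm[3L]),
                     path, row.names = FALSE, col.names = FALSE)
  sidecar <- c(list(dim = dm, voxel_size_mm = voxel_size_mm), meta)
  jsonlite::write_json(sidecar, sub("\\.[^.]+$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a plain-text volume written by [write_volume]
#'
#' @param path Path to the `.txt` values file (sidecar `.json` expected
#'   next to it).
#' @return 3-D array with attribute `"voxel_size_mm"`.
#' @export
read_volume <- function(path) {
  sidecar <- jsonlite::read_json(sub("\\.[^.]+$", ".json", path),
                                 simplifyVector = TRUE)
  dm <- as.integer(sidecar$dim)
  m <- as.matrix(utils::read.table(path))
  vol <- aperm(array(as.numeric(m), c(dm[3L], dm[1L], dm[2L])),
               c(2L, 3L, 1L))
  attr(vol, "voxel_size_mm") <- sidecar$voxel_size_mm
  vol
}

#' Serialise a psychometric fit to JSON
#'
#' @param fit A `psychfit`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_psychfit <- function(fit, path) {
  stopifnot(inherits(fit, "psychfit"))
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a psychometric fit from JSON
#'
#' @param path `.json` path written by [write_psychfit].
#' @return A `psychfit`.
#' @export
read_psychfit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_psychfit(x$t50, x$slope,
               n_trials = if (is.null(x$n_trials)) NA_integer_ else as.integer(x$n_trials),
               log_likelihood = if (is.null(x$log_likelihood)) NA_real_ else x$log_likelihood)
}

#' Write the resolved configuration next to a run's outputs
#'
#' Every pipeline run records its full provenance: the resolved
#' configuration, the master seed and the package version.
#'
#' @param config A `sim_config` (or any named list).
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  payload <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("detectbms"))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
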