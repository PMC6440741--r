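#' Per-level trial counts for the near-threshold design
#'
#' The number of trials at each of the 10 intensity levels follows a normal
#' density over levels, maximising trials near threshold. The printed design
#' constraints pin four of the ten counts (16 at levels 1 and 10, 64 at
#' levels 5 and 6, 400 in total); the remaining levels take
#' normal-density-weighted counts rounded to multiples of `n_runs` so each
#' run receives the totals divided evenly. With the default 4 runs the
#' session totals are 16, 28, 40, 52, 64, 64, 52, 40, 28, 16.
#'
#' @param n_runs Number of runs the totals must divide by.
#' @return Integer vector of 10 session totals.
#' @keywords internal
level_totals <- function(n_runs = 4L) {
  # sigma such that density(level 5)/density(level 1) = 64/16
  sigma2 <- (4.5^2 - 0.5^2) / (2 * log(4))
  d <- exp(-((2:4) - 5.5)^2 / (2 * sigma2))
  side <- (400L - 2L * 16L - 2L * 64L) / 2L              # 120 per side
  raw <- d / sum(d) * side
  counts <- round(raw / n_runs) * n_runs
  # distribute any rounding remainder to the level nearest threshold
  counts[3L] <- counts[3L] + (side - sum(counts))
  tot <- c(16L, counts, 64L, 64L, rev(counts), 16L)
  stopifnot(sum(tot) == 400L, all(tot %% n_runs == 0L))
  as.integer(tot)
}

#' Allocate trials to intensity levels and runs
#'
#' Builds the per-run trial lists for the detection task: session totals per
#' level from [level_totals] (scaled if a non-default trial count is
#' requested), split evenly across runs, plus null events, in seeded random
#' order within each run.
#'
#' @param n_runs Number of runs (default 4).
#' @param trials_per_run Experimental trials per run (default 100).
#' @param nulls_per_run Null events per run (default 10).
#' @param seed Integer seed for the per-run shuffles.
#' @return A tibble with columns `run`, `trial` (position within run),
#'   `level` (1-10, `NA` for null events) and `is_null`.
#' @export
allocate_trials <- function(n_runs = 4L, trials_per_run = 100L,
                            nulls_per_run = 10L, seed = 1L) {
  stopifnot(n_runs >= 1L, trials_per_run >= 1L, nulls_per_run >= 0L)
  if (n_runs * trials_per_run != 400L) {
    # scale the canonical totals; only exact scalings are supported
    tot400 <- level_totals(4L)
    scale <- n_runs * trials_per_run / 400
    tot <- round(tot400 * scale)
    if (sum(tot) != n_runs * trials_per_run || any(tot %% n_runs != 0)) {
      stop("level constraint set incompatible with requested totals",
           call. = FALSE)
    }
    tot <- as.integer(tot)
  } else {
    tot <- level_totals(n_runs)
  }
  per_run <- tot %/% n_runs
  set.seed(seed)
  purrr::map_dfr(seq_len(n_runs), function(r) {
    lv <- c(rep(seq_len(10L), times = per_run), rep(NA_integer_, nulls_per_run))
    lv <- sample(lv)
    tibble::tibble(run = r, trial = seq_along(lv), level = lv,
                   is_null = is.na(lv))
  })
}

#' Assign counterbalanced matching cues
#'
#' Matching cues (white disk = "stimulus present", dark disk = "stimulus
#' absent") are counterbalanced within each intensity level — present/absent
#' counts differ by at most one per level — and randomised across trials.
#' This is what severs overt reports from detection and intensity.
#'
#' @param levels Integer vector of intensity levels (`NA` for null events).
#' @param seed Integer seed.
#' @return Character vector (`"present"`/`"absent"`, `NA` for null events).
#' @export
assign_cues <- function(levels, seed = 1L) {
  set.seed(seed)
  cues <- rep(NA_character_, length(levels))
  for (lv in unique(levels[!is.na(levels)])) {
    idx <- which(!is.na(levels) & levels == lv)
    n <- length(idx)
    half <- c(rep("present", ceiling(n / 2)), rep("absent", floor(n / 2)))
    cues[idx] <- sample(half)
  }
  cues
}

#' Map a matching cue and a detection outcome to an overt report
#'
#' Truth table of the match/mismatch task: a report is "match" when the
#' percept agrees with the cue — target detected under a "present" cue, or
#' missed under an "absent" cue — and "mismatch" otherwise.
#'
#' @param cue `"present"` or `"absent"` (vectorised).
#' @param detected Binary detection outcome (vectorised).
#' @return `"match"` or `"mismatch"`.
#' @export
derive_report <- function(cue, detected) {
  stopifnot(all(cue %in% c("present", "absent") | is.na(cue)))
  det <- as.logical(detected)
  ifelse(is.na(cue) | is.na(det), NA_character_,
         ifelse((cue == "present") == det, "match", "mismatch"))
}

#' Generate trial onsets for one run
#'
#' Onsets accumulate a variable inter-trial interval (uniform within
#' `iti_bounds`) plus the fixed event duration (cue 0.8 s + delay 0.3 s +
#' response window 0.9 s = 2 s).
#'
#' @param n_events Number of events in the run.
#' @param iti_bounds Length-2 numeric, ITI bounds in seconds (default
#'   2.5-7 s).
#' @param event_duration Fixed event duration in seconds.
#' @param seed Integer seed.
#' @return Numeric vector of onset times (s from run start).
#' @export
generate_onsets <- function(n_events, iti_bounds = c(2.5, 7),
                            event_duration = 2, seed = 1L) {
  stopifnot(length(iti_bounds) == 2L, iti_bounds[1L] <= iti_bounds[2L])
  set.seed(seed)
  iti <- stats::runif(n_events, iti_bounds[1L], iti_bounds[2L])
  cumsum(iti + event_duration) - event_duration
}

#' Build a complete (stimulus-side) trial table
#'
#' Combines allocation, cue assignment, intensity mapping and onsets into a
#' per-run trial table ready for behaviour simulation. The behavioural
#' columns (`detected`, `report`, `rt`) are `NA` until
#' [simulate_behaviour()] fills them.
#'
#' @param grid An `intensity_grid` mapping levels to mA.
#' @inheritParams allocate_trials
#' @inheritParams generate_onsets
#' @return A trial-table tibble with columns `run`, `trial`, `onset`,
#'   `duration`, `level`, `intensity`, `cue`, `is_null`, `detected`,
#'   `report`, `rt`.
#' @export
build_trial_table <- function(grid, n_runs = 4L, trials_per_run = 100L,
                              nulls_per_run = 10L, iti_bounds = c(2.5, 7),
                              seed = 1L) {
  stopifnot(inherits(grid, "intensity_grid"))
  trials <- allocate_trials(n_runs, trials_per_run, nulls_per_run, seed = seed)
  trials$cue <- assign_cues(trials$level, seed = seed + 1L)
  trials$intensity <- ifelse(is.na(trials$level), NA_real_,
                             grid$levels[trials$level])
  trials <- trials |>
    dplyr::group_by(.data$run) |>
    dplyr::mutate(onset = generate_onsets(dplyr::n(), iti_bounds = iti_bounds,
                                          seed = seed + 100L + .data$run[1L]),
                  duration = 2) |>
    dplyr::ungroup()
  trials$detected <- NA_integer_
  trials$report <- NA_character_
  trials$rt <- NA_real_
  trials[, c("run", "trial", "onset", "duration", "level", "intensity",
             "cue", "is_null", "detected", "report", "rt")]
}

#' The five candidate modulators
#' @keywords internal
MODEL_NAMES <- c("intensity", "detection", "p_detect", "uncertainty", "report")

#' Build the five z-scored experimental regressors for one run
#'
#' From the non-null trials of one run, derives the five trial-wise
#' modulators that define the competing GLMs — linear stimulus intensity,
#' binary target detection, model-based detection probability, expected
#' uncertainty (psychometric slope at the presented intensity), and binary
#' match/mismatch report — plus z-scored reaction times. Each vector is
#' z-scored (mean 0, sd 1).
#'
#' @param trials Trial-table tibble for one run with behaviour filled in.
#' @param fit The participant's `psychfit`.
#' @param intensity_as_level Use the level index 1-10 as the intensity
#'   modulator (default; equivalent to mA after z-scoring when the grid is
#'   equidistant).
#' @return A tibble with columns `onset`, `intensity`, `detection`,
#'   `p_detect`, `uncertainty`, `report`, `rt_z` — one row per
#'   experimental trial.
#' @export
build_regressors <- function(trials, fit, intensity_as_level = TRUE) {
  stopifnot(inherits(fit, "psychfit"))
  tr <- dplyr::filter(trials, !.data$is_null)
  if (anyNA(tr$detected) || anyNA(tr$report) || anyNA(tr$rt)) {
    stop("trials carry unfilled behaviour; run simulate_behaviour() first",
         call. = FALSE)
  }
  raw_int <- if (intensity_as_level) as.numeric(tr$level) else tr$intensity
  tibble::tibble(
    onset = tr$onset,
    intensity = zscore(raw_int, "intensity"),
    detection = zscore(as.numeric(tr$detected), "detection"),
    p_detect = zscore(detection_probability(fit, tr$intensity), "p_detect"),
    uncertainty = zscore(uncertainty_value(fit, tr$intensity), "uncertainty"),
    report = zscore(as.numeric(tr$report == "match"), "report"),
    rt_z = zscore(tr$rt, "rt")
  )
}

#' Plot the five modulators against intensity level
#'
#' Averages each raw (pre-z-score) modulator within intensity level to show
#' the characteristic shapes that let model selection discriminate them:
#' linear (intensity), sigmoid (detection, detection probability), inverse-U
#' (uncertainty), flat (report).
#'
#' @param trials Trial table with behaviour.
#' @param fit The participant's `psychfit`.
#' @return A ggplot object.
#' @export
plot_regressor_shapes <- function(trials, fit) {
  tr <- dplyr::filter(trials, !.data$is_null)
  df <- tr |>
    dplyr::mutate(
      intensity_mod = as.numeric(.data$level),
      detection_mod = as.numeric(.data$detected),
      p_detect_mod = detection_probability(fit, .data$intensity),
      uncertainty_mod = uncertainty_value(fit, .data$intensity),
      report_mod = as.numeric(.data$report == "match")
    ) |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(dplyr::across(dplyr::ends_with("_mod"), mean),
                     .groups = "drop") |>
    tidyr::pivot_longer(-"level", names_to = "model", values_to = "value") |>
    dplyr::mutate(model = sub("_mod$", "", .data$model))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~model, scales = "free_y") +
    ggplot2::labs(x = "Intensity level", y = "Mean modulator value")
}
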