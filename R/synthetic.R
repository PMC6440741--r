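#' Simulation configuration for the synthetic cohort
#'
#' Collects every knob of the behaviour + BOLD generator in one validated
#' list. Defaults encode the experiment the analysis assumes: 4 runs of 100
#' experimental trials plus 10 null events, TR 2 s, 378 volumes per run, a
#' population of logistic observers with T50 = 2.40 +- 0.69 mA, reaction
#' times ~ 364 ms with detected targets 11.77 ms faster, and BOLD signals of
#' 1% per SD of modulator against 1% AR(1) noise on a 20x20x20 desk-scale
#' lattice holding five 60-voxel generator regions plus one null region.
#'
#' @param n_subjects Number of simulated participants.
#' @param t50_mean,t50_sd Population mean/SD of the detection threshold (mA).
#' @param slope_mean,slope_sd Population mean/SD of the psychometric slope
#'   (1/mA); draws truncated below at 0.5 /mA.
#' @param n_runs,trials_per_run,nulls_per_run Design counts.
#' @param tr Repetition time (s).
#' @param n_vols Volumes per run.
#' @param iti_bounds Inter-trial interval bounds (s).
#' @param amplitude Effect amplitude: % signal change per SD of the
#'   generating modulator.
#' @param onset_amplitude % signal change of the unmodulated onset response
#'   shared by all non-null regions.
#' @param noise_sd Marginal noise SD in % signal change.
#' @param ar1 AR(1) coefficient of the noise, in (-1, 1).
#' @param drift_amplitude Amplitude (%) of a 128 s cosine drift (0 disables).
#' @param rt_mean,rt_sd Reaction-time model: Gaussian mean/SD (s) for
#'   undetected targets, truncated to the response window
#'   \code{rt_bounds}.
#' @param rt_detected_shift Mean RT shift (s) for detected targets
#'   (negative = faster).
#' @param rt_bounds Response window (s).
#' @param dim Lattice dimensions (voxels).
#' @param region_size Dimensions of each embedded region (product = voxels
#'   per region).
#' @param voxel_size_mm Isotropic voxel size (mm).
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 12L,
                       t50_mean = 2.40, t50_sd = 0.69,
                       slope_mean = 2.05, slope_sd = 0.4,
                       n_runs = 4L, trials_per_run = 100L, nulls_per_run = 10L,
                       tr = 2, n_vols = 378L, iti_bounds = c(2.5, 7),
                       amplitude = 1, onset_amplitude = 1,
                       noise_sd = 1, ar1 = 0.2, drift_amplitude = 0.5,
                       rt_mean = 0.364, rt_sd = 0.053,
                       rt_detected_shift = -0.01177,
                       rt_bounds = c(0.15, 0.9),
                       dim = c(20L, 20L, 20L), region_size = c(5L, 4L, 3L),
                       voxel_size_mm = 3, seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), t50_mean = t50_mean,
              t50_sd = t50_sd, slope_mean = slope_mean, slope_sd = slope_sd,
              n_runs = as.integer(n_runs),
              trials_per_run = as.integer(trials_per_run),
              nulls_per_run = as.integer(nulls_per_run), tr = tr,
              n_vols = as.integer(n_vols), iti_bounds = iti_bounds,
              amplitude = amplitude, onset_amplitude = onset_amplitude,
              noise_sd = noise_sd, ar1 = ar1,
              drift_amplitude = drift_amplitude,
              rt_mean = rt_mean, rt_sd = rt_sd,
              rt_detected_shift = rt_detected_shift, rt_bounds = rt_bounds,
              dim = as.integer(dim), region_size = as.integer(region_size),
              voxel_size_mm = voxel_size_mm, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(is.finite(cfg$amplitude), is.finite(cfg$noise_sd),
            cfg$ar1 > -1, cfg$ar1 < 1,
            cfg$n_subjects >= 1L, cfg$tr > 0, cfg$n_vols >= 1L,
            length(cfg$dim) == 3L, length(cfg$region_size) == 3L,
            prod(cfg$region_size) <= prod(cfg$dim))
  invisible(cfg)
}

#' Region layout of the desk-scale phantom
#'
#' Places six disjoint rectangular regions (one per candidate model plus a
#' pure-noise null region) in the lattice, at alternating corners so no two
#' regions touch.
#'
#' @param dim Lattice dimensions.
#' @param region_size Region box dimensions.
#' @return Named list (`intensity`, `detection`, `p_detect`, `uncertainty`,
#'   `report`, `null`) of voxel linear indices.
#' @export
region_layout <- function(dim = c(20L, 20L, 20L), region_size = c(5L, 4L, 3L)) {
  rs <- region_size
  lo <- c(2L, 2L, 2L)
  hi <- dim - rs - 1L
  stopifnot(all(hi >= lo))
  origins <- list(
    intensity   = c(lo[1], lo[2], lo[3]),
    detection   = c(hi[1], lo[2], lo[3]),
    p_detect    = c(lo[1], hi[2], lo[3]),
    uncertainty = c(hi[1], hi[2], lo[3]),
    report      = c(lo[1], lo[2], hi[3]),
    null        = c(hi[1], hi[2], hi[3])
  )
  purrr::map(origins, function(o) {
    ix <- expand.grid(x = o[1]:(o[1] + rs[1] - 1L),
                      y = o[2]:(o[2] + rs[2] - 1L),
                      z = o[3]:(o[3] + rs[3] - 1L))
    as.integer((ix$z - 1L) * dim[1] * dim[2] + (ix$y - 1L) * dim[1] + ix$x)
  })
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, pl, pu), mean, sd)
}

#' Simulate behaviour for a trial table
#'
#' Fills `detected`, `report` and `rt` for the experimental trials:
#' detection is Bernoulli with probability given by the observer's
#' psychometric function at the presented intensity, reports follow the
#' match/mismatch truth table, and reaction times are truncated-Gaussian
#' with detected targets faster by a configurable mean shift.
#'
#' @param fit The observer's `psychfit`.
#' @param trials Trial table from [build_trial_table()].
#' @param config A `sim_config` (RT model parameters are read from it).
#' @param seed Integer seed.
#' @return The trial table with behaviour columns filled.
#' @export
simulate_behaviour <- function(fit, trials, config = sim_config(), seed = 1L) {
  stopifnot(inherits(fit, "psychfit"))
  set.seed(seed)
  exp_idx <- which(!trials$is_null)
  p <- detection_probability(fit, trials$intensity[exp_idx])
  det <- stats::rbinom(length(exp_idx), 1L, p)
  trials$detected[exp_idx] <- det
  trials$report[exp_idx] <- derive_report(trials$cue[exp_idx], det)
  mu <- config$rt_mean + config$rt_detected_shift * det
  trials$rt[exp_idx] <- rtruncnorm1(length(exp_idx), mu, config$rt_sd,
                                    config$rt_bounds[1L], config$rt_bounds[2L])
  trials
}

ar1_noise <- function(n_vols, n_voxels, sd, rho) {
  innov_sd <- sd * sqrt(1 - rho^2)
  e <- matrix(stats::rnorm(n_vols * n_voxels, 0, innov_sd), n_vols, n_voxels)
  if (rho != 0) {
    e <- apply(e, 2L, function(col) {
      as.numeric(stats::filter(col, rho, method = "recursive"))
    })
    e <- matrix(e, n_vols, n_voxels)
  }
  e
}

#' Simulate one run of BOLD data on the phantom lattice
#'
#' Each non-null region's signal is the HRF-convolved train of trial
#' impulses weighted by that region's generating modulator (plus a shared
#' unmodulated onset response), scaled to `amplitude` % signal change per SD
#' of modulator on a baseline of 100. All regions receive AR(1) Gaussian
#' noise and an optional low-frequency cosine drift; the null region and
#' background receive noise (and drift) only.
#'
#' @param trials One run's trial table with behaviour.
#' @param regressors The run's [build_regressors()] output.
#' @param config A `sim_config`.
#' @param seed Integer seed.
#' @param regions Region layout (defaults to [region_layout()] for
#'   `config$dim`).
#' @return A list: `bold` (volumes x voxels matrix, baseline 100), `truth`
#'   (character vector of generating model per voxel, `"background"`
#'   outside regions), `regions` (the layout).
#' @export
simulate_bold <- function(trials, regressors, config = sim_config(),
                          seed = 1L, regions = NULL) {
  last_evt <- max(trials$onset)
  if (config$n_vols * config$tr < last_evt + 20) {
    stop("scan duration too short for the last trial onset", call. = FALSE)
  }
  if (is.null(regions)) regions <- region_layout(config$dim, config$region_size)
  set.seed(seed)
  n_vox <- prod(config$dim)
  nv <- config$n_vols
  onsets <- regressors$onset
  base_resp <- convolve_events(onsets, NULL, nv, config$tr)
  bold <- matrix(100, nv, n_vox) +
    ar1_noise(nv, n_vox, config$noise_sd, config$ar1)
  if (config$drift_amplitude > 0) {
    t_s <- (seq_len(nv) - 1L) * config$tr
    phase <- stats::runif(n_vox, 0, 2 * pi)
    bold <- bold + config$drift_amplitude *
      cos(outer(2 * pi * t_s / 128, phase, "+"))
  }
  truth <- rep("background", n_vox)
  for (nm in names(regions)) {
    truth[regions[[nm]]] <- nm
    if (nm == "null") next
    mod_resp <- convolve_events(onsets, regressors[[nm]], nv, config$tr)
    signal <- config$onset_amplitude * base_resp + config$amplitude * mod_resp
    bold[, regions[[nm]]] <- bold[, regions[[nm]]] + signal
  }
  list(bold = bold, truth = truth, regions = regions)
}

#' Simulate a full multi-subject cohort with ground truth
#'
#' Draws per-subject psychometric observers from the population model,
#' builds each subject's adaptive intensity grid and counterbalanced trial
#' tables, simulates behaviour and per-run BOLD lattices, and records all
#' ground truth alongside. Onset sequences that would overrun the scan
#' (last onset + 20 s beyond the run) are redrawn with an incremented
#' subseed, mimicking an experimenter regenerating a protocol that does not
#' fit the scanner slot.
#'
#' @param config A `sim_config`.
#' @param bold Set `FALSE` to simulate behaviour only (fast; no volumes).
#' @return A list of class `synthetic_cohort`: `config`, `regions`, and
#'   `subjects` — each with `fit` (true `psychfit`), `grid`, `trials`
#'   (all runs), `regressors` (per run), `bold` (per run, unless
#'   `bold = FALSE`).
#' @export
simulate_cohort <- function(config = sim_config(), bold = TRUE) {
  validate_sim_config(config)
  set.seed(config$seed)
  t50s <- stats::rnorm(config$n_subjects, config$t50_mean, config$t50_sd)
  slopes <- pmax(stats::rnorm(config$n_subjects, config$slope_mean,
                              config$slope_sd), 0.5)
  regions <- region_layout(config$dim, config$region_size)
  subjects <- purrr::map(seq_len(config$n_subjects), function(s) {
    sseed <- config$seed * 1000L + s
    fit <- new_psychfit(t50s[s], slopes[s])
    grid <- derive_intensity_grid(fit)
    trials <- NULL
    for (attempt in 0:199) {
      cand <- build_trial_table(grid, config$n_runs, config$trials_per_run,
                                config$nulls_per_run, config$iti_bounds,
                                seed = sseed + attempt * 7919L)
      if (max(cand$onset) + 20 <= config$n_vols * config$tr) {
        trials <- cand
        break
      }
    }
    if (is.null(trials)) {
      stop("could not fit trial onsets within the scan duration", call. = FALSE)
    }
    trials <- simulate_behaviour(fit, trials, config, seed = sseed + 1L)
    runs <- split(trials, trials$run)
    regressors <- purrr::map(runs, build_regressors, fit = fit)
    out <- list(fit = fit, grid = grid, trials = trials,
                regressors = regressors)
    if (bold) {
      out$bold <- purrr::imap(runs, function(tr, r) {
        simulate_bold(tr, regressors[[r]], config,
                      seed = sseed + 10L + as.integer(r), regions = regions)
      })
    }
    out
  })
  structure(list(config = config, regions = regions, subjects = subjects),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d subjects, %d runs x %d trials (+%d nulls), lattice %s\n",
    x$config$n_subjects, x$config$n_runs, x$config$trials_per_run,
    x$config$nulls_per_run, paste(x$config$dim, collapse = "x")))
  invisible(x)
}
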