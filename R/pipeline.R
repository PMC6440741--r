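#' Run the full model-recovery pipeline on a synthetic cohort
#'
#' The end-to-end experiment the package exists to support: simulate a
#' cohort in which disjoint regions are generated by each of the five
#' candidate models, fit all five parametric-modulation GLMs per subject,
#' smooth the log-evidence maps, run voxel-wise random-effects BMS (model
#' level and family level), threshold EP maps into clusters, and extract
#' stimulus-response profiles at subject probability peaks.
#'
#' @param config A [sim_config]; its `seed` drives every stage.
#' @param prior A [glm_prior] for the first-level fits.
#' @param fwhm_mm Evidence-map smoothing FWHM (default 8 mm).
#' @param partition A `family_partition` (default [default_partition]).
#' @param ep_min,k_min EP and cluster-extent thresholds.
#' @param ep_samples Dirichlet samples per voxel for EP maps.
#' @param srp Also fit the ten-level GLM and extract SRPs per generating
#'   region (slower; default TRUE).
#' @param cohort Optionally pass a pre-simulated cohort (must match
#'   `config`).
#' @return A list of class `recovery_run`: `config`, `cohort`,
#'   `subject_maps` (smoothed evidence maps), `ep` (model-level `ep_maps`),
#'   `ep_family` (family-level `ep_maps`), `clusters` (per model),
#'   `region_summary` (tibble: per generating region, the fraction of
#'   voxels won by each model and the family), and, with `srp = TRUE`,
#'   `srp` (per region) and `srp_shapes`.
#' @export
run_recovery_pipeline <- function(config = sim_config(),
                                  prior = glm_prior(),
                                  fwhm_mm = 8,
                                  partition = default_partition(),
                                  ep_min = 0.99, k_min = 50L,
                                  ep_samples = 5000L,
                                  srp = TRUE,
                                  cohort = NULL) {
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  subject_maps <- purrr::map(cohort$subjects, function(s) {
    smooth_evidence_maps(fit_evidence_maps(s, config, prior), fwhm_mm)
  })
  ep <- run_bms_maps(subject_maps, partition = NULL,
                     n_samples = ep_samples, seed = config$seed + 17L)
  ep_family <- run_bms_maps(subject_maps, partition = partition,
                            n_samples = ep_samples, seed = config$seed + 18L)
  clusters <- purrr::map(ep$models, function(m) {
    threshold_ep_map(ep$ep[[m]], ep_min, k_min)
  }) |> rlang::set_names(ep$models)
  region_summary <- summarise_regions(cohort, ep, ep_family, partition)
  out <- list(config = config, cohort = cohort, subject_maps = subject_maps,
              ep = ep, ep_family = ep_family, clusters = clusters,
              region_summary = region_summary, partition = partition)
  if (srp) {
    beta_vols <- purrr::map(cohort$subjects, fit_ten_level_glm,
                            config = config, prior = prior)
    srp_list <- purrr::map(MODEL_NAMES, function(m) {
      mask <- array(FALSE, config$dim)
      mask[cohort$regions[[m]]] <- TRUE
      peaks <- purrr::map_dfr(subject_maps, find_subject_peak,
                              roi_mask = mask, model = m)
      extract_srp(peaks, beta_vols, radius_mm = 4,
                  voxel_mm = config$voxel_size_mm)
    }) |> rlang::set_names(MODEL_NAMES)
    out$srp <- srp_list
    out$srp_shapes <- purrr::map_chr(srp_list, classify_srp_shape)
    out$beta_volumes <- beta_vols
  }
  structure(out, class = "recovery_run")
}

# Per generating region: winner fractions at the model and family level.
summarise_regions <- function(cohort, ep, ep_family, partition) {
  dm <- ep$dim
  models <- ep$models
  ep_mat <- vapply(models, function(m) as.numeric(ep$ep[[m]]),
                   numeric(prod(dm)))
  win_model <- models[max.col(ep_mat, ties.method = "first")]
  fam_mat <- vapply(names(ep_family$family_ep),
                    function(f) as.numeric(ep_family$family_ep[[f]]),
                    numeric(prod(dm)))
  win_family <- names(ep_family$family_ep)[max.col(fam_mat,
                                                   ties.method = "first")]
  model_family <- stats::setNames(
    rep(names(partition), lengths(partition)), unlist(partition))
  purrr::map_dfr(MODEL_NAMES, function(m) {
    idx <- cohort$regions[[m]]
    fam <- model_family[[m]]
    tibble::tibble(
      region = m,
      family = fam,
      n_voxels = length(idx),
      frac_model_won = mean(win_model[idx] == m),
      frac_family_won = mean(win_family[idx] == fam),
      mean_model_ep = mean(ep_mat[idx, match(m, models)]),
      mean_family_ep = mean(fam_mat[idx, match(fam, colnames(fam_mat))])
    )
  })
}

#' @export
print.recovery_run <- function(x, ...) {
  cat("Model-recovery run:", x$config$n_subjects, "subjects, lattice",
      paste(x$config$dim, collapse = "x"), "\n\nRegion summary:\n")
  print(x$region_summary)
  if (!is.null(x$srp_shapes)) {
    cat("\nSRP shape calls:\n")
    print(x$srp_shapes)
  }
  invisible(x)
}

#' Cluster table across models
#'
#' Combines every model's surviving clusters into one tibble, one row per
#' cluster, mirroring the layout of a results table (model, size, peak
#' location, peak EP).
#'
#' @param run A `recovery_run`.
#' @return Tibble with columns `model`, `label`, `size`, `peak_x`,
#'   `peak_y`, `peak_z`, `peak_ep`.
#' @export
cluster_table <- function(run) {
  purrr::imap_dfr(run$clusters, function(cl, m) {
    if (nrow(cl$table) == 0L) return(NULL)
    dplyr::mutate(cl$table, model = m, .before = 1L)
  })
}
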