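# End-to-end synthetic study: generate masks and cohorts, fit the normal
# database, simulate error maps per regime, score the original and
# error-injected data, and evaluate agreement and diagnostic accuracy.

#' Study configuration
#'
#' One object holding every knob of the synthetic end-to-end study. All
#' randomness derives from the single `seed`.
#'
#' @param grid_shape template grid (default 32^3 for a fast study; the full
#'   template proxy is `c(91, 109, 91)`).
#' @param voxel_size_mm voxel edges in mm.
#' @param phantom a [phantom_params()] object (grid fields are overridden
#'   by `grid_shape`/`voxel_size_mm`).
#' @param n_controls normal-database size.
#' @param n_nc,n_ad test-cohort composition.
#' @param age_range simulated age range, years.
#' @param regimes named list of [error_field_params()], one per error
#'   regime to simulate.
#' @param n_maps_per_regime error maps per regime.
#' @param scoring a [scoring_config()]; defaults to pre-normalized scoring
#'   since phantoms are generated directly on the template grid.
#' @param cutoff fixed PET-score decision cutoff.
#' @param boot_reps bootstrap replicates for AUC CIs.
#' @param seed master seed.
#' @return A `study_config` list.
#' @export
study_config <- function(grid_shape = c(32, 32, 32),
                         voxel_size_mm = c(2, 2, 2),
                         phantom = phantom_params(grid_shape, voxel_size_mm),
                         n_controls = 40, n_nc = 40, n_ad = 40,
                         age_range = c(55, 85),
                         regimes = list(
                           ZTE_like = error_field_params("ZTE_like"),
                           Atlas_like = error_field_params("Atlas_like")),
                         n_maps_per_regime = 10,
                         scoring = scoring_config(pre_normalized = TRUE),
                         cutoff = 1, boot_reps = 2000, seed = 1) {
  phantom$grid_shape <- as.integer(grid_shape)
  phantom$voxel_size_mm <- as.numeric(voxel_size_mm)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 phantom = phantom, n_controls = n_controls,
                 n_nc = n_nc, n_ad = n_ad, age_range = age_range,
                 regimes = regimes, n_maps_per_regime = n_maps_per_regime,
                 scoring = scoring, cutoff = cutoff,
                 boot_reps = boot_reps, seed = seed),
            class = "study_config")
}

#' Run the full synthetic study
#'
#' Generates masks, a normal-control database cohort and a test cohort,
#' fits the voxelwise age regression, simulates and conditions error maps
#' for each regime, scores every (subject x error map) combination plus
#' the originals, and evaluates score differences, per-subject agreement
#' and diagnostic accuracy per series. When `outdir` is given, writes
#' `score_table.csv`, `metrics.json` and a `manifest.json` listing every
#' output file together with the seed.
#'
#' @param config a [study_config()].
#' @param outdir optional output directory (created if missing).
#' @return list with `score_table`, `diff_stats`, `per_subject`,
#'   `agreement` (per method: regression + Bland-Altman on per-subject
#'   means), `diagnostics` (per series incl. original), `config`.
#' @export
run_end_to_end <- function(config = study_config(), outdir = NULL) {
  stopifnot(inherits(config, "study_config"))
  seeds <- with_seed(config$seed, sample.int(2^31 - 1, 4 + length(config$regimes)))
  masks <- make_template_masks(config$grid_shape, config$voxel_size_mm)

  controls <- simulate_cohort(config$phantom, masks, n_nc = config$n_controls,
                              n_ad = 0, age_range = config$age_range,
                              seed = seeds[1], id_prefix = "C")
  db <- fit_age_regression(controls, masks, config$scoring)

  cht <- simulate_cohort(config$phantom, masks, n_nc = config$n_nc,
                         n_ad = config$n_ad, age_range = config$age_range,
                         seed = seeds[2], id_prefix = "S")

  maps <- list()
  for (i in seq_along(config$regimes)) {
    raw <- simulate_error_maps(config$regimes[[i]], masks$brain,
                               n_maps = config$n_maps_per_regime,
                               voxel_size_mm = config$voxel_size_mm,
                               seed = seeds[4 + i - 1])
    maps <- c(maps, lapply(raw, condition_error_map, brain = masks$brain,
                           fwhm_mm = config$scoring$fwhm_mm))
  }

  tab <- run_simulation(cht, maps, db, masks, config$scoring)

  diff_stats <- score_difference_stats(tab)
  sim <- tab[tab$method != "original", ]
  orig <- tab[tab$method == "original", ]
  per_subj <- per_subject_average(sim)

  agreement <- lapply(split(per_subj, per_subj$method), function(ps) {
    x <- orig$pet_score[match(ps$subject_id, orig$subject_id)]
    c(regression_agreement(x, ps$mean_score), bland_altman(x, ps$mean_score))
  })

  series <- c(list(original = orig), split(sim, sim$method))
  diagnostics <- lapply(series, function(s)
    diagnostic_report(s$pet_score, s$diagnosis, cutoff = config$cutoff,
                      boot_reps = config$boot_reps, seed = seeds[3]))

  result <- list(score_table = tab, diff_stats = diff_stats,
                 per_subject = per_subj, agreement = agreement,
                 diagnostics = diagnostics, config = config)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    p <- file.path(outdir, "score_table.csv")
    write_score_table(tab, p); files <- c(files, p)
    p <- file.path(outdir, "diff_stats.csv")
    utils::write.csv(diff_stats, p, row.names = FALSE); files <- c(files, p)
    metrics <- list(diff_stats = diff_stats, agreement = agreement,
                    diagnostics = lapply(diagnostics, function(d)
                      d[c("at_cutoff", "at_youden")] |>
                        c(list(roc = d$roc[c("auc", "auc_ci_low", "auc_ci_high",
                                             "youden_cutoff", "youden_index")]))))
    p <- file.path(outdir, "metrics.json")
    jsonlite::write_json(metrics, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, p)
    jsonlite::write_json(list(seed = config$seed, files = basename(files)),
                         file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}
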