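# Shared small fixtures: everything is generated in code, nothing on disk.

tiny_masks <- function(grid = c(16, 16, 16)) make_template_masks(grid)

# random small brain_volume with positive values
rand_volume <- function(d = c(6, 6, 6), lo = 0.5, hi = 1.5) {
  brain_volume(array(stats::runif(prod(d), lo, hi), d))
}

# a small noise-free phantom setup with its fitted normal database
tiny_study <- function(grid = c(16, 16, 16), noise = 0, n_controls = 6,
                       seed = 42) {
  masks <- make_template_masks(grid)
  params <- phantom_params(grid_shape = grid, subject_noise_sd = noise)
  controls <- simulate_cohort(params, masks, n_nc = n_controls, n_ad = 0,
                              seed = seed, id_prefix = "C")
  cfg <- scoring_config(pre_normalized = TRUE)
  db <- fit_age_regression(controls, masks, cfg)
  list(masks = masks, params = params, controls = controls, db = db,
       cfg = cfg)
}
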