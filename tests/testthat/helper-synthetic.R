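# Compact synthetic configurations for tests: same generative structure as
# the full assay (3 strains, 2 biological repeats, 3 trials) but fewer
# wells, fewer stages and shortened phases so suites stay fast.

tiny_config <- function(...) {
  defaults <- list(stages = c(4, 6),
                   stage_mult = c(`4` = 0.85, `6` = 1.1),
                   stage_resp = c(`4` = 0.6, `6` = 1.0),
                   rows = 2, cols = 3,
                   recorded_dark_s = 40, phase_len_s = 40, n_trials = 3)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

# Single-strain, single-stage config used for null / calibration studies.
flat_config <- function(n_animals = 100, pre_s = 35, post_s = 35, rho = 0.5,
                        innovation_sd = 0.03, ...) {
  synthetic_config(strains = list(WT = list(baseline = 0.3, resp_mod = 0)),
                   stages = 6, stage_mult = c(`6` = 1), stage_resp = c(`6` = 1),
                   rows = 1, cols = n_animals, n_bio_rep = 1,
                   bio_rep_sd = 0, tech_rep_sd = 0, location_coef = 0,
                   ar1_rho = rho, innovation_sd = innovation_sd,
                   recorded_dark_s = pre_s, phase_len_s = post_s, n_trials = 1,
                   ...)
}

tiny_windows <- function(seed = 1, ...) {
  sim <- generate_plate_experiment(tiny_config(...), seed = seed)
  extract_windows(sim$activity, sim$schedule)
}
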