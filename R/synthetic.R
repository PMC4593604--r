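#' Configuration of the synthetic VMR plate generator
#'
#' Describes a generative model of a plate-based visual motor response
#' experiment with the statistical structure the package's analyses assume:
#' strains with distinct baseline activity and response amplitudes,
#' developmental stages (dpf) scaling both, a radial well-location
#' illumination gradient, biological- and technical-repeat offsets, an
#' exponential-decay-to-plateau response kernel per stimulus type, and
#' temporally correlated within-animal noise (animal-level random intercept
#' plus an AR(1) process).
#'
#' The default schedule mirrors the standard assay: a dark-adaptation
#' period of which the last 30 min are recorded, then three consecutive
#' 30-min Light-On / 30-min Light-Off trials, sampled at 30 frames/s.
#' The default location gradient is 0 (uniform illumination); set
#' \code{location_coef} to induce a center-bright radial effect.
#'
#' @param strains named list: per-strain \code{baseline} movement rate
#'   (Burst Duration units) and \code{resp_mod} response-amplitude
#'   multiplier.
#' @param stages integer dpf vector.
#' @param stage_mult named numeric: per-stage multiplier on baseline rate.
#' @param stage_resp named numeric: per-stage multiplier on response
#'   amplitude (young larvae respond weakly).
#' @param rows,cols plate layout (default 8 x 12 = 96 wells).
#' @param location_coef radial gradient coefficient: rate offset =
#'   \code{location_coef * (1 - d)} with d the well's normalized distance
#'   from plate center (0 = center). Default 0.
#' @param n_bio_rep number of biological repeats.
#' @param bio_rep_sd,tech_rep_sd SDs of the per-repeat and per-trial rate
#'   offsets.
#' @param kernel_on,kernel_off stimulus response kernels, each
#'   \code{list(peak, decay, sustained)}: the noise-free response at
#'   relative second t >= 1 after the event is
#'   \code{peak * exp(-decay * (t - 1)) + sustained} above baseline,
#'   lasting until the next event.
#' @param animal_sd SD of the per-animal random intercept.
#' @param ar1_rho,innovation_sd AR(1) coefficient (in (-1, 1)) and
#'   innovation SD of the within-animal second-to-second noise.
#' @param obs_sd extra white observation noise added in second mode.
#' @param fps frames per second.
#' @param recorded_dark_s recorded dark seconds before the first onset.
#' @param n_trials number of On/Off trials.
#' @param phase_len_s length of each On and each Off phase, seconds.
#' @param clamp clamp latent rates into [0, 1] (default TRUE). Disable only
#'   for Gaussian power validation, where clamping would distort the
#'   nominal (mu, Sigma); a warning reports the out-of-range fraction.
#' @return list of class \code{vmr_config}.
#' @export
synthetic_config <- function(
    strains = list(AB   = list(baseline = 0.14, resp_mod = 1.0),
                   TL   = list(baseline = 0.12, resp_mod = 0.9),
                   TLAB = list(baseline = 0.10, resp_mod = 0.8)),
    stages = 3:9,
    stage_mult = stats::setNames(seq(0.7, 1.3, length.out = length(stages)),
                                 stages),
    stage_resp = stats::setNames(c(0.2, 0.6, 0.9, 1.0, 1.1, 1.15, 1.2)[
      seq_along(stages)], stages),
    rows = 8, cols = 12,
    location_coef = 0,
    n_bio_rep = 2, bio_rep_sd = 0.01, tech_rep_sd = 0.01,
    kernel_on = list(peak = 0.25, decay = 0.15, sustained = 0.05),
    kernel_off = list(peak = 0.45, decay = 0.8, sustained = 0.15),
    animal_sd = 0.02, ar1_rho = 0.5, innovation_sd = 0.03, obs_sd = 0,
    fps = 30,
    recorded_dark_s = 1800, n_trials = 3, phase_len_s = 1800,
    clamp = TRUE) {
  if (abs(ar1_rho) >= 1) vmr_abort("ar1_rho must lie in (-1, 1)", "vmr_validation_error")
  if (!is_count(fps)) vmr_abort("fps must be a positive integer", "vmr_validation_error")
  cfg <- list(strains = strains, stages = stages,
              stage_mult = stage_mult, stage_resp = stage_resp,
              rows = rows, cols = cols, location_coef = location_coef,
              n_bio_rep = n_bio_rep, bio_rep_sd = bio_rep_sd,
              tech_rep_sd = tech_rep_sd,
              kernel_on = kernel_on, kernel_off = kernel_off,
              animal_sd = animal_sd, ar1_rho = ar1_rho,
              innovation_sd = innovation_sd, obs_sd = obs_sd, fps = fps,
              recorded_dark_s = recorded_dark_s, n_trials = n_trials,
              phase_len_s = phase_len_s, clamp = clamp)
  class(cfg) <- "vmr_config"
  cfg
}

# Schedule implied by a config: On/Off events in recorded experiment time.
config_schedule <- function(config) {
  ev <- list()
  for (i in seq_len(config$n_trials)) {
    on_t <- config$recorded_dark_s + (i - 1) * 2 * config$phase_len_s
    ev[[length(ev) + 1L]] <- data.frame(event_time_s = on_t, transition = "on",
                                        trial_index = i)
    ev[[length(ev) + 1L]] <- data.frame(event_time_s = on_t + config$phase_len_s,
                                        transition = "off", trial_index = i)
  }
  stimulus_schedule(do.call(rbind, ev))
}

well_labels <- function(rows, cols) {
  as.vector(outer(LETTERS[seq_len(rows)], seq_len(cols), paste0))
}

# Normalized distance from plate center per well, in [0, 1].
well_center_distance <- function(rows, cols) {
  r <- rep(seq_len(rows), times = cols)
  c <- rep(seq_len(cols), each = rows)
  dr <- if (rows > 1) (r - (rows + 1) / 2) / ((rows - 1) / 2) else rep(0, length(r))
  dc <- if (cols > 1) (c - (cols + 1) / 2) / ((cols - 1) / 2) else rep(0, length(c))
  d <- sqrt(dr^2 + dc^2) / sqrt(2)
  stats::setNames(d, well_labels(rows, cols))
}

# Deterministic noise-free kernel contribution over recorded seconds 1..N.
kernel_profile <- function(config, schedule, n_seconds, amp_mod = 1) {
  k <- numeric(n_seconds)
  ev <- rbind(schedule, data.frame(event_time_s = n_seconds, transition = "end",
                                   trial_index = NA))
  for (i in seq_len(nrow(schedule))) {
    E <- schedule$event_time_s[i]
    kern <- if (schedule$transition[i] == "on") config$kernel_on else config$kernel_off
    upto <- min(ev$event_time_s[i + 1], n_seconds)
    if (upto <= E) next
    t_rel <- seq_len(upto - E)  # relative seconds 1..
    k[E + t_rel] <- amp_mod * (kern$peak * exp(-kern$decay * (t_rel - 1)) +
                                 kern$sustained)
  }
  k
}

#' Generate a synthetic VMR plate experiment
#'
#' Draws, for every animal a and recorded second t, a latent movement rate
#' \deqn{r(a,t) = \mathrm{clamp}_{[0,1]}(b_{strain} m_{stage} + loc(well) +
#'   \beta_{bio} + \gamma_{trial} + u_a + kernel(t) + \epsilon(a,t))}
#' with \eqn{u_a} an animal random intercept and \eqn{\epsilon} a
#' stationary AR(1) process. In \code{"second"} mode the observed Burst
#' Duration is r plus optional clamped Gaussian observation noise; in
#' \code{"frame"} mode, \code{fps} independent movement indicators are
#' drawn per second with probability r (so Burst Duration is
#' Binomial(fps, r)/fps) and a frame-level table is returned, exercising
#' \code{\link{summarize_burst_duration}} end to end.
#'
#' One plate is generated per (strain, biological repeat, stage)
#' combination. Randomness uses one root seed with per-animal counter
#' substreams, so adding animals or plates never perturbs the draws of
#' existing ones; a fixed seed gives bitwise-identical output.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param seed integer root seed.
#' @param mode \code{"second"} (default) or \code{"frame"}.
#' @return list of class \code{vmr_sim}: \code{activity} (second mode) or
#'   \code{frames} (frame mode), \code{metadata} (per-animal factors),
#'   \code{schedule}, \code{config}, \code{clamp_fraction}.
#' @export
generate_plate_experiment <- function(config, seed = 1,
                                      mode = c("second", "frame")) {
  mode <- match.arg(mode)
  schedule <- config_schedule(config)
  n_sec <- config$recorded_dark_s + 2 * config$n_trials * config$phase_len_s
  wells <- well_labels(config$rows, config$cols)
  loc_off <- config$location_coef * (1 - well_center_distance(config$rows, config$cols))

  set.seed(derive_seed(seed, 0))
  bio_off <- stats::rnorm(config$n_bio_rep, 0, config$bio_rep_sd)
  tech_off <- stats::rnorm(config$n_trials, 0, config$tech_rep_sd)

  # per-trial offset applies from that trial's onset up to the next trial
  trial_of_second <- findInterval(seq_len(n_sec) - 1L,
                                  schedule$event_time_s[schedule$transition == "on"])
  tech_vec <- ifelse(trial_of_second >= 1, tech_off[pmax(trial_of_second, 1)], 0)

  combos <- expand.grid(strain = names(config$strains),
                        bio_rep = seq_len(config$n_bio_rep),
                        stage_dpf = config$stages,
                        stringsAsFactors = FALSE)
  n_wells <- length(wells)
  n_animals <- nrow(combos) * n_wells
  values <- vector("list", n_animals)  # per-animal activity (or moved) vectors
  meta_id <- character(n_animals); meta_strain <- character(n_animals)
  meta_stage <- integer(n_animals); meta_well <- character(n_animals)
  meta_bio <- integer(n_animals); meta_plate <- character(n_animals)
  counter <- 0L
  n_clamped <- 0; n_rates <- 0
  sd0 <- config$innovation_sd / sqrt(1 - config$ar1_rho^2)
  for (ci in seq_len(nrow(combos))) {
    strain <- combos$strain[ci]
    stage <- as.character(combos$stage_dpf[ci])
    plate_id <- sprintf("P_%s_b%d_d%s", strain, combos$bio_rep[ci], stage)
    base <- config$strains[[strain]]$baseline * config$stage_mult[[stage]] +
      bio_off[combos$bio_rep[ci]]
    amp <- config$strains[[strain]]$resp_mod * config$stage_resp[[stage]]
    kprof <- kernel_profile(config, schedule, n_sec, amp)
    for (w in seq_len(n_wells)) {
      counter <- counter + 1L
      set.seed(derive_seed(seed, counter))
      u_a <- stats::rnorm(1, 0, config$animal_sd)
      innov <- stats::rnorm(n_sec, 0, config$innovation_sd)
      eps0 <- stats::rnorm(1, 0, sd0)
      eps <- as.numeric(stats::filter(innov, config$ar1_rho, method = "recursive",
                                      init = eps0))
      r <- base + loc_off[w] + u_a + kprof + tech_vec + eps
      n_rates <- n_rates + n_sec
      n_clamped <- n_clamped + sum(r < 0 | r > 1)
      if (config$clamp) r <- clamp01(r)
      if (mode == "second") {
        act <- r
        if (config$obs_sd > 0) {
          act <- act + stats::rnorm(n_sec, 0, config$obs_sd)
          if (config$clamp) act <- clamp01(act)
        }
        values[[counter]] <- act
      } else {
        values[[counter]] <- stats::rbinom(n_sec * config$fps, 1,
                                           rep(clamp01(r), each = config$fps))
      }
      meta_id[counter] <- sprintf("%s_w%s", plate_id, wells[w])
      meta_strain[counter] <- strain
      meta_stage[counter] <- combos$stage_dpf[ci]
      meta_well[counter] <- wells[w]
      meta_bio[counter] <- combos$bio_rep[ci]
      meta_plate[counter] <- plate_id
    }
  }
  clamp_fraction <- n_clamped / n_rates
  if (clamp_fraction > 0.01) {
    vmr_warn(sprintf("%.1f%% of latent rates fell outside [0, 1] before clamping (%d of %d)",
                     100 * clamp_fraction, n_clamped, n_rates), "vmr_clamp_warning")
  }
  metadata <- data.frame(animal_id = meta_id, strain = meta_strain,
                         stage_dpf = meta_stage, well = meta_well,
                         bio_rep = meta_bio, plate_id = meta_plate)
  out <- list(metadata = metadata, schedule = schedule, config = config,
              clamp_fraction = clamp_fraction)
  if (mode == "second") {
    act <- data.frame(animal_id = rep(meta_id, each = n_sec),
                      strain = rep(meta_strain, each = n_sec),
                      stage_dpf = rep(meta_stage, each = n_sec),
                      well = rep(meta_well, each = n_sec),
                      bio_rep = rep(meta_bio, each = n_sec),
                      plate_id = rep(meta_plate, each = n_sec),
                      second = rep.int(seq_len(n_sec), n_animals),
                      activity = unlist(values, use.names = FALSE))
    out$activity <- activity_matrix(act)
  } else {
    frames <- data.frame(animal_id = rep(meta_id, each = n_sec * config$fps),
                         frame_index = rep.int(seq.int(0L, n_sec * config$fps - 1L),
                                               n_animals),
                         moved = unlist(values, use.names = FALSE))
    out$frames <- frame_table(frames, fps = config$fps)
  }
  class(out) <- "vmr_sim"
  out
}

#' @export
print.vmr_sim <- function(x, ...) {
  cat(sprintf("Synthetic VMR experiment: %d animals, %d events, clamp fraction %.3g\n",
              nrow(x$metadata), nrow(x$schedule), x$clamp_fraction))
  invisible(x)
}

#' Null version of a synthetic experiment
#'
#' Same generator with every group-difference effect zeroed: all strains
#' share one baseline and response amplitude, all stage multipliers are 1,
#' the location gradient and repeat offsets are 0. Animal-level intercepts,
#' the AR(1) noise and the common stimulus kernel remain, so the data are
#' exchangeable across strains, stages, wells and repeats — the reference
#' condition for type-I-error studies.
#'
#' @inheritParams generate_plate_experiment
#' @export
null_experiment <- function(config, seed = 1, mode = c("second", "frame")) {
  mean_base <- mean(vapply(config$strains, function(s) s$baseline, numeric(1)))
  config$strains <- lapply(config$strains, function(s) {
    list(baseline = mean_base, resp_mod = 1)
  })
  config$stage_mult[] <- 1
  config$stage_resp[] <- 1
  config$location_coef <- 0
  config$bio_rep_sd <- 0
  config$tech_rep_sd <- 0
  generate_plate_experiment(config, seed = seed, mode = mode)
}

#' Empirical versus analytic power of the Hotelling test
#'
#' For each per-group sample size in \code{n_grid}, draws \code{reps}
#' pairs of Gaussian samples with the given means and common covariance,
#' runs \code{\link{hotelling_t2}} on each, and tabulates the empirical
#' rejection rate at level \code{alpha} next to the analytic
#' \code{\link{power_from_ncp}} value.
#'
#' @param mu1,mu2 population mean vectors.
#' @param sigma common covariance (positive definite).
#' @param n_grid per-group sample sizes.
#' @param reps Monte-Carlo replicates per grid point.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return data.frame: \code{n, analytic, empirical, mc_se, discrepancy}.
#' @export
power_recovery_study <- function(mu1, mu2, sigma, n_grid, reps = 1000,
                                 alpha = 0.05, seed = 1) {
  p <- length(mu1)
  rows <- list()
  for (i in seq_along(n_grid)) {
    n <- n_grid[i]
    ncp <- noncentrality(mu1, mu2, sigma, n, n)
    analytic <- power_from_ncp(p, n, n, ncp, alpha)
    set.seed(derive_seed(seed, i))
    rej <- 0L
    for (r in seq_len(reps)) {
      X1 <- MASS::mvrnorm(n, mu1, sigma)
      X2 <- MASS::mvrnorm(n, mu2, sigma)
      if (hotelling_t2(X1, X2)$p_value < alpha) rej <- rej + 1L
    }
    emp <- rej / reps
    rows[[i]] <- data.frame(n = n, analytic = analytic, empirical = emp,
                            mc_se = sqrt(analytic * (1 - analytic) / reps),
                            discrepancy = emp - analytic)
  }
  do.call(rbind, rows)
}
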