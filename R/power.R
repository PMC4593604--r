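#' Noncentrality parameter of the two-sample Hotelling test
#'
#' \deqn{\tau^2 = \frac{n_1 n_2}{n_1 + n_2}
#'   (\mu^{(1)} - \mu^{(2)})' \Sigma^{-1} (\mu^{(1)} - \mu^{(2)})}
#' Power analysis requires a proper (positive definite) population
#' covariance, so no ridge option is offered here.
#'
#' @param mu1,mu2 population mean vectors (same length p).
#' @param sigma p x p symmetric positive definite covariance.
#' @param n1,n2 group sizes.
#' @return the noncentrality parameter (non-negative scalar).
#' @export
noncentrality <- function(mu1, mu2, sigma, n1, n2) {
  if (length(mu1) != length(mu2)) {
    vmr_abort("mean vectors must have the same length", "vmr_validation_error")
  }
  sigma <- as.matrix(sigma)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= .Machine$double.eps * max(ev)) {
    vmr_abort("sigma must be positive definite for power analysis",
              "vmr_singular_covariance")
  }
  d <- mu1 - mu2
  as.numeric((n1 * n2 / (n1 + n2)) * crossprod(d, solve(sigma, d)))
}

#' Power of the Hotelling T-squared test from its noncentrality
#'
#' Power = \eqn{P(F_{p, n_1+n_2-p-1, \tau^2} \ge F_{p, n_1+n_2-p-1, \alpha})},
#' the upper tail of the noncentral F distribution at the central-F critical
#' value. Equals \code{alpha} exactly when \code{ncp = 0}.
#'
#' @param p_dim response dimension (length of the activity window, seconds).
#' @param n1,n2 group sizes.
#' @param ncp noncentrality parameter \eqn{\tau^2 \ge 0}.
#' @param alpha significance level in (0, 1).
#' @return power in [alpha, 1).
#' @export
power_from_ncp <- function(p_dim, n1, n2, ncp, alpha = 0.05) {
  df2 <- n1 + n2 - p_dim - 1
  if (df2 < 1 || p_dim < 1) vmr_abort("invalid degrees of freedom", "vmr_validation_error")
  if (ncp < 0) vmr_abort("noncentrality must be non-negative", "vmr_validation_error")
  if (alpha <= 0 || alpha >= 1) vmr_abort("alpha must lie in (0, 1)", "vmr_validation_error")
  crit <- stats::qf(1 - alpha, p_dim, df2)
  if (ncp == 0) return(alpha)  # exact null calibration, avoids ncp=0 code path
  stats::pf(crit, p_dim, df2, ncp = ncp, lower.tail = FALSE)
}

# tau^2 implied by an effect size Delta for equal groups of size n.
# "distance": Delta is the Mahalanobis distance, tau^2 = (n/2) * Delta^2.
# "quadratic": Delta is already the quadratic form, tau^2 = (n/2) * Delta.
ncp_from_effect <- function(n, delta, parametrization) {
  switch(parametrization,
         distance = (n / 2) * delta^2,
         quadratic = (n / 2) * delta,
         vmr_abort("parametrization must be 'distance' or 'quadratic'",
                   "vmr_validation_error"))
}

#' Minimal per-group sample size for a target power
#'
#' Smallest integer n (equal group sizes, n >= p_dim + 2) whose Hotelling
#' T-squared power reaches \code{power_target}. The search is an exact
#' integer scan upward from p_dim + 2: each power evaluation is cheap and a
#' scan cannot skip the minimal n.
#'
#' The effect size Delta is interpreted, by default, as the Mahalanobis
#' distance between the mean vectors, giving
#' \eqn{\tau^2 = (n/2) \Delta^2}; with
#' \code{parametrization = "quadratic"}, Delta is taken as the quadratic
#' form \eqn{(\mu^{(1)}-\mu^{(2)})' \Sigma^{-1} (\mu^{(1)}-\mu^{(2)})}
#' itself, giving \eqn{\tau^2 = (n/2) \Delta}. See the methods vignette for
#' why "distance" is the default.
#'
#' @param effect_size Delta > 0.
#' @param p_dim response dimension.
#' @param power_target target power in (alpha, 1).
#' @param alpha significance level.
#' @param parametrization \code{"distance"} (default) or
#'   \code{"quadratic"}.
#' @param n_max upper search bound (default 1e6).
#' @return the minimal n per group (integer).
#' @export
min_sample_size <- function(effect_size, p_dim, power_target = 0.8,
                            alpha = 0.05, parametrization = c("distance", "quadratic"),
                            n_max = 1e6) {
  parametrization <- match.arg(parametrization)
  if (effect_size <= 0) vmr_abort("effect size must be positive", "vmr_validation_error")
  if (power_target <= alpha || power_target >= 1) {
    vmr_abort("power target must lie in (alpha, 1)", "vmr_validation_error")
  }
  for (n in seq.int(p_dim + 2L, n_max)) {
    pow <- power_from_ncp(p_dim, n, n, ncp_from_effect(n, effect_size, parametrization),
                          alpha)
    if (pow >= power_target) return(as.integer(n))
  }
  vmr_abort(sprintf("no n <= %g reaches power %.3f", n_max, power_target),
            "vmr_no_solution")
}

#' Power curves over sample size or window length
#'
#' \code{power_curve} tabulates power over a grid of per-group sample sizes
#' at fixed effect size; \code{sample_size_curve} tabulates the minimal n
#' over a grid of window lengths (response dimensions) for one or more
#' effect sizes at fixed target power.
#'
#' @param p_dim response dimension.
#' @param effect_size Delta (scalar for \code{power_curve}; vector allowed
#'   in \code{sample_size_curve}).
#' @param n_grid integer grid of per-group sample sizes.
#' @param alpha significance level.
#' @param parametrization see \code{\link{min_sample_size}}.
#' @return \code{power_curve}: data.frame \code{n, power};
#'   \code{sample_size_curve}: data.frame \code{p_dim, effect_size, n}.
#' @export
power_curve <- function(p_dim, effect_size, n_grid = 16:100, alpha = 0.05,
                        parametrization = c("distance", "quadratic")) {
  parametrization <- match.arg(parametrization)
  n_grid <- n_grid[n_grid >= p_dim + 2]
  pow <- vapply(n_grid, function(n) {
    power_from_ncp(p_dim, n, n, ncp_from_effect(n, effect_size, parametrization), alpha)
  }, numeric(1))
  out <- data.frame(n = n_grid, power = pow)
  attr(out, "params") <- list(p_dim = p_dim, effect_size = effect_size,
                              alpha = alpha, parametrization = parametrization)
  out
}

#' @rdname power_curve
#' @param p_grid integer grid of window lengths (dimensions).
#' @param power_target target power for the sample-size solve.
#' @export
sample_size_curve <- function(p_grid = 2:100, effect_size = c(0.5, 0.6, 0.7, 0.8),
                              power_target = 0.8, alpha = 0.05,
                              parametrization = c("distance", "quadratic")) {
  parametrization <- match.arg(parametrization)
  grid <- expand.grid(p_dim = p_grid, effect_size = effect_size)
  grid$n <- mapply(function(p, d) {
    min_sample_size(d, p, power_target, alpha, parametrization)
  }, grid$p_dim, grid$effect_size)
  grid
}

#' AR(1) covariance matrix
#'
#' \eqn{\Sigma_{ij} = sd^2 \rho^{|i-j|}}: the default self-contained stand-in
#' for the within-window covariance of per-second activity, whose strongest
#' feature in real recordings is short-lag temporal correlation. This is a
#' synthetic default, not an estimate from any experimental dataset.
#'
#' @param p dimension.
#' @param rho lag-1 autocorrelation in (-1, 1).
#' @param sd marginal standard deviation.
#' @export
ar1_covariance <- function(p, rho = 0.5, sd = 1) {
  if (abs(rho) >= 1) vmr_abort("rho must lie in (-1, 1)", "vmr_validation_error")
  sd^2 * rho^abs(outer(seq_len(p), seq_len(p), "-"))
}

#' Analytic power for simulation scenarios with uniform mean profiles
#'
#' Each scenario draws the two population mean vectors elementwise from
#' stated uniform distributions (e.g. group 1 from U(0.1, 0.125) and group 2
#' from U(0.1251, 0.15) for small non-overlapping profiles), computes the
#' noncentrality against the supplied covariance, and tabulates analytic
#' power across a grid of per-group sample sizes. The covariance is a
#' required input: in the original use the population covariance is
#' estimated from experimental data, and \code{\link{ar1_covariance}} is
#' offered as a self-contained default that is not such an estimate.
#'
#' @param scenarios list of scenarios; each a list with \code{name},
#'   \code{bounds1 = c(a, b)} and \code{bounds2 = c(a, b)}.
#' @param sigma p x p positive definite covariance; its dimension sets the
#'   profile length.
#' @param n_grid grid of per-group sample sizes.
#' @param alpha significance level.
#' @param seed integer seed for the uniform mean draws.
#' @return data.frame \code{scenario, n, ncp, power}; one mean-vector draw
#'   per scenario (fixed by \code{seed}).
#' @export
simulate_power_scenarios <- function(scenarios, sigma, n_grid = 16:100,
                                     alpha = 0.05, seed = 1) {
  sigma <- as.matrix(sigma)
  p <- ncol(sigma)
  rows <- list()
  set.seed(seed)
  for (sc in scenarios) {
    for (b in c("bounds1", "bounds2")) {
      if (sc[[b]][1] >= sc[[b]][2]) {
        vmr_abort(sprintf("scenario '%s': %s must satisfy a < b", sc$name, b),
                  "vmr_bounds_error")
      }
    }
    mu1 <- stats::runif(p, sc$bounds1[1], sc$bounds1[2])
    mu2 <- stats::runif(p, sc$bounds2[1], sc$bounds2[2])
    for (n in n_grid) {
      ncp <- noncentrality(mu1, mu2, sigma, n, n)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc$name, n = n, ncp = ncp,
        power = power_from_ncp(p, n, n, ncp, alpha))
    }
  }
  do.call(rbind, rows)
}
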