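#' Standard deviation from a 95% confidence interval
#'
#' Reconstructs the standard deviation of a normally distributed estimate
#' from its 95% CI: `(upper - lower) / (2 * 1.959964)`. Isolated here so a
#' different reconstruction can be swapped in.
#'
#' @param lower,upper CI bounds, `upper > lower`.
#' @return Standard deviation on the parameter's scale.
#' @export
#' @examples
#' sd_from_ci(0.43, 0.84)
sd_from_ci <- function(lower, upper) {
  if (any(upper <= lower)) stop("upper must exceed lower", call. = FALSE)
  (upper - lower) / (2 * stats::qnorm(0.975))
}

#' Beta distribution from a mean and standard deviation
#'
#' Method-of-moments fit, used for probabilities, relative risks and
#' utilities (all restricted to `[0, 1]`):
#' `alpha = mean * (mean * (1 - mean) / sd^2 - 1)`,
#' `beta = alpha * (1 - mean) / mean`.
#'
#' @param mean Target mean, in `(0, 1)`.
#' @param sd Target standard deviation; requires `sd^2 < mean * (1 - mean)`.
#' @return A distribution spec: list with `family = "beta"`, `shape1`,
#'   `shape2`.
#' @export
#' @examples
#' beta_params_from_mean_sd(0.60, sd_from_ci(0.43, 0.84))
beta_params_from_mean_sd <- function(mean, sd) {
  if (mean <= 0 || mean >= 1)
    stop("mean must lie strictly in (0, 1)", call. = FALSE)
  if (sd <= 0) stop("sd must be > 0", call. = FALSE)
  if (sd^2 >= mean * (1 - mean))
    stop("variance too large for a beta distribution", call. = FALSE)
  nu <- mean * (1 - mean) / sd^2 - 1
  alpha <- mean * nu
  list(family = "beta", shape1 = alpha, shape2 = alpha * (1 - mean) / mean)
}

#' Gamma distribution from a mean and standard deviation
#'
#' Method-of-moments fit, used for cost parameters (positive support):
#' `shape = mean^2 / sd^2`, `scale = sd^2 / mean`.
#'
#' @param mean Target mean (> 0).
#' @param sd Target standard deviation (> 0).
#' @return A distribution spec: list with `family = "gamma"`, `shape`,
#'   `scale`.
#' @export
gamma_params_from_mean_sd <- function(mean, sd) {
  if (mean <= 0 || sd <= 0)
    stop("mean and sd must be > 0", call. = FALSE)
  list(family = "gamma", shape = mean^2 / sd^2, scale = sd^2 / mean)
}

#' Dirichlet distribution for the initial health-state mix
#'
#' The distribution of albuminuria states at diagnosis has three outcomes,
#' so its uncertainty is represented by a Dirichlet with concentrations
#' `ess * prevalences`, where `ess` plays the role of an effective sample
#' size.
#'
#' @param prevalences Probability vector summing to 1.
#' @param ess Effective sample size (> 0); default 100.
#' @return A distribution spec: list with `family = "dirichlet"`, `alpha`.
#' @export
dirichlet_spec <- function(prevalences, ess = 100) {
  if (abs(sum(prevalences) - 1) > 1e-9 || any(prevalences < 0))
    stop("prevalences must be a probability vector summing to 1",
         call. = FALSE)
  if (ess <= 0) stop("ess must be > 0", call. = FALSE)
  list(family = "dirichlet", alpha = ess * prevalences)
}

# One Dirichlet draw via normalised gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Sampling distributions for the probabilistic sensitivity analysis
#'
#' Builds one distribution spec per sampled parameter from the base-case
#' means and published ranges: initial prevalences follow a Dirichlet;
#' transition probabilities, relative risks, utilities and the ARB share
#' follow betas; the ESRD state cost and the SMR (a positive ratio) follow
#' gammas. Standard deviations come from [sd_from_ci()] on the published
#' range. Parameters whose base-case mean sits on the beta boundary
#' (treatment utility multiplier and test specificity, both 1.00) cannot
#' carry a beta and are held fixed; the drug-cost range is a deterministic
#' scenario and discount rates are varied deterministically only, so
#' neither is sampled.
#'
#' @param ps A `nephro_params` object.
#' @param ranges A data frame like [default_ranges()].
#' @param ess Dirichlet effective sample size (default 100).
#' @return A named list of distribution specs (including the `prev` Dirichlet).
#' @export
psa_distributions <- function(ps, ranges = default_ranges(), ess = 100) {
  beta_params <- c("q_nm", "q_mM", "q_ME", "rr_nm", "rr_mM", "rr_ME",
                   "u_diabetes", "u_esrd", "arb_rate")
  gamma_params <- c("c_esrd_override", "smr")
  specs <- list(
    prev = dirichlet_spec(c(ps$prev_normo, ps$prev_micro, ps$prev_macro),
                          ess)
  )
  for (i in seq_len(nrow(ranges))) {
    nm <- ranges$name[i]
    if (!(nm %in% c(beta_params, gamma_params))) next
    s <- sd_from_ci(ranges$low[i], ranges$high[i])
    specs[[nm]] <- if (nm %in% beta_params)
      beta_params_from_mean_sd(ps[[nm]], s)
    else
      gamma_params_from_mean_sd(ps[[nm]], s)
  }
  specs
}

# Draw one value from a spec
draw_spec <- function(spec) {
  switch(spec$family,
    beta = stats::rbeta(1, spec$shape1, spec$shape2),
    gamma = stats::rgamma(1, shape = spec$shape, scale = spec$scale),
    dirichlet = rdirichlet1(spec$alpha),
    fixed = spec$value,
    stop("unknown distribution family: ", spec$family, call. = FALSE)
  )
}

# One sampled parameter set (uses set_parameter so the ARB-rate/drug-cost
# coupling is applied)
sample_parameter_set <- function(ps, specs) {
  ps2 <- ps
  if (!is.null(specs$prev)) {
    prev <- draw_spec(specs$prev)
    ps2$prev_normo <- prev[1]
    ps2$prev_micro <- prev[2]
    ps2$prev_macro <- prev[3]
  }
  for (nm in setdiff(names(specs), "prev")) {
    ps2 <- set_parameter(ps2, nm, draw_spec(specs[[nm]]))
  }
  ps2
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: per draw, every
#' parameter with a sampling distribution (see [psa_distributions()]) is
#' drawn from its family, both strategies are evaluated under the sampled
#' set, and the incremental discounted cost and QALYs of treat-all versus
#' microalbuminuria screening are recorded. Reproducible for a fixed seed.
#'
#' @param ps A `nephro_params` object.
#' @param ranges A data frame like [default_ranges()].
#' @param demography See [default_demography()].
#' @param n_draws Number of Monte Carlo replications (default 1000).
#' @param seed RNG seed (default 20110, the package's documented default).
#' @param ess Dirichlet effective sample size.
#' @param strategy,reference Strategy pair compared.
#' @return A `nephro_psa` data frame with one row per draw: `draw`,
#'   `delta_cost`, `delta_qalys`, and the sampled scalar parameter values;
#'   attributes `seed` and `n_draws`.
#' @export
run_psa <- function(ps, ranges = default_ranges(),
                    demography = default_demography(ps),
                    n_draws = 1000, seed = 20110, ess = 100,
                    strategy = "treat_all", reference = "screen_micro") {
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  specs <- psa_distributions(ps, ranges, ess)
  set.seed(seed)
  scalar_names <- setdiff(names(specs), "prev")
  rows <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    ps_d <- sample_parameter_set(ps, specs)
    a <- evaluate_strategy(strategy, ps_d, demography)
    b <- evaluate_strategy(reference, ps_d, demography)
    sampled <- stats::setNames(lapply(scalar_names, function(nm) ps_d[[nm]]),
                               scalar_names)
    rows[[d]] <- data.frame(
      draw = d,
      delta_cost = a$discounted_cost - b$discounted_cost,
      delta_qalys = a$discounted_qalys - b$discounted_qalys,
      prev_normo = ps_d$prev_normo,
      as.data.frame(sampled)
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "n_draws") <- n_draws
  class(out) <- c("nephro_psa", "data.frame")
  out
}

#' Net monetary benefit
#'
#' @param delta_cost Incremental cost (euros).
#' @param delta_qalys Incremental QALYs.
#' @param wtp Willingness to pay per QALY (euros/QALY, >= 0).
#' @return `wtp * delta_qalys - delta_cost` (euros).
#' @export
#' @examples
#' nmb(-2719, 0.095, 20000)
nmb <- function(delta_cost, delta_qalys, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0", call. = FALSE)
  wtp * delta_qalys - delta_cost
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that the strategy is
#' cost-effective is the fraction of PSA draws with positive net monetary
#' benefit.
#'
#' @param samples A `nephro_psa` data frame (or any data frame with
#'   `delta_cost` and `delta_qalys`).
#' @param wtp_grid Non-negative increasing willingness-to-pay grid
#'   (default 0 to 100000 euros/QALY in 1000-euro steps).
#' @return A data frame with columns `wtp` and `prob_cost_effective`.
#' @export
ceac <- function(samples, wtp_grid = seq(0, 100000, by = 1000)) {
  if (nrow(samples) == 0) stop("no PSA samples", call. = FALSE)
  if (any(wtp_grid < 0) || is.unsorted(wtp_grid, strictly = TRUE))
    stop("wtp_grid must be non-negative and increasing", call. = FALSE)
  prob <- vapply(wtp_grid, function(l)
    mean(nmb(samples$delta_cost, samples$delta_qalys, l) > 0), numeric(1))
  data.frame(wtp = wtp_grid, prob_cost_effective = prob)
}

#' Probability that treat-all saves money
#'
#' Fraction of PSA draws with negative incremental cost; equals the
#' acceptability curve's value at a willingness to pay of zero.
#'
#' @param samples A `nephro_psa` data frame.
#' @return Proportion in `[0, 1]`.
#' @export
probability_of_savings <- function(samples) {
  if (nrow(samples) == 0) stop("no PSA samples", call. = FALSE)
  mean(samples$delta_cost < 0)
}

#' Summary of a probabilistic sensitivity analysis
#'
#' @param samples A `nephro_psa` data frame.
#' @return A list: `n_draws`, `probability_of_savings`, mean incremental
#'   cost and QALYs, and their 95% central (percentile) intervals.
#' @export
psa_summary <- function(samples) {
  qs <- function(x) unname(stats::quantile(x, c(0.025, 0.975)))
  list(
    n_draws = nrow(samples),
    probability_of_savings = probability_of_savings(samples),
    mean_delta_cost = mean(samples$delta_cost),
    mean_delta_qalys = mean(samples$delta_qalys),
    ci95_delta_cost = qs(samples$delta_cost),
    ci95_delta_qalys = qs(samples$delta_qalys)
  )
}
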