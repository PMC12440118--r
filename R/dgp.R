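#' Simulation configuration for a two-arm survival trial
#'
#' Describes one cell of the simulation study: the survival family
#' (Weibull or log-logistic regression), the treatment-heterogeneity
#' scenario (1 = linear, 2 = nonlinear with an interaction, 3 = complex
#' nonlinear with partially overlapping covariate sets per arm), and the
#' randomization design (`balanced` p = 0.5, `unbalanced` p = 0.05, or
#' `dependent` with logit(p | x) = beta0 + 1.3 x1 - 0.8 x5).
#'
#' Defaults are the study conditions: Weibull shape `eta = 2` with arm
#' scales `lambda0 = 18` (control) and `lambda1 = 20` (treatment);
#' log-logistic scales `sigma0 = 2, sigma1 = 1` for scenario 1 and
#' `sigma0 = 1, sigma1 = 0.5` for scenarios 2-3; an overall censoring
#' rate of 30% from an exponential censoring distribution; training
#' sample size 1000 (4000 under the unbalanced design) and a test
#' population of 10000.
#'
#' @param family survival family generating event times.
#' @param scenario heterogeneity scenario, 1, 2 or 3.
#' @param design randomization design.
#' @param n_train,n_test sample sizes; `n_train = NULL` picks the
#'   design default (1000, or 4000 when unbalanced).
#' @param eta Weibull shape (common to both arms).
#' @param lambda0,lambda1 Weibull scales per arm.
#' @param sigma0,sigma1 log-logistic scales per arm; `NULL` picks the
#'   scenario default.
#' @param target_censor_rate overall censoring probability to calibrate
#'   the exponential censoring rate to.
#' @param horizon_quantile quantile of the true assigned-arm event-time
#'   distribution defining the time of interest t* (0.5 = median).
#' @param seed master seed for dataset simulation.
#' @return A `scenario_config` object (a list).
#' @examples
#' cfg <- scenario_config("weibull", scenario = 1, design = "balanced", seed = 1)
#' @export
scenario_config <- function(family = c("weibull", "loglogistic"),
                            scenario = 1L,
                            design = c("balanced", "unbalanced", "dependent"),
                            n_train = NULL,
                            n_test = 10000L,
                            eta = 2,
                            lambda0 = 18,
                            lambda1 = 20,
                            sigma0 = NULL,
                            sigma1 = NULL,
                            target_censor_rate = 0.30,
                            horizon_quantile = 0.5,
                            seed = 1L) {
  family <- match.arg(family)
  design <- match.arg(design)
  if (!scenario %in% 1:3) abort_invalid("scenario must be 1, 2 or 3")
  if (target_censor_rate <= 0 || target_censor_rate >= 1) {
    abort_invalid("target_censor_rate must be in (0, 1)")
  }
  if (is.null(sigma0)) sigma0 <- if (scenario == 1) 2 else 1
  if (is.null(sigma1)) sigma1 <- if (scenario == 1) 1 else 0.5
  if (is.null(n_train)) n_train <- if (design == "unbalanced") 4000L else 1000L
  stopifnot(eta > 0, lambda0 > 0, lambda1 > 0, sigma0 > 0, sigma1 > 0,
            n_train >= 1, n_test >= 1)
  structure(
    list(family = family, scenario = as.integer(scenario), design = design,
         n_train = as.integer(n_train), n_test = as.integer(n_test),
         eta = eta, lambda0 = lambda0, lambda1 = lambda1,
         sigma0 = sigma0, sigma1 = sigma1,
         target_censor_rate = target_censor_rate,
         horizon_quantile = horizon_quantile,
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>", x$family, "scenario", x$scenario, x$design,
      "design\n  n_train =", x$n_train, ", n_test =", x$n_test,
      ", censoring =", x$target_censor_rate, "\n")
  invisible(x)
}

#' Simulate baseline covariates
#'
#' Draws ten independent covariates from N(0, 0.35^2); the last three are
#' dichotomized at zero, so `x8`, `x9`, `x10` are Bernoulli(0.5) binary
#' indicators. Draws are laid out per subject, so the first `m` rows are
#' identical for any two calls with the same seed and `n >= m`.
#'
#' @param n number of subjects.
#' @param seed integer seed.
#' @param sd standard deviation of the latent normals.
#' @return A tibble with columns `x1` ... `x10`.
#' @export
simulate_covariates <- function(n, seed = NULL, sd = 0.35) {
  if (length(n) != 1L || is.na(n) || n < 1) abort_invalid("n must be >= 1")
  n <- as.integer(n)
  m <- with_seed(seed, matrix(stats::rnorm(n * 10L, 0, sd), nrow = n, byrow = TRUE))
  m[, 8:10] <- (m[, 8:10] > 0) + 0
  colnames(m) <- covariate_names()
  tibble::as_tibble(m)
}

#' Assign treatment under a randomization design
#'
#' `balanced` assigns Bernoulli(0.5), `unbalanced` Bernoulli(0.05), and
#' `dependent` assigns with probability expit(beta0 + 1.3 x1 - 0.8 x5).
#' With covariates centred at zero the linear predictor is symmetric
#' about 0, so `beta0 = 0` yields a marginal 1:1 allocation.
#'
#' @param x covariate data frame (needs `x1`, `x5` for the dependent design).
#' @param design randomization design.
#' @param seed integer seed.
#' @param beta0 intercept of the dependent design.
#' @return Integer vector of 0/1 assignments.
#' @export
assign_treatment <- function(x, design = c("balanced", "unbalanced", "dependent"),
                             seed = NULL, beta0 = 0) {
  design <- match.arg(design)
  n <- nrow(x)
  p <- switch(design,
    balanced = rep(0.5, n),
    unbalanced = rep(0.05, n),
    dependent = stats::plogis(beta0 + 1.3 * x$x1 - 0.8 * x$x5)
  )
  with_seed(seed, stats::rbinom(n, 1L, p))
}

#' Solve the dependent-design intercept for a target allocation
#'
#' Monte-Carlo root finder for the intercept beta0 that achieves a given
#' marginal treated fraction under the covariate-dependent design. For
#' the default symmetric linear predictor and a 1:1 target the solution
#' is beta0 = 0; the solver is provided for non-symmetric extensions.
#'
#' @param target desired marginal treated fraction.
#' @param n Monte-Carlo sample size.
#' @param seed seed for the reference covariate draw.
#' @return The intercept `beta0`.
#' @export
solve_dependent_intercept <- function(target = 0.5, n = 1e5, seed = 76543003L) {
  x <- simulate_covariates(n, seed = seed)
  lp <- 1.3 * x$x1 - 0.8 * x$x5
  f <- function(b0) mean(stats::plogis(b0 + lp)) - target
  stats::uniroot(f, c(-20, 20), tol = 1e-8)$root
}

#' Linear predictor h_z(x) of the true survival models
#'
#' Evaluates the scenario-specific arm effect functions:
#' \describe{
#'   \item{Scenario 1}{h0 = 0.2 x1 + 0.7 x2 + 0.4 x9;
#'     h1 = -0.5 x1 - 2 x2 - 0.25 x9 (linear).}
#'   \item{Scenario 2}{h0 = -0.5 x1 + 0.7 x2 + 0.2 x9 + 0.9 x2 x9;
#'     h1 = -0.05 e^(x1) - 0.2 x2^2 + 0.35 x9.}
#'   \item{Scenario 3}{scenario 2's h0 plus 0.6 x3 - 0.5 x4^2 + 0.6 x8;
#'     h1 = -0.05 e^(x1) - 0.2 x2^2 + 0.2 x9 - 0.1 e^(x5) +
#'     0.7 sin(x6) + 0.5 x10.}
#' }
#'
#' @param x covariate data frame (columns `x1` ... `x10`, binary already
#'   thresholded).
#' @param arm 0 (control) or 1 (treatment).
#' @param scenario 1, 2 or 3.
#' @return Numeric vector, one value per row of `x`.
#' @export
h_function <- function(x, arm, scenario) {
  if (!arm %in% c(0, 1)) abort_invalid("arm must be 0 or 1")
  if (!scenario %in% 1:3) abort_invalid("scenario must be 1, 2 or 3")
  if (scenario == 1) {
    if (arm == 0) 0.2 * x$x1 + 0.7 * x$x2 + 0.4 * x$x9
    else -0.5 * x$x1 - 2 * x$x2 - 0.25 * x$x9
  } else if (scenario == 2) {
    if (arm == 0) -0.5 * x$x1 + 0.7 * x$x2 + 0.2 * x$x9 + 0.9 * x$x2 * x$x9
    else -0.05 * exp(x$x1) - 0.2 * x$x2^2 + 0.35 * x$x9
  } else {
    if (arm == 0) {
      -0.5 * x$x1 + 0.7 * x$x2 + 0.2 * x$x9 + 0.9 * x$x2 * x$x9 +
        0.6 * x$x3 - 0.5 * x$x4^2 + 0.6 * x$x8
    } else {
      -0.05 * exp(x$x1) - 0.2 * x$x2^2 + 0.2 * x$x9 -
        0.1 * exp(x$x5) + 0.7 * sin(x$x6) + 0.5 * x$x10
    }
  }
}

#' True conditional survival probability
#'
#' Weibull: S_z(t | x) = exp(-e^(h_z(x)) (t / lambda_z)^eta).
#' Log-logistic: S_z(t | x) = 1 / (1 + exp((log t - h_z(x)) / sigma_z)).
#'
#' @param t time(s), recycled against rows of `x`.
#' @param x covariate data frame.
#' @param arm 0 or 1.
#' @param config a [scenario_config()].
#' @return Survival probabilities in `[0, 1]`.
#' @export
true_survival <- function(t, x, arm, config) {
  if (any(t < 0)) abort_invalid("t must be non-negative")
  h <- h_function(x, arm, config$scenario)
  if (config$family == "weibull") {
    lam <- if (arm == 0) config$lambda0 else config$lambda1
    exp(-exp(h) * (t / lam)^config$eta)
  } else {
    sig <- if (arm == 0) config$sigma0 else config$sigma1
    1 / (1 + exp((log(t) - h) / sig))
  }
}

#' True individualized treatment effect at a horizon
#'
#' theta(t, x) = S1(t | x) - S0(t | x) under the generating model.
#'
#' @inheritParams true_survival
#' @return Numeric vector in `[-1, 1]`.
#' @export
true_ite <- function(t, x, config) {
  true_survival(t, x, 1, config) - true_survival(t, x, 0, config)
}

#' Sample an event time by inverse transform
#'
#' Weibull: T = lambda_z (-log(u) / e^(h_z(x)))^(1 / eta).
#' Log-logistic: T = exp(h_z(x) + sigma_z log((1 - u) / u)).
#' Satisfies `true_survival(sample_event_time(u, ...), ...) == u`.
#'
#' @param u uniform(0,1) draws, recycled against rows of `x`.
#' @inheritParams true_survival
#' @return Positive event times.
#' @export
sample_event_time <- function(u, x, arm, config) {
  if (any(u <= 0 | u >= 1)) abort_invalid("u must lie strictly in (0, 1)")
  h <- h_function(x, arm, config$scenario)
  if (config$family == "weibull") {
    lam <- if (arm == 0) config$lambda0 else config$lambda1
    lam * (-log(u) / exp(h))^(1 / config$eta)
  } else {
    sig <- if (arm == 0) config$sigma0 else config$sigma1
    exp(h + sig * log((1 - u) / u))
  }
}

# reference population of assigned-arm true event times used by the
# censoring calibration and the horizon; deterministic given ref_seed
reference_event_times <- function(config, n_ref = 1e5, ref_seed = 76543001L) {
  x <- simulate_covariates(n_ref, seed = derive_seed(ref_seed, 1))
  z <- assign_treatment(x, config$design, seed = derive_seed(ref_seed, 2))
  u <- with_seed(derive_seed(ref_seed, 3), stats::runif(n_ref))
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  t1 <- sample_event_time(u, x, 1, config)
  t0 <- sample_event_time(u, x, 0, config)
  ifelse(z == 1, t1, t0)
}

#' Calibrate the exponential censoring rate
#'
#' Finds the rate rho of an exponential censoring distribution such that
#' the overall censoring probability P(C < T) under the configured
#' design equals `config$target_censor_rate`. The event-time population
#' is simulated once (n >= 1e5, fixed internal seed) and the censoring
#' probability is integrated exactly over C given T
#' (P(censored | T = t) = 1 - exp(-rho t)), making the objective smooth
#' and the root-finding deterministic.
#'
#' @param config a [scenario_config()].
#' @param n_cal calibration sample size.
#' @param ref_seed fixed internal seed for the calibration population.
#' @return The exponential rate `rho`, with the achieved censoring
#'   fraction in attribute `"achieved"`.
#' @export
calibrate_censoring <- function(config, n_cal = 1e5, ref_seed = 76543001L) {
  target <- config$target_censor_rate
  tt <- reference_event_times(config, n_ref = n_cal, ref_seed = ref_seed)
  f <- function(rho) mean(1 - exp(-rho * tt)) - target
  root <- tryCatch(
    stats::uniroot(f, c(1e-10, 1), extendInt = "upX", tol = 1e-10, maxiter = 200),
    error = function(e) rlang::abort("censoring calibration failed to bracket a root",
                                     class = "survite_calibration_failure", parent = e)
  )
  rho <- root$root
  structure(rho, achieved = mean(1 - exp(-rho * tt)))
}

#' Time of interest from the true event-time distribution
#'
#' Computes the horizon t* as an empirical quantile (default the median)
#' of the assigned-arm true event times in a large seeded reference
#' simulation. The 0.25 and 0.75 quantiles support sensitivity analyses.
#'
#' @param config a [scenario_config()].
#' @param quantile probability level of the horizon.
#' @param n_ref reference population size.
#' @param ref_seed fixed internal seed.
#' @return The horizon t*.
#' @export
median_horizon <- function(config, quantile = config$horizon_quantile,
                           n_ref = 1e5, ref_seed = 76543001L) {
  tt <- reference_event_times(config, n_ref = n_ref, ref_seed = ref_seed)
  unname(stats::quantile(tt, probs = quantile, type = 7))
}

#' Simulate a two-arm trial with oracle ground truth
#'
#' Assembles a full simulated dataset: covariates, randomized treatment,
#' both potential event times (one shared uniform per subject, so the
#' potential outcomes are comonotone), an exponential censoring time at
#' the calibrated rate, the observed pair (y, delta) by consistency
#' (y = min(t_z, c), delta = 1 when t_z <= c), and the true ITE at the
#' horizon.
#'
#' @param config a [scenario_config()].
#' @param n number of subjects (defaults to `config$n_train`).
#' @param seed dataset seed (defaults to `config$seed`).
#' @param horizon time of interest; computed via [median_horizon()] when
#'   `NULL`.
#' @param censor_rate exponential censoring rate; calibrated via
#'   [calibrate_censoring()] when `NULL`.
#' @param oracle keep the ground-truth columns (`t0`, `t1`, `c`,
#'   `theta_true`)?
#' @return A tibble with columns `id, z, y, delta, x1..x10` and, when
#'   `oracle = TRUE`, `t0, t1, c, theta_true`; the horizon and censoring
#'   rate are stored in attributes `"horizon"` and `"censor_rate"`.
#' @examples
#' cfg <- scenario_config("weibull", 1, "balanced", n_train = 200, seed = 7)
#' dat <- simulate_dataset(cfg, n = 200)
#' @export
simulate_dataset <- function(config, n = config$n_train, seed = config$seed,
                             horizon = NULL, censor_rate = NULL, oracle = TRUE) {
  if (n < 1) abort_invalid("n must be >= 1")
  if (is.null(horizon)) horizon <- median_horizon(config)
  if (is.null(censor_rate)) censor_rate <- as.numeric(calibrate_censoring(config))
  x <- simulate_covariates(n, seed = derive_seed(seed, 1))
  z <- assign_treatment(x, config$design, seed = derive_seed(seed, 2))
  u <- with_seed(derive_seed(seed, 3), stats::runif(n))
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  t0 <- sample_event_time(u, x, 0, config)
  t1 <- sample_event_time(u, x, 1, config)
  cc <- with_seed(derive_seed(seed, 4), stats::rexp(n, rate = censor_rate))
  tz <- ifelse(z == 1, t1, t0)
  y <- pmin(tz, cc)
  delta <- as.integer(tz <= cc)
  out <- tibble::tibble(id = seq_len(n), z = as.integer(z), y = y, delta = delta)
  out <- dplyr::bind_cols(out, x)
  if (oracle) {
    out$t0 <- t0
    out$t1 <- t1
    out$c <- cc
    out$theta_true <- true_ite(horizon, x, config)
  }
  attr(out, "horizon") <- horizon
  attr(out, "censor_rate") <- censor_rate
  attr(out, "config") <- config
  out
}
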