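#' Base learner specifications
#'
#' A base learner fits a conditional survival function on one arm's data
#' and predicts S_hat(t | x). Four kinds are provided:
#' \describe{
#'   \item{`learner_oracle()`}{a correctly specified parametric AFT model
#'     (Weibull or log-logistic) fit by maximum likelihood on the true
#'     covariate basis of a simulation scenario — the optimal reference
#'     case. Parameters are always estimated from data, never plugged in
#'     from the generating truth.}
#'   \item{`learner_rsf()`}{a random survival forest (log-rank splitting,
#'     Nelson-Aalen leaf estimates averaged across trees).}
#'   \item{`learner_pseudo_nn()`}{a pseudo-value neural regressor:
#'     jackknife pseudo-observations of the survival probability on a
#'     time grid, regressed on (x, t) with a single-hidden-layer network
#'     and monotonized. A deliberately simple stand-in for deep survival
#'     networks, not a reimplementation of any published architecture.}
#'   \item{`learner_bayes_aft()`}{a parametric Bayesian AFT using a
#'     Laplace approximation of the posterior around the MLE; predicts
#'     the posterior-mean survival probability. Not a tree-ensemble
#'     Bayesian AFT.}
#' }
#'
#' @param family AFT family for the parametric learners.
#' @param scenario simulation scenario whose true basis the oracle uses;
#'   ignored when `basis0`/`basis1` are supplied.
#' @param basis0,basis1 optional functions mapping a covariate data frame
#'   to the design matrix for arm 0 / arm 1.
#' @param num_trees,mtry,min_node_size random survival forest settings;
#'   `mtry = NULL` uses ceiling(sqrt(d)).
#' @param grid_size number of time-grid points (equally spaced quantiles
#'   of observed times) for the pseudo-value learner.
#' @param hidden,decay,maxit network size and training controls.
#' @param restarts independent network restarts averaged at prediction
#'   time (reduces initialization variance).
#' @param min_events minimum events required per arm by the pseudo-value
#'   learner.
#' @param n_draws posterior draws for the Bayesian AFT.
#' @return A learner specification object consumed by
#'   [fit_base_learner()], [t_learner()] and [x_learner()].
#' @name base_learners
NULL

#' @rdname base_learners
#' @export
learner_oracle <- function(family = c("weibull", "loglogistic"), scenario = 1L,
                           basis0 = NULL, basis1 = NULL) {
  family <- match.arg(family)
  structure(list(kind = "oracle_aft", family = family, scenario = scenario,
                 basis0 = basis0, basis1 = basis1,
                 label = paste0("oracle_", family)),
            class = c("oracle_spec", "learner_spec"))
}

#' @rdname base_learners
#' @param max_time_points cap on distinct event times stored per tree;
#'   continuous observed times are snapped down onto a quantile grid of
#'   this size before fitting, which bounds the forest's memory without
#'   materially changing the curves.
#' @export
learner_rsf <- function(num_trees = 1000L, mtry = NULL, min_node_size = 15L,
                        max_time_points = 128L) {
  structure(list(kind = "rsf", num_trees = num_trees, mtry = mtry,
                 min_node_size = min_node_size,
                 max_time_points = max_time_points, label = "rsf"),
            class = c("rsf_spec", "learner_spec"))
}

#' @rdname base_learners
#' @export
learner_pseudo_nn <- function(grid_size = 10L, hidden = 16L, decay = 5,
                              maxit = 500L, restarts = 3L, min_events = 100L) {
  structure(list(kind = "pseudo_nn", grid_size = grid_size, hidden = hidden,
                 decay = decay, maxit = maxit, restarts = restarts,
                 min_events = min_events, label = "pseudo_nn"),
            class = c("pseudo_nn_spec", "learner_spec"))
}

#' @rdname base_learners
#' @export
learner_bayes_aft <- function(family = c("weibull", "loglogistic"),
                              n_draws = 500L) {
  family <- match.arg(family)
  structure(list(kind = "bayes_aft", family = family, n_draws = n_draws,
                 label = paste0("bayes_aft_", family)),
            class = c("bayes_aft_spec", "learner_spec"))
}

#' True covariate basis of a scenario's h-function
#'
#' Returns a function mapping a covariate data frame to the design
#' matrix containing exactly the terms of the true h_z(x) for the given
#' scenario and arm (e.g. `exp(x1)`, `x2^2`, the `x2 * x9` interaction).
#'
#' @param scenario 1, 2 or 3.
#' @param arm 0 or 1.
#' @return A function `x -> matrix`.
#' @export
oracle_basis <- function(scenario, arm) {
  if (!scenario %in% 1:3) abort_invalid("scenario must be 1, 2 or 3")
  if (!arm %in% c(0, 1)) abort_invalid("arm must be 0 or 1")
  if (scenario == 1) {
    function(x) cbind(x1 = x$x1, x2 = x$x2, x9 = x$x9)
  } else if (scenario == 2) {
    if (arm == 0) {
      function(x) cbind(x1 = x$x1, x2 = x$x2, x9 = x$x9, x2_x9 = x$x2 * x$x9)
    } else {
      function(x) cbind(exp_x1 = exp(x$x1), x2_sq = x$x2^2, x9 = x$x9)
    }
  } else {
    if (arm == 0) {
      function(x) cbind(x1 = x$x1, x2 = x$x2, x9 = x$x9, x2_x9 = x$x2 * x$x9,
                        x3 = x$x3, x4_sq = x$x4^2, x8 = x$x8)
    } else {
      function(x) cbind(exp_x1 = exp(x$x1), x2_sq = x$x2^2, x9 = x$x9,
                        exp_x5 = exp(x$x5), sin_x6 = sin(x$x6), x10 = x$x10)
    }
  }
}

#' Fit a base learner on one arm's data
#'
#' Dispatches on the learner specification. `data` must be a single-arm
#' survival table with columns `y`, `delta` and covariates `x*`.
#'
#' @param spec a learner specification, see [base_learners].
#' @param data one-arm survival data.
#' @param arm which arm the data belong to (0/1); required by the oracle
#'   learner to select the true basis.
#' @param seed seed controlling any randomness in fitting.
#' @return A fitted `survival_model` supporting [predict_survival()].
#' @export
fit_base_learner <- function(spec, data, arm = NULL, seed = NULL) {
  UseMethod("fit_base_learner")
}

#' Predict conditional survival probabilities
#'
#' @param object a fitted `survival_model`.
#' @param newdata covariate data frame.
#' @param times time point(s) at which to evaluate S_hat(t | x).
#' @param ... unused.
#' @return A numeric vector (one time) or an `nrow(newdata)` by
#'   `length(times)` matrix, values in `[0, 1]`, non-increasing in t,
#'   with S_hat(x, 0) = 1.
#' @export
predict_survival <- function(object, newdata, times, ...) {
  UseMethod("predict_survival")
}

clamp01 <- function(p) pmin(pmax(p, 0), 1)

shape_pred <- function(m, times) {
  if (length(times) == 1L) as.numeric(m) else m
}

## ---- oracle parametric AFT --------------------------------------------

#' Maximum-likelihood parametric AFT fit on a fixed basis
#'
#' Fits `survreg(Surv(y, delta) ~ basis(x), dist = family)` on one arm.
#' The h-scale coefficients of the generating model are recoverable via
#' [h_coefficients()]: for the Weibull family h-coefficients equal
#' `-coef * shape` (shape = 1 / scale); for the log-logistic family they
#' equal the AFT coefficients directly.
#'
#' @param data one-arm survival data (`y`, `delta`, covariates).
#' @param family `"weibull"` or `"loglogistic"`.
#' @param basis function mapping covariates to the design matrix.
#' @return An `oracle_aft` model.
#' @export
fit_oracle_aft <- function(data, family = c("weibull", "loglogistic"), basis) {
  family <- match.arg(family)
  if (sum(data$delta) < 2) abort_fit_failure("need at least 2 events to fit an AFT model")
  x <- covariate_cols(data)
  b <- basis(x)
  fit <- tryCatch(
    survival::survreg(survival::Surv(data$y, data$delta) ~ b, dist = family),
    error = function(e) abort_fit_failure("parametric AFT fit failed", parent = e),
    warning = function(w) {
      suppressWarnings(survival::survreg(survival::Surv(data$y, data$delta) ~ b,
                                         dist = family))
    }
  )
  if (any(!is.finite(fit$coefficients))) {
    abort_fit_failure("parametric AFT fit did not converge to finite coefficients")
  }
  structure(list(fit = fit, family = family, basis = basis),
            class = c("oracle_aft", "survival_model"))
}

#' @export
fit_base_learner.oracle_spec <- function(spec, data, arm = NULL, seed = NULL) {
  basis0 <- spec$basis0 %||% oracle_basis(spec$scenario, 0)
  basis1 <- spec$basis1 %||% oracle_basis(spec$scenario, 1)
  if (is.null(arm) && is.null(spec$basis0)) {
    abort_invalid("oracle learner needs `arm` to select the true basis")
  }
  basis <- if (!is.null(arm) && arm == 1) basis1 else basis0
  fit_oracle_aft(data, spec$family, basis)
}

aft_lp <- function(object, newdata) {
  b <- object$basis(covariate_cols(newdata))
  as.numeric(object$fit$coefficients[1] + b %*% object$fit$coefficients[-1])
}

#' @export
predict_survival.oracle_aft <- function(object, newdata, times, ...) {
  lp <- aft_lp(object, newdata)
  m <- vapply(times, function(t) {
    if (t == 0) return(rep(1, length(lp)))
    if (object$family == "weibull") {
      exp(-(t / exp(lp))^(1 / object$fit$scale))
    } else {
      1 / (1 + exp((log(t) - lp) / object$fit$scale))
    }
  }, numeric(length(lp)))
  shape_pred(clamp01(matrix(m, nrow = length(lp))), times)
}

#' Recover h-scale coefficients from a fitted oracle AFT
#'
#' @param object an `oracle_aft` model.
#' @return Named vector of coefficients on the scale of the generating
#'   h-function.
#' @export
h_coefficients <- function(object) {
  stopifnot(inherits(object, "oracle_aft"))
  beta <- object$fit$coefficients[-1]
  names(beta) <- sub("^b", "", names(beta))
  if (object$family == "weibull") -beta / object$fit$scale else beta
}

## ---- random survival forest -------------------------------------------

#' @export
fit_base_learner.rsf_spec <- function(spec, data, arm = NULL, seed = NULL) {
  if (sum(data$delta) < 1) abort_fit_failure("cannot fit a survival forest on an all-censored arm")
  x <- covariate_cols(data)
  df <- data.frame(y = data$y, delta = data$delta, x)
  if (length(unique(df$y)) > spec$max_time_points) {
    grid <- unique(stats::quantile(df$y, seq(0, 1, length.out = spec$max_time_points),
                                   type = 7, names = FALSE))
    df$y <- grid[pmax(findInterval(df$y, grid), 1L)]
  }
  mtry <- spec$mtry %||% ceiling(sqrt(ncol(x)))
  fit <- ranger::ranger(
    survival::Surv(y, delta) ~ ., data = df,
    num.trees = spec$num_trees, mtry = mtry,
    min.node.size = spec$min_node_size,
    splitrule = "logrank",
    seed = seed %||% 1L,
    num.threads = 1,
    verbose = FALSE
  )
  structure(list(fit = fit, covars = names(x)),
            class = c("rsf_model", "survival_model"))
}

# right-continuous step interpolation of per-row survival curves
step_interp <- function(surv, grid, times) {
  idx <- findInterval(times, grid)
  m <- vapply(seq_along(times), function(j) {
    if (idx[j] == 0) rep(1, nrow(surv)) else surv[, idx[j]]
  }, numeric(nrow(surv)))
  matrix(m, nrow = nrow(surv))
}

#' @export
predict_survival.rsf_model <- function(object, newdata, times, ...) {
  x <- covariate_cols(newdata)[object$covars]
  pr <- stats::predict(object$fit, data = as.data.frame(x), num.threads = 1)
  m <- step_interp(pr$survival, pr$unique.death.times, times)
  shape_pred(clamp01(m), times)
}

## ---- pseudo-value neural learner --------------------------------------

# jackknife pseudo-observations of S(t) under the Kaplan-Meier estimator
km_pseudo_obs <- function(y, delta, grid) {
  n <- length(y)
  km_at <- function(idx) {
    fit <- survival::survfit(survival::Surv(y[idx], delta[idx]) ~ 1)
    summary(fit, times = grid, extend = TRUE)$surv
  }
  s_full <- km_at(seq_len(n))
  po <- matrix(NA_real_, n, length(grid))
  for (i in seq_len(n)) {
    po[i, ] <- n * s_full - (n - 1) * km_at(setdiff(seq_len(n), i))
  }
  po
}

#' @export
fit_base_learner.pseudo_nn_spec <- function(spec, data, arm = NULL, seed = NULL) {
  if (sum(data$delta) < spec$min_events) {
    abort_fit_failure(paste0(
      "pseudo-value neural learner needs at least ", spec$min_events,
      " events in the arm (got ", sum(data$delta), "); ",
      "use a larger arm or a different base learner"))
  }
  x <- covariate_cols(data)
  probs <- seq_len(spec$grid_size) / (spec$grid_size + 1)
  grid <- unname(stats::quantile(data$y, probs = probs, type = 7))
  grid <- unique(grid)
  po <- km_pseudo_obs(data$y, data$delta, grid)
  # decompose: marginal survival curve (the per-time pseudo mean, which
  # equals the KM estimate) plus a covariate-specific deviation fitted
  # by the network; weight decay shrinks the deviation toward zero when
  # covariates carry no signal
  marg <- colMeans(po)
  dev <- sweep(po, 2, marg)
  t_scale <- max(grid)
  xtrain <- do.call(rbind, lapply(seq_along(grid), function(k) {
    cbind(as.matrix(x), t = grid[k] / t_scale)
  }))
  ytrain <- as.numeric(dev)
  fits <- lapply(seq_len(spec$restarts), function(r) {
    with_seed(derive_seed(seed %||% 1L, r),
      nnet::nnet(x = xtrain, y = ytrain, size = spec$hidden, linout = TRUE,
                 decay = spec$decay, maxit = spec$maxit, trace = FALSE,
                 MaxNWts = 10000))
  })
  structure(list(fits = fits, marginal = marg, grid = grid,
                 t_scale = t_scale, covars = names(x)),
            class = c("pseudo_nn_model", "survival_model"))
}

#' @export
predict_survival.pseudo_nn_model <- function(object, newdata, times, ...) {
  x <- as.matrix(covariate_cols(newdata)[object$covars])
  # predict on the training grid, clamp, enforce monotone non-increase
  sg <- vapply(seq_along(object$grid), function(k) {
    tk <- object$grid[k]
    dev <- rowMeans(vapply(object$fits, function(f) {
      as.numeric(stats::predict(f, cbind(x, t = tk / object$t_scale)))
    }, numeric(nrow(x))))
    object$marginal[k] + dev
  }, numeric(nrow(x)))
  sg <- matrix(clamp01(sg), nrow = nrow(x))
  for (k in seq_len(ncol(sg))[-1]) sg[, k] <- pmin(sg[, k], sg[, k - 1])
  m <- vapply(times, function(t) {
    if (t == 0) return(rep(1, nrow(x)))
    idx <- findInterval(t, object$grid)
    if (idx == 0) sg[, 1] else sg[, idx]
  }, numeric(nrow(x)))
  shape_pred(matrix(m, nrow = nrow(x)), times)
}

## ---- Laplace-approximation Bayesian AFT --------------------------------

#' @export
fit_base_learner.bayes_aft_spec <- function(spec, data, arm = NULL, seed = NULL) {
  if (sum(data$delta) < 2) abort_fit_failure("need at least 2 events to fit an AFT model")
  x <- covariate_cols(data)
  xm <- as.matrix(x)
  fit <- tryCatch(
    survival::survreg(survival::Surv(data$y, data$delta) ~ xm, dist = spec$family),
    error = function(e) abort_fit_failure("Bayesian AFT fit failed", parent = e)
  )
  # Laplace approximation: flat prior, posterior ~ MVN(MLE, vcov);
  # the last parameter of survreg's vcov is log(scale)
  mu <- c(fit$coefficients, `Log(scale)` = log(fit$scale))
  sig <- fit$var
  if (any(!is.finite(mu)) || any(!is.finite(sig))) {
    abort_fit_failure("Bayesian AFT posterior approximation is degenerate")
  }
  draws <- with_seed(seed %||% 1L, MASS::mvrnorm(spec$n_draws, mu, sig))
  structure(list(draws = draws, family = spec$family, covars = names(x)),
            class = c("bayes_aft_model", "survival_model"))
}

#' @export
predict_survival.bayes_aft_model <- function(object, newdata, times, ...) {
  xm <- cbind(1, as.matrix(covariate_cols(newdata)[object$covars]))
  p <- ncol(object$draws)
  lp <- xm %*% t(object$draws[, -p, drop = FALSE])   # n x n_draws
  scale <- exp(object$draws[, p])
  m <- vapply(times, function(t) {
    if (t == 0) return(rep(1, nrow(xm)))
    if (object$family == "weibull") {
      s <- exp(-sweep((t / exp(lp)), 2, 1 / scale, `^`))
    } else {
      s <- 1 / (1 + exp(sweep(log(t) - lp, 2, scale, `/`)))
    }
    rowMeans(s)
  }, numeric(nrow(xm)))
  shape_pred(clamp01(matrix(m, nrow = nrow(xm))), times)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
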