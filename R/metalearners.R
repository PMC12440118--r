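#' Treatment recommendation rule
#'
#' Recommends treatment (`"RT"`) for subjects with a strictly positive
#' estimated ITE and control (`"RC"`) otherwise; an ITE of exactly zero
#' is non-positive and maps to `"RC"`.
#'
#' @param theta numeric vector of estimated ITEs.
#' @return Factor with levels `RC`, `RT`.
#' @examples
#' recommend(c(0.2, 0, -0.1))
#' @export
recommend <- function(theta) {
  factor(ifelse(theta > 0, "RT", "RC"), levels = c("RC", "RT"))
}

#' Weight functions for the X-learner combination
#'
#' `weight_constant()` returns the known randomization probability p as
#' a constant weight g(x) = p, appropriate for a simple RCT.
#' `weight_propensity()` fits a random-forest classifier of treatment on
#' covariates and returns the estimated propensity score, clipped to
#' `[eps, 1 - eps]`, for designs where assignment depends on covariates.
#'
#' @param p randomization probability in (0, 1).
#' @param data two-arm survival data used to fit the propensity model.
#' @param num_trees forest size.
#' @param eps clipping bound keeping g strictly inside (0, 1).
#' @param seed seed for the forest.
#' @return An `ite_weight` object: call it on a covariate data frame to
#'   obtain g(x).
#' @export
weight_constant <- function(p = 0.5) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    abort_invalid("p must be a single number in (0, 1)")
  }
  structure(list(mode = "constant", p = p,
                 fn = function(x) rep(p, nrow(x))),
            class = "ite_weight")
}

#' @rdname weight_constant
#' @export
weight_propensity <- function(data, num_trees = 500L, eps = 0.01, seed = NULL) {
  assert_survival_data(data)
  if (length(unique(data$z)) < 2L) abort_invalid("both arms required to estimate the propensity score")
  x <- covariate_cols(data)
  fit <- with_seed(seed %||% 1L,
    randomForest::randomForest(x = as.data.frame(x), y = factor(data$z, levels = c(0, 1)),
                               ntree = num_trees)
  )
  fn <- function(newx) {
    g <- stats::predict(fit, newdata = as.data.frame(newx), type = "prob")[, "1"]
    pmin(pmax(as.numeric(g), eps), 1 - eps)
  }
  structure(list(mode = "estimated", fit = fit, fn = fn), class = "ite_weight")
}

eval_weight <- function(weight, x) {
  g <- weight$fn(x)
  if (any(g <= 0 | g >= 1)) rlang::abort("weights must lie strictly in (0, 1)",
                                         class = "survite_invalid_weight")
  g
}

fit_arm_models <- function(data, spec, seed = NULL) {
  assert_survival_data(data)
  if (!any(data$z == 0) || !any(data$z == 1)) {
    abort_fit_failure("both treatment arms must be present in the training data")
  }
  list(
    m0 = fit_base_learner(spec, dplyr::filter(data, .data$z == 0), arm = 0,
                          seed = if (is.null(seed)) NULL else derive_seed(seed, 10)),
    m1 = fit_base_learner(spec, dplyr::filter(data, .data$z == 1), arm = 1,
                          seed = if (is.null(seed)) NULL else derive_seed(seed, 11))
  )
}

new_ite_result <- function(theta, horizon, meta, spec, newdata, models = NULL,
                           extra = list()) {
  res <- tibble::tibble(
    id = if ("id" %in% names(newdata)) newdata$id else seq_along(theta),
    theta_hat = as.numeric(theta),
    recommendation = recommend(theta)
  )
  structure(c(list(ite = res, horizon = horizon, meta = meta,
                   base_learner = spec$label, models = models), extra),
            class = "survite_ite")
}

#' @export
print.survite_ite <- function(x, ...) {
  cat("<survite_ite>", x$meta, "with", x$base_learner, "base learner\n",
      " horizon t* =", signif(x$horizon, 4), "; n =", nrow(x$ite),
      "; RT fraction =", round(mean(x$ite$recommendation == "RT"), 3), "\n")
  invisible(x)
}

#' T-learner for survival ITE
#'
#' Fits one base learner per arm (the treatment indicator is not a
#' covariate) and estimates the individualized treatment effect at the
#' horizon as the difference of predicted survival probabilities,
#' theta_hat(t*) = S1_hat(t* | x) - S0_hat(t* | x), for every row of
#' `newdata`.
#'
#' @param data two-arm training data (`z`, `y`, `delta`, covariates).
#' @param spec a base-learner specification, see [base_learners].
#' @param horizon time of interest t*.
#' @param newdata covariate table to score; defaults to the training
#'   covariates.
#' @param seed seed passed to the base learners.
#' @return A `survite_ite` object; `tidy()` returns the per-subject
#'   table `id, theta_hat, recommendation`.
#' @examples
#' cfg <- scenario_config("weibull", 1, "balanced", n_train = 300, seed = 2)
#' dat <- simulate_dataset(cfg, n = 300, horizon = 15, censor_rate = 0.02)
#' fit <- t_learner(dat, learner_oracle("weibull", 1), horizon = 15)
#' head(tidy(fit))
#' @export
t_learner <- function(data, spec, horizon, newdata = NULL, seed = NULL) {
  newdata <- newdata %||% data
  models <- fit_arm_models(data, spec, seed = seed)
  s1 <- predict_survival(models$m1, newdata, horizon)
  s0 <- predict_survival(models$m0, newdata, horizon)
  new_ite_result(s1 - s0, horizon, "t_learner", spec, newdata, models)
}

#' X-learner stage 1: imputed effect differences
#'
#' Fits the arm-specific base learners and evaluates the T-learner-type
#' difference D_i(t*) = S1_hat(t* | x_i) - S0_hat(t* | x_i) at every
#' training subject. Because the outcome is censored, both the factual
#' and the counterfactual survival probabilities are estimated.
#'
#' @inheritParams t_learner
#' @return A list with `models` and a tibble `d` (`id`, `z`, `d_tilde`).
#' @export
x_learner_stage1 <- function(data, spec, horizon, seed = NULL) {
  models <- fit_arm_models(data, spec, seed = seed)
  s1 <- predict_survival(models$m1, data, horizon)
  s0 <- predict_survival(models$m0, data, horizon)
  structure(list(models = models,
                 d = tibble::tibble(id = data$id %||% seq_len(nrow(data)),
                                    z = data$z, d_tilde = s1 - s0)),
            class = "x_stage1")
}

#' Stage-2 regressor specifications
#'
#' The X-learner's second stage regresses the stage-1 differences on
#' covariates within each arm; any regressor for continuous outcomes is
#' admissible. `stage2_gbm()` is the default: gradient-boosted trees
#' with 1000 trees, depth 6, minimum terminal node size 10 and subsample
#' fraction 0.8 (shrinkage 0.1). `stage2_lm()` is a linear least-squares
#' alternative, useful when the effect surface is (near-)linear or for
#' fast checks.
#'
#' @param nrounds,max_depth,min_child_weight,subsample,eta boosting
#'   parameters.
#' @return A stage-2 specification consumed by [x_learner_stage2()].
#' @export
stage2_gbm <- function(nrounds = 1000L, max_depth = 6L, min_child_weight = 10,
                       subsample = 0.8, eta = 0.1) {
  structure(list(kind = "gbm", nrounds = nrounds, max_depth = max_depth,
                 min_child_weight = min_child_weight, subsample = subsample,
                 eta = eta),
            class = c("stage2_gbm", "stage2_spec"))
}

#' @rdname stage2_gbm
#' @export
stage2_lm <- function() {
  structure(list(kind = "lm"), class = c("stage2_lm", "stage2_spec"))
}

#' Fit or predict a stage-2 CATE regressor
#'
#' Low-level generics behind [x_learner_stage2()]: `fit_stage2()` fits a
#' stage-2 specification on one arm's (covariates, differences) pairs
#' and `predict_stage2()` evaluates the fitted regressor at new
#' covariates.
#'
#' @param spec a stage-2 specification, see [stage2_gbm()].
#' @param x covariate data frame.
#' @param d stage-1 difference values.
#' @param seed seed for stochastic regressors.
#' @param object a fitted stage-2 regressor.
#' @return `fit_stage2()` a fitted regressor; `predict_stage2()` a
#'   numeric vector.
#' @export
fit_stage2 <- function(spec, x, d, seed = NULL) UseMethod("fit_stage2")

#' @export
fit_stage2.stage2_gbm <- function(spec, x, d, seed = NULL) {
  if (nrow(x) < spec$min_child_weight) {
    abort_fit_failure("arm too small for the stage-2 regressor")
  }
  xm <- as.matrix(x)
  fit <- xgboost::xgboost(
    xm, d,
    objective = "reg:squarederror",
    nrounds = spec$nrounds,
    max_depth = spec$max_depth,
    learning_rate = spec$eta,
    min_child_weight = spec$min_child_weight,
    subsample = spec$subsample,
    nthreads = 1,
    seed = seed %||% 1L,
    verbosity = 0
  )
  structure(list(fit = fit, covars = colnames(x), settings = unclass(spec)),
            class = "stage2_fit_gbm")
}

#' @export
fit_stage2.stage2_lm <- function(spec, x, d, seed = NULL) {
  df <- data.frame(d = d, x)
  structure(list(fit = stats::lm(d ~ ., data = df), covars = colnames(x),
                 settings = unclass(spec)),
            class = "stage2_fit_lm")
}

#' @rdname fit_stage2
#' @export
predict_stage2 <- function(object, x) UseMethod("predict_stage2")

#' @export
predict_stage2.stage2_fit_gbm <- function(object, x) {
  as.numeric(stats::predict(object$fit, newdata = as.matrix(x[object$covars])))
}

#' @export
predict_stage2.stage2_fit_lm <- function(object, x) {
  as.numeric(stats::predict(object$fit, newdata = as.data.frame(x)))
}

#' X-learner stage 2: arm-wise CATE regressions
#'
#' Regresses the stage-1 differences on covariates separately within the
#' treated and control arms, giving two CATE estimators
#' theta_hat_z1(t*, x) (fit on treated subjects) and theta_hat_z0(t*, x)
#' (fit on controls).
#'
#' @param stage1 result of [x_learner_stage1()], or a tibble with
#'   columns `z` and `d_tilde`.
#' @param data the training data (covariates are taken from here).
#' @param stage2 a stage-2 specification, see [stage2_gbm()].
#' @param seed seed for the regressors.
#' @return List with elements `reg0`, `reg1`.
#' @export
x_learner_stage2 <- function(stage1, data, stage2 = stage2_gbm(), seed = NULL) {
  d <- if (inherits(stage1, "x_stage1")) stage1$d else stage1
  x <- covariate_cols(data)
  if (!any(d$z == 0) || !any(d$z == 1)) abort_fit_failure("both arms required in stage 2")
  list(
    reg0 = fit_stage2(stage2, x[d$z == 0, , drop = FALSE], d$d_tilde[d$z == 0],
                      seed = if (is.null(seed)) NULL else derive_seed(seed, 20)),
    reg1 = fit_stage2(stage2, x[d$z == 1, , drop = FALSE], d$d_tilde[d$z == 1],
                      seed = if (is.null(seed)) NULL else derive_seed(seed, 21))
  )
}

#' Combine the X-learner CATE estimates
#'
#' Convex combination theta_hat(t*, x) = g(x) theta_hat_z0(t*, x) +
#' (1 - g(x)) theta_hat_z1(t*, x): the estimator fitted on controls gets
#' weight g(x) and the one fitted on treated subjects gets 1 - g(x).
#' The combined value is not re-clipped to `[-1, 1]`; stage-2
#' regressions may exceed the probability-difference range slightly.
#'
#' @param pred0,pred1 predictions of the control-arm and treated-arm
#'   stage-2 regressors at the target covariates.
#' @param g weights in (0, 1), one per subject (or a single constant).
#' @return Combined ITE estimates.
#' @export
combine_x_learner <- function(pred0, pred1, g) {
  if (length(g) == 1L) g <- rep(g, length(pred0))
  if (length(pred0) != length(pred1) || length(g) != length(pred0)) {
    abort_invalid("pred0, pred1 and g must have equal lengths")
  }
  if (any(g <= 0 | g >= 1)) rlang::abort("weights must lie strictly in (0, 1)",
                                         class = "survite_invalid_weight")
  g * pred0 + (1 - g) * pred1
}

#' X-learner for survival ITE
#'
#' Two-step meta-algorithm: stage 1 computes imputed effect differences
#' D_i(t*) from arm-specific base learners at every training subject;
#' stage 2 regresses D on covariates within each arm; the two resulting
#' CATE estimates are convexly combined with a weight function g(x)
#' (the randomization probability, or an estimated propensity score).
#' No sample splitting is performed between the stages.
#'
#' @inheritParams t_learner
#' @param weight an `ite_weight`, see [weight_constant()].
#' @param stage2 a stage-2 regressor specification, see [stage2_gbm()].
#' @return A `survite_ite` object.
#' @export
x_learner <- function(data, spec, horizon, newdata = NULL,
                      weight = weight_constant(0.5), stage2 = stage2_gbm(),
                      seed = NULL) {
  newdata <- newdata %||% data
  s1res <- x_learner_stage1(data, spec, horizon, seed = seed)
  regs <- x_learner_stage2(s1res, data, stage2 = stage2, seed = seed)
  xnew <- covariate_cols(newdata)
  g <- eval_weight(weight, xnew)
  theta <- combine_x_learner(predict_stage2(regs$reg0, xnew),
                             predict_stage2(regs$reg1, xnew), g)
  new_ite_result(theta, horizon, "x_learner", spec, newdata,
                 models = s1res$models,
                 extra = list(stage2 = regs, weight_mode = weight$mode))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname t_learner
#' @param x a `survite_ite` object.
#' @param ... unused.
#' @export
tidy.survite_ite <- function(x, ...) x$ite

#' @rdname t_learner
#' @export
glance.survite_ite <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$ite),
    horizon = x$horizon,
    meta = x$meta,
    base_learner = x$base_learner,
    mean_theta = mean(x$ite$theta_hat),
    prop_rt = mean(x$ite$recommendation == "RT")
  )
}
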