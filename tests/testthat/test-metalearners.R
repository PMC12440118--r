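test_that("recommendation rule sends non-positive effects to control", {
  expect_equal(as.character(recommend(c(0.2, 0, -0.1))), c("RT", "RC", "RC"))
  expect_true(all(recommend(runif(20, 0.01, 1)) == "RT"))
})

test_that("negating estimates flips labels except at exact zero", {
  th <- c(-0.3, 0, 0.4, 0.1)
  a <- recommend(th)
  b <- recommend(-th)
  nz <- th != 0
  expect_true(all(a[nz] != b[nz]))
  expect_true(all(a[!nz] == "RC" & b[!nz] == "RC"))
})

test_that("T-learner estimates a null effect as approximately zero", {
  dat <- null_effect_data(3000, seed = 12)
  tstar <- median(dat$y)
  # identity basis: same parametric family fit on each (identical) arm
  spec <- learner_oracle("weibull", basis0 = function(x) as.matrix(x),
                         basis1 = function(x) as.matrix(x))
  fit <- t_learner(dat, spec, horizon = tstar)
  expect_lt(abs(mean(fit$ite$theta_hat)), 0.02)
  expect_true(all(abs(fit$ite$theta_hat) <= 1))
})

test_that("oracle T-learner recovers the true ITE closely at n = 5000", {
  cfg <- quick_config()
  p <- cell_params(cfg)
  train <- quick_data(5000, cfg, seed = 101)
  test <- quick_data(4000, cfg, seed = 102)
  fit <- t_learner(train, learner_oracle("weibull", 1), horizon = p$horizon,
                   newdata = test)
  rmse <- sqrt(mean((fit$ite$theta_hat - test$theta_true)^2))
  expect_lt(rmse, 0.03)
})

test_that("stage-1 differences equal the T-learner at the training points", {
  cfg <- quick_config()
  p <- cell_params(cfg)
  train <- quick_data(600, cfg, seed = 103)
  s1 <- x_learner_stage1(train, learner_oracle("weibull", 1), p$horizon)
  tl <- t_learner(train, learner_oracle("weibull", 1), horizon = p$horizon)
  expect_equal(s1$d$d_tilde, tl$ite$theta_hat)
  expect_true(all(abs(s1$d$d_tilde) <= 1))
  s1b <- x_learner_stage1(train, learner_oracle("weibull", 1), p$horizon)
  expect_equal(s1$d, s1b$d)
})

test_that("stage-2 regressors reproduce a constant and a linear surface", {
  x <- simulate_covariates(2000, seed = 31)
  dat <- dplyr::bind_cols(tibble::tibble(id = 1:2000, z = rep(0:1, 1000),
                                         y = 1, delta = 1L), x)
  # constant differences -> both regressors predict the constant
  d_const <- tibble::tibble(id = dat$id, z = dat$z, d_tilde = rep(0.37, 2000))
  regs <- x_learner_stage2(d_const, dat, stage2 = stage2_gbm(nrounds = 50), seed = 1)
  held <- simulate_covariates(200, seed = 32)
  expect_equal(predict_stage2(regs$reg0, held), rep(0.37, 200), tolerance = 1e-3)
  expect_equal(predict_stage2(regs$reg1, held), rep(0.37, 200), tolerance = 1e-3)
  # noiseless linear surface, treated-arm fit generalizes
  d_lin <- tibble::tibble(id = dat$id, z = dat$z, d_tilde = 0.8 * x$x1)
  regs2 <- x_learner_stage2(d_lin, dat, stage2 = stage2_gbm(), seed = 1)
  truth <- 0.8 * held$x1
  pred <- predict_stage2(regs2$reg1, held)
  r2 <- 1 - sum((pred - truth)^2) / sum((truth - mean(truth))^2)
  expect_gt(r2, 0.9)
})

test_that("X-learner combination obeys its algebra exactly", {
  p0 <- c(0.1, -0.2, 0.5)
  p1 <- c(0.3, 0.0, -0.1)
  expect_identical(combine_x_learner(p0, p1, 0.5), (p0 + p1) / 2)
  expect_equal(combine_x_learner(p0, p1, 1 - 1e-12), p0, tolerance = 1e-9)
  expect_equal(combine_x_learner(p0, p0, 0.77), p0, tolerance = 1e-14)
  g <- c(0.2, 0.5, 0.9)
  comb <- combine_x_learner(p0, p1, g)
  expect_true(all(comb >= pmin(p0, p1) & comb <= pmax(p0, p1)))
  expect_error(combine_x_learner(p0, p1, 1.2), class = "survite_invalid_weight")
  expect_error(combine_x_learner(p0, p1, 0), class = "survite_invalid_weight")
})

test_that("X-learner output is constant when stage-1 differences are constant", {
  cfg <- quick_config()
  p <- cell_params(cfg)
  train <- quick_data(600, cfg, seed = 104)
  const_d <- tibble::tibble(id = train$id, z = train$z,
                            d_tilde = rep(0.25, nrow(train)))
  regs <- x_learner_stage2(const_d, train, stage2 = stage2_lm())
  held <- simulate_covariates(100, seed = 105)
  th <- combine_x_learner(predict_stage2(regs$reg0, held),
                          predict_stage2(regs$reg1, held),
                          runif(100, 0.05, 0.95))
  expect_equal(th, rep(0.25, 100), tolerance = 1e-10)
})

test_that("weight functions return valid probabilities", {
  w <- weight_constant(0.5)
  x <- simulate_covariates(10, seed = 1)
  expect_identical(w$fn(x), rep(0.5, 10))
  expect_error(weight_constant(1.5), class = "survite_invalid_argument")
  expect_error(weight_constant(0), class = "survite_invalid_argument")

  cfg <- scenario_config("weibull", 1, "dependent")
  dat <- quick_data(5000, cfg, seed = 106)
  wp <- weight_propensity(dat, num_trees = 300, seed = 2)
  held <- simulate_covariates(1000, seed = 107)
  g <- wp$fn(held)
  expect_true(all(g > 0 & g < 1))
  truth <- plogis(1.3 * held$x1 - 0.8 * held$x5)
  expect_gt(cor(g, truth, method = "spearman"), 0.5)
})

test_that("end-to-end X-learner with estimated propensity runs on the dependent design", {
  cfg <- scenario_config("weibull", 1, "dependent")
  p <- cell_params(cfg)
  train <- quick_data(800, cfg, seed = 108)
  test <- quick_data(500, cfg, seed = 109)
  fit <- x_learner(train, learner_oracle("weibull", 1), p$horizon,
                   newdata = test,
                   weight = weight_propensity(train, num_trees = 200, seed = 3),
                   stage2 = stage2_lm(), seed = 4)
  expect_equal(nrow(fit$ite), 500)
  expect_lt(sqrt(mean((fit$ite$theta_hat - test$theta_true)^2)), 0.15)
})

test_that("one-arm training data is rejected", {
  dat <- dplyr::mutate(quick_data(100, seed = 9), z = 1L)
  expect_error(t_learner(dat, learner_oracle("weibull", 1), 10),
               class = "survite_fit_failure")
})
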