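test_that("covariates have the stated marginal distributions", {
  x <- simulate_covariates(1e5, seed = 42)
  expect_equal(mean(x$x1), 0, tolerance = 0.01)
  expect_equal(sd(x$x1), 0.35, tolerance = 0.01)
  expect_equal(mean(x$x9), 0.5, tolerance = 0.01)
  expect_true(all(unlist(x[c("x8", "x9", "x10")]) %in% c(0, 1)))
  expect_error(simulate_covariates(0), class = "survite_invalid_argument")
})

test_that("covariate draws are deterministic and prefix-stable in n", {
  a <- simulate_covariates(500, seed = 7)
  b <- simulate_covariates(500, seed = 7)
  expect_identical(a, b)
  big <- simulate_covariates(800, seed = 7)
  expect_identical(a, big[1:500, ])
})

test_that("treatment assignment matches each design's allocation", {
  x <- simulate_covariates(1e5, seed = 11)
  zb <- assign_treatment(x, "balanced", seed = 1)
  expect_equal(mean(zb), 0.5, tolerance = 0.01)
  zu <- assign_treatment(x, "unbalanced", seed = 1)
  expect_lt(abs(mean(zu) - 0.05), 0.005)
  zd <- assign_treatment(x, "dependent", seed = 1)
  expect_equal(mean(zd), 0.5, tolerance = 0.01)
  # dependent assignment actually follows the covariates
  p_true <- plogis(1.3 * x$x1 - 0.8 * x$x5)
  expect_gt(cor(zd, p_true), 0.1)
  expect_error(assign_treatment(x, "adaptive"))
})

test_that("dependent-design intercept solves to 0 for a 1:1 allocation", {
  expect_equal(solve_dependent_intercept(0.5, n = 2e4), 0, tolerance = 0.02)
})

test_that("h functions evaluate to the printed coefficients", {
  x1 <- tibble::tibble(x1 = 1, x2 = 1, x3 = 0, x4 = 0, x5 = 0, x6 = 0,
                       x7 = 0, x8 = 0, x9 = 1, x10 = 0)
  expect_equal(h_function(x1, 0, 1), 0.2 + 0.7 + 0.4)
  x0 <- dplyr::mutate(x1, dplyr::across(dplyr::everything(), ~0))
  expect_equal(h_function(x0, 1, 1), 0)
  x2 <- dplyr::mutate(x0, x2 = 1)
  expect_equal(h_function(x2, 1, 2), -0.05 - 0.2)
  # scenario 3 arm-specific extra terms
  x3 <- dplyr::mutate(x0, x3 = 1, x4 = 2, x8 = 1)
  expect_equal(h_function(x3, 0, 3), 0.6 - 0.5 * 4 + 0.6)
  x5 <- dplyr::mutate(x0, x5 = 1, x6 = pi / 2, x10 = 1)
  expect_equal(h_function(x5, 1, 3), -0.05 - 0.1 * exp(1) + 0.7 + 0.5)
})

test_that("true survival matches the closed forms", {
  cfg <- quick_config()
  x0 <- simulate_covariates(1, seed = 1) |>
    dplyr::mutate(dplyr::across(dplyr::everything(), ~0))
  expect_equal(true_survival(0, x0, 0, cfg), 1)
  expect_equal(true_survival(18, x0, 0, cfg), exp(-1))
  expect_equal(true_survival(10, x0, 0, cfg), exp(-(10 / 18)^2))
  expect_equal(true_survival(10, x0, 1, cfg), exp(-(10 / 20)^2))
  expect_equal(true_ite(10, x0, cfg),
               exp(-(10 / 20)^2) - exp(-(10 / 18)^2), tolerance = 1e-12)
  cfl <- quick_config("loglogistic")
  # median of a log-logistic is exp(h), for any sigma
  expect_equal(true_survival(1, x0, 0, cfl), 0.5)
  expect_equal(true_survival(1, x0, 1, cfl), 0.5)
  expect_equal(true_survival(0, x0, 1, cfl), 1)
  expect_error(true_survival(-1, x0, 0, cfg), class = "survite_invalid_argument")
})

test_that("event-time sampling inverts the survival function", {
  cfg <- quick_config()
  x0 <- simulate_covariates(1, seed = 1) |>
    dplyr::mutate(dplyr::across(dplyr::everything(), ~0))
  expect_equal(sample_event_time(exp(-1), x0, 0, cfg), 18)
  cfl <- quick_config("loglogistic")
  expect_equal(sample_event_time(0.5, x0, 1, cfl), 1)
  expect_error(sample_event_time(1.2, x0, 0, cfg), class = "survite_invalid_argument")

  # round trip identity across families, scenarios, arms, random x and u
  set.seed(99)
  for (fam in c("weibull", "loglogistic")) {
    for (sc in 1:3) {
      cfgi <- scenario_config(fam, sc, "balanced")
      x <- simulate_covariates(200, seed = sc)
      for (arm in 0:1) {
        u <- runif(200, 0.001, 0.999)
        tt <- sample_event_time(u, x, arm, cfgi)
        expect_lt(max(abs(true_survival(tt, x, arm, cfgi) - u)), 1e-10)
      }
    }
  }
})

test_that("censoring calibration hits the 30% target on independent draws", {
  cfg <- quick_config()
  rho <- calibrate_censoring(cfg)
  expect_equal(attr(rho, "achieved"), 0.30, tolerance = 0.005)
  dat <- simulate_dataset(cfg, n = 1e5, seed = 2024, horizon = 10,
                          censor_rate = as.numeric(rho))
  expect_equal(1 - mean(dat$delta), 0.30, tolerance = 0.01)
  # monotone: smaller target -> smaller rate
  cfg_lo <- scenario_config("weibull", 1, "balanced", target_censor_rate = 0.1)
  expect_lt(as.numeric(calibrate_censoring(cfg_lo)), as.numeric(rho))
  expect_identical(as.numeric(calibrate_censoring(cfg)), as.numeric(rho))
})

test_that("calibration holds across families and designs", {
  for (fam in c("weibull", "loglogistic")) {
    for (des in c("unbalanced", "dependent")) {
      cfg <- scenario_config(fam, 2, des)
      rho <- calibrate_censoring(cfg, n_cal = 5e4)
      dat <- simulate_dataset(cfg, n = 5e4, seed = 321, horizon = 1,
                              censor_rate = as.numeric(rho))
      expect_equal(1 - mean(dat$delta), 0.30, tolerance = 0.012)
    }
  }
})

test_that("simulated datasets satisfy consistency and ITE range", {
  cfg <- quick_config()
  dat <- quick_data(5000, cfg, seed = 5)
  tz <- ifelse(dat$z == 1, dat$t1, dat$t0)
  expect_identical(dat$y[dat$delta == 1], tz[dat$delta == 1])
  expect_identical(dat$y[dat$delta == 0], dat$c[dat$delta == 0])
  expect_true(all(abs(dat$theta_true) <= 1))
  x <- dat[paste0("x", 1:10)]
  expect_equal(true_ite(0, x, cfg), rep(0, nrow(dat)))
  expect_identical(quick_data(5000, cfg, seed = 5), dat)
})

test_that("horizon quantiles are monotone and stable across reference seeds", {
  cfg <- quick_config()
  q25 <- median_horizon(cfg, quantile = 0.25)
  q50 <- median_horizon(cfg, quantile = 0.5)
  q75 <- median_horizon(cfg, quantile = 0.75)
  expect_true(q25 <= q50 && q50 <= q75)
  alt <- median_horizon(cfg, ref_seed = 20250101L)
  expect_equal(alt, q50, tolerance = 0.01)
})
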