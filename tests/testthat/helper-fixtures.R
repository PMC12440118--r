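# shared fixtures: cache the per-cell horizon and censoring rate so each
# test file pays the reference-simulation cost at most once per cell
.cell_cache <- new.env(parent = emptyenv())

cell_params <- function(config) {
  key <- paste(config$family, config$scenario, config$design, sep = "_")
  if (is.null(.cell_cache[[key]])) {
    .cell_cache[[key]] <- list(
      horizon = median_horizon(config),
      censor_rate = as.numeric(calibrate_censoring(config))
    )
  }
  .cell_cache[[key]]
}

quick_config <- function(family = "weibull", scenario = 1, design = "balanced",
                         seed = 1) {
  scenario_config(family, scenario, design, seed = seed)
}

# simulated dataset with the cell's calibrated censoring and horizon
quick_data <- function(n, config = quick_config(), seed = 1) {
  p <- cell_params(config)
  simulate_dataset(config, n = n, seed = seed, horizon = p$horizon,
                   censor_rate = p$censor_rate)
}

# two-arm data with no covariate effect on survival (null DGP)
null_effect_data <- function(n, seed = 1, censor_rate = 0.02) {
  set.seed(seed)
  x <- simulate_covariates(n, seed = seed)
  z <- stats::rbinom(n, 1, 0.5)
  tt <- stats::rweibull(n, shape = 2, scale = 19)
  cc <- stats::rexp(n, censor_rate)
  tibble::tibble(id = seq_len(n), z = z, y = pmin(tt, cc),
                 delta = as.integer(tt <= cc)) |>
    dplyr::bind_cols(x)
}
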