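#' Describe a method cell (meta-learner + base learner)
#'
#' @param meta `"t"` or `"x"`.
#' @param base a base-learner specification, see [base_learners].
#' @param label column label in summary tables; defaults to
#'   `<meta>-<base>`.
#' @param weight X-learner weight (defaults to the known randomization
#'   probability 0.5 under the balanced design).
#' @param stage2 X-learner stage-2 regressor.
#' @return A `method_spec` object.
#' @export
method_spec <- function(meta = c("t", "x"), base, label = NULL,
                        weight = weight_constant(0.5), stage2 = stage2_gbm()) {
  meta <- match.arg(meta)
  structure(list(meta = meta, base = base,
                 label = label %||% paste0(toupper(meta), "-", base$label),
                 weight = weight, stage2 = stage2),
            class = "method_spec")
}

fit_method <- function(method, train, horizon, newdata, seed) {
  if (method$meta == "t") {
    t_learner(train, method$base, horizon, newdata = newdata, seed = seed)
  } else {
    x_learner(train, method$base, horizon, newdata = newdata,
              weight = method$weight, stage2 = method$stage2, seed = seed)
  }
}

#' Run replicated simulations for one method cell
#'
#' For each replicate: simulate fresh training and test datasets from
#' seeds derived from the master seed, estimate the ITE on the test
#' population at the horizon, and compute bias, quantile-binned RMSE and
#' the six recommendation metrics against the true ITE. Replicate
#' failures are recorded (metrics `NA`) rather than aborting, unless
#' more than 20% of replicates fail.
#'
#' @param config a [scenario_config()].
#' @param method a [method_spec()].
#' @param B number of replicates.
#' @param seed master seed.
#' @param n_train,n_test sample sizes (default from `config`).
#' @param Q quantile bins for the binned RMSE.
#' @param horizon,censor_rate precomputed t* and censoring rate; derived
#'   from `config` when `NULL` (fixed internal reference seeds, so they
#'   do not vary with `seed`).
#' @return A tibble with one row per replicate: seeds, `bias`, `rmse`
#'   and the recommendation metrics (proportions).
#' @export
run_cell <- function(config, method, B = 100L, seed = config$seed,
                     n_train = config$n_train, n_test = config$n_test,
                     Q = 50L, horizon = NULL, censor_rate = NULL) {
  if (B < 1) abort_invalid("B must be >= 1")
  horizon <- horizon %||% median_horizon(config)
  censor_rate <- censor_rate %||% as.numeric(calibrate_censoring(config))
  rows <- purrr::map(seq_len(B), function(b) {
    train_seed <- derive_seed(seed, 3L * b)
    test_seed <- derive_seed(seed, 3L * b + 1L)
    fit_seed <- derive_seed(seed, 3L * b + 2L)
    out <- tryCatch({
      train <- simulate_dataset(config, n = n_train, seed = train_seed,
                                horizon = horizon, censor_rate = censor_rate)
      test <- simulate_dataset(config, n = n_test, seed = test_seed,
                               horizon = horizon, censor_rate = censor_rate)
      fit <- fit_method(method, train, horizon, newdata = test, seed = fit_seed)
      th <- fit$ite$theta_hat
      cm <- confusion_metrics(th, test$theta_true)
      dplyr::bind_cols(
        tibble::tibble(replicate = b, seed = train_seed, failed = FALSE,
                       bias = ite_bias(th, test$theta_true),
                       rmse = binned_rmse(th, test$theta_true, Q = Q),
                       censor_obs = 1 - mean(train$delta)),
        cm
      )
    }, error = function(e) {
      tibble::tibble(replicate = b, seed = train_seed, failed = TRUE,
                     bias = NA_real_, rmse = NA_real_, censor_obs = NA_real_)
    })
    out
  })
  res <- dplyr::bind_rows(rows)
  if (mean(res$failed) > 0.2) {
    rlang::abort(paste0("more than 20% of replicates failed for method ",
                        method$label), class = "survite_batch_failure")
  }
  res$method <- method$label
  attr(res, "horizon") <- horizon
  attr(res, "censor_rate") <- censor_rate
  res
}

# canonical column order of the summary tables
method_order <- function(labels) {
  canon <- c("R-T", "R-X", "B-T", "B-X", "D-T", "D-X", "CSF",
             "Weib", "Logistic")
  c(intersect(canon, labels), setdiff(labels, canon))
}

#' Run a full methods-by-metrics summary table
#'
#' Runs [run_cell()] for every method and formats the six
#' recommendation metrics (as percentages) plus bias and binned RMSE as
#' `"mean (SD)"` strings, methods as columns in the canonical order.
#'
#' @inheritParams run_cell
#' @param methods list of [method_spec()]s.
#' @return A list with `records` (long per-replicate tibble) and `table`
#'   (wide formatted tibble).
#' @export
run_table <- function(config, methods, B = 100L, seed = config$seed, ...) {
  if (length(methods) < 1L) abort_invalid("need at least one method")
  horizon <- median_horizon(config)
  censor_rate <- as.numeric(calibrate_censoring(config))
  records <- purrr::map_dfr(methods, function(m) {
    run_cell(config, m, B = B, seed = seed,
             horizon = horizon, censor_rate = censor_rate, ...)
  })
  pct <- c("acc", "ppv", "npv", "sensitivity", "specificity", "f_score")
  long <- records |>
    dplyr::select(dplyr::all_of(c("method", "replicate", "bias", "rmse", pct))) |>
    tidyr::pivot_longer(-c("method", "replicate"),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(value = ifelse(.data$metric %in% pct,
                                 .data$value * 100, .data$value),
                  scenario = config$scenario)
  agg <- aggregate_replicates(long)
  labels <- method_order(unique(agg$method))
  metrics <- c(pct, "bias", "rmse")
  tab <- agg |>
    dplyr::mutate(method = factor(.data$method, levels = labels),
                  metric = factor(.data$metric, levels = metrics)) |>
    dplyr::arrange(.data$metric, .data$method) |>
    dplyr::select(dplyr::all_of(c("scenario", "metric", "method", "label"))) |>
    tidyr::pivot_wider(names_from = "method", values_from = "label")
  list(records = records, table = tab, horizon = horizon,
       censor_rate = censor_rate)
}

#' Cross-validated ITE estimation
#'
#' Splits the data into K folds stratified on treatment; each subject's
#' ITE is predicted by a model trained on the other folds, so no subject
#' is scored by a model that saw them. Returns a `survite_ite` covering
#' all subjects.
#'
#' @param data two-arm survival data with an `id` column.
#' @param method a [method_spec()].
#' @param horizon time of interest t*.
#' @param K number of folds (default 4).
#' @param seed seed for the fold split and fits.
#' @return A `survite_ite` with per-subject out-of-fold estimates and a
#'   `fold` column in the tidy table.
#' @export
cross_validated_ite <- function(data, method, horizon, K = 4L, seed = 1L) {
  assert_survival_data(data)
  if (K < 2) abort_invalid("K must be >= 2")
  if (!"id" %in% names(data)) data$id <- seq_len(nrow(data))
  folds <- integer(nrow(data))
  folds[data$z == 1] <- with_seed(derive_seed(seed, 1),
    sample(rep_len(seq_len(K), sum(data$z == 1))))
  folds[data$z == 0] <- with_seed(derive_seed(seed, 2),
    sample(rep_len(seq_len(K), sum(data$z == 0))))
  res <- purrr::map_dfr(seq_len(K), function(k) {
    train <- data[folds != k, ]
    test <- data[folds == k, ]
    if (!any(train$z == 0) || !any(train$z == 1)) {
      abort_fit_failure("a training split lost an entire arm; reduce K")
    }
    fit <- fit_method(method, train, horizon, newdata = test,
                      seed = derive_seed(seed, 10 + k))
    dplyr::mutate(fit$ite, fold = k)
  })
  res <- dplyr::arrange(res, .data$id)
  structure(list(ite = res, horizon = horizon, meta = method$meta,
                 base_learner = method$base$label, models = NULL,
                 folds = folds),
            class = "survite_ite")
}
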