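#' Mean signed error of ITE estimates
#'
#' Bias = mean(theta_hat - theta_true).
#'
#' @param theta_hat,theta_true estimated and true ITE vectors of equal
#'   length.
#' @return A single number.
#' @export
ite_bias <- function(theta_hat, theta_true) {
  if (length(theta_hat) != length(theta_true) || length(theta_hat) < 1L) {
    abort_invalid("theta_hat and theta_true must be non-empty and of equal length")
  }
  mean(theta_hat - theta_true)
}

#' Quantile-binned root mean squared error
#'
#' Subjects are grouped into Q bins by the sample quantiles (type 7) of
#' the TRUE ITE values; the within-bin mean squared errors are averaged
#' across bins and square-rooted:
#' RMSE = sqrt( (1/Q) sum_q (1/n_q) sum_i (theta_hat_i - theta_i)^2 ).
#' With `Q = 1` this is the ordinary RMSE. Ties at a bin edge fall into
#' the lower bin; bins emptied by duplicated quantiles are dropped.
#'
#' @inheritParams ite_bias
#' @param Q number of quantile bins (default 50).
#' @return A single non-negative number.
#' @export
binned_rmse <- function(theta_hat, theta_true, Q = 50L) {
  if (length(theta_hat) != length(theta_true)) {
    abort_invalid("theta_hat and theta_true must have equal length")
  }
  n <- length(theta_true)
  if (n < Q) abort_invalid("need at least Q observations")
  if (Q < 1) abort_invalid("Q must be >= 1")
  br <- unique(stats::quantile(theta_true, probs = seq(0, 1, length.out = Q + 1),
                               type = 7, names = FALSE))
  if (length(br) < 2L) br <- c(br - 1e-12, br + 1e-12)
  bins <- cut(theta_true, breaks = br, include.lowest = TRUE, right = TRUE)
  se <- (theta_hat - theta_true)^2
  mse_q <- tapply(se, bins, mean)
  sqrt(mean(mse_q, na.rm = TRUE))
}

#' Recommendation-accuracy metrics
#'
#' Classifies each subject's recommended treatment from the estimated
#' ITE (`theta_hat > 0` means recommend treatment) against the gold
#' standard derived from the true ITE (`theta_true > 0`), and reports
#' the confusion counts together with overall accuracy
#' ACC = (TP + TN) / N, PPV = TP / (TP + FP), NPV = TN / (TN + FN),
#' sensitivity = TP / (TP + FN), specificity = TN / (TN + FP) and the
#' F-score 2 / (PPV^-1 + sensitivity^-1). Ratios with a zero denominator
#' are reported as `NA`, not 0.
#'
#' @inheritParams ite_bias
#' @return A one-row tibble with columns `tp, tn, fp, fn, acc, ppv, npv,
#'   sensitivity, specificity, f_score` (proportions in `[0, 1]`).
#' @export
confusion_metrics <- function(theta_hat, theta_true) {
  if (length(theta_hat) != length(theta_true) || length(theta_hat) < 1L) {
    abort_invalid("theta_hat and theta_true must be non-empty and of equal length")
  }
  pred <- theta_hat > 0
  truth <- theta_true > 0
  tp <- sum(pred & truth)
  tn <- sum(!pred & !truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  ppv <- ratio(tp, tp + fp)
  sens <- ratio(tp, tp + fn)
  f <- if (is.na(ppv) || is.na(sens) || (ppv + sens) == 0) {
    if (isTRUE(ppv == 0) || isTRUE(sens == 0)) 0 else NA_real_
  } else {
    2 * ppv * sens / (ppv + sens)
  }
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    acc = (tp + tn) / length(pred),
    ppv = ppv,
    npv = ratio(tn, tn + fn),
    sensitivity = sens,
    specificity = ratio(tn, tn + fp),
    f_score = f
  )
}

km_surv_at <- function(y, delta, t) {
  fit <- survival::survfit(survival::Surv(y, delta) ~ 1)
  summary(fit, times = t, extend = TRUE)$surv
}

#' Kaplan-Meier treatment effect within recommendation cohorts
#'
#' Within each recommendation cohort (RT, RC) and in the whole
#' population, estimates the mean treatment effect at the horizon as the
#' difference of Kaplan-Meier survival estimates between arms,
#' KM_1(t*) - KM_0(t*). A cohort in which either arm lacks an observed
#' event by t* yields `NA` with a warning.
#'
#' @param data two-arm survival data (`z`, `y`, `delta`).
#' @param cohort factor of per-subject recommendation labels (RT/RC).
#' @param horizon evaluation time t*.
#' @return A tibble with one row per cohort plus `"overall"`: `cohort`,
#'   `n`, `surv1`, `surv0`, `effect`.
#' @export
km_cohort_effect <- function(data, cohort, horizon) {
  assert_survival_data(data)
  if (length(cohort) != nrow(data)) abort_invalid("cohort labels must match the data rows")
  cohort <- factor(cohort, levels = c("RC", "RT"))
  groups <- c(stats::setNames(levels(cohort), levels(cohort)), overall = "overall")
  purrr::map_dfr(names(groups), function(gname) {
    idx <- if (gname == "overall") rep(TRUE, nrow(data)) else cohort == gname
    sub <- data[idx, ]
    ok <- function(arm) {
      d <- sub[sub$z == arm, ]
      # KM(t*) is identified if follow-up reaches t* or an event occurs
      # by t*; an arm whose every subject is censored before t* is not
      nrow(d) > 0 &&
        (horizon == 0 || max(d$y) >= horizon || any(d$delta == 1 & d$y <= horizon))
    }
    if (nrow(sub) == 0 || !ok(0) || !ok(1)) {
      if (gname != "overall" || nrow(sub) > 0) {
        rlang::warn(paste0("cohort '", gname, "': an arm has no event before the horizon; effect is NA"))
      }
      return(tibble::tibble(cohort = gname, n = nrow(sub),
                            surv1 = NA_real_, surv0 = NA_real_, effect = NA_real_))
    }
    s1 <- km_surv_at(sub$y[sub$z == 1], sub$delta[sub$z == 1], horizon)
    s0 <- km_surv_at(sub$y[sub$z == 0], sub$delta[sub$z == 0], horizon)
    tibble::tibble(cohort = gname, n = nrow(sub), surv1 = s1, surv0 = s0,
                   effect = s1 - s0)
  })
}

#' Format a mean and standard deviation
#'
#' @param x numeric vector (at least two values).
#' @param digits decimals.
#' @return `"mean (SD)"` string.
#' @export
format_mean_sd <- function(x, digits = 2) {
  x <- x[!is.na(x)]
  sprintf(paste0("%.", digits, "f (%.", digits, "f)"), mean(x), stats::sd(x))
}

#' Aggregate per-replicate metrics into a mean (SD) table
#'
#' Takes a long table of per-replicate metric values and summarizes each
#' method-by-metric cell as `"mean (SD)"` with two decimals, the layout
#' used for the simulation summary tables. `NA` values (undefined ratios
#' in degenerate replicates) are excluded from the summary and counted.
#'
#' @param records long tibble with columns `method`, `metric`, `value`
#'   and one row per replicate (extra grouping columns such as
#'   `scenario` are preserved).
#' @param digits decimals in the formatted label.
#' @return A tibble with `mean`, `sd`, `n_missing` and `label` per group.
#' @export
aggregate_replicates <- function(records, digits = 2) {
  need <- c("method", "metric", "value")
  if (!all(need %in% names(records))) {
    abort_invalid("records must have columns method, metric, value")
  }
  extra <- setdiff(names(records), c(need, "replicate", "seed"))
  grp <- c(extra, "method", "metric")
  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_rep = dplyr::n(),
      n_missing = sum(is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      .groups = "drop"
    )
  if (any(out$n_rep < 2)) abort_invalid("need at least 2 replicates per cell")
  out$label <- sprintf(paste0("%.", digits, "f (%.", digits, "f)"), out$mean, out$sd)
  out
}
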