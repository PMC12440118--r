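#' Read and write trial tables as CSV
#'
#' The on-disk layout is a plain CSV with header
#' `id,z,y,delta,x1,...,x10` and optional oracle columns
#' `t0,t1,c,theta_true` (present only for simulated data).
#'
#' @param data a survival data tibble.
#' @param path file path.
#' @return `read_survival_csv()` returns a validated tibble;
#'   `write_survival_csv()` returns `path` invisibly.
#' @export
write_survival_csv <- function(data, path) {
  assert_survival_data(data)
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_csv
#' @export
read_survival_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path))
  assert_survival_data(out)
  out
}

#' Write per-subject ITE estimates to CSV
#'
#' Columns: `id, theta_hat, recommendation, horizon, meta, base_learner`.
#'
#' @param fit a `survite_ite` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ite_csv <- function(fit, path) {
  stopifnot(inherits(fit, "survite_ite"))
  out <- dplyr::mutate(fit$ite, horizon = fit$horizon, meta = fit$meta,
                       base_learner = fit$base_learner)
  utils::write.csv(as.data.frame(out), path, row.names = FALSE)
  invisible(path)
}

#' Read a simulation configuration from YAML or JSON
#'
#' The file mirrors the [scenario_config()] arguments, e.g.
#' `family: weibull`, `scenario: 1`, `design: balanced`, `seed: 1`.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    abort_invalid(paste0("unknown config fields: ", paste(unknown, collapse = ", ")))
  }
  do.call(scenario_config, cfg)
}
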