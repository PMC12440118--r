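# internal helpers shared across modules

# Deterministic sub-seed derivation. Keeps every derived seed inside the
# 32-bit integer range and never reuses the master seed directly, so the
# component streams (covariates, treatment, event draws, censoring) are
# mutually independent and stable when sample sizes change.
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(k))
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + 1000003 * k) %% 2147483646 + 1)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

abort_invalid <- function(msg) {
  rlang::abort(msg, class = "survite_invalid_argument")
}

abort_fit_failure <- function(msg, parent = NULL) {
  rlang::abort(msg, class = "survite_fit_failure", parent = parent)
}

covariate_names <- function() paste0("x", 1:10)

# extract the covariate block (x1..x10 or whatever x* columns exist)
covariate_cols <- function(data) {
  nm <- grep("^x[0-9]+$", names(data), value = TRUE)
  if (length(nm) == 0L) abort_invalid("no covariate columns (x1, x2, ...) found")
  data[nm]
}

assert_survival_data <- function(data) {
  need <- c("z", "y", "delta")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L) {
    abort_invalid(paste0("missing required columns: ", paste(miss, collapse = ", ")))
  }
  if (any(data$y <= 0)) abort_invalid("observed times must be positive")
  if (!all(data$z %in% c(0, 1))) abort_invalid("treatment indicator must be 0/1")
  if (!all(data$delta %in% c(0, 1))) abort_invalid("event indicator must be 0/1")
  invisible(data)
}
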