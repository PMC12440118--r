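#' Augment features with permuted shadow copies
#'
#' Copies every original column and independently permutes the copy,
#' destroying any association with the outcome while preserving each
#' marginal distribution; the feature count doubles. Shadow columns are
#' named `shadow_<original>`.
#'
#' @param x feature data frame or matrix.
#' @param seed integer seed controlling the shuffles.
#' @return A tibble with the original columns followed by their shadows.
#' @export
make_shadows <- function(x, seed = NULL) {
  x <- tibble::as_tibble(as.data.frame(x))
  if (ncol(x) < 1L) abort_invalid("need at least one feature")
  sh <- with_seed(seed, purrr::map(x, ~ .x[sample.int(length(.x))]))
  names(sh) <- paste0("shadow_", names(x))
  dplyr::bind_cols(x, tibble::as_tibble(sh))
}

#' One Boruta iteration: hit flags against the shadow threshold
#'
#' Trains a random-forest classifier on the shadow-augmented features
#' and computes an importance z-score per feature (permutation
#' importance scaled by its standard error across trees). An original
#' feature scores a "hit" when its z-score exceeds the maximum z-score
#' among all shadow features.
#'
#' @param x_aug shadow-augmented feature table from [make_shadows()].
#' @param labels binary outcome (two classes present).
#' @param num_trees forest size.
#' @param seed seed for the forest.
#' @return Named logical vector of hits for the original features.
#' @export
boruta_iteration <- function(x_aug, labels, num_trees = 500L, seed = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L) abort_invalid("labels must contain exactly two classes")
  is_shadow <- grepl("^shadow_", names(x_aug))
  if (!any(is_shadow)) abort_invalid("x_aug must contain shadow features")
  fit <- with_seed(seed %||% 1L,
    randomForest::randomForest(x = as.data.frame(x_aug), y = labels,
                               ntree = num_trees, importance = TRUE)
  )
  # scale = TRUE divides the mean decrease in accuracy by its SE -> z-score
  zs <- randomForest::importance(fit, type = 1, scale = TRUE)[, 1]
  threshold <- max(zs[is_shadow])
  hits <- zs[!is_shadow] > threshold
  stats::setNames(hits, names(x_aug)[!is_shadow])
}

#' Boruta all-relevant feature selection
#'
#' Iteratively compares each feature's random-forest importance z-score
#' with the best shadow (permuted-copy) feature. Per iteration a feature
#' whose z-score beats the shadow maximum records a hit; after each
#' iteration a two-sided binomial test of the hit count against chance
#' (p = 0.5, Bonferroni-corrected over the original feature count)
#' confirms features with significantly many hits and permanently
#' rejects (removes) features with significantly few. Shadows are
#' regenerated from the remaining features every iteration. Iteration
#' stops when every feature is decided or `max_iterations` is reached;
#' undecided features are reported as tentative.
#'
#' @param x feature data frame (rows = subjects).
#' @param labels binary outcome, e.g. RT/RC recommendation labels.
#' @param max_iterations iteration cap.
#' @param alpha significance level of the binomial decision test.
#' @param num_trees random-forest size per iteration.
#' @param seed master seed; per-iteration seeds are derived from it.
#' @return A `boruta_result`: tibble of `feature`, `decision`
#'   (confirmed / rejected / tentative), `hits`, `iterations`, plus the
#'   per-iteration hit trace in attribute `"trace"`.
#' @examples
#' \donttest{
#' x <- as.data.frame(matrix(rnorm(200 * 5), 200))
#' names(x) <- paste0("f", 1:5)
#' y <- as.integer(x$f1 > 0)
#' boruta_select(x, y, max_iterations = 20, num_trees = 100, seed = 1)
#' }
#' @export
boruta_select <- function(x, labels, max_iterations = 100L, alpha = 0.05,
                          num_trees = 500L, seed = 1L) {
  x <- tibble::as_tibble(as.data.frame(x))
  if (alpha <= 0 || alpha >= 1) abort_invalid("alpha must be in (0, 1)")
  if (max_iterations < 1) abort_invalid("max_iterations must be >= 1")
  features <- names(x)
  d <- length(features)
  alpha_adj <- alpha / (2 * d)   # two-sided + Bonferroni over features
  status <- stats::setNames(rep("tentative", d), features)
  hits <- stats::setNames(rep(0L, d), features)
  iters <- stats::setNames(rep(0L, d), features)
  trace <- list()
  for (it in seq_len(max_iterations)) {
    active <- features[status == "tentative"]
    if (length(active) == 0L) break
    x_aug <- make_shadows(x[active], seed = derive_seed(seed, 2L * it))
    h <- boruta_iteration(x_aug, labels, num_trees = num_trees,
                          seed = derive_seed(seed, 2L * it + 1L))
    hits[active] <- hits[active] + as.integer(h)
    iters[active] <- iters[active] + 1L
    trace[[it]] <- tibble::tibble(iteration = it, feature = active,
                                  hit = unname(h))
    for (f in active) {
      k <- hits[[f]]; m <- iters[[f]]
      p_hi <- stats::pbinom(k - 1L, m, 0.5, lower.tail = FALSE)  # P(X >= k)
      p_lo <- stats::pbinom(k, m, 0.5)                            # P(X <= k)
      if (p_hi < alpha_adj) status[[f]] <- "confirmed"
      else if (p_lo < alpha_adj) status[[f]] <- "rejected"
    }
  }
  res <- tibble::tibble(feature = features,
                        decision = unname(status),
                        hits = unname(hits),
                        iterations = unname(iters))
  structure(list(result = res,
                 trace = dplyr::bind_rows(trace),
                 alpha = alpha, max_iterations = max_iterations),
            class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  cat("<boruta_result>", nrow(x$result), "features,",
      max(x$result$iterations), "iterations\n",
      " confirmed:", sum(x$result$decision == "confirmed"),
      " rejected:", sum(x$result$decision == "rejected"),
      " tentative:", sum(x$result$decision == "tentative"), "\n")
  invisible(x)
}

#' @rdname boruta_select
#' @export
tidy.boruta_result <- function(x, ...) x$result

#' @rdname boruta_select
#' @export
glance.boruta_result <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$result),
    n_confirmed = sum(x$result$decision == "confirmed"),
    n_rejected = sum(x$result$decision == "rejected"),
    n_tentative = sum(x$result$decision == "tentative"),
    iterations = max(x$result$iterations)
  )
}
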