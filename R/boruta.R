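#' Random-forest configuration
#'
#' @param n_trees Number of trees (default 1000).
#' @param mtry_rule Rule for the number of candidate features per split;
#'   only `"sqrt"` (mtry = floor of the square root of the number of input
#'   features) is provided.
#' @param importance Importance measure used for feature/shadow comparisons:
#'   Gini impurity decrease (default) or out-of-bag permutation importance.
#' @param seed RNG seed.
#' @return A list of class `"rf_config"`.
#' @export
rf_config <- function(n_trees = 1000, mtry_rule = "sqrt",
                      importance = c("impurity", "permutation"),
                      seed = NULL) {
  stopifnot(n_trees >= 1)
  mtry_rule <- match.arg(mtry_rule, "sqrt")
  structure(list(n_trees = n_trees, mtry_rule = mtry_rule,
                 importance = match.arg(importance), seed = seed),
            class = "rf_config")
}

# one reshuffled shadow copy per column
shadow_matrix <- function(x) {
  s <- apply(x, 2, sample)
  colnames(s) <- paste0("shadow_", colnames(x))
  s
}

rf_importance <- function(x, y, rf, seed) {
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = rf$n_trees,
    mtry = max(1L, floor(sqrt(ncol(x)))),
    importance = rf$importance,
    num.threads = 1,
    seed = seed
  )
  fit$variable.importance
}

#' All-relevant feature selection with shadow features
#'
#' A Boruta-style selector: the feature table is extended with one
#' independently shuffled "shadow" copy of every still-undecided feature, a
#' random forest is trained on the extended table, and a real feature scores
#' a *hit* in an iteration when its importance strictly exceeds the best
#' shadow importance of that iteration. After every iteration each undecided
#' feature's cumulative hit count is tested against Binomial(iterations,
#' 1/2): an upper-tail probability below the (optionally
#' Bonferroni-corrected) `alpha` confirms the feature, a lower-tail
#' probability below it rejects the feature. Decided features are dropped
#' from subsequent forests; the loop stops when every feature is decided or
#' `max_iter` is reached, leaving the remainder *tentative*.
#'
#' Tentative features are not treated as selected: [selected_features()]
#' returns confirmed features only.
#'
#' @param x Numeric matrix or data frame of features (columns named).
#' @param y Two-level group factor.
#' @param rf An [rf_config()].
#' @param max_iter Maximum number of shadow/importance iterations.
#' @param alpha Two-sided significance level of the binomial hit test
#'   (default 0.01).
#' @param bonferroni Correct `alpha` by the number of currently undecided
#'   features (default `TRUE`).
#' @param seed RNG seed (shadow shuffles and forests).
#'
#' @return A list of class `"boruta_result"`: `decision` (factor
#'   `confirmed`/`tentative`/`rejected` named by feature), `hits` (cumulative
#'   hit counts), `n_iterations_run`, per-feature `n_trials` (iterations in
#'   which the feature was still undecided, hence eligible for hits), and
#'   `importance_history` (per iteration: named real importances and the
#'   shadow importance vector).
#' @export
boruta_select <- function(x, y, rf = rf_config(), max_iter = 100,
                          alpha = 0.01, bonferroni = TRUE,
                          seed = rf$seed) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  stopifnot(nlevels(y) == 2, nrow(x) == length(y), max_iter >= 1,
            !is.null(colnames(x)), ncol(x) >= 2)
  if (ncol(x) < 5) {
    warning("fewer than 5 features: the max-shadow reference is unstable")
  }
  if (!is.null(seed)) set.seed(seed)

  ids <- colnames(x)
  decision <- stats::setNames(rep("tentative", length(ids)), ids)
  hits <- stats::setNames(integer(length(ids)), ids)
  trials <- stats::setNames(integer(length(ids)), ids)
  history <- vector("list", max_iter)

  iter <- 0L
  while (iter < max_iter) {
    und <- ids[decision == "tentative"]
    if (length(und) == 0) break
    iter <- iter + 1L

    xu <- x[, und, drop = FALSE]
    ext <- cbind(xu, shadow_matrix(xu))
    imp <- rf_importance(ext, y, rf,
                         seed = sample.int(.Machine$integer.max, 1))
    real_imp <- imp[und]
    shadow_imp <- imp[setdiff(names(imp), und)]
    hit <- real_imp > max(shadow_imp)
    hits[und] <- hits[und] + hit
    trials[und] <- trials[und] + 1L
    history[[iter]] <- list(real = real_imp, shadow = unname(shadow_imp))

    thr <- if (bonferroni) alpha / length(und) else alpha
    up <- stats::pbinom(hits[und] - 1L, trials[und], 0.5, lower.tail = FALSE)
    lo <- stats::pbinom(hits[und], trials[und], 0.5)
    decision[und[up < thr]] <- "confirmed"
    decision[und[lo < thr]] <- "rejected"
  }

  structure(list(
    decision = factor(decision, levels = c("confirmed", "tentative",
                                           "rejected")),
    hits = hits,
    n_trials = trials,
    n_iterations_run = iter,
    importance_history = history[seq_len(iter)],
    alpha = alpha, bonferroni = bonferroni
  ), class = "boruta_result")
}

#' Features confirmed by an all-relevant selection run
#'
#' @param result A `"boruta_result"`.
#' @return Character vector of confirmed feature ids.
#' @export
selected_features <- function(result) {
  stopifnot(inherits(result, "boruta_result"))
  names(result$decision)[result$decision == "confirmed"]
}

#' @export
print.boruta_result <- function(x, ...) {
  tab <- table(x$decision)
  cat("All-relevant selection:", x$n_iterations_run, "iterations;",
      tab[["confirmed"]], "confirmed,", tab[["rejected"]], "rejected,",
      tab[["tentative"]], "tentative\n")
  invisible(x)
}
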