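#' Estimate the binomial null selection rate from permuted datasets
#'
#' The null per-iteration selection rate `p0` is the grand mean of the
#' per-feature selection frequencies pooled over all features and all
#' label-permuted datasets. Per-permutation means are kept for diagnostics.
#'
#' @param perm_freqs List with one element per permuted dataset, each a
#'   numeric vector of per-feature selection frequencies (as produced by
#'   [selection_frequency()]).
#' @param n_iterations The number of CV iterations (`M`) underlying each
#'   frequency.
#' @return A list of class `"null_model"`: `p0`, `n_iterations`,
#'   `n_permutations`, `per_permutation_mean_freq`, `degenerate` (`TRUE`
#'   when `p0` is exactly 0, which turns downstream p-values into a 0/1
#'   indicator).
#' @export
estimate_null_rate <- function(perm_freqs, n_iterations) {
  if (length(perm_freqs) == 0) stop("no permutation records supplied")
  stopifnot(n_iterations >= 1)
  all_f <- unlist(perm_freqs)
  stopifnot(all(all_f >= 0 & all_f <= 1))
  p0 <- mean(all_f)
  structure(list(p0 = p0,
                 n_iterations = n_iterations,
                 n_permutations = length(perm_freqs),
                 per_permutation_mean_freq = vapply(perm_freqs, mean,
                                                    numeric(1)),
                 degenerate = p0 == 0),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat("Binomial null model: p0 =", signif(x$p0, 4), "from",
      x$n_permutations, "permutations x", x$n_iterations, "iterations\n")
  if (x$degenerate) cat("(degenerate: p0 = 0)\n")
  invisible(x)
}

#' Upper-tail binomial probability P(X >= k)
#'
#' For X ~ Binomial(M, p0), computed through the numerically stable
#' survival function.
#'
#' @param k Observed selection count(s), `0 <= k <= M`.
#' @param M Number of trials.
#' @param p0 Null success probability in `[0, 1]`.
#' @return `P(X >= k)`, vectorized over `k`.
#' @export
binomial_tail_p <- function(k, M, p0) {
  stopifnot(M >= 1, p0 >= 0, p0 <= 1)
  if (any(k < 0 | k > M)) stop("k must lie in [0, M]")
  stats::pbinom(k - 1, M, p0, lower.tail = FALSE)
}

#' Significance test on observed selection frequencies
#'
#' For each feature, the observed selection count `k = round(freq * M)` is
#' tested against the permutation-calibrated Binomial(M, p0) null with a
#' Bonferroni-adjusted upper-tail p-value. A feature is declared significant
#' iff its adjusted p-value is below `alpha` *and* its observed frequency
#' reaches the minimum-frequency floor (default one half of the iterations),
#' which guards against features that are statistically enriched but rarely
#' selected in the original data.
#'
#' @param freqs Named numeric vector of observed per-feature selection
#'   frequencies (original labels), computed on the same `M` as `null`.
#' @param null A `"null_model"` from [estimate_null_rate()] or
#'   [run_permutation_calibration()].
#' @param alpha Family-wise significance level (default 0.05).
#' @param min_freq Minimum original-data selection frequency (default 0.5).
#' @param n_tests Bonferroni family size; defaults to the number of features
#'   tested (the screen-surviving set).
#' @param n_iterations Iteration count `M` behind `freqs`; defaults to the
#'   null model's. Supply it explicitly when the permutation calibration ran
#'   a reduced CV scheme (the null rate `p0` is a per-iteration rate and
#'   transfers across schemes).
#' @return A data frame of class `"significance_report"`, sorted by
#'   descending frequency: `feature_id`, `frequency`, `hits`, `p_raw`,
#'   `p_adjusted`, `passes_min_freq`, `significant`; attributes `alpha`,
#'   `n_tests`, `p0`, `n_iterations`.
#' @export
significant_features <- function(freqs, null, alpha = 0.05, min_freq = 0.5,
                                 n_tests = length(freqs),
                                 n_iterations = null$n_iterations) {
  stopifnot(inherits(null, "null_model"))
  if (min_freq < 0 || min_freq > 1) stop("min_freq must lie in [0, 1]")
  M <- n_iterations
  k <- round(freqs * M)
  p_raw <- binomial_tail_p(k, M, null$p0)
  p_adj <- pmin(1, p_raw * n_tests)
  passes <- freqs >= min_freq
  rep <- data.frame(feature_id = names(freqs),
                    frequency = unname(freqs),
                    hits = unname(k),
                    p_raw = unname(p_raw),
                    p_adjusted = unname(p_adj),
                    passes_min_freq = unname(passes),
                    significant = unname(p_adj < alpha & passes),
                    row.names = NULL, stringsAsFactors = FALSE)
  rep <- rep[order(-rep$frequency, rep$feature_id), ]
  rownames(rep) <- NULL
  structure(rep, alpha = alpha, n_tests = n_tests, p0 = null$p0,
            n_iterations = M,
            class = c("significance_report", "data.frame"))
}

#' @export
print.significance_report <- function(x, ...) {
  cat("Selection-frequency inference: p0 =", signif(attr(x, "p0"), 4),
      ", M =", attr(x, "n_iterations"), ", Bonferroni over",
      attr(x, "n_tests"), "tests, alpha =", attr(x, "alpha"), "\n")
  sig <- x[x$significant, , drop = FALSE]
  cat(nrow(sig), "significant feature(s)\n")
  if (nrow(sig)) print.data.frame(sig, digits = 4)
  invisible(x)
}

#' Permutation calibration of the selection-frequency null
#'
#' Reruns the cross-validated all-relevant selection on `n_perm` datasets
#' whose label column has been randomly permuted (classifier metrics are
#' discarded) and pools the resulting selection frequencies into a single
#' binomial null rate. The CV scheme used inside the permutations may be
#' reduced relative to the original-data run; the scheme actually used is
#' recorded on the returned model.
#'
#' @param x Screened feature matrix (columns named).
#' @param y Original group labels.
#' @param n_perm Number of permuted datasets (>= 1).
#' @param cv_k,cv_repeats,stratified CV scheme per permutation.
#' @param rf,boruta_max_iter,boruta_alpha Selector settings, matching the
#'   original-data run.
#' @param seed RNG seed.
#' @return A `"null_model"` whose `n_iterations` is the permutation-run
#'   iteration count `cv_k * cv_repeats`, with the calibration scheme in the
#'   `scheme` field.
#' @export
run_permutation_calibration <- function(x, y, n_perm, cv_k = 5,
                                        cv_repeats = 1, stratified = TRUE,
                                        rf = rf_config(),
                                        boruta_max_iter = 100,
                                        boruta_alpha = 0.01, seed = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  x <- as.matrix(x)
  if (!is.null(seed)) set.seed(seed)
  perms <- permute_labels(y, n_perm)
  M <- cv_k * cv_repeats
  freqs <- lapply(perms, function(yp) {
    cvp <- run_nested_cv(x, yp, cv_k = cv_k, cv_repeats = cv_repeats,
                         stratified = stratified, rf = rf,
                         boruta_max_iter = boruta_max_iter,
                         boruta_alpha = boruta_alpha,
                         fit_classifier = FALSE,
                         seed = sample.int(.Machine$integer.max, 1))
    selection_frequency(cvp, feature_ids = colnames(x))
  })
  null <- estimate_null_rate(freqs, n_iterations = M)
  null$scheme <- list(n_perm = n_perm, cv_k = cv_k, cv_repeats = cv_repeats,
                      stratified = stratified)
  null
}
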