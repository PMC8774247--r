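#' Repeated k-fold partitions
#'
#' For each repeat, partitions subjects into k disjoint folds whose sizes
#' differ by at most one. With `stratified = TRUE` (default) subjects are
#' allocated within group, keeping per-fold group proportions within one
#' subject of the global proportions; extras are spread so overall fold
#' sizes stay balanced. Deterministic under a fixed seed.
#'
#' @param labels Group label factor, one per subject.
#' @param k Number of folds (>= 2).
#' @param repeats Number of independent partitioning schemes (>= 1).
#' @param stratified Stratify folds by group (default `TRUE`).
#' @param seed RNG seed.
#'
#' @return A list of `repeats` integer vectors, each assigning every subject
#'   a fold in `1..k`.
#' @export
make_partitions <- function(labels, k = 5, repeats = 100, stratified = TRUE,
                            seed = NULL) {
  labels <- as.factor(labels)
  n <- length(labels)
  stopifnot(k >= 2, repeats >= 1, n >= k)
  if (stratified && any(table(labels) < k)) {
    stop("a group has fewer members than k; cannot stratify")
  }
  if (!is.null(seed)) set.seed(seed)

  one_partition <- function() {
    fold <- integer(n)
    sizes <- numeric(k)
    groups <- if (stratified) split(seq_len(n), labels) else list(seq_len(n))
    for (idx in groups) {
      ng <- length(idx)
      cnt <- rep(ng %/% k, k)
      r <- ng %% k
      if (r > 0) {
        # give extras to the currently smallest folds (random tie-break)
        extra <- order(sizes, sample.int(k))[seq_len(r)]
        cnt[extra] <- cnt[extra] + 1
      }
      sizes <- sizes + cnt
      fold[sample(idx)] <- rep.int(seq_len(k), cnt)
    }
    fold
  }
  lapply(seq_len(repeats), function(i) one_partition())
}

#' Classification metrics from a confusion matrix
#'
#' Case (the positive class) sensitivity, control specificity, overall
#' accuracy and Cohen's kappa, with expected agreement from the marginal
#' products. Ratios with a zero denominator are returned as `NA` and named
#' in the `"flags"` attribute.
#'
#' @param tp,fp,tn,fn Confusion counts with case as the positive class.
#' @return Named numeric vector `accuracy`, `sensitivity`, `specificity`,
#'   `kappa`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  stopifnot(n > 0, tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  flags <- character(0)
  div <- function(num, den, what) {
    if (den == 0) {
      flags <<- c(flags, what)
      return(NA_real_)
    }
    num / den
  }
  acc <- (tp + tn) / n
  sens <- div(tp, tp + fn, "sensitivity")
  spec <- div(tn, tn + fp, "specificity")
  pe <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / n^2
  kappa <- if (pe == 1) {
    flags <- c(flags, "kappa")
    NA_real_
  } else {
    (acc - pe) / (1 - pe)
  }
  structure(c(accuracy = acc, sensitivity = sens, specificity = spec,
              kappa = kappa),
            flags = flags)
}

#' Repeated cross-validation with embedded all-relevant selection
#'
#' The evaluation harness: in every CV iteration the all-relevant selector
#' runs on the training folds only, a random forest (default 1000 trees,
#' mtry = floor sqrt of the number of selected features) is trained on the
#' selected features, and the held-out fold — never visible to the selector
#' or the trainer — is predicted. Per-iteration confusion metrics and the
#' selected feature sets are recorded; performance is summarized as
#' mean +/- SD over all `k * repeats` iterations.
#'
#' Iterations in which no feature is confirmed record an empty selection and
#' predict the training-fold majority class (flagged), so the iteration
#' accounting stays intact on null data.
#'
#' @param x Numeric feature matrix (columns named), already screened.
#' @param y Two-level group factor; the first level is the positive (case)
#'   class.
#' @param cv_k,cv_repeats,stratified Partitioning scheme; see
#'   [make_partitions()].
#' @param rf An [rf_config()] used for both the selector's forests and the
#'   final per-iteration classifier.
#' @param boruta_max_iter,boruta_alpha Selector settings; see
#'   [boruta_select()].
#' @param scale_within_fold If `TRUE`, features are z-scored with training
#'   fold statistics (applied to the held-out fold) instead of relying on
#'   table-level normalization; leak-free alternative, off by default.
#' @param fit_classifier If `FALSE`, skip classifier training/prediction and
#'   record selections only (used by permutation calibration, where the
#'   metrics are discarded).
#' @param seed RNG seed.
#'
#' @return A list of class `"nested_cv"`: `summary` (data frame of
#'   mean/SD per metric), `iteration_metrics`, `selections` (list of
#'   selected-feature character vectors, one per iteration), `records`
#'   (per-iteration repeat/fold/test indices/empty-selection flag), and
#'   `n_iterations`.
#' @export
run_nested_cv <- function(x, y, cv_k = 5, cv_repeats = 100, stratified = TRUE,
                          rf = rf_config(), boruta_max_iter = 100,
                          boruta_alpha = 0.01, scale_within_fold = FALSE,
                          fit_classifier = TRUE, seed = NULL) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  stopifnot(nlevels(y) == 2, nrow(x) == length(y))
  if (!is.null(seed)) set.seed(seed)
  positive <- levels(y)[1]

  partitions <- make_partitions(y, k = cv_k, repeats = cv_repeats,
                                stratified = stratified)
  n_iter <- cv_k * cv_repeats
  metrics <- matrix(NA_real_, n_iter, 4,
                    dimnames = list(NULL, c("accuracy", "sensitivity",
                                            "specificity", "kappa")))
  selections <- vector("list", n_iter)
  records <- vector("list", n_iter)

  it <- 0L
  for (r in seq_len(cv_repeats)) {
    fold <- partitions[[r]]
    for (f in seq_len(cv_k)) {
      it <- it + 1L
      test_idx <- which(fold == f)
      train_idx <- which(fold != f)
      if (length(unique(y[test_idx])) < 2 && stratified) {
        stop("degenerate fold: held-out fold contains a single class")
      }
      xtr <- x[train_idx, , drop = FALSE]
      xte <- x[test_idx, , drop = FALSE]
      if (scale_within_fold) {
        mu <- colMeans(xtr)
        sdv <- apply(xtr, 2, stats::sd)
        sdv[sdv == 0] <- 1
        xtr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
        xte <- sweep(sweep(xte, 2, mu), 2, sdv, "/")
      }
      sel <- boruta_select(xtr, y[train_idx], rf = rf,
                           max_iter = boruta_max_iter, alpha = boruta_alpha,
                           seed = sample.int(.Machine$integer.max, 1))
      keep <- selected_features(sel)
      selections[[it]] <- keep
      empty <- length(keep) == 0

      if (fit_classifier) {
        if (empty) {
          maj <- names(which.max(table(y[train_idx])))
          pred <- factor(rep(maj, length(test_idx)), levels = levels(y))
        } else {
          fit <- ranger::ranger(
            x = xtr[, keep, drop = FALSE], y = y[train_idx],
            num.trees = rf$n_trees,
            mtry = max(1L, floor(sqrt(length(keep)))),
            num.threads = 1,
            seed = sample.int(.Machine$integer.max, 1)
          )
          pred <- stats::predict(fit,
                                 data = xte[, keep, drop = FALSE])$predictions
        }
        truth <- y[test_idx]
        metrics[it, ] <- confusion_metrics(
          tp = sum(pred == positive & truth == positive),
          fp = sum(pred == positive & truth != positive),
          tn = sum(pred != positive & truth != positive),
          fn = sum(pred != positive & truth == positive)
        )
      }
      records[[it]] <- list(repeat_index = r, fold = f, test_idx = test_idx,
                            empty_selection = empty)
    }
  }

  summary <- data.frame(
    metric = colnames(metrics),
    mean = colMeans(metrics, na.rm = TRUE),
    sd = apply(metrics, 2, stats::sd, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(summary = if (fit_classifier) summary else NULL,
                 iteration_metrics = if (fit_classifier)
                   as.data.frame(metrics) else NULL,
                 selections = selections,
                 records = records,
                 n_iterations = n_iter,
                 positive = positive),
            class = "nested_cv")
}

#' @export
print.nested_cv <- function(x, ...) {
  cat("Repeated CV:", x$n_iterations, "iterations\n")
  if (!is.null(x$summary)) {
    s <- x$summary
    for (i in seq_len(nrow(s))) {
      cat(sprintf("  %-12s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
    }
  }
  invisible(x)
}

#' Per-feature selection frequency over CV iterations
#'
#' `frequency(f)` = number of iterations selecting `f` divided by the total
#' number of iterations; features never selected get frequency 0.
#'
#' @param selections A `"nested_cv"` object or a list of selected-feature
#'   character vectors.
#' @param n_iterations Total iteration count; must equal the number of
#'   selection records.
#' @param feature_ids Feature universe to report on (default: all features
#'   appearing in `selections`).
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
selection_frequency <- function(selections,
                                n_iterations = length(selections),
                                feature_ids = NULL) {
  if (inherits(selections, "nested_cv")) selections <- selections$selections
  if (length(selections) != n_iterations) {
    stop("selection record count (", length(selections),
         ") does not match n_iterations (", n_iterations, ")")
  }
  stopifnot(n_iterations >= 1)
  counts <- table(unlist(selections))
  if (is.null(feature_ids)) feature_ids <- sort(names(counts))
  freq <- stats::setNames(numeric(length(feature_ids)), feature_ids)
  hit <- intersect(names(counts), feature_ids)
  freq[hit] <- as.numeric(counts[hit]) / n_iterations
  freq
}
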