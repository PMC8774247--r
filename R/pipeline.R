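#' Simulate a complete synthetic study
#'
#' Generates a demographics table and a schema-shaped feature table with
#' planted group effects, optionally writing both as CSV together with a
#' JSON provenance sidecar (configuration summary + seed). A convenience
#' wrapper around [generate_cohort()] and [generate_feature_table()] with
#' one master seed: the cohort and the feature noise draw from named
#' sub-seeds derived from it, so either component can be regenerated in
#' isolation.
#'
#' @param schema A `"feature_schema"` (default: the full 2,084-feature
#'   schema).
#' @param cohort A [cohort_config()].
#' @param effects Planted effects data frame (see [table_effects()]); pass a
#'   zero-row data frame for an all-null table.
#' @param noise A [noise_config()].
#' @param seed Master RNG seed.
#' @param dir Optional output directory for `demographics.csv`,
#'   `features.csv` and `provenance.json`.
#'
#' @return A list with `demographics`, `features` (data frame:
#'   `subject_id`, `group`, one column per schema feature) and `seeds`.
#' @export
simulate_study <- function(schema = build_schema(), cohort = cohort_config(),
                           effects = table_effects(), noise = noise_config(),
                           seed = 1, dir = NULL) {
  seeds <- derive_seeds(seed, c("cohort", "noise"))
  demo <- generate_cohort(cohort, seed = seeds[["cohort"]])
  features <- generate_feature_table(schema, demo$group, effects = effects,
                                     noise = noise, seed = seeds[["noise"]],
                                     subject_ids = demo$subject_id)
  out <- list(demographics = demo, features = features, seeds = seeds)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(demo, file.path(dir, "demographics.csv"),
                     row.names = FALSE)
    utils::write.csv(features, file.path(dir, "features.csv"),
                     row.names = FALSE)
    prov <- list(seed = seed, seeds = as.list(seeds),
                 n_case = cohort$n_case, n_control = cohort$n_control,
                 n_features = nrow(schema),
                 n_effects = nrow(effects),
                 block_size = noise$block_size,
                 within_block_corr = noise$within_block_corr)
    jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

# named sub-seeds below 2^31, reproducibly derived from one master seed
derive_seeds <- function(seed, names) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max, length(names)), names)
}

#' Run the full discrimination pipeline on a feature table
#'
#' Executes the whole analysis on a subjects-by-features table with a binary
#' group column: z-score normalization, the one-way ANOVA coarse screen,
#' repeated stratified k-fold cross-validation with the all-relevant
#' selector embedded in the training folds and a random-forest classifier
#' evaluated on the held-out folds, permutation calibration of the binomial
#' selection-frequency null, and the Bonferroni-corrected significance test
#' with the minimum-frequency floor.
#'
#' Scale-sensitive parameters (`cv_repeats`, `n_perm`, `perm_cv_repeats`,
#' `rf`, `boruta_max_iter`) default to the full-size scheme (100 repeats,
#' 1000 permutations, 1000 trees); reduce them for desk-scale runs.
#'
#' @param features Data frame with a `group_col` column (exactly two
#'   distinct values; the factor's first level is treated as the case /
#'   positive class) and numeric feature columns; a `subject_id` column is
#'   ignored. A path to a CSV/TSV file is also accepted.
#' @param group_col Name of the group column.
#' @param screen_alpha ANOVA screen retention threshold.
#' @param cv_k,cv_repeats,stratified CV scheme for the original-data run.
#' @param rf An [rf_config()].
#' @param boruta_max_iter,boruta_alpha All-relevant selector settings.
#' @param n_perm Number of label permutations for null calibration.
#' @param perm_cv_repeats CV repeats inside each permutation (default: same
#'   as `cv_repeats`).
#' @param alpha,min_freq Significance settings; see [significant_features()].
#' @param scale_within_fold Use training-fold z-scoring inside CV instead of
#'   table-level normalization (leak-free variant; default `FALSE`).
#' @param seed Master seed; deterministically split into `screen`, `cv` and
#'   `perm` sub-streams.
#'
#' @return A list of class `"radselect_run"`: `funnel` (feature counts
#'   total/screened/significant), `screen`, `cv` (with its mean +/- SD
#'   metric summary), `frequencies`, `null`, `report`, `seed`.
#' @export
run_study <- function(features, group_col = "group",
                      screen_alpha = 0.05,
                      cv_k = 5, cv_repeats = 100, stratified = TRUE,
                      rf = rf_config(),
                      boruta_max_iter = 100, boruta_alpha = 0.01,
                      n_perm = 1000, perm_cv_repeats = cv_repeats,
                      alpha = 0.05, min_freq = 0.5,
                      scale_within_fold = FALSE, seed = 1) {
  if (is.character(features) && length(features) == 1) {
    features <- read_feature_table(features)
  }
  if (!group_col %in% names(features)) {
    stop("no `", group_col, "` column in the feature table")
  }
  y <- factor(features[[group_col]])
  if (nlevels(y) != 2) {
    stop("group column must be binary; found values: ",
         paste(levels(y), collapse = ", "))
  }
  x <- feature_matrix(features, group_col = group_col)
  seeds <- derive_seeds(seed, c("cv", "perm"))

  z <- if (scale_within_fold) x else zscore_normalize(x)
  screen <- anova_filter(z, y, alpha = screen_alpha)
  if (length(screen$kept_ids) < 2) {
    stop("fewer than 2 features survive the ANOVA screen; nothing to select")
  }
  xs <- z[, screen$kept_ids, drop = FALSE]

  cv <- run_nested_cv(xs, y, cv_k = cv_k, cv_repeats = cv_repeats,
                      stratified = stratified, rf = rf,
                      boruta_max_iter = boruta_max_iter,
                      boruta_alpha = boruta_alpha,
                      scale_within_fold = scale_within_fold,
                      seed = seeds[["cv"]])
  freqs <- selection_frequency(cv, feature_ids = screen$kept_ids)

  null <- run_permutation_calibration(xs, y, n_perm = n_perm, cv_k = cv_k,
                                      cv_repeats = perm_cv_repeats,
                                      stratified = stratified, rf = rf,
                                      boruta_max_iter = boruta_max_iter,
                                      boruta_alpha = boruta_alpha,
                                      seed = seeds[["perm"]])
  report <- significant_features(freqs, null, alpha = alpha,
                                 min_freq = min_freq,
                                 n_tests = length(screen$kept_ids),
                                 n_iterations = cv$n_iterations)

  structure(list(
    funnel = c(total = ncol(x), screened = length(screen$kept_ids),
               significant = sum(report$significant)),
    screen = screen, cv = cv, frequencies = freqs, null = null,
    report = report, seed = seed
  ), class = "radselect_run")
}

#' @export
print.radselect_run <- function(x, ...) {
  cat("Radiomic discrimination pipeline\n")
  cat(sprintf("  feature funnel: %d total -> %d screened -> %d significant\n",
              x$funnel[["total"]], x$funnel[["screened"]],
              x$funnel[["significant"]]))
  s <- x$cv$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.2f +/- %.2f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  cat("  null selection rate p0 =", signif(x$null$p0, 4), "\n")
  sig <- x$report[x$report$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat("  significant features (selection frequency):\n")
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("    %5.1f%%  %s\n", 100 * sig$frequency[i],
                  sig$feature_id[i]))
    }
  } else cat("  no significant features\n")
  invisible(x)
}

#' Demographic and clinical comparison report
#'
#' Builds a two-group summary table for a demographics data frame: every
#' numeric column is compared with the normality-gated two-sample test
#' ([compare_groups_raw()]); the `sex` column, if present, with the
#' uncorrected chi-square test of independence.
#'
#' @param demographics Data frame with a `group` column (two levels) and
#'   demographic/clinical columns, as produced by [generate_cohort()].
#' @param normality_alpha KS normality-gate level.
#' @return Data frame of class `"cohort_report"`: one row per variable with
#'   per-group mean/SD (or counts for sex), the test statistic, df, p-value
#'   and test name.
#' @export
cohort_report <- function(demographics, normality_alpha = 0.05) {
  y <- factor(demographics$group)
  stopifnot(nlevels(y) == 2)
  g1 <- y == levels(y)[1]
  rows <- list()
  for (v in setdiff(names(demographics), c("subject_id", "group"))) {
    col <- demographics[[v]]
    if (is.numeric(col)) {
      tst <- compare_groups_raw(col[g1], col[!g1],
                                normality_alpha = normality_alpha)
      rows[[v]] <- data.frame(
        variable = v,
        case_mean = mean(col[g1]), case_sd = stats::sd(col[g1]),
        control_mean = mean(col[!g1]), control_sd = stats::sd(col[!g1]),
        statistic = tst$statistic, df = tst$df, p_value = tst$p_value,
        test = tst$test_name, stringsAsFactors = FALSE)
    } else if (v == "sex") {
      tab <- table(factor(col), y)
      tst <- chi2_independence(t(tab))
      rows[[v]] <- data.frame(
        variable = "sex",
        case_mean = NA_real_, case_sd = NA_real_,
        control_mean = NA_real_, control_sd = NA_real_,
        statistic = tst$statistic, df = tst$df, p_value = tst$p_value,
        test = tst$test_name, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("cohort_report", "data.frame"))
}

#' Read / write a feature table as CSV or TSV
#'
#' Feature tables are stored with feature ids as column headers plus
#' `subject_id` and `group` columns; the delimiter is inferred from the file
#' extension (`.tsv` = tab, otherwise comma).
#'
#' @param path File path.
#' @param table Feature table data frame.
#' @return `read_feature_table` returns the data frame with `group` as a
#'   factor; `write_feature_table` invisibly returns `path`.
#' @export
read_feature_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if ("group" %in% names(tab)) tab$group <- factor(tab$group)
  tab
}

#' @rdname read_feature_table
#' @export
write_feature_table <- function(table, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(table, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
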