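#' Cohort configuration for the synthetic study generator
#'
#' Describes a two-group cohort: group sizes, per-group sex counts, and
#' per-group mean/SD for age and the clinical scales (CIAS, BIS-11, SAS,
#' SDS). The defaults emulate a 59-case / 69-control internet-gaming-disorder
#' study cohort: 47/12 vs 58/11 male/female, and group-level scale summaries
#' such as CIAS 78.27 +/- 10.31 (case) vs 44.38 +/- 11.34 (control).
#'
#' @param n_case,n_control Group sizes (each >= 2).
#' @param sex_counts Named list with `case` and `control`, each a named
#'   integer vector `c(male=, female=)` summing to the group size.
#' @param scale_params Data frame with columns `scale`, `case_mean`,
#'   `case_sd`, `control_mean`, `control_sd`; one row per simulated variable.
#' @param seed Default RNG seed used by [generate_cohort()].
#'
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_case = 59, n_control = 69,
                          sex_counts = list(case = c(male = 47, female = 12),
                                            control = c(male = 58, female = 11)),
                          scale_params = default_scale_params(),
                          seed = NULL) {
  stopifnot(n_case >= 2, n_control >= 2,
            is.data.frame(scale_params),
            all(c("scale", "case_mean", "case_sd", "control_mean",
                  "control_sd") %in% names(scale_params)))
  if (any(scale_params$case_sd <= 0) || any(scale_params$control_sd <= 0)) {
    stop("all scale SDs must be > 0")
  }
  if (sum(sex_counts$case) != n_case || sum(sex_counts$control) != n_control) {
    stop("sex counts must sum to the group sizes")
  }
  structure(list(n_case = n_case, n_control = n_control,
                 sex_counts = sex_counts, scale_params = scale_params,
                 seed = seed),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_scale_params <- function() {
  data.frame(
    scale        = c("age", "CIAS", "BIS11", "SAS", "SDS"),
    case_mean    = c(21.39, 78.27, 63.02, 50.51, 51.97),
    case_sd      = c(3.06, 10.31, 7.72, 8.19, 7.09),
    control_mean = c(20.34, 44.38, 53.81, 42.65, 45.74),
    control_sd   = c(3.98, 11.34, 7.42, 6.39, 8.92),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic demographics table
#'
#' Draws per-subject age and clinical scale scores from per-group normal
#' distributions with the configured means/SDs; sex is assigned to match the
#' configured per-group counts exactly (in shuffled order). Deterministic
#' under a fixed seed.
#'
#' @param config A [cohort_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#'
#' @return Data frame with columns `subject_id`, `group` (factor with levels
#'   `case`, `control`), `sex`, and one column per configured scale.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_case + config$n_control
  group <- factor(rep(c("case", "control"), c(config$n_case, config$n_control)),
                  levels = c("case", "control"))
  sex <- c(sample(rep(c("male", "female"), config$sex_counts$case)),
           sample(rep(c("male", "female"), config$sex_counts$control)))
  out <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = group,
    sex = sex,
    stringsAsFactors = FALSE
  )
  sp <- config$scale_params
  for (i in seq_len(nrow(sp))) {
    mu <- ifelse(group == "case", sp$case_mean[i], sp$control_mean[i])
    sg <- ifelse(group == "case", sp$case_sd[i], sp$control_sd[i])
    out[[sp$scale[i]]] <- stats::rnorm(n, mu, sg)
  }
  out
}

#' Planted discriminative effects for the default synthetic study
#'
#' The eight features planted by default in [generate_feature_table()], with
#' per-group means and SDs. They span cortical thickness, curvature and
#' sulcal-depth statistics of the rostral middle frontal, fusiform, cuneus
#' and pars orbitalis regions, and mean-diffusivity statistics of the
#' internal capsule and uncinate fasciculus — standardized group differences
#' of roughly 0.5-0.75 SD.
#'
#' @return Data frame with columns `feature_id`, `case_mean`, `case_sd`,
#'   `control_mean`, `control_sd`.
#' @export
table_effects <- function() {
  data.frame(
    feature_id = c(
      "gray.left.rostral_middle_frontal.local_thickness.std",
      "white.left.anterior_limb_of_internal_capsule.md.std",
      "gray.right.fusiform.mean_curvature.mean",
      "gray.left.fusiform.local_thickness.skewness",
      "gray.left.cuneus.local_thickness.mean",
      "white.right.uncinate_fasciculus.md.skewness",
      "gray.left.rostral_middle_frontal.travel_depth.skewness",
      "gray.left.pars_orbitalis.local_thickness.std"
    ),
    case_mean    = c(0.66, 0.000089, -3.83, 0.70, 1.99, 0.25, 0.21, 0.52),
    case_sd      = c(0.05, 0.000013, 0.26, 0.22, 0.17, 0.33, 0.02, 0.05),
    control_mean = c(0.62, 0.000095, -4.00, 0.86, 1.88, 0.03, 0.22, 0.49),
    control_sd   = c(0.06, 0.000010, 0.23, 0.26, 0.16, 0.32, 0.01, 0.06),
    stringsAsFactors = FALSE
  )
}

#' Correlated-noise configuration for null features
#'
#' Null (non-discriminative) features are generated in consecutive blocks
#' sharing one latent factor, giving an exchangeable within-block correlation
#' of `within_block_corr` and zero correlation across blocks. This mimics the
#' correlation of radiomic features computed from the same region or map
#' without claiming any specific empirical covariance.
#'
#' @param block_size Features per correlated block (default 16).
#' @param within_block_corr Within-block correlation in `[0, 1)` (default
#'   0.3); values in this range always give a positive-definite block
#'   covariance.
#'
#' @return A list of class `"noise_config"`.
#' @export
noise_config <- function(block_size = 16, within_block_corr = 0.3) {
  stopifnot(block_size >= 1,
            within_block_corr >= 0, within_block_corr < 1)
  structure(list(block_size = block_size,
                 within_block_corr = within_block_corr),
            class = "noise_config")
}

#' Generate a synthetic feature table with planted group effects
#'
#' For each feature listed in `effects`, subject values are drawn from a
#' normal distribution with that subject's group mean/SD. All remaining
#' schema features are null: identically distributed in both groups
#' (standard normal marginals) with block correlation per `noise`. Column
#' order follows the schema.
#'
#' @param schema A `"feature_schema"` from [build_schema()].
#' @param labels Factor of group labels (levels `case`, `control`), one per
#'   subject.
#' @param effects Data frame as returned by [table_effects()]; may have zero
#'   rows for an all-null table.
#' @param noise A [noise_config()].
#' @param seed RNG seed.
#' @param subject_ids Optional character vector of subject ids.
#'
#' @return Data frame with columns `subject_id`, `group`, then one numeric
#'   column per schema feature.
#' @export
generate_feature_table <- function(schema, labels, effects = table_effects(),
                                   noise = noise_config(), seed = NULL,
                                   subject_ids = NULL) {
  stopifnot(inherits(schema, "feature_schema"), inherits(noise, "noise_config"))
  labels <- as.factor(labels)
  n <- length(labels)
  ids <- schema$feature_id
  if (nrow(effects) > 0) {
    missing <- setdiff(effects$feature_id, ids)
    if (length(missing)) {
      stop("effect feature ids not in schema: ", paste(missing, collapse = ", "))
    }
    stopifnot(all(effects$case_sd > 0), all(effects$control_sd > 0))
  }
  if (!is.null(seed)) set.seed(seed)

  x <- matrix(NA_real_, n, length(ids), dimnames = list(NULL, ids))
  is_effect <- ids %in% effects$feature_id

  # null block: shared latent factor per block of consecutive null features
  null_ids <- ids[!is_effect]
  p0 <- length(null_ids)
  if (p0 > 0) {
    rho <- noise$within_block_corr
    block <- rep(seq_len(ceiling(p0 / noise$block_size)),
                 each = noise$block_size, length.out = p0)
    z <- matrix(stats::rnorm(n * max(block)), n, max(block))
    e <- matrix(stats::rnorm(n * p0), n, p0)
    x[, null_ids] <- sqrt(rho) * z[, block, drop = FALSE] + sqrt(1 - rho) * e
  }

  is_case <- labels == levels(labels)[1]
  for (j in seq_len(nrow(effects))) {
    mu <- ifelse(is_case, effects$case_mean[j], effects$control_mean[j])
    sg <- ifelse(is_case, effects$case_sd[j], effects$control_sd[j])
    x[, effects$feature_id[j]] <- stats::rnorm(n, mu, sg)
  }

  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(n))
  cbind(data.frame(subject_id = subject_ids, group = labels,
                   stringsAsFactors = FALSE),
        as.data.frame(x, optional = TRUE))
}

#' Draw label permutations for null calibration
#'
#' Each permutation is a uniform random rearrangement of the label vector;
#' group sizes are preserved exactly and permutations are sampled
#' independently (duplicates allowed). Deterministic under a fixed seed.
#'
#' @param labels Group label vector (factor).
#' @param n_perm Number of permutations (>= 1).
#' @param seed RNG seed.
#'
#' @return A list of `n_perm` permuted label factors.
#' @export
permute_labels <- function(labels, n_perm, seed = NULL) {
  stopifnot(n_perm >= 1)
  labels <- as.factor(labels)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_perm), function(i) labels[sample.int(length(labels))])
}

#' Split a feature table into a feature matrix and label vector
#'
#' @param table A feature table as returned by [generate_feature_table()], or
#'   any data frame with a group column and numeric feature columns.
#' @param group_col Name of the group column.
#' @return `feature_matrix` returns the numeric matrix of features (id
#'   columns dropped); `group_labels` the label factor.
#' @export
feature_matrix <- function(table, group_col = "group") {
  drop <- intersect(c("subject_id", group_col), names(table))
  as.matrix(table[, setdiff(names(table), drop), drop = FALSE])
}

#' @rdname feature_matrix
#' @export
group_labels <- function(table, group_col = "group") {
  if (!group_col %in% names(table)) {
    stop("no `", group_col, "` column in feature table")
  }
  factor(table[[group_col]])
}
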