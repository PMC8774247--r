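#' Group summary (n, mean, SD)
#'
#' @param n Sample size (>= 2).
#' @param mean Sample mean.
#' @param sd Sample standard deviation (>= 0).
#' @return A list of class `"group_summary"`.
#' @export
group_summary <- function(n, mean, sd) {
  stopifnot(n >= 2, sd >= 0)
  structure(list(n = n, mean = mean, sd = sd), class = "group_summary")
}

test_result <- function(statistic, df, p_value, test_name, flag = NULL) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), test_name = test_name,
                 flag = flag),
            class = "radselect_test")
}

#' @export
print.radselect_test <- function(x, ...) {
  cat(x$test_name, ": statistic = ", signif(x$statistic, 4),
      if (!is.na(x$df)) paste0(", df = ", signif(x$df, 4)),
      ", p = ", signif(x$p_value, 4), "\n", sep = "")
  if (!is.null(x$flag)) cat("flag:", x$flag, "\n")
  invisible(x)
}

#' Two-sample pooled-variance t-test from summary statistics
#'
#' Student's t with pooled variance, computed from per-group (n, mean, sd)
#' only: `sp^2 = ((n1-1)s1^2 + (n2-1)s2^2) / (n1+n2-2)`,
#' `t = (m1-m2) / (sp * sqrt(1/n1 + 1/n2))`, df = n1+n2-2, two-sided p from
#' the t distribution. This is the test that reproduces published group
#' comparison tables from their printed means and SDs.
#'
#' @param a,b [group_summary()] objects.
#' @return A `"radselect_test"` with `test_name = "pooled_t"`.
#'
#' @examples
#' # CIAS internet-addiction scores, 59 cases vs 69 controls
#' pooled_t_from_summary(group_summary(59, 78.27, 10.31),
#'                       group_summary(69, 44.38, 11.34))  # t = 17.57, df = 126
#' @export
pooled_t_from_summary <- function(a, b) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  if (a$sd == 0 && b$sd == 0 && a$mean == b$mean) {
    stop("undefined statistic: both SDs are zero and the means are equal")
  }
  df <- a$n + b$n - 2
  sp <- sqrt(((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df)
  tt <- (a$mean - b$mean) / (sp * sqrt(1 / a$n + 1 / b$n))
  test_result(tt, df, 2 * stats::pt(abs(tt), df, lower.tail = FALSE),
              "pooled_t")
}

#' Compare two raw samples with a normality-gated test
#'
#' Each sample is first checked against a normal distribution with its own
#' mean and SD by a one-sample Kolmogorov-Smirnov test. If both samples pass
#' the gate at `normality_alpha`, a pooled-variance t-test is run on the raw
#' data; otherwise a two-sided Mann-Whitney U (normal approximation with tie
#' correction). The returned result records which branch ran.
#'
#' @param x,y Numeric samples (each n >= 3).
#' @param normality_alpha Significance level of the KS normality gate.
#' @return A `"radselect_test"` with `test_name` `"pooled_t"` or
#'   `"mann_whitney"`.
#' @export
compare_groups_raw <- function(x, y, normality_alpha = 0.05) {
  stopifnot(length(x) >= 3, length(y) >= 3)
  ks_p <- function(v) {
    if (stats::sd(v) == 0) return(0)  # constant sample is not normal
    suppressWarnings(stats::ks.test(v, "pnorm", mean(v), stats::sd(v))$p.value)
  }
  if (ks_p(x) > normality_alpha && ks_p(y) > normality_alpha) {
    return(pooled_t_from_summary(
      group_summary(length(x), mean(x), stats::sd(x)),
      group_summary(length(y), mean(y), stats::sd(y))
    ))
  }
  if (stats::sd(c(x, y)) == 0) {
    return(test_result(NA_real_, NA_real_, 1, "mann_whitney",
                       flag = "all values tied"))
  }
  w <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                           correct = TRUE))
  test_result(w$statistic, NA_real_, w$p.value, "mann_whitney")
}

#' Pearson chi-square test of independence for a 2x2 table
#'
#' Without continuity correction (the convention that reproduces published
#' sex-by-group comparisons from the printed counts); df = 1.
#'
#' @param counts A 2x2 matrix of counts.
#' @return A `"radselect_test"` with `test_name = "chi2"`.
#'
#' @examples
#' chi2_independence(matrix(c(47, 12, 58, 11), 2, byrow = TRUE))  # 0.417
#' @export
chi2_independence <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2, 2)), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("chi-square undefined: zero row or column margin")
  }
  ct <- stats::chisq.test(counts, correct = FALSE)
  test_result(ct$statistic, ct$parameter, ct$p.value, "chi2")
}

#' Internet-addiction classification from the 8-item YDQ
#'
#' Young's Diagnostic Questionnaire (Beard modification): positive iff items
#' 1-5 are all "yes" and at least one of items 6-8 is "yes".
#'
#' @param answers Logical vector of exactly 8 yes/no responses.
#' @return `TRUE` if the rule classifies the respondent as having internet
#'   addiction.
#' @export
ydq_classify <- function(answers) {
  answers <- as.logical(answers)
  if (length(answers) != 8 || anyNA(answers)) {
    stop("`answers` must be 8 yes/no responses")
  }
  all(answers[1:5]) && any(answers[6:8])
}

#' Internet-addiction severity classification from a CIAS total score
#'
#' The Chen Internet Addiction Scale total (26 items on a 4-point scale,
#' range 26-104) with the 63/64 diagnostic cutoff: scores of 64 and above
#' classify as addicted.
#'
#' @param score Numeric CIAS total score(s) in `[26, 104]`.
#' @param cutoff Decision boundary (default 63.5, i.e. the 63/64 split).
#' @return Logical vector, `TRUE` where `score` exceeds the cutoff.
#' @export
cias_classify <- function(score, cutoff = 63.5) {
  if (any(score < 26 | score > 104)) {
    stop("CIAS total must lie in [26, 104]")
  }
  score > cutoff
}
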