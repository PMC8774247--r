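#' Z-score normalize a feature matrix
#'
#' Centers and scales every feature column to mean 0 and sample SD 1.
#' Constant columns cannot be scaled; they are passed through as all-zero
#' and listed in the `"constant_features"` attribute.
#'
#' @param x Numeric matrix or data frame of features (columns = features).
#' @return A numeric matrix of the same dimensions, with attribute
#'   `"constant_features"` (character vector, possibly empty).
#' @export
zscore_normalize <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  const <- sd == 0
  sd[const] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sd, "/")
  z[, const] <- 0
  structure(z, constant_features = colnames(x)[const])
}

#' Coarse one-way ANOVA screen
#'
#' The noise filter applied before all-relevant selection: a per-feature
#' one-way ANOVA of feature value on group, keeping features with
#' uncorrected p < `alpha`. For two groups the F statistic equals the square
#' of the pooled-variance t statistic. Constant features are excluded and
#' recorded with an undefined F.
#'
#' @param x Numeric matrix or data frame of features.
#' @param labels Group label factor (two levels, each with n >= 2).
#' @param alpha Retention threshold on the per-feature p-value.
#' @return A list of class `"screen_result"`: `kept_ids` (feature ids
#'   passing the screen, input order preserved) and `stats` (data frame with
#'   `feature_id`, `F`, `p`, `kept`, `constant`).
#' @export
anova_filter <- function(x, labels, alpha = 0.05) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2, all(table(labels) >= 2),
            nrow(x) == length(labels))
  g1 <- labels == levels(labels)[1]
  n1 <- sum(g1); n2 <- sum(!g1); n <- n1 + n2

  m1 <- colMeans(x[g1, , drop = FALSE])
  m2 <- colMeans(x[!g1, , drop = FALSE])
  v1 <- apply(x[g1, , drop = FALSE], 2, stats::var)
  v2 <- apply(x[!g1, , drop = FALSE], 2, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n - 2)

  const <- v1 + v2 == 0 & m1 == m2
  Fstat <- ifelse(sp2 == 0,
                  ifelse(m1 == m2, NA_real_, Inf),
                  (m1 - m2)^2 / (sp2 * (1 / n1 + 1 / n2)))
  p <- stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  kept <- !is.na(p) & p < alpha & !const

  stats <- data.frame(feature_id = colnames(x), F = Fstat, p = p,
                      kept = kept, constant = const,
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(kept_ids = colnames(x)[kept], stats = stats, alpha = alpha),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("ANOVA screen (alpha = ", x$alpha, "): kept ",
      length(x$kept_ids), " of ", nrow(x$stats), " features\n", sep = "")
  invisible(x)
}
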