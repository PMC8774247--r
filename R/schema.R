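#' Atlas label sets used by the default radiomic feature schema
#'
#' The default schema draws its vocabulary from the Desikan-Killiany-Tourville
#' (DKT) cortical parcellation (31 regions per hemisphere), the JHU-ICBM-DTI-81
#' white-matter atlas (48 tract labels, 21 of them paired left/right plus 6
#' unpaired midline structures), and 7 bilateral subcortical structures.
#'
#' @name atlas_labels
#' @keywords internal
NULL

dkt_cortical_labels <- c(
  "caudal_anterior_cingulate", "caudal_middle_frontal", "cuneus",
  "entorhinal", "fusiform", "inferior_parietal", "inferior_temporal",
  "insula", "isthmus_cingulate", "lateral_occipital",
  "lateral_orbitofrontal", "lingual", "medial_orbitofrontal",
  "middle_temporal", "paracentral", "parahippocampal",
  "pars_opercularis", "pars_orbitalis", "pars_triangularis",
  "pericalcarine", "postcentral", "posterior_cingulate", "precentral",
  "precuneus", "rostral_anterior_cingulate", "rostral_middle_frontal",
  "superior_frontal", "superior_parietal", "superior_temporal",
  "supramarginal", "transverse_temporal"
)

jhu_paired_labels <- c(
  "corticospinal_tract", "medial_lemniscus", "inferior_cerebellar_peduncle",
  "superior_cerebellar_peduncle", "cerebral_peduncle",
  "anterior_limb_of_internal_capsule", "posterior_limb_of_internal_capsule",
  "retrolenticular_part_of_internal_capsule", "anterior_corona_radiata",
  "superior_corona_radiata", "posterior_corona_radiata",
  "posterior_thalamic_radiation", "sagittal_stratum", "external_capsule",
  "cingulum_cingulate_gyrus", "cingulum_hippocampus",
  "fornix_stria_terminalis", "superior_longitudinal_fasciculus",
  "superior_fronto_occipital_fasciculus", "uncinate_fasciculus", "tapetum"
)

jhu_midline_labels <- c(
  "middle_cerebellar_peduncle", "pontine_crossing_tract",
  "genu_of_corpus_callosum", "body_of_corpus_callosum",
  "splenium_of_corpus_callosum", "fornix"
)

subcortical_labels <- c(
  "thalamus", "caudate", "putamen", "pallidum", "hippocampus",
  "amygdala", "accumbens"
)

#' Configuration for a radiomic feature schema
#'
#' Collects the atlas label sets, per-tissue measures and summary statistics
#' from which [build_schema()] enumerates the feature universe. The defaults
#' reproduce the standard 2,084-feature layout: 1,316 gray-matter features
#' (62 DKT cortical regions x 5 vertex-wise shape measures x 4 distribution
#' statistics = 1,240, plus 62 cortical and 14 subcortical volume scalars)
#' and 768 white-matter features (48 JHU-ICBM-81 tract labels x 4 diffusion
#' measures x 4 distribution statistics).
#'
#' @param dkt_regions Character vector of cortical region labels, enumerated
#'   once per hemisphere.
#' @param subcortical Character vector of subcortical structure labels,
#'   enumerated once per hemisphere (volume scalars only).
#' @param jhu_paired Character vector of paired (left/right) white-matter
#'   tract labels.
#' @param jhu_midline Character vector of unpaired midline tract labels
#'   (hemisphere recorded as `"midline"`).
#' @param gray_measures Vertex-wise gray-matter shape measures.
#' @param diffusion_measures Diffusion-tensor scalar measures.
#' @param statistics Distribution statistics computed per label for the
#'   vertex-wise and diffusion measures.
#' @param include_volumes Logical; add per-region cortical and subcortical
#'   volume scalars to the gray-matter block.
#'
#' @return A list of class `"schema_config"`.
#' @seealso [build_schema()]
#' @export
schema_config <- function(dkt_regions = dkt_cortical_labels,
                          subcortical = subcortical_labels,
                          jhu_paired = jhu_paired_labels,
                          jhu_midline = jhu_midline_labels,
                          gray_measures = c("local_thickness", "geodesic_depth",
                                            "travel_depth", "mean_curvature",
                                            "convexity"),
                          diffusion_measures = c("FA", "MD", "RD", "AD"),
                          statistics = c("mean", "std", "kurtosis", "skewness"),
                          include_volumes = TRUE) {
  for (nm in c("dkt_regions", "subcortical", "jhu_paired", "jhu_midline",
               "gray_measures", "diffusion_measures", "statistics")) {
    v <- get(nm)
    if (anyDuplicated(v)) {
      stop("duplicate labels in `", nm, "`: ",
           paste(unique(v[duplicated(v)]), collapse = ", "))
    }
  }
  structure(list(dkt_regions = dkt_regions,
                 subcortical = subcortical,
                 jhu_paired = jhu_paired,
                 jhu_midline = jhu_midline,
                 gray_measures = gray_measures,
                 diffusion_measures = diffusion_measures,
                 statistics = statistics,
                 include_volumes = isTRUE(include_volumes)),
            class = "schema_config")
}

feature_id <- function(tissue, hemisphere, label, measure, statistic) {
  tolower(paste(tissue, hemisphere, label, measure, statistic, sep = "."))
}

#' Enumerate the radiomic feature universe
#'
#' Builds the ordered table of feature descriptors shared by the synthetic
#' generator, the screening filter and the reporting layer. Each descriptor
#' records tissue class, hemisphere, atlas label, measure and summary
#' statistic; the `feature_id` is derived deterministically from these fields
#' (lowercase, dot-separated), so two builds from the same configuration are
#' identical.
#'
#' The default configuration yields 2,084 features: a 1,316-feature
#' gray-matter block followed by a 768-feature white-matter block.
#'
#' @param config A [schema_config()].
#'
#' @return A data frame of class `"feature_schema"` with columns `feature_id`,
#'   `tissue`, `hemisphere`, `atlas_label`, `measure`, `statistic`, and
#'   attributes `n_gray` / `n_white` holding the per-tissue counts.
#'
#' @examples
#' sch <- build_schema()
#' nrow(sch)                  # 2084
#' attr(sch, "n_white")      # 768
#' @export
build_schema <- function(config = schema_config()) {
  stopifnot(inherits(config, "schema_config"))
  hemis <- c("left", "right")

  # gray vertex-wise block: hemisphere x region x measure x statistic
  gv <- expand.grid(statistic = config$statistics,
                    measure = config$gray_measures,
                    atlas_label = config$dkt_regions,
                    hemisphere = hemis,
                    stringsAsFactors = FALSE)[, 4:1]
  gv$tissue <- rep("gray", nrow(gv))

  blocks <- list(gv)
  if (config$include_volumes) {
    cvvol <- expand.grid(atlas_label = config$dkt_regions, hemisphere = hemis,
                         stringsAsFactors = FALSE)[, 2:1]
    scvol <- expand.grid(atlas_label = config$subcortical, hemisphere = hemis,
                         stringsAsFactors = FALSE)[, 2:1]
    vols <- rbind(cvvol, scvol)
    vols$tissue <- rep("gray", nrow(vols))
    vols$measure <- rep("volume", nrow(vols))
    vols$statistic <- rep("scalar", nrow(vols))
    blocks <- c(blocks, list(vols))
  }

  wm_labels <- data.frame(
    hemisphere = c(rep(hemis, each = length(config$jhu_paired)),
                   rep("midline", length(config$jhu_midline))),
    atlas_label = c(rep(config$jhu_paired, 2), config$jhu_midline),
    stringsAsFactors = FALSE
  )
  wm <- merge(merge(wm_labels,
                    data.frame(measure = config$diffusion_measures), by = NULL),
              data.frame(statistic = config$statistics), by = NULL)
  # merge() does not guarantee input order; restore label-major ordering
  wm <- wm[order(match(paste(wm$hemisphere, wm$atlas_label),
                       paste(wm_labels$hemisphere, wm_labels$atlas_label)),
                 match(wm$measure, config$diffusion_measures),
                 match(wm$statistic, config$statistics)), ]
  wm$tissue <- rep("white", nrow(wm))

  sch <- do.call(rbind, c(blocks, list(wm)))
  sch <- sch[, c("tissue", "hemisphere", "atlas_label", "measure", "statistic")]
  sch$feature_id <- feature_id(sch$tissue, sch$hemisphere, sch$atlas_label,
                               sch$measure, sch$statistic)
  sch <- sch[, c("feature_id", "tissue", "hemisphere", "atlas_label",
                 "measure", "statistic")]
  rownames(sch) <- NULL
  if (anyDuplicated(sch$feature_id)) {
    stop("schema construction produced duplicate feature ids")
  }
  structure(sch,
            n_gray = sum(sch$tissue == "gray"),
            n_white = sum(sch$tissue == "white"),
            class = c("feature_schema", "data.frame"))
}

#' Look up a feature descriptor by id
#'
#' @param schema A `"feature_schema"` from [build_schema()].
#' @param id A single feature id.
#'
#' @return The one-row descriptor for `id`.
#' @export
schema_lookup <- function(schema, id) {
  stopifnot(inherits(schema, "feature_schema"), length(id) == 1L)
  i <- match(id, schema$feature_id)
  if (is.na(i)) stop("feature not found in schema: ", id)
  schema[i, , drop = FALSE]
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("Radiomic feature schema:", nrow(x), "features (",
      attr(x, "n_gray"), "gray-matter,", attr(x, "n_white"),
      "white-matter )\n")
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Write / read a feature schema as JSON
#'
#' @param schema A `"feature_schema"`.
#' @param path File path.
#' @return `schema_to_json` invisibly returns `path`; `schema_from_json`
#'   returns the reconstructed `"feature_schema"`.
#' @export
schema_to_json <- function(schema, path) {
  stopifnot(inherits(schema, "feature_schema"))
  jsonlite::write_json(as.data.frame(schema), path, digits = NA)
  invisible(path)
}

#' @rdname schema_to_json
#' @export
schema_from_json <- function(path) {
  sch <- jsonlite::fromJSON(path)
  stopifnot(is.data.frame(sch),
            all(c("feature_id", "tissue", "hemisphere", "atlas_label",
                  "measure", "statistic") %in% names(sch)))
  if (anyDuplicated(sch$feature_id)) stop("duplicate feature ids in ", path)
  structure(sch,
            n_gray = sum(sch$tissue == "gray"),
            n_white = sum(sch$tissue == "white"),
            class = c("feature_schema", "data.frame"))
}
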