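# Shared fixtures: small schemas and fast RF settings keep module tests quick
# while the acceptance tests exercise the full-width table.

# ~158-feature schema (still exercises both tissue blocks and volumes)
small_schema <- function() {
  build_schema(schema_config(
    dkt_regions = dkt_cortical_labels[1:5],
    subcortical = subcortical_labels[1:2],
    jhu_paired = jhu_paired_labels[1:3],
    jhu_midline = jhu_midline_labels[1:2],
    gray_measures = c("local_thickness", "mean_curvature"),
    diffusion_measures = c("MD", "FA")
  ))
}

# schema subset that contains all eight default planted-effect features
effect_schema <- function() {
  build_schema(schema_config(
    dkt_regions = c("cuneus", "fusiform", "rostral_middle_frontal",
                    "pars_orbitalis", "superior_frontal", "precuneus",
                    "lingual", "insula"),
    subcortical = subcortical_labels[1:3],
    jhu_paired = c("anterior_limb_of_internal_capsule", "uncinate_fasciculus",
                   "external_capsule", "corticospinal_tract"),
    jhu_midline = c("genu_of_corpus_callosum", "fornix"),
    gray_measures = c("local_thickness", "travel_depth", "mean_curvature"),
    diffusion_measures = c("MD", "FA")
  ))
}

fast_rf <- function(n_trees = 100) rf_config(n_trees = n_trees)

no_effects <- function() table_effects()[0, ]

# default-size label vector: 59 cases, 69 controls
default_labels <- function() {
  factor(rep(c("case", "control"), c(59, 69)), levels = c("case", "control"))
}

# n x p matrix of named null features
null_features <- function(n, p, prefix = "f") {
  matrix(rnorm(n * p), n, p,
         dimnames = list(NULL, paste0(prefix, seq_len(p))))
}
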