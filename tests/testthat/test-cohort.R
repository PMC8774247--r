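test_that("default cohort matches the configured sizes and sex counts", {
  demo <- generate_cohort(seed = 7)
  expect_equal(nrow(demo), 128)
  expect_equal(sum(demo$group == "case"), 59)
  tab <- table(demo$sex, demo$group)
  expect_equal(tab["male", "case"], 47)
  expect_equal(tab["female", "case"], 12)
  expect_equal(tab["male", "control"], 58)
  expect_equal(tab["female", "control"], 11)
  expect_true(all(c("age", "CIAS", "BIS11", "SAS", "SDS") %in% names(demo)))
})

test_that("cohort generation is deterministic under a fixed seed", {
  expect_identical(generate_cohort(seed = 3), generate_cohort(seed = 3))
  expect_false(identical(generate_cohort(seed = 3), generate_cohort(seed = 4)))
})

test_that("tiny cohorts recover the configured means within 3 SE", {
  cfg <- cohort_config(
    n_case = 2, n_control = 2,
    sex_counts = list(case = c(male = 1, female = 1),
                      control = c(male = 1, female = 1)),
    scale_params = data.frame(scale = "CIAS", case_mean = 80, case_sd = 1e-4,
                              control_mean = 40, control_sd = 1e-4))
  demo <- generate_cohort(cfg, seed = 1)
  se <- 1e-4 / sqrt(2)
  expect_lt(abs(mean(demo$CIAS[demo$group == "case"]) - 80), 3 * se)
  expect_lt(abs(mean(demo$CIAS[demo$group == "control"]) - 40), 3 * se)
})

test_that("per-group moments converge to configured values at large n", {
  n <- 10000
  cfg <- cohort_config(
    n_case = n, n_control = n,
    sex_counts = list(case = c(male = n, female = 0),
                      control = c(male = n, female = 0)))
  demo <- generate_cohort(cfg, seed = 11)
  sp <- default_scale_params()
  for (i in seq_len(nrow(sp))) {
    v <- demo[[sp$scale[i]]]
    expect_lt(abs(mean(v[demo$group == "case"]) / sp$case_mean[i] - 1), 0.01)
    expect_lt(abs(sd(v[demo$group == "case"]) / sp$case_sd[i] - 1), 0.05)
    expect_lt(abs(mean(v[demo$group == "control"]) / sp$control_mean[i] - 1),
              0.01)
  }
})

test_that("planted effects land at their configured per-group means", {
  sch <- effect_schema()
  labels <- default_labels()
  ft <- generate_feature_table(sch, labels, seed = 5)
  eff <- table_effects()
  ic <- "white.left.anterior_limb_of_internal_capsule.md.std"
  row <- eff[eff$feature_id == ic, ]
  v <- ft[[ic]]
  expect_lt(abs(mean(v[labels == "case"]) - row$case_mean),
            3 * row$case_sd / sqrt(59))
  expect_lt(abs(mean(v[labels == "control"]) - row$control_mean),
            3 * row$control_sd / sqrt(69))
  # column order follows the schema
  expect_identical(colnames(feature_matrix(ft)), sch$feature_id)
})

test_that("all-null tables show no Bonferroni-significant feature in almost
           all seeded generations", {
  sch <- build_schema(schema_config(
    dkt_regions = dkt_cortical_labels[1:3], subcortical = character(0),
    jhu_paired = character(0), jhu_midline = "fornix",
    gray_measures = c("local_thickness", "mean_curvature"),
    include_volumes = FALSE))  # 52 features
  labels <- default_labels()
  g1 <- labels == "case"
  p <- nrow(sch)
  tcrit <- qt(1 - 0.025 / p, 126)
  clean <- 0L
  for (s in 1:100) {
    ft <- generate_feature_table(sch, labels, effects = no_effects(),
                                 seed = 5000 + s)
    x <- feature_matrix(ft)
    # independent oracle: direct pooled-t sweep
    m1 <- colMeans(x[g1, ]); m2 <- colMeans(x[!g1, ])
    v1 <- apply(x[g1, ], 2, var); v2 <- apply(x[!g1, ], 2, var)
    sp2 <- (58 * v1 + 68 * v2) / 126
    tt <- (m1 - m2) / sqrt(sp2 * (1 / 59 + 1 / 69))
    clean <- clean + (max(abs(tt)) < tcrit)
  }
  expect_gte(clean, 95)
})

test_that("a 10-sigma effect produces the closed-form t magnitude", {
  sch <- build_schema(schema_config(
    dkt_regions = "cuneus", subcortical = character(0),
    jhu_paired = character(0), jhu_midline = "fornix",
    gray_measures = "local_thickness", include_volumes = FALSE))
  id <- "gray.left.cuneus.local_thickness.mean"
  eff <- data.frame(feature_id = id, case_mean = 10, case_sd = 1,
                    control_mean = 0, control_sd = 1)
  labels <- default_labels()
  ft <- generate_feature_table(sch, labels, effects = eff, seed = 2)
  tt <- t.test(ft[[id]][labels == "case"], ft[[id]][labels == "control"],
               var.equal = TRUE)
  # expected t ~ delta / (sigma * sqrt(1/n1 + 1/n2)) ~ 56
  expect_gt(abs(tt$statistic), 10)
})

test_that("unknown effect feature ids are rejected by name", {
  sch <- small_schema()
  eff <- data.frame(feature_id = "bogus.feature", case_mean = 1, case_sd = 1,
                    control_mean = 0, control_sd = 1)
  expect_error(generate_feature_table(sch, default_labels(), effects = eff),
               "bogus.feature")
})

test_that("label permutations preserve group sizes and are seed-stable", {
  labels <- default_labels()
  perms <- permute_labels(labels, n_perm = 1000, seed = 9)
  expect_length(perms, 1000)
  expect_true(all(vapply(perms[1:50],
                         function(p) sum(p == "case"), 0) == 59))
  expect_identical(permute_labels(labels, 5, seed = 1),
                   permute_labels(labels, 5, seed = 1))
  # permutations differ from one another (sampled independently)
  expect_false(identical(perms[[1]], perms[[2]]))
})
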