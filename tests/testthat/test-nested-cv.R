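test_that("partitions are balanced, disjoint, covering and stratified", {
  labels <- default_labels()
  parts <- make_partitions(labels, k = 5, repeats = 100, seed = 21)
  expect_length(parts, 100)              # 100 x 5 = 500 (iteration, fold) pairs
  for (fold in parts[1:10]) {
    sizes <- as.vector(table(fold))
    expect_equal(sort(sizes), c(25, 25, 26, 26, 26))
    expect_equal(sort(unique(fold)), 1:5)
    expect_length(fold, 128)             # every subject in exactly one fold
    case_per_fold <- table(fold[labels == "case"])
    expect_true(all(abs(case_per_fold - 59 / 5) <= 1))
  }
  expect_identical(make_partitions(labels, 5, 3, seed = 2),
                   make_partitions(labels, 5, 3, seed = 2))
  expect_error(make_partitions(factor(rep(c("a", "b"), c(3, 60))), k = 5),
               "fewer members than k")
})

test_that("confusion metrics match hand calculations and brute recounts", {
  m <- confusion_metrics(tp = 10, fp = 0, tn = 10, fn = 0)
  expect_equal(unname(m["accuracy"]), 1)
  expect_equal(unname(m["kappa"]), 1)

  m <- confusion_metrics(tp = 8, fp = 3, tn = 7, fn = 2)
  expect_equal(unname(m["accuracy"]), 0.75)
  expect_equal(unname(m["kappa"]), 0.5)   # p_o = 0.75, p_e = 0.5

  m <- confusion_metrics(tp = 0, fp = 10, tn = 0, fn = 10)
  expect_equal(unname(m["accuracy"]), 0)
  expect_equal(unname(m["kappa"]), -1)

  # brute-force recount from raw (truth, prediction) pairs
  set.seed(44)
  for (i in 1:1000) {
    n <- sample(4:15, 1)
    truth <- factor(sample(c("case", "control"), n, replace = TRUE),
                    levels = c("case", "control"))
    pred <- factor(sample(c("case", "control"), n, replace = TRUE),
                   levels = c("case", "control"))
    m <- confusion_metrics(tp = sum(pred == "case" & truth == "case"),
                           fp = sum(pred == "case" & truth == "control"),
                           tn = sum(pred == "control" & truth == "control"),
                           fn = sum(pred == "control" & truth == "case"))
    expect_equal(unname(m["accuracy"]), mean(pred == truth))
    po <- mean(pred == truth)
    pe <- sum(prop.table(table(truth)) * prop.table(table(pred)))
    if (pe < 1) expect_equal(unname(m["kappa"]), (po - pe) / (1 - pe))
    if (any(truth == "case")) {
      expect_equal(unname(m["sensitivity"]),
                   mean(pred[truth == "case"] == "case"))
    } else {
      expect_true(is.na(m["sensitivity"]))
    }
  }
})

test_that("a strongly separating feature drives accuracy near one", {
  labels <- default_labels()
  set.seed(10)
  x <- cbind(sep = ifelse(labels == "case", 6, 0) + rnorm(128),
             null_features(128, 4))
  res <- suppressWarnings(
    run_nested_cv(x, labels, cv_k = 5, cv_repeats = 5, rf = fast_rf(),
                  boruta_max_iter = 15, seed = 33))
  # Bayes error of two unit-variance Gaussians at d = 6 is ~0.0013
  expect_gt(res$summary$mean[res$summary$metric == "accuracy"], 0.95)
  expect_equal(res$n_iterations, 25)
})

test_that("null data stays inside the permutation-null chance band", {
  labels <- default_labels()
  set.seed(20)
  x <- null_features(128, 10)
  res <- suppressWarnings(
    run_nested_cv(x, labels, cv_k = 5, cv_repeats = 5, rf = fast_rf(),
                  boruta_max_iter = 10, seed = 55))
  acc <- res$summary$mean[res$summary$metric == "accuracy"]
  kap <- res$summary$mean[res$summary$metric == "kappa"]
  expect_gt(acc, 0.35); expect_lt(acc, 0.65)
  expect_gt(kap, -0.2); expect_lt(kap, 0.2)
  # metric ranges and SDs
  expect_true(all(res$summary$sd >= 0))
  expect_true(all(res$summary$mean[res$summary$metric != "kappa"] >= 0))
})

test_that("the held-out fold never influences selection (no leakage)", {
  labels <- default_labels()
  set.seed(14)
  x <- cbind(sig = ifelse(labels == "case", 1.5, 0) + rnorm(128),
             null_features(128, 7))
  base <- suppressWarnings(
    run_nested_cv(x, labels, cv_k = 2, cv_repeats = 1, rf = fast_rf(),
                  boruta_max_iter = 8, seed = 88))
  # corrupt the rows of fold 1 (the test fold of iteration 1): training of
  # iteration 1 is untouched, so its selection must be identical
  test1 <- base$records[[1]]$test_idx
  x2 <- x
  x2[test1, ] <- 1e6
  mod <- suppressWarnings(
    run_nested_cv(x2, labels, cv_k = 2, cv_repeats = 1, rf = fast_rf(),
                  boruta_max_iter = 8, seed = 88))
  expect_identical(mod$records[[1]]$test_idx, test1)
  expect_identical(mod$selections[[1]], base$selections[[1]])
  # and test indices are disjoint from the training data by construction
  expect_length(intersect(base$records[[1]]$test_idx,
                          base$records[[2]]$test_idx), 0)
})

test_that("repeated CV is deterministic under a fixed seed", {
  labels <- default_labels()
  set.seed(3)
  x <- cbind(sig = ifelse(labels == "case", 2, 0) + rnorm(128),
             null_features(128, 6))
  r1 <- suppressWarnings(run_nested_cv(x, labels, cv_k = 3, cv_repeats = 2,
                                       rf = fast_rf(), boruta_max_iter = 8,
                                       seed = 77))
  r2 <- suppressWarnings(run_nested_cv(x, labels, cv_k = 3, cv_repeats = 2,
                                       rf = fast_rf(), boruta_max_iter = 8,
                                       seed = 77))
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$selections, r2$selections)
})

test_that("selection frequency counts iterations correctly", {
  recs <- c(replicate(498, list("f1")), replicate(2, list(character(0))))
  freq <- selection_frequency(recs, 500, feature_ids = c("f1", "f2"))
  expect_equal(unname(freq["f1"]), 0.996)
  expect_equal(unname(freq["f2"]), 0)     # never selected, still reported
  recs2 <- c(replicate(250, list("f1")), replicate(250, list(character(0))))
  expect_equal(unname(selection_frequency(recs2, 500)["f1"]), 0.5)
  expect_error(selection_frequency(recs, 400), "does not match")
})
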