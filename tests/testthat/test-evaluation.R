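test_that("the stratified split rounds per class and stays disjoint-exhaustive", {
  tab <- make_gauss_table(70, 71, mu1 = 1, mu0 = 0, seed = 1)
  sp <- stratified_split(tab, 0.7, seed = 2)
  expect_equal(sum(sp$train$group == "FXS"), 49)   # round(70 * 0.7)
  expect_equal(sum(sp$train$group == "CON"), 50)   # round(71 * 0.7)
  expect_equal(sum(sp$test$group == "FXS"), 21)
  expect_equal(sum(sp$test$group == "CON"), 21)
  expect_equal(sort(c(sp$train$participant, sp$test$participant)),
               sort(tab$participant))
  expect_error(stratified_split(tab, 1.0), "empty test set")
  sp2 <- stratified_split(tab, 0.7, seed = 2)
  expect_identical(sp, sp2)
  sp3 <- stratified_split(tab, 0.7, seed = 3)
  expect_false(identical(sp$train$participant, sp3$train$participant))
  expect_equal(table(sp3$train$group), table(sp$train$group))
})

test_that("rank-based AUC matches exhaustive pair counting and trapezoids", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.3), c("FXS", "FXS", "CON", "CON")), 1.0)
  expect_equal(roc_auc(c(0.9, 0.4, 0.8, 0.3), c("FXS", "FXS", "CON", "CON")), 0.75)
  expect_error(roc_auc(1:3, rep("FXS", 3)), "both classes")

  pair_count_auc <- function(scores, labels) {
    pos <- scores[labels == "FXS"]; neg <- scores[labels == "CON"]
    g <- outer(pos, neg, `>`); t <- outer(pos, neg, `==`)
    (sum(g) + 0.5 * sum(t)) / (length(pos) * length(neg))
  }
  set.seed(4)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    labels <- sample(rep(c("FXS", "CON"), length.out = n + 1))
    scores <- round(runif(n + 1), sample(1:3, 1))  # force ties
    a <- roc_auc(scores, labels)
    expect_equal(a, pair_count_auc(scores, labels), tolerance = 1e-12)
    expect_equal(a, roc_trapezoid_auc(roc_points(scores, labels)),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(5)
  for (i in 1:20) {
    labels <- sample(rep(c("FXS", "CON"), each = 15))
    scores <- round(rnorm(30) + (labels == "FXS"), 1)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("CON", "FXS"),
                                          direction = "<", quiet = TRUE)))
    expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(6)
  labels <- sample(rep(c("FXS", "CON"), each = 25))
  scores <- rnorm(50) + (labels == "FXS")
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(scores), labels), a, tolerance = 1e-12)
  expect_equal(roc_auc(rank(scores), labels), a, tolerance = 1e-12)
})

test_that("ROC curves run from (0,0) to (1,1) with both axes non-decreasing", {
  set.seed(7)
  labels <- sample(rep(c("FXS", "CON"), each = 10))
  roc <- roc_points(round(runif(20), 1), labels)
  expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("cross-validation error hits the obvious limits", {
  sep <- make_gauss_table(50, 50, mu1 = 100, mu0 = 0, sd1 = 0.1, sd0 = 0.1, seed = 8)
  expect_equal(kfold_cv_error(sep, "f1", seed = 1), 0)

  same <- make_gauss_table(100, 100, mu1 = 0, mu0 = 0, seed = 9)
  expect_lt(abs(kfold_cv_error(same, "f1", seed = 1) - 0.5), 0.12)
})

test_that("cross-validation error approaches the two-Gaussian Bayes rate", {
  tab <- make_gauss_table(500, 500, mu1 = 2, mu0 = 0, seed = 10)
  err <- kfold_cv_error(tab, "f1", seed = 2)
  expect_lt(abs(err - pnorm(-1)), 0.035)  # Phi(-1) ~ 0.159, 3 binomial SE
})

test_that("small classes reduce the fold count with a warning", {
  tab <- make_gauss_table(6, 30, mu1 = 2, mu0 = 0, seed = 11)
  expect_warning(kfold_cv_error(tab, "f1", k = 10, seed = 1), "reducing folds")
  expect_error(kfold_cv_error(tab, "f1", k = 10, seed = 1, strict = TRUE),
               "cannot fill")
})

test_that("label permutation drives AUC and accuracy to chance", {
  set.seed(12)
  tab <- make_gauss_table(150, 150, mu1 = 2, mu0 = 0, seed = 12)
  tab$group <- sample(tab$group)
  ev <- suppressWarnings(evaluate_variable_set(tab, "f1", seed = 13))
  expect_lt(abs(ev$summary$auc_full - 0.5), 0.12)
  expect_lt(abs(ev$summary$cv_error - 0.5), 0.12)
})

test_that("the full evaluation report is complete, consistent and reproducible", {
  sep <- make_gauss_table(40, 40, mu1 = 50, mu0 = 0, sd1 = 0.5, sd0 = 0.5, seed = 14)
  ev <- evaluate_variable_set(sep, "f1", seed = 15, name = "separable")
  s <- ev$summary
  expect_equal(s$auc_holdout, 1)
  expect_equal(s$auc_full, 1)
  expect_equal(s$cv_error, 0)
  expect_equal(s$tp + s$fp + s$tn + s$fn, nrow(sep))
  expect_equal(s$n, 80)
  ev2 <- evaluate_variable_set(sep, "f1", seed = 15, name = "separable")
  expect_identical(ev$summary, ev2$summary)
  expect_identical(ev$roc, ev2$roc)
})

test_that("NBC evaluation matches analytic AUC for the peak-alpha parameters", {
  # raw variable as score: population AUC = Phi(0.40 / sqrt(0.52^2 + 0.29^2))
  stats <- cohort_stats("alphapeak")
  comp <- tibble::tibble(group = c("FXS", "CON"), sex = "M", mosaic = FALSE,
                         n = 1000L, cohort = c("fxs", "con"))
  tab <- simulate_feature_table(stats, comp, seed = 16)
  raw_auc <- roc_auc(-tab$Posterior, tab$group)  # FXS peaks are slower
  expect_lt(abs(raw_auc - 0.7491), 0.035)

  # fitted-NBC posterior as score: the quadratic discriminant's population
  # AUC under these unequal variances is 0.7712 (numeric oracle)
  ev <- evaluate_variable_set(tab, "Posterior", seed = 17)
  expect_lt(abs(ev$summary$auc_full - 0.7712), 0.035)

  # equal variances: posterior is monotone in x, the two routes coincide
  eq <- make_gauss_table(400, 400, mu1 = 1, mu0 = 0, seed = 18)
  m <- nbc_fit(eq, "f1")
  expect_equal(roc_auc(nbc_posterior(m, eq), eq$group),
               roc_auc(eq$f1, eq$group), tolerance = 1e-12)
})
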