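test_that("metric panel matches closed forms and the pair-counting AUC oracle", {
  lab <- c(1, 1, 0, 0, 1, 0)
  m <- metric_panel(lab, lab)
  expect_true(all(m[c("roc_auc", "pr_auc", "sensitivity", "specificity",
                      "accuracy", "precision")] == 1))

  cst <- metric_panel(rep(0.5, 6), lab)
  expect_equal(unname(cst["roc_auc"]), 0.5)
  expect_equal(unname(cst["sensitivity"]), 1)   # 0.5 >= threshold
  expect_equal(unname(cst["specificity"]), 0)

  for (seed in 1:8) {
    set.seed(seed)
    n <- 30
    s <- round(stats::runif(n), 2)               # ties included
    y <- stats::rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_equal(unname(metric_panel(s, y)["roc_auc"]), oracle_auc(s, y),
                 tolerance = 1e-12)
  }
  expect_error(metric_panel(c(0.1, 0.9), c(1, 1)), "one class")
})

test_that("stratified folds partition the cohort and preserve the class ratio", {
  set.seed(2)
  y <- stats::rbinom(244, 1, 0.34)
  f <- stratified_folds(y, 50, seed = 7)
  expect_equal(sort(unique(f)), 1:50)
  expect_equal(length(f), 244)
  expect_true(all(table(f) %in% 4:5))
  # per-fold positive count within rounding of the stratified share
  pos_per_fold <- tapply(y, f, sum)
  expect_true(all(abs(pos_per_fold - sum(y) / 50) <= 1))
  expect_identical(f, stratified_folds(y, 50, seed = 7))
  expect_false(identical(f, stratified_folds(y, 50, seed = 8)))
})

test_that("cross-validation is perfect on separable data and null on noise", {
  set.seed(9)
  n <- 300
  x <- stats::rnorm(n)
  sep <- data.frame(y = as.integer(x > 0), f1 = x, center = 1)
  rec <- model_recipe("y", clinical = character(), tumor_features = "f1",
                      screen_alpha = NULL, selection = "none")
  cv <- suppressWarnings(stratified_cv(rec, sep, k = 10, seed = 3))
  expect_equal(unname(cv$mean["roc_auc"]), 1)
  expect_equal(unname(cv$mean["accuracy"]), 1)

  # labels independent of features: mean AUC near 1/2
  nul <- data.frame(y = stats::rbinom(500, 1, 0.5),
                    f1 = stats::rnorm(500), f2 = stats::rnorm(500))
  recn <- model_recipe("y", clinical = character(),
                       tumor_features = c("f1", "f2"),
                       screen_alpha = NULL, selection = "none")
  cvn <- suppressWarnings(stratified_cv(recn, nul, k = 50, seed = 5))
  expect_lt(abs(cvn$mean[["roc_auc"]] - 0.5), 0.05)

  # determinism: same seed, same folds and metrics
  cvn2 <- suppressWarnings(stratified_cv(recn, nul, k = 50, seed = 5))
  expect_identical(cvn$fold, cvn2$fold)
  expect_equal(cvn$per_fold, cvn2$per_fold)
})

test_that("single-class held-out folds are excluded with a count", {
  set.seed(4)
  n <- 60
  d <- data.frame(y = c(rep(1, 6), rep(0, n - 6)), f1 = stats::rnorm(n))
  rec <- model_recipe("y", clinical = character(), tumor_features = "f1",
                      screen_alpha = NULL, selection = "none")
  cv <- suppressWarnings(stratified_cv(rec, d, k = 20, seed = 1))
  # only 6 positives in 20 folds: most folds have one class only
  expect_gte(cv$n_excluded[["roc_auc"]], 14)
  expect_true(all(is.finite(cv$mean[c("roc_auc", "accuracy", "sensitivity",
                                      "specificity")])))
})

test_that("paired permutation test has the stated null and extreme behavior", {
  set.seed(11)
  k <- 50
  fold <- rep(1:k, length.out = 200)
  mk_cv <- function(auc) {
    pf <- data.frame(roc_auc = auc, pr_auc = auc, sensitivity = auc,
                     specificity = auc, accuracy = auc, precision = auc)
    structure(list(per_fold = pf, fold = fold, k = k, seed = 1,
                   outcome = "y"), class = "cv_result")
  }
  a <- mk_cv(stats::runif(k, 0.5, 0.9))
  pid <- permutation_compare(a, a, n_perm = 500, seed = 2)
  expect_true(all(pid$p_value >= 0.5))           # identical models: p = 1
  expect_equal(unname(pid$p_value["roc_auc"]), 1)

  b <- mk_cv(a$per_fold$roc_auc + 0.2)           # uniform +0.2 shift
  psh <- permutation_compare(a, b, n_perm = 1000, seed = 3)
  expect_equal(unname(psh$p_value["roc_auc"]), 1 / 1001)

  bad <- mk_cv(stats::runif(k)); bad$fold <- rev(fold)
  expect_error(permutation_compare(a, bad, n_perm = 10), "not paired")
  bad2 <- mk_cv(stats::runif(49)[c(1:49, 49)]); bad2$k <- 49
  expect_error(permutation_compare(a, bad2, n_perm = 10), "not paired")
})

test_that("permutation p-values are super-uniform under an exchangeable null", {
  set.seed(21)
  k <- 50
  fold <- 1:k
  mk <- function(v) structure(list(
    per_fold = data.frame(roc_auc = v), fold = fold, k = k, seed = 1),
    class = "cv_result")
  pvals <- replicate(120, {
    a <- mk(stats::rnorm(k, 0.7, 0.1))
    b <- mk(stats::rnorm(k, 0.7, 0.1))
    permutation_compare(a, b, n_perm = 400,
                        seed = sample.int(1e6, 1))$p_value[["roc_auc"]]
  })
  rej <- mean(pvals < 0.05)
  expect_gte(rej, 0.0)
  expect_lte(rej, 0.1)
  expect_gt(mean(pvals), 0.4)
})

test_that("cohort summary prints counts with one-decimal percentages", {
  n <- 244
  tab <- data.frame(
    G3 = rep(c(1, 0), c(82, 162)),
    MVI = rep(c(1, 0), c(139, 105)),
    major_hepatectomy = rep(c(1, 0), c(128, 116)),
    preop_chemo = rep(c(1, 0), c(26, 218)),
    cirrhosis = rep(c(1, 0), c(0, 244)))
  s <- cohort_summary(tab)
  val <- function(ch) s$value[s$characteristic == ch]
  expect_equal(val("Tumor grading, G3"), "82 (33.6%)")
  expect_equal(val("Microscopic vascular invasion"), "139 (57.0%)")
  expect_equal(val("Major hepatectomy"), "128 (52.5%)")
  expect_equal(val("Liver cirrhosis"), "0 (0.0%)")     # empty category
  expect_equal(s$percent[s$characteristic == "Tumor grading, G3"], 33.6)
})
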