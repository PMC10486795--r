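#' Classification metric panel
#'
#' ROC AUC by the rank (Mann-Whitney) statistic with tie correction; PR AUC
#' by step integration of the precision-recall curve over descending score
#' thresholds; sensitivity, specificity, accuracy and precision at a fixed
#' probability threshold (default 0.5). Precision with no predicted
#' positives is reported NA.
#'
#' @param scores numeric predicted probabilities/scores.
#' @param labels binary 0/1 labels; both classes must be present.
#' @param threshold classification threshold on the score.
#' @return Named numeric: roc_auc, pr_auc, sensitivity, specificity,
#'   accuracy, precision.
#' @export
metric_panel <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  if (anyNA(scores) || anyNA(labels)) stop("scores/labels contain NA")
  if (length(unique(labels)) < 2L)
    stop("metric panel undefined: only one class present")
  pos <- labels == 1
  np <- sum(pos); nn <- sum(!pos)
  r <- rank(scores)
  auc <- (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)

  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)   # evaluate at threshold group ends
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / np
  precision <- tp / (tp + fp)
  pr_auc <- sum(diff(c(0, recall)) * precision)

  pred <- as.integer(scores >= threshold)
  tp2 <- sum(pred == 1 & labels == 1)
  tn2 <- sum(pred == 0 & labels == 0)
  fp2 <- sum(pred == 1 & labels == 0)
  fn2 <- sum(pred == 0 & labels == 1)
  c(roc_auc = auc,
    pr_auc = pr_auc,
    sensitivity = tp2 / (tp2 + fn2),
    specificity = tn2 / (tn2 + fp2),
    accuracy = (tp2 + tn2) / length(labels),
    precision = if (tp2 + fp2 > 0) tp2 / (tp2 + fp2) else NA_real_)
}

#' Stratified k-fold assignment
#'
#' Folds partition the rows; within each outcome class, rows are shuffled
#' under the seed and dealt round-robin, so every fold's class ratio matches
#' the cohort's up to rounding.
#'
#' @param labels binary outcome vector.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return Integer fold id per row.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  n <- length(labels)
  if (k < 2L || k > n) stop("`k` must be between 2 and n")
  fold <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx)   # stagger classes across folds
    }
  })
  fold
}

#' Stratified k-fold cross-validation of a model recipe
#'
#' Repeats the entire pipeline (standardization, per-block pruning,
#' screening, model selection, fitting) inside each training split, so the
#' held-out fold never informs selection (\code{refit_selection = TRUE},
#' the strict default). With \code{refit_selection = FALSE} the candidate
#' set is selected once on the full table and only the selected model's
#' coefficients are refit per training split. Per-fold metrics are computed
#' on the held-out fold at the probability threshold; with k large relative
#' to n, folds hold very few patients and per-fold metrics are highly
#' variable (large SDs are expected). Folds whose held-out part contains a
#' single class have an undefined panel: they are excluded from the
#' mean/SD, with the count reported.
#'
#' @param recipe a \code{\link{model_recipe}}.
#' @param data complete-case data.frame.
#' @param k number of folds (default 50).
#' @param seed fold-assignment seed; cv results sharing \code{k} and
#'   \code{seed} are paired.
#' @param refit_selection rerun selection inside each fold (default TRUE).
#' @param threshold classification threshold (default 0.5).
#' @return Object of class \code{cv_result}: \code{per_fold} (k x metric
#'   data.frame, NA for undefined folds), \code{mean}, \code{sd},
#'   \code{n_excluded} per metric, \code{fold} assignment, \code{k},
#'   \code{seed}.
#' @export
stratified_cv <- function(recipe, data, k = 50L, seed = 1L,
                          refit_selection = TRUE, threshold = 0.5) {
  stopifnot(inherits(recipe, "model_recipe"))
  y <- data[[recipe$outcome]]
  fold <- stratified_folds(y, k, seed)
  base_recipe <- recipe
  if (!refit_selection) {
    full <- fit_pipeline(recipe, data, seed = seed)
    sel <- full$model$selected_terms %||% full$candidates
    sel <- gsub("^`|`$", "", sel)
    base_recipe <- model_recipe(
      outcome = recipe$outcome,
      clinical = intersect(recipe$clinical, sel),
      tumor_features = intersect(recipe$tumor_features, sel),
      margin_features = intersect(recipe$margin_features, sel),
      prune_threshold = recipe$prune_threshold,
      screen_alpha = NULL, selection = "none",
      standardize = recipe$standardize)
  }
  metrics <- c("roc_auc", "pr_auc", "sensitivity", "specificity",
               "accuracy", "precision")
  per_fold <- matrix(NA_real_, k, length(metrics),
                     dimnames = list(NULL, metrics))
  for (f in seq_len(k)) {
    tr <- data[fold != f, , drop = FALSE]
    te <- data[fold == f, , drop = FALSE]
    if (nrow(te) == 0L) next
    fitted <- suppressWarnings(fit_pipeline(base_recipe, tr, seed = seed))
    p <- predict(fitted, te)
    yt <- te[[recipe$outcome]]
    if (length(unique(yt)) < 2L) next          # undefined fold, stays NA
    per_fold[f, ] <- metric_panel(p, yt, threshold)
  }
  pf <- as.data.frame(per_fold)
  structure(list(per_fold = pf,
                 mean = colMeans(pf, na.rm = TRUE),
                 sd = apply(pf, 2, stats::sd, na.rm = TRUE),
                 n_excluded = colSums(is.na(pf)),
                 fold = fold, k = k, seed = seed,
                 outcome = recipe$outcome,
                 refit_selection = refit_selection),
            class = "cv_result")
}

#' @exportS3Method
print.cv_result <- function(x, digits = 3, ...) {
  cat(sprintf("<cv_result> %s, stratified %d-fold CV (seed %d)%s\n",
              x$outcome, x$k, x$seed,
              if (x$refit_selection) ", selection refit per fold" else ""))
  tab <- data.frame(metric = names(x$mean),
                    mean = signif(x$mean, digits),
                    sd = signif(x$sd, digits),
                    n_excluded = x$n_excluded)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
plot.cv_result <- function(x, ...) {
  graphics::boxplot(x$per_fold, las = 2, ylab = "per-fold value",
                    main = sprintf("%s: %d-fold CV", x$outcome, x$k), ...)
  invisible(x)
}

#' Paired one-sided permutation comparison of two cross-validated models
#'
#' Requires two \code{cv_result}s computed on identical fold assignments
#' (same k, same fold seed, same rows). For each metric, the per-fold
#' differences d = b - a (complete pairs only) are sign-flipped
#' \code{n_perm} times; the one-sided p-value for the alternative "model b
#' exceeds model a on average" is
#' \deqn{p = (1 + \#\{permuted\ mean \ge observed\ mean\}) / (1 + n_{perm}).}
#'
#' @param cv_a,cv_b \code{cv_result} objects (reference and comparison).
#' @param n_perm number of sign-flip permutations (default 10000).
#' @param seed RNG seed.
#' @param metrics metric columns to compare (default: all shared).
#' @return Object of class \code{perm_result}: per-metric one-sided
#'   p-values, observed mean differences, n_perm, seed, direction.
#' @export
permutation_compare <- function(cv_a, cv_b, n_perm = 10000L, seed = 1L,
                                metrics = NULL) {
  stopifnot(inherits(cv_a, "cv_result"), inherits(cv_b, "cv_result"))
  if (cv_a$k != cv_b$k || !identical(cv_a$fold, cv_b$fold))
    stop("cv results are not paired: fold assignments differ (same k and fold seed required)")
  metrics <- metrics %||% intersect(names(cv_a$per_fold), names(cv_b$per_fold))
  p <- obs <- stats::setNames(numeric(length(metrics)), metrics)
  npairs <- stats::setNames(integer(length(metrics)), metrics)
  with_seed(seed, {
    for (mm in metrics) {
      d <- cv_b$per_fold[[mm]] - cv_a$per_fold[[mm]]
      d <- d[!is.na(d)]
      npairs[mm] <- length(d)
      if (length(d) == 0L) { p[mm] <- NA_real_; obs[mm] <- NA_real_; next }
      o <- mean(d)
      signs <- matrix(sample(c(-1, 1), n_perm * length(d), replace = TRUE),
                      nrow = n_perm)
      perm <- as.numeric(signs %*% d) / length(d)
      p[mm] <- (1 + sum(perm >= o - 1e-12)) / (1 + n_perm)
      obs[mm] <- o
    }
  })
  structure(list(p_value = p, observed_diff = obs, n_pairs = npairs,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 direction = "b > a (one-sided)"),
            class = "perm_result")
}

#' @exportS3Method
print.perm_result <- function(x, digits = 4, ...) {
  cat(sprintf("<perm_result> paired sign-flip test, %d permutations, H1: %s\n",
              x$n_perm, x$direction))
  print(data.frame(metric = names(x$p_value),
                   mean_diff = signif(x$observed_diff, digits),
                   p_one_sided = signif(x$p_value, digits),
                   n_pairs = x$n_pairs),
        row.names = FALSE)
  invisible(x)
}
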