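#' Define a clinical-radiomic model recipe
#'
#' A recipe bundles everything needed to rebuild a predictive model from a
#' training table: the outcome, the clinical candidate block, the Tumor-VOI
#' and Margin-VOI feature blocks, the pruning threshold, the univariate
#' screening rule and the selection family. Nested blocks
#' (clinical -> +Tumor -> +Tumor+Margin) are obtained by supplying the
#' corresponding feature columns.
#'
#' @param outcome \code{"G3"} or \code{"MVI"} (any binary 0/1 column).
#' @param clinical clinical candidate columns.
#' @param tumor_features,margin_features feature columns of the two VOI
#'   blocks (either may be empty for a smaller block).
#' @param prune_threshold absolute-correlation cutoff applied per VOI block
#'   (default 0.85).
#' @param screen_alpha univariate screening threshold on clinical variables
#'   (default 0.1); \code{NULL} disables screening.
#' @param a_priori clinical columns always kept as candidates regardless of
#'   screening.
#' @param selection model family: \code{"backward"} (default),
#'   \code{"forward"}, \code{"stepwise"}, \code{"lasso"}, \code{"ridge"} or
#'   \code{"none"} (full model).
#' @param criterion elimination criterion for subset selection.
#' @param standardize z-score continuous predictors using training
#'   statistics (default TRUE, so coefficients/ORs are per SD).
#' @return An object of class \code{model_recipe}.
#' @export
model_recipe <- function(outcome,
                         clinical = c("age", "sex", "hbv", "hcv", "cirrhosis",
                                      "diameter_mm", "solitary", "pattern",
                                      "ca19_9", "preop_chemo",
                                      "major_hepatectomy"),
                         tumor_features = character(),
                         margin_features = character(),
                         prune_threshold = 0.85,
                         screen_alpha = 0.1,
                         a_priori = character(),
                         selection = c("backward", "forward", "stepwise",
                                       "lasso", "ridge", "none"),
                         criterion = "AIC",
                         standardize = TRUE) {
  selection <- match.arg(selection)
  structure(list(outcome = outcome, clinical = clinical,
                 tumor_features = tumor_features,
                 margin_features = margin_features,
                 prune_threshold = prune_threshold,
                 screen_alpha = screen_alpha, a_priori = a_priori,
                 selection = selection, criterion = criterion,
                 standardize = standardize),
            class = "model_recipe")
}

#' Fit the clinical-radiomic pipeline on a training table
#'
#' Runs, on the training data only: (1) z-scoring of continuous predictors
#' by training mean/SD; (2) correlation pruning of the Tumor-VOI and
#' Margin-VOI blocks independently; (3) univariate screening of the
#' clinical block; (4) the configured model selection over the surviving
#' candidates. No information from data outside \code{data} enters any
#' step, so the same function can be called inside cross-validation folds
#' without selection leakage.
#'
#' @param recipe a \code{\link{model_recipe}}.
#' @param data training data.frame (complete cases for used columns).
#' @param seed seed for stochastic members (penalty CV).
#' @return An object of class \code{icc_pipeline}: the final
#'   \code{icc_logit}, the kept candidates and the standardization
#'   statistics, with a \code{predict} method.
#' @export
fit_pipeline <- function(recipe, data, seed = 1L) {
  stopifnot(inherits(recipe, "model_recipe"))
  used <- unique(c(recipe$outcome, recipe$clinical, recipe$tumor_features,
                   recipe$margin_features))
  miss <- setdiff(used, names(data))
  if (length(miss))
    stop("columns missing from table: ", paste(miss, collapse = ", "))
  df <- data[, used, drop = FALSE]
  if (anyNA(df))
    stop("pipeline input contains missing values; run apply_missingness_policy/impute_chained first")

  # (1) standardization statistics from the training data
  cont <- vapply(used, function(cc) {
    x <- df[[cc]]
    cc != recipe$outcome && is.numeric(x) && !is_binary01(x)
  }, logical(1))
  std <- NULL
  if (recipe$standardize && any(cont)) {
    cols <- used[cont]
    mu <- vapply(cols, function(cc) mean(df[[cc]]), numeric(1))
    sdv <- vapply(cols, function(cc) stats::sd(df[[cc]]), numeric(1))
    sdv[sdv == 0] <- 1
    std <- list(cols = cols, mean = mu, sd = sdv)
    for (cc in cols) df[[cc]] <- (df[[cc]] - mu[[cc]]) / sdv[[cc]]
  }

  # (2) per-block feature pruning
  prune_block <- function(cols) {
    if (length(cols) < 2L) return(list(kept = cols, report = NULL))
    rep <- suppressWarnings(
      prune_correlated(df[, cols, drop = FALSE], recipe$prune_threshold))
    list(kept = rep$kept, report = rep)
  }
  pt <- prune_block(recipe$tumor_features)
  pm <- prune_block(recipe$margin_features)

  # (3) clinical screening
  clin <- recipe$clinical
  screen <- NULL
  if (!is.null(recipe$screen_alpha) && length(clin)) {
    screen <- univariate_screen(df, recipe$outcome, clin,
                                alpha = recipe$screen_alpha)
    clin <- union(intersect(recipe$a_priori, recipe$clinical),
                  screen$variable[screen$retained])
  }

  candidates <- c(clin, pt$kept, pm$kept)
  f <- stats::reformulate(if (length(candidates)) sprintf("`%s`", candidates)
                          else "1",
                          response = recipe$outcome)
  model <- switch(recipe$selection,
    none = fit_logistic(f, df, family = "ml"),
    lasso = fit_logistic(f, df, family = "lasso", seed = seed),
    ridge = fit_logistic(f, df, family = "ridge", seed = seed),
    backward_select(f, df, direction = recipe$selection,
                    criterion = recipe$criterion))
  structure(list(recipe = recipe, model = model, std = std,
                 candidates = candidates,
                 prune_tumor = pt$report, prune_margin = pm$report,
                 screen = screen),
            class = "icc_pipeline")
}

#' @export
predict.icc_pipeline <- function(object, newdata, type = "response", ...) {
  df <- newdata
  if (!is.null(object$std))
    for (cc in object$std$cols)
      df[[cc]] <- (df[[cc]] - object$std$mean[[cc]]) / object$std$sd[[cc]]
  predict(object$model, newdata = df, type = type)
}

#' @exportS3Method
print.icc_pipeline <- function(x, ...) {
  cat(sprintf("<icc_pipeline> outcome %s, selection %s\n",
              x$recipe$outcome, x$recipe$selection))
  cat(sprintf("  candidates: %d (clinical %d, tumor %d, margin %d after pruning)\n",
              length(x$candidates),
              length(setdiff(x$candidates,
                             c(x$recipe$tumor_features, x$recipe$margin_features))),
              length(intersect(x$candidates, x$recipe$tumor_features)),
              length(intersect(x$candidates, x$recipe$margin_features))))
  print(x$model)
  invisible(x)
}

#' Report a fitted model as an odds-ratio table
#'
#' Human-readable panel (term, OR, confidence bounds, p) plus an optional
#' JSON export, mirroring the usual multivariate-analysis table layout.
#'
#' @param x an \code{icc_logit}, \code{icc_mem} or \code{icc_pipeline}.
#' @param path optional JSON output path.
#' @return The coefficient table (invisibly if printed).
#' @export
model_report <- function(x, path = NULL) {
  ct <- if (inherits(x, "icc_pipeline")) x$model$coef_table
        else if (inherits(x, "icc_mem")) x$fixed
        else x$coef_table
  if (!is.null(path))
    jsonlite::write_json(ct, path, auto_unbox = TRUE, digits = NA)
  ct
}
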