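#' Apply the cohort missing-data policy
#'
#' Rows missing an outcome or any radiomic feature are excluded. Covariates
#' missing in at least \code{max_missing_frac} of the remaining rows are
#' flagged and excluded from modelling; covariates below the threshold are
#' routed to imputation (\code{\link{impute_chained}}).
#'
#' @param table cohort data.frame.
#' @param outcomes outcome column names (default \code{c("G3", "MVI")}).
#' @param feature_cols radiomic feature column names (default: columns
#'   prefixed \code{Portal_}/\code{Arterial_}).
#' @param max_missing_frac exclusion threshold (default 0.15).
#' @return List of class \code{missingness_report}: \code{table} (rows
#'   filtered), \code{excluded_covariates} (names at/above threshold),
#'   \code{impute_covariates} (names below threshold with any missing),
#'   \code{n_dropped_rows}, \code{missing_fractions}.
#' @export
apply_missingness_policy <- function(table, outcomes = c("G3", "MVI"),
                                     feature_cols = NULL,
                                     max_missing_frac = 0.15) {
  stopifnot(is.data.frame(table))
  outcomes <- intersect(outcomes, names(table))
  if (length(outcomes) == 0L) stop("no outcome columns found in table")
  if (is.null(feature_cols))
    feature_cols <- grep("^(Portal|Arterial)_", names(table), value = TRUE)
  hard <- c(outcomes, feature_cols)
  keep <- !Reduce(`|`, lapply(hard, function(cc) is.na(table[[cc]])),
                  accumulate = FALSE)
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("missing-data policy removed every row (all outcomes/features missing)")
  covars <- setdiff(names(out), c(hard, "id", "center"))
  mf <- vapply(covars, function(cc) mean(is.na(out[[cc]])), numeric(1))
  structure(list(table = out,
                 excluded_covariates = names(mf)[mf >= max_missing_frac],
                 impute_covariates = names(mf)[mf > 0 & mf < max_missing_frac],
                 n_dropped_rows = sum(!keep),
                 missing_fractions = mf),
            class = "missingness_report")
}

#' @exportS3Method
print.missingness_report <- function(x, ...) {
  cat(sprintf("<missingness_report> %d rows dropped; %d covariates excluded (>=15%% missing); %d routed to imputation\n",
              x$n_dropped_rows, length(x$excluded_covariates),
              length(x$impute_covariates)))
  if (length(x$excluded_covariates))
    cat("  excluded:", paste(x$excluded_covariates, collapse = ", "), "\n")
  if (length(x$impute_covariates))
    cat("  to impute:", paste(x$impute_covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Chained-equation imputation
#'
#' Iteratively regresses each incomplete column on all other predictor
#' columns and replaces its missing cells with draws from the fitted
#' predictive distribution (normal linear model with residual-SD noise for
#' numeric columns; logistic Bernoulli draws for binary 0/1 columns).
#' Observed cells are never altered, and results are deterministic under a
#' fixed seed. One completed dataset is returned per call (single-imputation
#' semantics); draw several seeds for multiple imputations.
#'
#' @param table data.frame.
#' @param columns columns to impute (default: all with any NA). Each must be
#'   numeric or binary 0/1; other types must be encoded upstream.
#' @param predictors columns used as regressors (default: all numeric/binary
#'   columns except \code{id}; factors are not auto-encoded).
#' @param n_iterations chained passes over the incomplete columns.
#' @param seed RNG seed.
#' @return The completed data.frame.
#' @export
impute_chained <- function(table, columns = NULL, predictors = NULL,
                           n_iterations = 5L, seed = 1L) {
  stopifnot(is.data.frame(table))
  if (is.null(columns))
    columns <- names(table)[vapply(table, anyNA, logical(1))]
  if (length(columns) == 0L) return(table)
  for (cc in columns) {
    if (!is.numeric(table[[cc]]))
      stop(sprintf("column '%s' is not numeric; declare an encoding before imputation", cc))
  }
  if (is.null(predictors)) {
    predictors <- names(table)[vapply(table, is.numeric, logical(1))]
    predictors <- setdiff(predictors, "id")
  }
  miss <- lapply(columns, function(cc) which(is.na(table[[cc]])))
  names(miss) <- columns
  with_seed(seed, {
    # initialize with column means
    for (cc in columns) {
      mu <- mean(table[[cc]], na.rm = TRUE)
      table[[cc]][miss[[cc]]] <- mu
    }
    for (it in seq_len(n_iterations)) {
      for (cc in columns) {
        ii <- miss[[cc]]
        if (length(ii) == 0L) next
        rhs <- setdiff(predictors, cc)
        X <- as.matrix(table[, rhs, drop = FALSE])
        keep <- apply(X, 2, function(x) stats::sd(x) > 0)
        X <- X[, keep, drop = FALSE]
        y <- table[[cc]]
        obs <- setdiff(seq_len(nrow(table)), ii)
        binary <- is_binary01(y[obs])
        if (binary) {
          fit <- suppressWarnings(
            stats::glm.fit(cbind(1, X[obs, , drop = FALSE]), y[obs],
                           family = stats::binomial()))
          eta <- cbind(1, X[ii, , drop = FALSE]) %*% fit$coefficients
          table[[cc]][ii] <- stats::rbinom(length(ii), 1, stats::plogis(eta))
        } else {
          fit <- stats::lm.fit(cbind(1, X[obs, , drop = FALSE]), y[obs])
          sigma <- sqrt(sum(fit$residuals^2) /
                          max(1, length(obs) - length(fit$coefficients)))
          beta <- fit$coefficients
          beta[is.na(beta)] <- 0
          mu <- cbind(1, X[ii, , drop = FALSE]) %*% beta
          table[[cc]][ii] <- mu + stats::rnorm(length(ii), sd = sigma)
        }
      }
    }
  })
  table
}

#' Prune pairwise-correlated features
#'
#' Greedy deterministic pruning: while any pair of kept features has
#' absolute Pearson correlation above the threshold, the pair with the
#' largest |r| is taken and the member with the larger mean absolute
#' correlation to all other kept features is dropped (ties broken by later
#' column order). The final kept set has max pairwise |r| <= threshold.
#' Constant columns have undefined correlation; they are treated as
#' correlation 0 with a warning (and therefore always kept).
#'
#' @param features data.frame or matrix of feature columns (>= 2), finite
#'   values.
#' @param threshold absolute-correlation cutoff (default 0.85; strictly
#'   greater triggers removal).
#' @return An object of class \code{prune_report}: \code{kept} (names),
#'   \code{dropped} (data.frame with dropped, kept_partner, correlation),
#'   \code{threshold}.
#' @export
prune_correlated <- function(features, threshold = 0.85) {
  X <- as.matrix(as.data.frame(features))
  if (ncol(X) < 2L) stop("need at least 2 feature columns")
  if (!is.numeric(X) || anyNA(X) || any(!is.finite(X)))
    stop("features must be finite numeric values")
  if (is.null(colnames(X))) colnames(X) <- paste0("F", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    warning("constant feature column(s) (undefined correlation) treated as correlation 0: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
  C <- suppressWarnings(abs(stats::cor(X)))
  C[!is.finite(C)] <- 0
  diag(C) <- 0
  keep <- rep(TRUE, ncol(X))
  dropped <- list()
  repeat {
    Ck <- C
    Ck[!keep, ] <- 0
    Ck[, !keep] <- 0
    mx <- max(Ck)
    if (mx <= threshold) break
    idx <- which(Ck == mx, arr.ind = TRUE)[1, ]
    i <- idx[1]; j <- idx[2]
    mac_i <- mean(Ck[i, keep & seq_len(ncol(X)) != i])
    mac_j <- mean(Ck[j, keep & seq_len(ncol(X)) != j])
    drop <- if (mac_i > mac_j) i else if (mac_j > mac_i) j else max(i, j)
    partner <- if (drop == i) j else i
    keep[drop] <- FALSE
    dropped[[length(dropped) + 1L]] <-
      data.frame(dropped = colnames(X)[drop],
                 kept_partner = colnames(X)[partner],
                 correlation = stats::cor(X[, drop], X[, partner]))
  }
  structure(list(kept = colnames(X)[keep],
                 dropped = if (length(dropped)) do.call(rbind, dropped)
                           else data.frame(dropped = character(),
                                           kept_partner = character(),
                                           correlation = numeric()),
                 threshold = threshold),
            class = "prune_report")
}

#' @exportS3Method
print.prune_report <- function(x, ...) {
  cat(sprintf("<prune_report> kept %d features, dropped %d (|r| > %.2f)\n",
              length(x$kept), nrow(x$dropped), x$threshold))
  if (nrow(x$dropped)) print(x$dropped, row.names = FALSE)
  invisible(x)
}

#' Write a prune report as JSON
#' @param x a \code{prune_report}.
#' @param path output path.
#' @export
write_prune_report <- function(x, path) {
  stopifnot(inherits(x, "prune_report"))
  jsonlite::write_json(list(kept = x$kept, dropped = x$dropped,
                            threshold = x$threshold),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
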