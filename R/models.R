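#' Fit a (penalized) multivariate logistic regression
#'
#' Maximum-likelihood logistic regression (\code{family = "ml"}), or
#' lasso/ridge-penalized logistic regression with the penalty strength
#' chosen by internal cross-validated deviance under a fixed seed.
#' Coefficients are reported with odds ratios (\code{OR = exp(coef)}), Wald
#' confidence bounds and p-values (penalized fits report coefficients and
#' ORs only). Complete separation is detected and flagged; a penalized
#' refit is suggested rather than silently returned.
#'
#' @param formula model formula, e.g. \code{G3 ~ age + major_hepatectomy}.
#' @param data data.frame; the outcome must be binary with both classes
#'   present.
#' @param family \code{"ml"}, \code{"lasso"} or \code{"ridge"}.
#' @param conf_level Wald confidence level (default 0.95).
#' @param seed seed for the penalty cross-validation folds.
#' @param nfolds CV folds for the penalty search.
#' @return An object of class \code{icc_logit} with methods \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{residuals} and
#'   \code{simulate}.
#' @export
fit_logistic <- function(formula, data, family = c("ml", "lasso", "ridge"),
                         conf_level = 0.95, seed = 1L, nfolds = 10L) {
  family <- match.arg(family)
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (!is_binary01(y) || length(unique(y)) < 2L)
    stop("outcome must be binary 0/1 with both classes present")
  if (family == "ml") {
    fit <- withCallingHandlers(
      stats::glm(formula, data = data, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    separated <- any(fit$fitted.values > 1 - 1e-8) &&
      any(fit$fitted.values < 1e-8) ||
      max(abs(stats::coef(fit)[-1]), 0, na.rm = TRUE) > 15
    if (separated)
      warning("possible complete separation detected; consider family = 'ridge' or 'lasso'")
    obj <- list(fit = fit, family = family, formula = formula,
                terms = stats::terms(fit), conf_level = conf_level,
                separated = separated,
                coef_table = wald_table(fit, conf_level))
  } else {
    X <- stats::model.matrix(formula, mf)[, -1, drop = FALSE]
    if (ncol(X) < 2L)
      stop("penalized fit needs at least 2 predictors (glmnet constraint)")
    alpha <- if (family == "lasso") 1 else 0
    foldid <- with_seed(seed, sample(rep_len(seq_len(nfolds), nrow(X))))
    cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = alpha,
                            foldid = foldid, type.measure = "deviance")
    cf <- as.numeric(stats::coef(cv, s = "lambda.min"))
    names(cf) <- rownames(stats::coef(cv, s = "lambda.min"))
    ct <- data.frame(term = names(cf), coefficient = cf, OR = exp(cf),
                     lower = NA_real_, upper = NA_real_, p_value = NA_real_,
                     row.names = NULL)
    obj <- list(fit = cv, family = family, formula = formula,
                conf_level = conf_level, separated = FALSE,
                lambda = cv$lambda.min, coef_table = ct,
                x_names = colnames(X))
  }
  obj$n <- length(y)
  obj$outcome <- as.character(formula[[2]])
  structure(obj, class = "icc_logit")
}

wald_table <- function(fit, conf_level) {
  s <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(term = rownames(s),
             coefficient = s[, 1],
             OR = exp(s[, 1]),
             lower = exp(s[, 1] - z * s[, 2]),
             upper = exp(s[, 1] + z * s[, 2]),
             p_value = s[, 4],
             row.names = NULL)
}

#' @exportS3Method
print.icc_logit <- function(x, digits = 3, ...) {
  cat(sprintf("<icc_logit> %s logistic model of %s (n = %d)\n",
              x$family, x$outcome, x$n))
  ct <- x$coef_table
  ct[-1] <- lapply(ct[-1], function(v) signif(v, digits))
  print(ct, row.names = FALSE)
  if (isTRUE(x$separated)) cat("  [flag] possible complete separation\n")
  invisible(x)
}

#' @exportS3Method
summary.icc_logit <- function(object, ...) {
  object$coef_table
}

#' @export
coef.icc_logit <- function(object, ...) {
  stats::setNames(object$coef_table$coefficient, object$coef_table$term)
}

#' @export
predict.icc_logit <- function(object, newdata,
                              type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (object$family == "ml") {
    stats::predict(object$fit, newdata = newdata, type = type)
  } else {
    rhs <- stats::delete.response(stats::terms(object$formula))
    X <- stats::model.matrix(rhs, newdata)[, -1, drop = FALSE]
    eta <- as.numeric(stats::predict(object$fit, newx = X, s = "lambda.min"))
    if (type == "response") stats::plogis(eta) else eta
  }
}

#' @export
residuals.icc_logit <- function(object, type = "deviance", ...) {
  if (object$family != "ml")
    stop("residuals are available for maximum-likelihood fits only")
  stats::residuals(object$fit, type = type)
}

#' @export
simulate.icc_logit <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  p <- predict(object, newdata = newdata, type = "response")
  with_seed(seed, {
    out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1, p)))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

#' Univariate clinical screening
#'
#' Mirrors the standard candidate-screening step: each clinical variable is
#' tested against the binary outcome; categorical variables with the
#' chi-square test (Fisher's exact test when any expected cell count is
#' below 5), continuous variables with the unpaired t-test when
#' approximately normal or the Mann-Whitney U-test otherwise. Normality is
#' mechanized as |skewness| < 1 and |excess kurtosis| < 2 over the pooled
#' values (a documented stand-in for graphical assessment).
#'
#' @param table data.frame.
#' @param outcome binary outcome column name.
#' @param variables candidate clinical columns.
#' @param alpha retention threshold on the univariate p-value (default 0.1).
#' @return data.frame with variable, test used, p-value and retained flag.
#' @export
univariate_screen <- function(table, outcome, variables, alpha = 0.1) {
  y <- table[[outcome]]
  res <- lapply(variables, function(v) {
    x <- table[[v]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; yy <- y[ok]
    if (is.factor(x) || is_binary01(x)) {
      tb <- table(x, yy)
      expected <- outer(rowSums(tb), colSums(tb)) / sum(tb)
      test <- if (any(expected < 5)) "fisher" else "chisq"
      p <- if (test == "fisher") stats::fisher.test(tb)$p.value
           else suppressWarnings(stats::chisq.test(tb, correct = FALSE)$p.value)
    } else {
      mu <- mean(x); s2 <- mean((x - mu)^2)
      sk <- if (s2 > 0) mean((x - mu)^3) / s2^1.5 else 0
      ku <- if (s2 > 0) mean((x - mu)^4) / s2^2 - 3 else 0
      normalish <- abs(sk) < 1 && abs(ku) < 2
      test <- if (normalish) "t" else "mann-whitney"
      p <- if (normalish) stats::t.test(x ~ yy)$p.value
           else suppressWarnings(stats::wilcox.test(x ~ yy)$p.value)
    }
    data.frame(variable = v, test = test, p_value = p, retained = p < alpha)
  })
  do.call(rbind, res)
}

#' Subset selection for logistic regression
#'
#' Backward (default), forward or bidirectional stepwise term selection by
#' AIC (an alpha-threshold mode drops the largest-p term while above
#' \code{alpha}). Selection operates on whole terms (a factor's dummies
#' enter and leave together) using fast IRLS refits; the selected model is
#' then refit with \code{\link{fit_logistic}} for Wald inference. An empty
#' final model (intercept only) is permitted and reported.
#'
#' @param formula full candidate model formula.
#' @param data data.frame with complete cases for the candidate columns.
#' @param direction \code{"backward"}, \code{"forward"} or
#'   \code{"stepwise"}.
#' @param criterion \code{"AIC"} or \code{"alpha"}.
#' @param alpha p-value threshold for \code{criterion = "alpha"}.
#' @return An \code{icc_logit} with extra fields \code{selected_terms} and
#'   \code{trace} (the selection path).
#' @export
backward_select <- function(formula, data,
                            direction = c("backward", "forward", "stepwise"),
                            criterion = c("AIC", "alpha"), alpha = 0.05) {
  direction <- match.arg(direction)
  criterion <- match.arg(criterion)
  tt <- stats::terms(formula, data = data)
  labels <- attr(tt, "term.labels")
  outcome <- as.character(formula[[2]])
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  Xfull <- stats::model.matrix(tt, mf)
  asg <- attr(Xfull, "assign")
  if (qr(Xfull)$rank < ncol(Xfull))
    stop("candidate model matrix is rank deficient; resolve collinearity upstream")

  dev_aic <- function(active) {     # active: logical over labels
    cols <- asg == 0L | asg %in% which(active)
    f <- suppressWarnings(stats::glm.fit(Xfull[, cols, drop = FALSE], y,
                                         family = stats::binomial()))
    c(dev = f$deviance, aic = f$deviance + 2 * sum(cols))
  }
  term_p <- function(active) {      # Wald p per active term (max over dummies)
    cols <- asg == 0L | asg %in% which(active)
    f <- suppressWarnings(stats::glm(y ~ Xfull[, cols, drop = FALSE] - 1,
                                     family = stats::binomial()))
    s <- summary(f)$coefficients
    pv <- rep(NA_real_, length(labels))
    sub_asg <- asg[cols]
    for (k in which(active))
      pv[k] <- max(s[sub_asg == k, 4], na.rm = TRUE)
    pv
  }

  active <- rep(direction != "forward", length(labels))
  trace <- list(list(step = 0L, action = "start",
                     terms = labels[active], aic = dev_aic(active)[["aic"]]))
  repeat {
    cur <- dev_aic(active)[["aic"]]
    best <- NULL
    if (criterion == "alpha" && direction == "backward") {
      pv <- term_p(active)
      if (!any(active) || all(pv[active] <= alpha, na.rm = TRUE)) break
      k <- which.max(ifelse(active, pv, -Inf))
      active[k] <- FALSE
      trace[[length(trace) + 1L]] <- list(step = length(trace),
                                          action = paste("drop", labels[k]),
                                          terms = labels[active],
                                          aic = dev_aic(active)[["aic"]])
      next
    }
    cand <- list()
    if (direction %in% c("backward", "stepwise"))
      for (k in which(active)) {
        a2 <- active; a2[k] <- FALSE
        cand[[length(cand) + 1L]] <- list(a = a2, act = paste("drop", labels[k]))
      }
    if (direction %in% c("forward", "stepwise"))
      for (k in which(!active)) {
        a2 <- active; a2[k] <- TRUE
        cand[[length(cand) + 1L]] <- list(a = a2, act = paste("add", labels[k]))
      }
    if (length(cand) == 0L) break
    aics <- vapply(cand, function(cc) dev_aic(cc$a)[["aic"]], numeric(1))
    if (min(aics) >= cur - 1e-10) break
    best <- cand[[which.min(aics)]]
    active <- best$a
    trace[[length(trace) + 1L]] <- list(step = length(trace), action = best$act,
                                        terms = labels[active],
                                        aic = min(aics))
  }

  kept <- labels[active]
  final_formula <- stats::reformulate(if (length(kept)) kept else "1",
                                      response = outcome)
  out <- fit_logistic(final_formula, data = data, family = "ml")
  out$selected_terms <- kept
  out$candidate_terms <- labels
  out$trace <- trace
  out$direction <- direction
  out$criterion <- criterion
  out
}
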