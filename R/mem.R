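#' Random-intercept logistic model with center-effect quantification
#'
#' Fits a mixed-effect logistic regression with a per-center random
#' intercept, \code{outcome ~ fixed terms + (1 | center)}, and quantifies
#' the center effect with the Variance Partition Coefficient under the
#' latent-threshold method: \deqn{VPC = \sigma^2_u / (\sigma^2_u + \pi^2/3)}
#' where \eqn{\sigma^2_u} is the random-intercept variance and
#' \eqn{\pi^2/3} the residual variance of the latent logistic scale.
#'
#' @param formula fixed-effects formula, e.g.
#'   \code{MVI ~ major_hepatectomy + Portal_Margin_HUQ2}.
#' @param data data.frame.
#' @param group grouping column name (default \code{"center"}); must have at
#'   least 2 levels.
#' @param ... passed to \code{\link[lme4]{glmer}}.
#' @return An object of class \code{icc_mem}: the \code{glmer} fit plus
#'   \code{sigma2_u}, \code{vpc}, \code{fixed} (coefficient table) and
#'   \code{converged}.
#' @export
fit_mem <- function(formula, data, group = "center", ...) {
  if (!group %in% names(data)) stop("grouping column not found: ", group)
  g <- data[[group]]
  if (length(unique(g[!is.na(g)])) < 2L)
    stop("mixed-effect center model needs at least 2 centers")
  full <- stats::update(formula,
                        paste(". ~ . + (1 |", group, ")"))
  fit <- suppressMessages(
    lme4::glmer(full, data = data, family = stats::binomial(),
                control = lme4::glmerControl(calc.derivs = FALSE), ...))
  vc <- lme4::VarCorr(fit)
  s2u <- as.numeric(vc[[group]][1, 1])
  msgs <- fit@optinfo$conv$lme4$messages
  conv <- is.null(msgs)
  if (!conv)
    warning("mixed model convergence diagnostics: ",
            paste(unlist(msgs), collapse = "; "))
  fx <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- stats::qnorm(0.975)
  structure(list(fit = fit,
                 sigma2_u = s2u,
                 vpc = vpc(s2u),
                 fixed = data.frame(term = names(fx), coefficient = fx,
                                    OR = exp(fx),
                                    lower = exp(fx - z * se),
                                    upper = exp(fx + z * se),
                                    p_value = 2 * stats::pnorm(-abs(fx / se)),
                                    row.names = NULL),
                 group = group, converged = conv),
            class = "icc_mem")
}

#' Variance partition coefficient of a random-intercept logistic model
#'
#' @param sigma2_u random-intercept variance (>= 0).
#' @return VPC in \code{[0, 1)}.
#' @export
vpc <- function(sigma2_u) {
  stopifnot(sigma2_u >= 0)
  sigma2_u / (sigma2_u + pi^2 / 3)
}

#' @exportS3Method
print.icc_mem <- function(x, digits = 3, ...) {
  cat(sprintf("<icc_mem> random-intercept logistic model (group = %s)\n", x$group))
  cat(sprintf("  sigma^2_u = %.4g, VPC = %.1f%%%s\n", x$sigma2_u, 100 * x$vpc,
              if (x$converged) "" else "  [convergence flagged]"))
  ct <- x$fixed
  ct[-1] <- lapply(ct[-1], function(v) signif(v, digits))
  print(ct, row.names = FALSE)
  invisible(x)
}

#' @export
coef.icc_mem <- function(object, ...) {
  stats::setNames(object$fixed$coefficient, object$fixed$term)
}
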