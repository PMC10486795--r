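#' Configuration for the synthetic multicenter cohort
#'
#' Generates a per-patient table whose structure mirrors a multicenter ICC
#' surgical cohort: clinical covariates drawn from documented marginal
#' distributions, radiomic feature columns (multivariate normal, or attached
#' externally from phantom extraction), per-center random intercepts, and
#' binary outcomes \code{G3} and \code{MVI} drawn from a logistic model
#'
#' \deqn{logit P(y=1) = intercept + X_clin beta_clinical +
#' X_feat beta_features + u_center, u_center ~ N(0, center_sd^2).}
#'
#' Effects are per SD for continuous covariates (age, tumor diameter and
#' log CA 19-9 are standardized internally before entering the linear
#' predictor) and per category for binary ones. Missingness is applied
#' completely at random, at rate \code{missing_rate}, to the covariates in
#' \code{missing_cols}.
#'
#' Default clinical marginals (documented; chosen for recognisable realism,
#' not fidelity): age ~ N(67, 11) clipped to 21-86; female 51\%; HBV 7.8\%;
#' HCV 11.1\%; cirrhosis 10.7\%; diameter log-normal, median 50 mm; tumor
#' pattern 1/2/3 with probabilities 0.62/0.25/0.13; solitary 84.4\%;
#' CA 19-9 log-normal, median 29 U/mL; preoperative chemotherapy 10.7\%;
#' major hepatectomy 52.5\%.
#'
#' @param n_patients number of rows.
#' @param n_centers number of centers (>= 1), uneven sizes.
#' @param center_sd SD (nonnegative) of the per-center random intercept on
#'   the log-odds scale.
#' @param beta_clinical named numeric of clinical log-odds effects, or a
#'   list with elements \code{G3} and \code{MVI} for outcome-specific
#'   effects. Names must match generated columns.
#' @param beta_features named numeric (or \code{list(G3=, MVI=)}) of feature
#'   log-odds effects per SD.
#' @param intercept baseline log-odds (single number or
#'   \code{list(G3=, MVI=)}). Ignored for an outcome with a prevalence
#'   target.
#' @param outcome_prevalence_target optional named vector/list, e.g.
#'   \code{c(G3 = 0.336, MVI = 0.57)}; the intercept is then calibrated so
#'   the expected prevalence over the drawn covariates matches the target.
#' @param missing_rate MCAR missingness fraction in \code{[0, 1)} applied to
#'   \code{missing_cols}.
#' @param missing_cols covariates receiving missingness (default
#'   \code{"ca19_9"}, mirroring the typical preoperative-marker gap).
#' @param n_tumor_features,n_margin_features number of synthetic feature
#'   columns per VOI when features are drawn rather than attached; columns
#'   are named \code{Portal_Tumor_F1...}/\code{Portal_Margin_F1...} unless
#'   \code{feature_names} is given.
#' @param feature_names optional full character vector of feature column
#'   names (overrides the two counts).
#' @param feature_rho AR(1) correlation between consecutive feature columns
#'   within each VOI block.
#' @param seed integer RNG seed.
#' @return An object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_patients = 244L, n_centers = 6L, center_sd = 1.0,
                          beta_clinical = NULL, beta_features = NULL,
                          intercept = 0,
                          outcome_prevalence_target = c(G3 = 0.336, MVI = 0.57),
                          missing_rate = 0.123, missing_cols = "ca19_9",
                          n_tumor_features = 8L, n_margin_features = 8L,
                          feature_names = NULL, feature_rho = 0.6,
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_centers = as.integer(n_centers),
              center_sd = center_sd,
              beta_clinical = beta_clinical,
              beta_features = beta_features,
              intercept = intercept,
              outcome_prevalence_target = outcome_prevalence_target,
              missing_rate = missing_rate, missing_cols = missing_cols,
              n_tumor_features = as.integer(n_tumor_features),
              n_margin_features = as.integer(n_margin_features),
              feature_names = feature_names, feature_rho = feature_rho,
              seed = as.integer(seed))
  if (cfg$n_patients < 1L) stop("`n_patients` must be >= 1")
  if (cfg$n_centers < 1L) stop("`n_centers` must be >= 1")
  if (cfg$center_sd < 0) stop("`center_sd` must be >= 0")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("`missing_rate` must be in [0, 1)")
  if (abs(cfg$feature_rho) >= 1) stop("`feature_rho` must be in (-1, 1)")
  structure(cfg, class = "cohort_config")
}

# default clinical effect sizes: log odds ratios on the scale of the
# standardized design, loosely matched to the magnitude of the final-model
# odds ratios of the target study population
default_beta_clinical <- function() {
  list(G3 = c(major_hepatectomy = log(1.661)),
       MVI = c(age = log(0.75), ca19_9 = log(1.3),
               major_hepatectomy = log(2.760)))
}

#' Generate a synthetic multicenter cohort table
#'
#' @param config a \code{\link{cohort_config}}.
#' @param features optional data.frame/matrix of externally extracted feature
#'   columns (e.g. from \code{\link{extract_all}} over phantoms), one row per
#'   patient; replaces the drawn feature block.
#' @return A \code{data.frame} with columns \code{id}, \code{center},
#'   clinical covariates (\code{age}, \code{sex}, \code{hbv}, \code{hcv},
#'   \code{cirrhosis}, \code{diameter_mm}, \code{solitary}, \code{pattern},
#'   \code{ca19_9}, \code{preop_chemo}, \code{major_hepatectomy}), outcomes
#'   \code{G3} and \code{MVI}, and the feature columns. Deterministic given
#'   the config seed.
#' @export
make_cohort <- function(config = cohort_config(), features = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  with_seed(config$seed, {
    center_w <- stats::rgamma(config$n_centers, shape = 2)
    center <- sample.int(config$n_centers, n, replace = TRUE,
                         prob = center_w / sum(center_w))
    tab <- data.frame(
      id = seq_len(n),
      center = factor(center, levels = seq_len(config$n_centers)),
      age = pmin(pmax(round(stats::rnorm(n, 67, 11)), 21), 86),
      sex = stats::rbinom(n, 1, 0.492),           # 1 = male
      hbv = stats::rbinom(n, 1, 0.078),
      hcv = stats::rbinom(n, 1, 0.111),
      cirrhosis = stats::rbinom(n, 1, 0.107),
      diameter_mm = pmin(pmax(stats::rlnorm(n, log(50), 0.55), 10), 270),
      solitary = stats::rbinom(n, 1, 0.844),
      pattern = factor(sample(1:3, n, replace = TRUE,
                              prob = c(0.62, 0.25, 0.13)), levels = 1:3),
      ca19_9 = stats::rlnorm(n, log(29), 1.6),
      preop_chemo = stats::rbinom(n, 1, 0.107),
      major_hepatectomy = stats::rbinom(n, 1, 0.525))

    if (is.null(features)) {
      fn <- config$feature_names %||% c(
        if (config$n_tumor_features > 0)
          paste0("Portal_Tumor_F", seq_len(config$n_tumor_features)),
        if (config$n_margin_features > 0)
          paste0("Portal_Margin_F", seq_len(config$n_margin_features)))
      nt <- if (is.null(config$feature_names)) config$n_tumor_features
            else length(fn)
      X <- if (length(fn) > 0)
        ar1_block(n, length(fn),
                  if (is.null(config$feature_names))
                    c(config$n_tumor_features, config$n_margin_features)
                  else length(fn),
                  config$feature_rho)
      else NULL
      if (!is.null(X)) { colnames(X) <- fn; tab <- cbind(tab, X) }
    } else {
      features <- as.data.frame(features)
      if (nrow(features) != n)
        stop("external `features` must have one row per patient")
      tab <- cbind(tab, features)
    }

    u <- stats::rnorm(config$n_centers, 0, config$center_sd)
    for (oc in c("G3", "MVI")) {
      lp0 <- linear_predictor(tab, config, oc) + u[as.integer(tab$center)]
      tgt <- prevalence_target(config, oc)
      a <- if (!is.null(tgt)) calibrate_intercept(lp0, tgt)
           else outcome_field(config$intercept, oc, 0)
      tab[[oc]] <- stats::rbinom(n, 1, stats::plogis(a + lp0))
    }

    if (config$missing_rate > 0 && length(config$missing_cols) > 0) {
      for (cc in config$missing_cols) {
        if (!cc %in% names(tab)) stop("missingness column not in table: ", cc)
        miss <- stats::runif(n) < config$missing_rate
        tab[[cc]][miss] <- NA
      }
    }
    tab
  })
}

# AR(1)-correlated standard-normal block; correlation resets between the
# sub-blocks given in `blocks` (vector of block sizes).
ar1_block <- function(n, p, blocks, rho) {
  X <- matrix(stats::rnorm(n * p), n, p)
  if (rho != 0) {
    start <- cumsum(c(1, blocks))[seq_along(blocks)]
    for (j in 2:max(2, p)) {
      if (p < 2) break
      if (j %in% start) next
      X[, j] <- rho * X[, j - 1] + sqrt(1 - rho^2) * X[, j]
    }
  }
  X
}

outcome_field <- function(x, outcome, default) {
  if (is.null(x)) return(default)
  if (is.list(x) && !is.null(names(x)) && outcome %in% names(x))
    return(x[[outcome]])
  if (is.list(x)) return(default)
  x
}

prevalence_target <- function(config, outcome) {
  tgt <- config$outcome_prevalence_target
  if (is.null(tgt)) return(NULL)
  if (outcome %in% names(tgt)) return(as.numeric(tgt[[outcome]]))
  NULL
}

# standardized continuous columns used in the generative linear predictor
.continuous_clinical <- c("age", "diameter_mm", "ca19_9")

linear_predictor <- function(tab, config, outcome) {
  bc <- outcome_field(config$beta_clinical %||% default_beta_clinical(),
                      outcome, numeric(0))
  bf <- outcome_field(config$beta_features, outcome, numeric(0))
  lp <- numeric(nrow(tab))
  add <- function(lp, betas) {
    for (nm in names(betas)) {
      if (!nm %in% names(tab))
        stop(sprintf("effect named for absent column '%s'", nm))
      x <- tab[[nm]]
      if (nm == "pattern") {            # per-step effect on pattern level
        x <- as.numeric(as.character(x))
      } else if (is.factor(x)) x <- as.numeric(x)
      if (nm %in% .continuous_clinical || !all(x %in% c(0, 1))) {
        if (nm == "ca19_9") x <- log(x)
        s <- stats::sd(x)
        x <- if (s > 0) (x - mean(x)) / s else x * 0
      }
      lp <- lp + betas[[nm]] * x
    }
    lp
  }
  lp <- add(lp, bc)
  add(lp, bf)
}

# choose intercept a s.t. mean(plogis(a + lp0)) == target
calibrate_intercept <- function(lp0, target) {
  f <- function(a) mean(stats::plogis(a + lp0)) - target
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}
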