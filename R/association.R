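# Regression-based association analyses --------------------------------------

# Internal: logistic ML fit returning coefficients, Wald SEs, log-likelihood
# and diagnostics.  Convergence control: relative deviance change < 1e-8,
# at most 100 iterations.
fit_glm_binomial <- function(X, y) {
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100L)))
  p <- fit$fitted.values
  W <- fit$weights
  XtWX <- crossprod(X * sqrt(W))
  vcov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
  flag <- ""
  if (!fit$converged) flag <- "non-convergence"
  if (any(p < 1e-10 | p > 1 - 1e-10) && any(abs(fit$coefficients) > 12))
    flag <- paste0(flag, if (nzchar(flag)) ";", "possible separation")
  if (is.null(vcov)) {
    flag <- paste0(flag, if (nzchar(flag)) ";", "singular information")
    vcov <- matrix(NA_real_, ncol(X), ncol(X))
  }
  list(coefficients = fit$coefficients, se = sqrt(diag(vcov)),
       fitted = p, loglik = sum(stats::dbinom(y, 1L, p, log = TRUE)),
       converged = fit$converged, flag = flag)
}

new_assoc_result <- function(outcome, predictor, beta, se, n_case, n_control,
                             r2 = NA_real_, auc = NA_real_,
                             auc_covariates = NA_real_, flag = "") {
  z <- beta / se
  structure(list(
    outcome = outcome, predictor = predictor, beta = beta, se = se,
    or_ = exp(beta), ci95 = exp(beta + c(-1, 1) * 1.96 * se),
    p = 2 * stats::pnorm(-abs(z)), r2_nagelkerke = r2, auc = auc,
    auc_covariates = auc_covariates, n_case = n_case, n_control = n_control,
    flag = flag), class = "assoc_result")
}

#' Logistic regression association test
#'
#' Maximum-likelihood logistic regression of a binary outcome on a
#' predictor plus covariates (Wald inference from the observed
#' information).  Also reports the increment in Nagelkerke pseudo R²
#' over the covariate-only model, and the ROC AUC of the full-model and
#' covariate-only fitted probabilities.  Rows with any missing value are
#' removed (listwise deletion).  Separation or non-convergence is flagged
#' in the result, never silent.
#'
#' @param y binary outcome (0/1 or logical).
#' @param x predictor of interest.
#' @param covariates optional matrix/data.frame of covariates.
#' @param outcome,predictor labels carried into the result.
#' @param metrics compute pseudo-R2/AUC metrics (default TRUE; disable in
#'   tight simulation loops).
#' @return object of class `assoc_result` with elements `beta`, `se`,
#'   `or_`, `ci95`, `p`, `r2_nagelkerke`, `auc`, `auc_covariates`,
#'   `n_case`, `n_control`, `flag`.
#' @export
fit_logistic <- function(y, x, covariates = NULL, outcome = "outcome",
                         predictor = "predictor", metrics = TRUE) {
  y <- as.numeric(y)
  x <- as.numeric(x)
  C <- if (!is.null(covariates)) as.matrix(covariates)
  keep <- !is.na(y) & !is.na(x)
  if (!is.null(C)) keep <- keep & stats::complete.cases(C)
  y <- y[keep]; x <- x[keep]
  if (!is.null(C)) C <- C[keep, , drop = FALSE]
  if (length(unique(y)) < 2L) stop("outcome has a single class")
  if (stats::sd(x) == 0) stop("predictor has no variation")
  X <- cbind(`(Intercept)` = 1, x = x, C)
  full <- fit_glm_binomial(X, y)
  r2 <- auc_full <- auc_cov <- NA_real_
  if (metrics) {
    null <- fit_glm_binomial(X[, -2L, drop = FALSE], y)
    if (!is.null(C)) {
      # delta Nagelkerke R2: (predictor + covariates) minus (covariates only),
      # both against the intercept-only baseline
      base <- fit_glm_binomial(X[, 1L, drop = FALSE], y)
      r2 <- nagelkerke_r2(full$loglik, base$loglik, length(y)) -
        nagelkerke_r2(null$loglik, base$loglik, length(y))
    } else {
      r2 <- nagelkerke_r2(full$loglik, null$loglik, length(y))
    }
    auc_full <- roc_auc(full$fitted, y)
    auc_cov <- if (!is.null(C)) roc_auc(null$fitted, y) else NA_real_
  }
  new_assoc_result(outcome, predictor, full$coefficients[2L], full$se[2L],
                   n_case = sum(y == 1), n_control = sum(y == 0),
                   r2 = r2, auc = auc_full, auc_covariates = auc_cov,
                   flag = full$flag)
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s ~ %s: OR %.3f (95%% CI %.3f-%.3f), p = %.3g",
              x$outcome, x$predictor, x$or_, x$ci95[1], x$ci95[2], x$p))
  if (!is.na(x$r2_nagelkerke))
    cat(sprintf(", dR2 = %.4f, AUC = %.3f", x$r2_nagelkerke, x$auc))
  cat(sprintf(" [%d cases / %d controls]", x$n_case, x$n_control))
  if (nzchar(x$flag)) cat(" FLAG:", x$flag)
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.assoc_result <- function(x, ...) {
  data.frame(outcome = x$outcome, predictor = x$predictor, beta = x$beta,
             se = x$se, or_ = x$or_, ci_lower = x$ci95[1],
             ci_upper = x$ci95[2], p = x$p,
             r2_nagelkerke = x$r2_nagelkerke, auc = x$auc,
             auc_covariates = x$auc_covariates, n_case = x$n_case,
             n_control = x$n_control, flag = x$flag,
             stringsAsFactors = FALSE)
}

#' Nagelkerke pseudo R-squared
#'
#' Cox-Snell R² = 1 - exp(2 (L0 - L1) / n) rescaled by its maximum
#' 1 - exp(2 L0 / n).
#'
#' @param loglik_full,loglik_null log-likelihoods of the two models.
#' @param n number of observations.
#' @return R² in [0, 1].
#' @export
nagelkerke_r2 <- function(loglik_full, loglik_null, n) {
  if (n <= 0) stop("n must be positive")
  if (loglik_full < loglik_null - 1e-8)
    stop("full-model log-likelihood below null model")
  cs <- 1 - exp(2 * (loglik_null - loglik_full) / n)
  cs_max <- 1 - exp(2 * loglik_null / n)
  if (cs_max <= 0) return(0)
  cs / cs_max
}

#' ROC area under the curve (Mann-Whitney form)
#'
#' AUC = P(score_case > score_control) + 0.5 P(tie), computed from
#' mid-ranks.
#'
#' @param scores numeric predictions.
#' @param y binary labels.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, y) {
  y <- as.logical(y)
  keep <- !is.na(scores) & !is.na(y)
  scores <- scores[keep]; y <- y[keep]
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Bivariate standard-normal CDF P(Z1 <= a, Z2 <= b) at correlation rho,
# via the deterministic TVPACK algorithm.
binorm_cdf <- function(a, b, rho) {
  if (!is.finite(a) || !is.finite(b))
    return(ifelse(is.finite(a), stats::pnorm(a),
                  ifelse(is.finite(b), stats::pnorm(b), 1)))
  mvtnorm::pmvnorm(upper = c(a, b),
                   corr = matrix(c(1, rho, rho, 1), 2L),
                   algorithm = mvtnorm::TVPACK())[1]
}

#' Tetrachoric correlation of a 2x2 table
#'
#' Maximum-likelihood correlation of a latent bivariate standard normal
#' dichotomised at thresholds matching the table margins; the likelihood
#' is maximised over rho by 1-D optimisation with deterministic
#' bivariate-normal orthant probabilities.  Perfectly concordant tables
#' return the boundary value +/-0.9995.
#'
#' @param tab 2x2 matrix of counts; `tab[1,1]` counts individuals positive
#'   on both traits.
#' @return estimated correlation; NA (with a warning) if a margin is empty.
#' @export
tetrachoric <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L))
  n <- sum(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("tetrachoric undefined: empty margin")
    return(NA_real_)
  }
  if (tab[1, 2] == 0 && tab[2, 1] == 0) return(0.9995)
  if (tab[1, 1] == 0 && tab[2, 2] == 0) return(-0.9995)
  q1 <- sum(tab[2, ]) / n  # P(trait 1 negative)
  q2 <- sum(tab[, 2]) / n
  a <- stats::qnorm(q1)
  b <- stats::qnorm(q2)
  nll <- function(rho) {
    p00 <- binorm_cdf(a, b, rho)
    p <- c(pp = 1 - q1 - q2 + p00, pn = q2 - p00, np = q1 - p00, nn = p00)
    p <- pmax(p, 1e-12)
    -(tab[1, 1] * log(p["pp"]) + tab[1, 2] * log(p["pn"]) +
        tab[2, 1] * log(p["np"]) + tab[2, 2] * log(p["nn"]))
  }
  stats::optimise(nll, c(-0.9995, 0.9995), tol = 1e-6)$minimum
}

#' Interaction test between two predictors
#'
#' Fits `y ~ x1 + x2 + x1:x2 + covariates` and reports the product-term
#' coefficient.  An inestimable interaction (either predictor constant
#' after listwise deletion) is returned flagged, not as an error.
#'
#' @inheritParams fit_logistic
#' @param x1,x2 the interacting predictors.
#' @return an `assoc_result` for the interaction term.
#' @export
interaction_test <- function(y, x1, x2, covariates = NULL,
                             outcome = "outcome",
                             predictor = "x1:x2") {
  y <- as.numeric(y); x1 <- as.numeric(x1); x2 <- as.numeric(x2)
  C <- if (!is.null(covariates)) as.matrix(covariates)
  keep <- !is.na(y) & !is.na(x1) & !is.na(x2)
  if (!is.null(C)) keep <- keep & stats::complete.cases(C)
  y <- y[keep]; x1 <- x1[keep]; x2 <- x2[keep]
  if (!is.null(C)) C <- C[keep, , drop = FALSE]
  if (stats::sd(x1) == 0 || stats::sd(x2) == 0 ||
      stats::sd(x1 * x2) == 0)
    return(new_assoc_result(outcome, predictor, NA_real_, NA_real_,
                            n_case = sum(y == 1), n_control = sum(y == 0),
                            flag = "interaction inestimable"))
  X <- cbind(1, x1, x2, x1 * x2, C)
  fit <- fit_glm_binomial(X, y)
  new_assoc_result(outcome, predictor, fit$coefficients[4L], fit$se[4L],
                   n_case = sum(y == 1), n_control = sum(y == 0),
                   flag = fit$flag)
}

#' Conditional association test (anxiety conditioned on mood)
#'
#' Fits `y ~ x + condition + covariates` and reports the coefficient of
#' `x`, e.g. P-CNV association with anxiety disorder conditioning on mood
#' disorder status.  A degenerate conditioning variable (identical to the
#' outcome, or constant) is flagged.
#'
#' @inheritParams fit_logistic
#' @param condition the conditioning binary variable.
#' @return an `assoc_result` for `x` given `condition`.
#' @export
conditional_test <- function(y, x, condition, covariates = NULL,
                             outcome = "outcome", predictor = "predictor") {
  y <- as.numeric(y); x <- as.numeric(x)
  condition <- as.numeric(condition)
  C <- if (!is.null(covariates)) as.matrix(covariates)
  keep <- !is.na(y) & !is.na(x) & !is.na(condition)
  if (!is.null(C)) keep <- keep & stats::complete.cases(C)
  y <- y[keep]; x <- x[keep]; condition <- condition[keep]
  if (!is.null(C)) C <- C[keep, , drop = FALSE]
  flag <- ""
  if (all(y == condition) || stats::sd(condition) == 0)
    flag <- "degenerate conditioning variable"
  X <- cbind(1, x, condition, C)
  fit <- fit_glm_binomial(X, y)
  if (nzchar(fit$flag))
    flag <- paste(c(flag[nzchar(flag)], fit$flag), collapse = ";")
  new_assoc_result(outcome, predictor, fit$coefficients[2L], fit$se[2L],
                   n_case = sum(y == 1), n_control = sum(y == 0),
                   flag = flag)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests number of tests (>= 1).
#' @return alpha / n_tests.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (n_tests < 1) stop("n_tests must be at least 1")
  alpha / n_tests
}
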