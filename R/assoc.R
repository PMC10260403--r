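#' Linear burden association test
#'
#' OLS of the INT-transformed phenotype on the burden plus an intercept and
#' covariates; two-sided t-test on the burden coefficient, CI from the t
#' quantile.
#'
#' @param burden Per-sample cumulative minor allele count.
#' @param pheno Quantitative phenotype (INT-transformed upstream).
#' @param covariates Covariate matrix or NULL.
#' @param unit_id Label for the output row.
#' @return One-row data.frame: unit_id, beta, se, ci_low, ci_high, p, test,
#'   carrier_count, n.
#' @export
linear_burden_test <- function(burden, pheno, covariates = NULL,
                               unit_id = "unit") {
  if (stats::var(burden) <= 0) stop("burden has zero variance")
  B <- Matrix::Matrix(as.numeric(burden), ncol = 1, sparse = TRUE)
  units <- data.frame(unit_id = unit_id, chrom = NA_integer_,
                      carrier_count = sum(burden >= 1, na.rm = TRUE))
  .burden_scan(B, units, pheno, covariates, loco = NULL)
}

# shared IRLS logistic fit returning the pieces the wrappers need
.logistic_fit <- function(y, Xfull) {
  fit <- suppressWarnings(
    stats::glm.fit(Xfull, y, family = stats::binomial()))
  fit
}

#' Logistic burden association test
#'
#' Maximum-likelihood logistic regression of a binary outcome on the burden
#' plus covariates; reports the log-OR and OR with Wald CI and p. Possible
#' (quasi-)separation or non-convergence is flagged in the `flag` column so
#' callers can route the unit to [firth_logistic()].
#'
#' @param burden Per-sample burden.
#' @param pheno Binary 0/1 outcome; both classes must be present.
#' @param covariates Covariate matrix or NULL.
#' @param unit_id Label for the output row.
#' @return One-row data.frame: unit_id, beta (log-OR), se, ci_low, ci_high,
#'   or, p, test, flag, carrier_count, n.
#' @export
logistic_burden_test <- function(burden, pheno, covariates = NULL,
                                 unit_id = "unit") {
  y <- as.numeric(pheno)
  if (length(unique(y[!is.na(y)])) != 2)
    stop("binary phenotype must contain both classes")
  X <- cbind(`(Intercept)` = 1, burden = as.numeric(burden),
             if (!is.null(covariates)) as.matrix(covariates))
  fit <- .logistic_fit(y, X)
  cf <- fit$coefficients["burden"]
  # observed information at the MLE
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  se <- if (is.null(cov)) NA_real_ else sqrt(diag(cov))[["burden"]]
  flag <- "ok"
  if (!fit$converged || is.null(cov)) flag <- "nonconverged"
  else if (abs(cf) > 15 || se > 100) flag <- "separation"
  z <- cf / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(unit_id = unit_id, beta = unname(cf), se = unname(se),
             ci_low = unname(cf - 1.96 * se), ci_high = unname(cf + 1.96 * se),
             or = exp(unname(cf)), p = unname(p), test = "logistic-wald",
             flag = flag,
             carrier_count = sum(burden >= 1, na.rm = TRUE),
             n = length(y), row.names = NULL, stringsAsFactors = FALSE)
}

# Firth-penalized logistic Newton-Raphson core. Returns coefficients,
# covariance and the penalized log-likelihood at the optimum.
.firth_core <- function(y, X, max_iter = 100, tol = 1e-6, fixed = NULL) {
  p <- ncol(X)
  beta <- rep(0, p)
  free <- setdiff(seq_len(p), fixed)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * sqrt(w)
    I <- crossprod(XW)
    Iinv <- solve(I)
    # hat diagonal of W^{1/2} X (X'WX)^{-1} X' W^{1/2}
    h <- rowSums((XW %*% Iinv) * XW)
    U <- drop(crossprod(X, y - mu + h * (0.5 - mu)))
    if (sqrt(sum(U[free]^2)) < tol) {
      ll <- sum(y * eta - log(1 + exp(eta))) + 0.5 * determinant(I)$modulus
      return(list(beta = beta, cov = Iinv, ll = as.numeric(ll),
                  iterations = it, converged = TRUE))
    }
    step <- rep(0, p)
    if (length(free) == p) {
      step <- drop(Iinv %*% U)
    } else {
      Iff <- I[free, free, drop = FALSE]
      step[free] <- drop(solve(Iff, U[free]))
    }
    # damp very large Newton steps for stability
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
  }
  stop("Firth logistic regression did not converge in ", max_iter,
       " iterations (|U| = ", signif(sqrt(sum(U[free]^2)), 3), ")")
}

#' Firth penalized logistic burden test
#'
#' Logistic regression with Jeffreys-prior penalty `0.5 * log det I(beta)`,
#' guaranteeing finite estimates under complete or quasi-complete
#' separation. Newton iterations run until the (penalized) score norm drops
#' below `tol`. The default p-value is Wald; `p_method = "plr"` uses the
#' penalized likelihood-ratio test for the burden term.
#'
#' @param burden Per-sample burden.
#' @param pheno Binary 0/1 outcome.
#' @param covariates Covariate matrix or NULL.
#' @param unit_id Label for the output row.
#' @param p_method "wald" (default) or "plr".
#' @param max_iter,tol Newton iteration controls.
#' @return One-row data.frame as in [logistic_burden_test()] with
#'   `test = "firth"`.
#' @export
firth_logistic <- function(burden, pheno, covariates = NULL,
                           unit_id = "unit", p_method = c("wald", "plr"),
                           max_iter = 100, tol = 1e-6) {
  p_method <- match.arg(p_method)
  y <- as.numeric(pheno)
  if (length(unique(y[!is.na(y)])) != 2)
    stop("binary phenotype must contain both classes")
  X <- cbind(`(Intercept)` = 1, burden = as.numeric(burden),
             if (!is.null(covariates)) as.matrix(covariates))
  fit <- .firth_core(y, X, max_iter = max_iter, tol = tol)
  j <- which(colnames(X) == "burden")
  cf <- fit$beta[j]
  se <- sqrt(diag(fit$cov))[j]
  if (p_method == "wald") {
    p <- 2 * stats::pnorm(-abs(cf / se))
  } else {
    fit0 <- .firth_core(y, X, max_iter = max_iter, tol = tol, fixed = j)
    p <- stats::pchisq(2 * (fit$ll - fit0$ll), df = 1, lower.tail = FALSE)
  }
  data.frame(unit_id = unit_id, beta = cf, se = se,
             ci_low = cf - 1.96 * se, ci_high = cf + 1.96 * se,
             or = exp(cf), p = p, test = "firth", flag = "ok",
             carrier_count = sum(burden >= 1, na.rm = TRUE),
             n = length(y), row.names = NULL, stringsAsFactors = FALSE)
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(n_tests >= 1)
  alpha / n_tests
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR q-values with enforced monotonicity (via
#' `stats::p.adjust(method = "BH")`).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return q-values, same order as the input.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Genomic inflation factor
#'
#' `lambda_GC`: the median of the chi-square(1) statistics implied by the
#' p-values, divided by the chi-square(1) median (~0.455).
#'
#' @param p At least 10 p-values.
#' @return `lambda_GC`.
#' @export
genomic_lambda <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 10) stop("genomic_lambda needs at least 10 p-values")
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Inverse-variance-weighted random-effects meta-analysis
#'
#' DerSimonian-Laird between-study variance (truncated at zero), weights
#' `1 / (se^2 + tau^2)`, combined effect and SE, two-sided normal p. With
#' `tau^2 = 0` this reduces to the fixed-effects IVW estimate.
#'
#' @param betas Study effect estimates (length >= 2; a single study is
#'   returned unchanged with a warning).
#' @param ses Study standard errors (> 0).
#' @return One-row data.frame: beta, se, ci_low, ci_high, p, tau2, q_stat,
#'   n_studies.
#' @export
ivw_random_effects_meta <- function(betas, ses) {
  stopifnot(length(betas) == length(ses), all(ses > 0))
  k <- length(betas)
  if (k < 2) {
    warning("single study: returning the input unchanged")
    return(data.frame(beta = betas, se = ses,
                      ci_low = betas - 1.96 * ses, ci_high = betas + 1.96 * ses,
                      p = 2 * stats::pnorm(-abs(betas / ses)),
                      tau2 = NA_real_, q_stat = NA_real_, n_studies = 1L))
  }
  w <- 1 / ses^2
  b_fe <- sum(w * betas) / sum(w)
  q <- sum(w * (betas - b_fe)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (ses^2 + tau2)
  b <- sum(ws * betas) / sum(ws)
  se <- sqrt(1 / sum(ws))
  data.frame(beta = b, se = se,
             ci_low = b - 1.96 * se, ci_high = b + 1.96 * se,
             p = 2 * stats::pnorm(-abs(b / se)),
             tau2 = tau2, q_stat = q, n_studies = k)
}
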