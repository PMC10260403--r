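#' Build the standard covariate matrix
#'
#' Columns: sex, age, age^2, sex:age, sex:age^2, the supplied principal
#' components, and centre indicator columns (first level as reference).
#' Rows with any missing covariate are flagged for complete-case exclusion
#' via the `complete` attribute rather than silently dropped.
#'
#' @param sex 0/1 vector.
#' @param age Numeric vector.
#' @param pcs Matrix (or data frame) of principal components, or NULL.
#' @param centers Factor/character of recruitment centres, or NULL; must
#'   have at least 2 levels when supplied.
#' @return Numeric matrix (no intercept column) with attribute `complete`,
#'   a logical vector of rows with no missing covariate.
#' @export
build_covariates <- function(sex, age, pcs = NULL, centers = NULL) {
  n <- length(sex)
  stopifnot(length(age) == n)
  X <- cbind(sex = sex, age = age, age2 = age^2,
             sex_age = sex * age, sex_age2 = sex * age^2)
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    stopifnot(nrow(pcs) == n)
    if (is.null(colnames(pcs))) colnames(pcs) <- paste0("pc", seq_len(ncol(pcs)))
    X <- cbind(X, pcs)
  }
  if (!is.null(centers)) {
    f <- factor(centers)
    if (nlevels(f) < 2) stop("centers must have at least 2 levels (or be omitted)")
    D <- stats::model.matrix(~f)[, -1, drop = FALSE]
    colnames(D) <- paste0("center_", levels(f)[-1])
    # model.matrix drops NA rows; rebuild at full length
    full <- matrix(NA_real_, n, ncol(D), dimnames = list(NULL, colnames(D)))
    full[!is.na(f), ] <- D
    X <- cbind(X, full)
  }
  attr(X, "complete") <- stats::complete.cases(X)
  X
}

#' Rank-based inverse-normal transformation
#'
#' `z_i = qnorm((r_i - c) / (n - 2c + 1))` with offset `c` (Blom's 3/8 by
#' default) and average ranks for ties; `n` counts non-missing values and
#' missing values stay missing.
#'
#' @param values Numeric vector.
#' @param offset Rank offset constant; one of 3/8 (Blom), 1/2, 0.
#' @return Transformed vector, same length and missingness as the input.
#' @export
rank_int <- function(values, offset = 3 / 8) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 2) stop("rank_int needs at least 2 non-missing values")
  if (length(unique(values[ok])) == 1L)
    stop("rank_int is undefined for a constant vector")
  r <- rank(values[ok], ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

#' Residualize a phenotype on covariates
#'
#' OLS residuals of `pheno` on an intercept plus `covariates`; residuals are
#' orthogonal to every covariate column. Rank-deficient designs are
#' rejected with the offending columns named.
#'
#' @param pheno Numeric vector (complete cases only).
#' @param covariates Covariate matrix as from [build_covariates()].
#' @return Residual vector.
#' @export
residualize <- function(pheno, covariates) {
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  if (anyNA(pheno) || anyNA(X))
    stop("residualize expects complete cases; drop missing rows first")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("collinear covariate column(s): ", paste(bad, collapse = ", "))
  }
  drop(qr.resid(qx, pheno))
}

#' Single-pass outlier exclusion mask
#'
#' Marks values more than `k` SD from the mean for exclusion; mean and SD
#' are computed once (no re-iteration after removal). A constant vector
#' (SD 0) retains everything.
#'
#' @param values Numeric vector (length >= 2); NA values are excluded.
#' @param k SD multiple, default 5.
#' @return Logical inclusion mask.
#' @export
exclude_outliers <- function(values, k = 5) {
  stopifnot(length(values) >= 2)
  m <- mean(values, na.rm = TRUE)
  s <- stats::sd(values, na.rm = TRUE)
  if (is.na(s) || s == 0) return(!is.na(values))
  !is.na(values) & abs(values - m) <= k * s
}
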