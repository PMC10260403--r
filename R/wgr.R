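#' Configuration for two-step whole-genome regression
#'
#' @param block_size Variants per ridge block (default 1000); blocks never
#'   span chromosomes.
#' @param h2_grid Ridge shrinkage grid expressed as assumed-heritability
#'   proxies; penalty `lambda = M (1 - h2) / h2` with M the total variant
#'   count. Default `c(0.01, 0.1, 0.25, 0.5, 0.75)`.
#' @param k_folds Cross-validation folds (default 10).
#' @param seed Seed for the fold assignment.
#' @return List of class `wgr_config`.
#' @export
wgr_config <- function(block_size = 1000L, h2_grid = c(0.01, 0.1, 0.25, 0.5, 0.75),
                       k_folds = 10L, seed = 1L) {
  stopifnot(block_size >= 2, k_folds >= 2, length(h2_grid) >= 1,
            all(h2_grid > 0), all(h2_grid < 1))
  structure(list(block_size = as.integer(block_size), h2_grid = h2_grid,
                 k_folds = as.integer(k_folds), seed = as.integer(seed)),
            class = "wgr_config")
}

# Mean-impute missing dosages, then center by 2p and scale by sqrt(2p(1-p)).
# Monomorphic columns become all-zero.
standardize_genotypes <- function(G) {
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  n <- nrow(G)
  p <- unname(colMeans(G)) / 2
  sc <- sqrt(2 * p * (1 - p))
  inv <- ifelse(sc > 0, 1 / sc, 0) # monomorphic columns zero out
  Z <- (G - rep(2 * p, each = n)) * rep(inv, each = n)
  Z[, sc == 0] <- 0
  Z
}

# closed-form ridge solutions for several penalties at once
.ridge_solve <- function(C, cy, lambdas) {
  vapply(lambdas, function(l)
    drop(solve(C + diag(l, nrow(C)), cy)), numeric(length(cy)))
}

#' Step 1: stacked block ridge regression with LOCO predictions
#'
#' Level 0 fits, per block of standardized variants, ridge predictors across
#' the shrinkage grid with k-fold cross-validation, retaining out-of-fold
#' predictions. Level 1, per chromosome left out, combines the block
#' predictions from all other chromosomes by cross-validated ridge stacking.
#' Column `c` of the output is therefore computed with chromosome `c`
#' masked entirely (the exclusion contract).
#'
#' @param genotypes Samples x variants dosage matrix of common variants.
#' @param chrom Integer chromosome label per variant.
#' @param pheno Covariate-adjusted, standardized phenotype (e.g. residuals
#'   of the INT trait on the covariates).
#' @param config A [wgr_config()].
#' @return Matrix samples x chromosomes of leave-one-chromosome-out genetic
#'   predictions (columns named `chr<k>`).
#' @export
step1_ridge_loco <- function(genotypes, chrom, pheno, config = wgr_config()) {
  stopifnot(inherits(config, "wgr_config"))
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  stopifnot(length(chrom) == m, length(pheno) == n)
  chroms <- sort(unique(chrom))
  if (length(chroms) < 2)
    stop("LOCO is undefined with a single chromosome holding all variants")
  if (n < config$k_folds) stop("fewer samples than cross-validation folds")
  Z <- standardize_genotypes(genotypes)
  y <- pheno - mean(pheno)
  set.seed(config$seed)
  fold <- sample(rep_len(seq_len(config$k_folds), n))
  lambdas <- m * (1 - config$h2_grid) / config$h2_grid

  # block layout: contiguous chunks within each chromosome
  blocks <- list()
  for (c in chroms) {
    j <- which(chrom == c)
    nb <- ceiling(length(j) / config$block_size)
    cut_id <- rep(seq_len(nb), each = config$block_size, length.out = length(j))
    blocks <- c(blocks, lapply(split(j, cut_id), function(jj)
      list(chrom = c, cols = jj)))
  }
  L <- length(lambdas)
  W <- matrix(0, n, length(blocks) * L)
  wchrom <- rep(vapply(blocks, `[[`, numeric(1), "chrom"), each = L)
  for (b in seq_along(blocks)) {
    Xb <- Z[, blocks[[b]]$cols, drop = FALSE]
    for (k in seq_len(config$k_folds)) {
      tr <- fold != k
      A <- Xb[tr, , drop = FALSE]
      beta <- .ridge_solve(crossprod(A), crossprod(A, y[tr]), lambdas)
      W[!tr, (b - 1L) * L + seq_len(L)] <- Xb[!tr, , drop = FALSE] %*% beta
    }
  }

  loco <- matrix(0, n, length(chroms),
                 dimnames = list(rownames(genotypes), paste0("chr", chroms)))
  for (ci in seq_along(chroms)) {
    keep <- wchrom != chroms[ci]
    Wk <- W[, keep, drop = FALSE]
    mu_w <- colMeans(Wk)
    Wc <- sweep(Wk, 2, mu_w, "-")
    mus <- ncol(Wc) * (1 - config$h2_grid) / config$h2_grid
    # CV over the level-1 penalty grid using the same folds
    cv_mse <- numeric(length(mus))
    for (k in seq_len(config$k_folds)) {
      tr <- fold != k
      A <- Wc[tr, , drop = FALSE]
      beta <- .ridge_solve(crossprod(A), crossprod(A, y[tr]), mus)
      pred <- Wc[!tr, , drop = FALSE] %*% beta
      cv_mse <- cv_mse + colSums((y[!tr] - pred)^2)
    }
    mu_best <- mus[which.min(cv_mse)]
    beta <- .ridge_solve(crossprod(Wc), crossprod(Wc, y), mu_best)
    loco[, ci] <- drop(Wc %*% beta)
  }
  loco
}

# Core vectorized association scan via Frisch-Waugh projection: regress
# (pheno - offset) on each burden column plus intercept and covariates.
# burdens: samples x units matrix (sparse ok); unit_chrom: chromosome per
# unit (NA or loco NULL => no offset); returns one row per unit.
.burden_scan <- function(burdens, units, pheno, covariates, loco = NULL,
                         ci_mult = NULL) {
  B <- burdens
  n <- nrow(B)
  X <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(covariates)) as.matrix(covariates))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("collinear covariate column(s): ", paste(bad, collapse = ", "))
  }
  Q <- qr.Q(qx)
  p <- ncol(X)
  df <- n - p - 1L
  qb <- as.matrix(Matrix::crossprod(Q, B))                     # p x U
  xstarsq <- Matrix::colSums(B^2) - colSums(qb^2)      # ||x*||^2 per unit
  if (any(xstarsq <= 1e-10 * n))
    stop("no carriers after filtering: zero-variance burden for unit(s) ",
         paste(units$unit_id[xstarsq <= 1e-10 * n], collapse = ", "))
  beta <- se <- pval <- numeric(ncol(B))
  if (is.null(loco)) {
    ystar <- drop(qr.resid(qx, pheno))
    xty <- as.numeric(Matrix::crossprod(B, ystar))
    beta <- xty / xstarsq
    sse <- sum(ystar^2) - beta * xty
    se <- sqrt(pmax(sse, 0) / df / xstarsq)
  } else {
    for (cc in unique(units$chrom)) {
      j <- which(units$chrom == cc)
      col <- paste0("chr", cc)
      if (!col %in% colnames(loco))
        stop("LOCO predictions missing column ", col)
      ystar <- drop(qr.resid(qx, pheno - loco[, col]))
      xty <- as.numeric(Matrix::crossprod(B[, j, drop = FALSE], ystar))
      beta[j] <- xty / xstarsq[j]
      sse <- sum(ystar^2) - beta[j] * xty
      se[j] <- sqrt(pmax(sse, 0) / df / xstarsq[j])
    }
  }
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  mult <- if (is.null(ci_mult)) stats::qt(0.975, df) else ci_mult
  data.frame(unit_id = units$unit_id,
             beta = beta, se = se,
             ci_low = beta - mult * se, ci_high = beta + mult * se,
             p = pval,
             test = if (is.null(loco)) "linear-t" else "linear-t-loco",
             carrier_count = units$carrier_count,
             n = n, row.names = NULL, stringsAsFactors = FALSE)
}

#' Step 2: burden association test with a LOCO offset
#'
#' OLS of `(phenotype - loco[, chrom])` on the burden plus covariates;
#' treating the leave-one-chromosome-out genetic prediction as an offset
#' absorbs polygenic background and relatedness. Reports beta, SE, 95% CI
#' (+-1.96 SE), two-sided t-test p and carrier count.
#'
#' @param burden Per-sample burden vector for one unit.
#' @param pheno INT-transformed phenotype.
#' @param covariates Covariate matrix (or NULL).
#' @param loco LOCO prediction matrix from [step1_ridge_loco()].
#' @param chrom Chromosome of the tested unit.
#' @param unit_id Label for the output row.
#' @return One-row data.frame (unit_id, beta, se, ci_low, ci_high, p, test,
#'   carrier_count, n).
#' @export
step2_offset_test <- function(burden, pheno, covariates, loco, chrom,
                              unit_id = "unit") {
  B <- Matrix::Matrix(as.numeric(burden), ncol = 1, sparse = TRUE)
  units <- data.frame(unit_id = unit_id, chrom = chrom,
                      carrier_count = sum(burden >= 1, na.rm = TRUE))
  .burden_scan(B, units, pheno, covariates, loco = loco, ci_mult = 1.96)
}

#' Whole-exome gene burden scan with optional LOCO offsets
#'
#' Vectorized step-2 test over every unit of a [build_burden()] result;
#' with `loco = NULL` this is the plain covariate-adjusted linear burden
#' scan.
#'
#' @param burdens Output of [build_burden()] (after carrier filtering).
#' @param pheno INT-transformed phenotype.
#' @param covariates Covariate matrix (or NULL).
#' @param loco LOCO matrix from [step1_ridge_loco()], or NULL.
#' @return Data.frame, one row per unit, as in [step2_offset_test()].
#' @export
burden_scan <- function(burdens, pheno, covariates = NULL, loco = NULL) {
  .burden_scan(burdens$burden, burdens$units, pheno, covariates, loco = loco,
               ci_mult = if (is.null(loco)) NULL else 1.96)
}
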