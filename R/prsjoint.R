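#' Polygenic score as a weighted allele sum
#'
#' `score_i = sum_v w_v * dosage_i(effect allele of v)` over the
#' intersection of weight variants and genotype variants. Dosages count the
#' alt allele; when the effect allele is the ref allele the dosage is
#' flipped to `2 - dosage`. Strand-ambiguous variants (A/T, C/G) and
#' variants whose effect allele matches neither ref nor alt are dropped
#' with a message. Missing dosages contribute the variant's mean dosage.
#'
#' @param genotypes Samples x variants dosage matrix.
#' @param variant_info Data.frame with variant_id, ref, alt, matching the
#'   genotype columns.
#' @param weights Data.frame with variant_id, effect_allele, weight.
#' @return Numeric per-sample score.
#' @export
score_prs <- function(genotypes, variant_info, weights) {
  stopifnot(all(c("variant_id", "effect_allele", "weight") %in% names(weights)),
            !anyDuplicated(weights$variant_id), all(is.finite(weights$weight)))
  idx <- match(weights$variant_id, variant_info$variant_id)
  keep <- !is.na(idx)
  w <- weights[keep, ]
  vi <- variant_info[idx[keep], ]
  ambiguous <- (vi$ref == "A" & vi$alt == "T") | (vi$ref == "T" & vi$alt == "A") |
    (vi$ref == "C" & vi$alt == "G") | (vi$ref == "G" & vi$alt == "C")
  onref <- w$effect_allele == vi$ref
  onalt <- w$effect_allele == vi$alt
  usable <- !ambiguous & (onref | onalt)
  dropped <- sum(keep) - sum(usable)
  if (dropped > 0)
    message(dropped, " weight variant(s) dropped (strand-ambiguous or allele mismatch)")
  if (sum(usable) == 0) stop("no usable overlap between weights and genotypes")
  w <- w[usable, ]
  vi <- vi[usable, ]
  onref <- onref[usable]
  D <- as.matrix(genotypes[, match(vi$variant_id, colnames(genotypes)),
                           drop = FALSE])
  storage.mode(D) <- "double"
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    na_idx <- which(is.na(D), arr.ind = TRUE)
    D[na_idx] <- mu[na_idx[, 2]]
  }
  D[, onref] <- 2 - D[, onref, drop = FALSE]
  drop(D %*% w$weight)
}

#' Rare damaging-variant carrier flags
#'
#' Flags each sample as a carrier of (a) a rare high-confidence PTV and/or
#' (b) a rare damaging missense variant (MPC > 2, i.e. tiers 1-2), in both
#' cases restricted to LoF-intolerant genes and to variants below the MAF
#' threshold.
#'
#' @param genotypes Samples x variants rare dosage matrix.
#' @param annotations Classified annotations ([classify_variants()]).
#' @param pli_threshold pLI cutoff for LoF-intolerant genes (default 0.9).
#' @param pli_strict If TRUE use `pli > threshold` (as in joint PRS
#'   analyses); FALSE uses `pli >= threshold`. Default TRUE.
#' @param maf_threshold Rarity cutoff (strict `<`).
#' @return Data.frame: sample_id, ptv_carrier, damaging_missense_carrier.
#' @export
carrier_flags <- function(genotypes, annotations, pli_threshold = 0.9,
                          pli_strict = TRUE, maf_threshold = 1e-5) {
  stopifnot(ncol(genotypes) == nrow(annotations))
  pli_ok <- if (pli_strict) annotations$pli > pli_threshold
            else annotations$pli >= pli_threshold
  pli_ok[is.na(pli_ok)] <- FALSE
  rare <- annotations$maf < maf_threshold
  ptv <- annotations$class == "PTV" & pli_ok & rare
  dmis <- annotations$class %in% c("missense_t1", "missense_t2") & pli_ok & rare
  any_carrier <- function(sel) {
    if (!any(sel)) return(rep(FALSE, nrow(genotypes)))
    Matrix::rowSums(genotypes[, sel, drop = FALSE]) >= 1
  }
  data.frame(sample_id = if (!is.null(rownames(genotypes)))
               rownames(genotypes) else seq_len(nrow(genotypes)),
             ptv_carrier = any_carrier(ptv),
             damaging_missense_carrier = any_carrier(dmis),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Joint model of PRS and rare damaging-variant carrier status
#'
#' OLS of the INT phenotype on standardized PRS, PTV carrier status and
#' damaging-missense carrier status plus covariates. Partial R^2 per
#' predictor is `(SSE_reduced - SSE_full) / SSE_reduced` for the model
#' dropping that predictor. With `interaction = TRUE`, PRS x carrier
#' product terms are added and their Wald p-values reported.
#'
#' @param pheno INT-transformed phenotype.
#' @param prs Polygenic score (standardized internally to mean 0, SD 1 so
#'   effects are per PRS SD).
#' @param ptv_flag,missense_flag Logical/0-1 carrier flags; a flag with no
#'   carriers is dropped with a warning.
#' @param covariates Covariate matrix or NULL.
#' @param interaction Add PRS x carrier interaction terms (default FALSE).
#' @return List of class `joint_model_result`: `estimates` (term, beta, se,
#'   p, partial_r2), `interactions` (term, beta, se, p; when requested),
#'   `r2_full`, `n`.
#' @export
joint_model <- function(pheno, prs, ptv_flag, missense_flag,
                        covariates = NULL, interaction = FALSE) {
  prs_z <- as.numeric(scale(prs))
  preds <- list(prs = prs_z,
                ptv_carrier = as.numeric(ptv_flag),
                damaging_missense_carrier = as.numeric(missense_flag))
  for (nm in c("ptv_carrier", "damaging_missense_carrier")) {
    if (sum(preds[[nm]]) == 0) {
      warning("no carriers for ", nm, "; term dropped")
      preds[[nm]] <- NULL
    }
  }
  P <- do.call(cbind, preds)
  X <- cbind(`(Intercept)` = 1, P,
             if (!is.null(covariates)) as.matrix(covariates))
  if (interaction) {
    for (nm in setdiff(colnames(P), "prs"))
      X <- cbind(X, matrix(prs_z * P[, nm], ncol = 1,
                           dimnames = list(NULL, paste0("prs_x_", nm))))
  }
  fit <- stats::lm.fit(X, pheno)
  n <- length(pheno)
  df <- n - ncol(X)
  sse_full <- sum(fit$residuals^2)
  sigma2 <- sse_full / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- colnames(X)
  tval <- fit$coefficients / se
  pval <- 2 * stats::pt(-abs(tval), df)
  partial_r2 <- vapply(colnames(P), function(nm) {
    Xr <- X[, colnames(X) != nm, drop = FALSE]
    sse_red <- sum(stats::lm.fit(Xr, pheno)$residuals^2)
    (sse_red - sse_full) / sse_red
  }, numeric(1))
  est <- data.frame(term = colnames(P),
                    beta = fit$coefficients[colnames(P)],
                    se = se[colnames(P)],
                    p = pval[colnames(P)],
                    partial_r2 = partial_r2,
                    row.names = NULL, stringsAsFactors = FALSE)
  inter <- NULL
  if (interaction) {
    iterms <- grep("^prs_x_", colnames(X), value = TRUE)
    inter <- data.frame(term = iterms,
                        beta = fit$coefficients[iterms],
                        se = se[iterms], p = pval[iterms],
                        row.names = NULL, stringsAsFactors = FALSE)
  }
  sst <- sum((pheno - mean(pheno))^2)
  structure(list(estimates = est, interactions = inter,
                 r2_full = 1 - sse_full / sst, n = n),
            class = "joint_model_result")
}

#' Median phenotype by PRS quantile group and carrier stratum
#'
#' Groups samples into PRS quantile bins of width `q` (e.g. 0.2 or 0.02) or
#' into top-10%-vs-rest when `top_binary = TRUE`, crossed with carrier
#' stratum (non-carrier / PTV carrier / damaging-missense carrier; PTV wins
#' when both), and returns the median standardized residualized phenotype
#' and group size per cell.
#'
#' @param prs Polygenic score.
#' @param pheno Standardized residualized phenotype.
#' @param flags Data.frame from [carrier_flags()].
#' @param q Quantile width; `1/q` must be a whole number of groups.
#' @param top_binary Use a top-10%-vs-remaining-90% split instead of
#'   quantile bins.
#' @return Data.frame: prs_group, stratum, n, median.
#' @export
quantile_summary <- function(prs, pheno, flags, q = 0.2, top_binary = FALSE) {
  stopifnot(q > 0, q <= 1)
  k <- 1 / q
  if (abs(k - round(k)) > 1e-8) stop("q must evenly divide [0, 1]")
  k <- as.integer(round(k))
  if (top_binary) {
    grp <- factor(ifelse(prs >= stats::quantile(prs, 0.9),
                         "top10", "rest90"), levels = c("rest90", "top10"))
  } else {
    ranks <- rank(prs, ties.method = "first")
    grp <- factor(ceiling(k * ranks / length(prs)), levels = seq_len(k))
  }
  stratum <- ifelse(flags$ptv_carrier, "ptv",
                    ifelse(flags$damaging_missense_carrier,
                           "damaging_missense", "noncarrier"))
  agg <- stats::aggregate(pheno,
                          by = list(prs_group = grp, stratum = stratum),
                          FUN = stats::median)
  cnt <- stats::aggregate(pheno,
                          by = list(prs_group = grp, stratum = stratum),
                          FUN = length)
  out <- merge(cnt, agg, by = c("prs_group", "stratum"))
  names(out)[3:4] <- c("n", "median")
  out[order(out$stratum, out$prs_group), ]
}
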