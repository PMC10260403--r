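#' Build a phenotype catalogue
#'
#' @param info Data.frame with columns id, name, category, type
#'   ("binary" or "quantitative"); ids must be unique.
#' @param values Samples x phenotypes matrix, columns in the order of
#'   `info$id`.
#' @return List of class `pheno_catalogue`.
#' @export
pheno_catalogue <- function(info, values) {
  stopifnot(all(c("id", "name", "category", "type") %in% names(info)),
            !anyDuplicated(info$id),
            all(info$type %in% c("binary", "quantitative")),
            ncol(values) == nrow(info))
  colnames(values) <- info$id
  structure(list(info = info, values = values), class = "pheno_catalogue")
}

#' Phenome-wide association scan of one burden
#'
#' Binary phenotypes with fewer than `min_cases` cases are dropped; the rest
#' are tested by logistic regression and, where the association p falls
#' below `firth_p`, re-tested with Firth penalized logistic regression (the
#' Firth row is the one reported). Quantitative phenotypes with fewer than
#' `min_obs` observations are dropped; the rest have outliers beyond
#' `outlier_k` SD excluded, are INT-transformed and tested by linear
#' regression. Phenotypes left with a single outcome class are skipped with
#' a message. The phenome-wide threshold reported is `alpha` divided by the
#' catalogue size (with `alpha / tests run` also returned).
#'
#' @param burden Per-sample burden vector (>= 1 carrier).
#' @param catalogue A [pheno_catalogue()].
#' @param covariates Covariate matrix or NULL.
#' @param min_cases Minimum case count for binary phenotypes (default 100).
#' @param min_obs Minimum observation count for quantitative phenotypes
#'   (default 100).
#' @param firth_p Firth re-test trigger (default 0.01).
#' @param outlier_k Outlier SD multiple (default 5).
#' @param alpha Family-wise error rate (default 0.05).
#' @return List with `results` (one row per tested phenotype: phenotype
#'   metadata + association columns), `threshold` (catalogue-based),
#'   `threshold_tests_run`, and `n_tests`.
#' @export
run_phewas <- function(burden, catalogue, covariates = NULL,
                       min_cases = 100, min_obs = 100, firth_p = 0.01,
                       outlier_k = 5, alpha = 0.05) {
  stopifnot(inherits(catalogue, "pheno_catalogue"))
  if (nrow(catalogue$info) == 0) stop("empty phenotype catalogue")
  if (sum(burden >= 1, na.rm = TRUE) < 1) stop("burden has no carriers")
  rows <- vector("list", nrow(catalogue$info))
  for (i in seq_len(nrow(catalogue$info))) {
    meta <- catalogue$info[i, ]
    v <- catalogue$values[, i]
    if (meta$type == "binary") {
      if (sum(v == 1, na.rm = TRUE) < min_cases) next
      ok <- !is.na(v)
      if (length(unique(v[ok])) < 2) {
        message("phenotype ", meta$id, " has a single class; skipped")
        next
      }
      res <- logistic_burden_test(burden[ok], v[ok],
                                  covariates[ok, , drop = FALSE],
                                  unit_id = meta$id)
      if (is.finite(res$p) && res$p < firth_p) {
        res <- firth_logistic(burden[ok], v[ok],
                              covariates[ok, , drop = FALSE],
                              unit_id = meta$id)
      }
      res$or <- NULL
      res$flag <- NULL
    } else {
      ok <- !is.na(v)
      if (sum(ok) < min_obs) next
      ok[ok] <- exclude_outliers(v[ok], k = outlier_k)
      vt <- rank_int(v[ok])
      res <- linear_burden_test(burden[ok], vt, covariates[ok, , drop = FALSE],
                                unit_id = meta$id)
    }
    rows[[i]] <- cbind(meta[, c("id", "name", "category", "type")], res,
                       row.names = NULL)
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  n_run <- if (is.null(results)) 0L else nrow(results)
  list(results = results,
       threshold = bonferroni_threshold(alpha, nrow(catalogue$info)),
       threshold_tests_run = if (n_run > 0)
         bonferroni_threshold(alpha, n_run) else NA_real_,
       n_tests = n_run)
}
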