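#' Common-variant genotype QC filter
#'
#' Keeps variants with call rate >= 0.9, Hardy-Weinberg equilibrium
#' p >= 1e-15 and MAF >= 0.01 (the standard pre-step-1 genotype QC for
#' whole-genome regression).
#'
#' @param call_rate,hwe_p,maf Equal-length numeric vectors, one entry per
#'   variant.
#' @return Logical vector, TRUE for retained variants.
#' @export
qc_filter_common <- function(call_rate, hwe_p, maf) {
  if (length(unique(c(length(call_rate), length(hwe_p), length(maf)))) != 1L)
    stop("call_rate, hwe_p and maf must have the same length")
  call_rate >= 0.9 & hwe_p >= 1e-15 & maf >= 0.01
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against the HWE proportions implied by the observed allele frequency.
#' Monomorphic input returns p = 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa Non-negative genotype counts.
#' @return Two-sided p-value.
#' @export
hwe_chisq <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n <= 0) stop("total genotype count must be positive")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  exp_counts <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(n_AA, n_Aa, n_aa) - exp_counts)^2 / exp_counts)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Classify variants into functional class and pLI stratum
#'
#' Class is a total function of (consequence, lof_confidence, mpc):
#' stop-gain / frameshift / splice-disrupting variants with high-confidence
#' LoF status are PTVs; missense variants are tiered by deleteriousness as
#' MPC > 3 (tier 1), 2 < MPC <= 3 (tier 2) and all remaining missense
#' including missing MPC (tier 3); synonymous is its own class; anything
#' else (or a low-confidence LoF call) is "other". The pLI stratum is
#' "high" iff pLI >= 0.9, "low" for pLI < 0.9 and "unknown" when pLI is
#' missing.
#'
#' @param annotations Data frame with columns consequence, lof_confidence,
#'   mpc, pli (as produced by [simulate_rare_variants()]).
#' @return The input with `class` and `pli_stratum` columns appended.
#' @export
classify_variants <- function(annotations) {
  csq <- annotations$consequence
  lof <- annotations$lof_confidence
  mpc <- annotations$mpc
  ptv_csq <- c("stop_gained", "stop_lost", "frameshift_variant",
               "splice_donor_variant", "splice_acceptor_variant")
  cls <- rep("other", nrow(annotations))
  is_ptv <- csq %in% ptv_csq & !is.na(lof) & lof == "HC"
  cls[is_ptv] <- "PTV"
  mis <- csq == "missense_variant"
  cls[mis & !is.na(mpc) & mpc > 3] <- "missense_t1"
  cls[mis & !is.na(mpc) & mpc > 2 & mpc <= 3] <- "missense_t2"
  cls[mis & (is.na(mpc) | mpc <= 2)] <- "missense_t3"
  cls[csq == "synonymous_variant"] <- "synonymous"
  unknown <- !(csq %in% c(ptv_csq, "missense_variant", "synonymous_variant"))
  if (any(unknown))
    message(sum(unknown), " variant(s) with unrecognized consequence -> class 'other'")
  pli <- annotations$pli
  stratum <- ifelse(is.na(pli), "unknown", ifelse(pli >= 0.9, "high", "low"))
  annotations$class <- cls
  annotations$pli_stratum <- stratum
  annotations
}

#' Rarity filter on in-cohort minor allele frequency
#'
#' Strict inequality: keeps variants with `maf < maf_threshold`.
#'
#' @param annotations Annotation data frame with a `maf` column.
#' @param maf_threshold Frequency cutoff (default 1e-5).
#' @return Row subset of `annotations`.
#' @export
filter_rare <- function(annotations, maf_threshold = 1e-5) {
  if (anyNA(annotations$maf)) stop("maf must be populated for all variants")
  annotations[annotations$maf < maf_threshold, , drop = FALSE]
}

#' Convert a minor allele count cutoff to the equivalent MAF cutoff
#'
#' @param mac_threshold Minor allele count.
#' @param n_individuals Number of diploid individuals.
#' @return `mac_threshold / (2 * n_individuals)`.
#' @export
mac_to_maf <- function(mac_threshold, n_individuals) {
  stopifnot(n_individuals > 0)
  mac_threshold / (2 * n_individuals)
}

#' Build cumulative minor-allele burden vectors
#'
#' Per-sample cumulative minor allele count over qualifying variants, at
#' exome-wide, per-gene or gene-set granularity, optionally restricted to a
#' set of functional classes and/or a pLI stratum. Missing dosages
#' contribute 0 (carriers are defined by observed alternate alleles).
#'
#' @param genotypes Samples x variants dosage matrix (dense or sparse);
#'   columns named by variant_id.
#' @param annotations Classified annotation table ([classify_variants()]),
#'   one row per genotype column.
#' @param grouping One of "exome", "gene", "gene_set".
#' @param classes Character vector of classes to include (NULL = all).
#' @param pli_stratum Optional stratum filter: "high", "low" or NULL for no
#'   stratification (unknown-pLI variants are included only when NULL).
#' @param gene_sets Named list of character vectors (gene symbols), required
#'   for `grouping = "gene_set"`; see [read_gmt()].
#' @return List with `burden` (samples x units matrix, sparse) and `units`
#'   (data.frame: unit_id, chrom, n_variants, carrier_count).
#' @export
build_burden <- function(genotypes, annotations,
                         grouping = c("gene", "exome", "gene_set"),
                         classes = NULL, pli_stratum = NULL,
                         gene_sets = NULL) {
  grouping <- match.arg(grouping)
  stopifnot(ncol(genotypes) == nrow(annotations))
  keep <- rep(TRUE, nrow(annotations))
  if (!is.null(classes)) keep <- keep & annotations$class %in% classes
  if (!is.null(pli_stratum)) {
    stopifnot(pli_stratum %in% c("high", "low"))
    keep <- keep & annotations$pli_stratum == pli_stratum
  }
  ann <- annotations[keep, , drop = FALSE]
  G <- genotypes[, keep, drop = FALSE]
  if (!methods::is(G, "sparseMatrix") && anyNA(G))
    G[is.na(G)] <- 0 # missing dosage contributes nothing to the burden
  if (nrow(ann) == 0) warning("no qualifying variants; burden is all zero")
  n <- nrow(genotypes)
  if (grouping == "exome") {
    unit_of <- rep("exome-wide", nrow(ann))
    units <- "exome-wide"
    uchrom <- NA_integer_
  } else if (grouping == "gene") {
    unit_of <- ann$gene
    units <- unique(ann$gene)
    uchrom <- ann$chrom[match(units, ann$gene)]
  } else {
    if (is.null(gene_sets) || is.null(names(gene_sets)))
      stop("gene_set grouping requires a named list of gene sets")
    # a variant can land in several sets; expand membership
    idx <- lapply(gene_sets, function(gs) which(ann$gene %in% gs))
    units <- names(gene_sets)
    uchrom <- rep(NA_integer_, length(units))
  }
  if (grouping %in% c("exome", "gene")) {
    J <- Matrix::sparseMatrix(i = seq_len(nrow(ann)),
                              j = match(unit_of, units),
                              x = 1, dims = c(nrow(ann), length(units)))
    B <- G %*% J
  } else {
    cols <- lapply(idx, function(j)
      if (length(j) > 0) Matrix::rowSums(G[, j, drop = FALSE]) else numeric(n))
    B <- Matrix::Matrix(do.call(cbind, c(cols, list(deparse.level = 0))),
                        sparse = TRUE)
  }
  B <- methods::as(B, "CsparseMatrix")
  dimnames(B) <- list(rownames(genotypes), units)
  list(burden = B,
       units = data.frame(unit_id = units,
                          chrom = uchrom,
                          n_variants = if (grouping == "gene_set")
                            vapply(idx, length, integer(1))
                          else as.integer(table(factor(unit_of, levels = units))),
                          carrier_count = Matrix::colSums(B >= 1),
                          row.names = NULL, stringsAsFactors = FALSE))
}

#' Drop burden units with too few carriers
#'
#' Keeps units with `carrier_count >= min_carriers` (default 10, the
#' standard minimum for gene-based PTV burden tests).
#'
#' @param burdens Output of [build_burden()].
#' @param min_carriers Minimum carrier count.
#' @return Filtered burden list, possibly with zero units.
#' @export
filter_units_by_carriers <- function(burdens, min_carriers = 10) {
  keep <- burdens$units$carrier_count >= min_carriers
  list(burden = burdens$burden[, keep, drop = FALSE],
       units = burdens$units[keep, , drop = FALSE])
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path (set name, description, tab-separated genes).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE))
    stop("reading GMT requires the fgsea package")
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets Named list of character vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm)
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
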