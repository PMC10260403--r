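#' Write a synthetic cohort to plain-text files
#'
#' Emits, under `directory`: `variants_common.tsv` + `genotypes_common.tsv`
#' (wide sample x variant dosage; only when common genotypes exist),
#' `genotypes_rare.tsv` (long triplets sample_id / variant_id / dosage),
#' `genotypes_rare.vcf` (VCF v4.2, single-allele GT records),
#' `annotations.tsv`, `phenotypes.tsv` (covariates plus traits) and
#' `truth.tsv` (gene, beta). Files round-trip losslessly through
#' [read_cohort()].
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param directory Output directory, created if needed.
#' @param formats Genotype formats to emit: any of "tsv" (always
#'   recommended; the format [read_cohort()] consumes) and "vcf".
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, directory, formats = c("tsv", "vcf")) {
  formats <- match.arg(formats, several.ok = TRUE)
  stopifnot(inherits(cohort, "cohort"))
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!ok || !dir.exists(directory))
    stop("cannot create output directory: ", directory)
  fw <- function(x, f) data.table::fwrite(x, file.path(directory, f), sep = "\t")
  if (!is.null(cohort$common)) {
    fw(cohort$common$info, "variants_common.tsv")
    gw <- data.table::as.data.table(cohort$common$dosage)
    gw <- cbind(data.table::data.table(sample_id = rownames(cohort$common$dosage)), gw)
    fw(gw, "genotypes_common.tsv")
  }
  ann <- cohort$annotations
  if (is.null(ann))
    ann <- data.frame(variant_id = character(0), chrom = integer(0),
                      pos = integer(0), ref = character(0), alt = character(0),
                      gene = character(0), consequence = character(0),
                      lof_confidence = character(0), mpc = numeric(0),
                      pli = numeric(0), maf = numeric(0))
  fw(ann, "annotations.tsv")
  if (!is.null(cohort$rare) && ncol(cohort$rare$dosage) > 0) {
    trip <- Matrix::summary(cohort$rare$dosage)
    long <- data.table::data.table(
      sample_id = rownames(cohort$rare$dosage)[trip$i],
      variant_id = colnames(cohort$rare$dosage)[trip$j],
      dosage = as.integer(trip$x))
    data.table::setorder(long, variant_id, sample_id)
  } else {
    long <- data.table::data.table(sample_id = character(0),
                                   variant_id = character(0),
                                   dosage = integer(0))
  }
  fw(long, "genotypes_rare.tsv")
  if ("vcf" %in% formats)
    write_vcf(if (!is.null(cohort$rare)) cohort$rare$dosage else NULL,
              ann, cohort$pheno$sample_id,
              file.path(directory, "genotypes_rare.vcf"))
  fw(cohort$pheno, "phenotypes.tsv")
  eff <- cohort$truth$gene_effects
  truth <- if (!is.null(eff) && length(eff) > 0)
    data.frame(gene = names(eff), beta = as.numeric(eff))
  else data.frame(gene = character(0), beta = numeric(0))
  fw(truth, "truth.tsv")
  invisible(directory)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param directory Directory produced by [write_cohort()].
#' @return A `cohort`-shaped list (without the simulation truth internals
#'   beyond gene effects).
#' @export
read_cohort <- function(directory) {
  fr <- function(f, ...) data.table::fread(file.path(directory, f),
                                           sep = "\t", data.table = FALSE, ...)
  pheno <- fr("phenotypes.tsv")
  n <- nrow(pheno)
  common <- NULL
  if (file.exists(file.path(directory, "genotypes_common.tsv"))) {
    gw <- fr("genotypes_common.tsv")
    dos <- as.matrix(gw[, -1, drop = FALSE])
    storage.mode(dos) <- "integer"
    rownames(dos) <- gw$sample_id
    common <- list(dosage = dos, info = fr("variants_common.tsv"))
  }
  ann <- fr("annotations.tsv",
            colClasses = list(character = c("ref", "alt", "gene", "consequence",
                                            "lof_confidence")))
  ann$lof_confidence[ann$lof_confidence == ""] <- NA_character_
  long <- fr("genotypes_rare.tsv")
  rare <- NULL
  if (nrow(ann) > 0) {
    i <- match(long$sample_id, pheno$sample_id)
    j <- match(long$variant_id, ann$variant_id)
    dos <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(long$dosage),
                                dims = c(n, nrow(ann)),
                                dimnames = list(pheno$sample_id, ann$variant_id))
    genes <- unique(ann[, c("gene", "chrom", "pli")])
    rare <- list(dosage = dos, annotations = ann, genes = genes)
  }
  truth <- fr("truth.tsv")
  eff <- if (nrow(truth) > 0) stats::setNames(truth$beta, truth$gene) else NULL
  out <- list(config = NULL, common = common, rare = rare,
              annotations = if (nrow(ann) > 0) ann else NULL,
              pheno = pheno, truth = list(gene_effects = eff))
  class(out) <- "cohort"
  out
}

#' Write genotypes as a minimal VCF v4.2
#'
#' Single-allele records with a GT FORMAT field; dosage 0/1/2/NA maps to
#' 0/0, 0/1, 1/1, ./..
#'
#' @param dosage Samples x variants matrix (dense or sparse) or NULL.
#' @param info Variant table with variant_id, chrom, pos, ref, alt.
#' @param sample_ids Sample names for the header.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(dosage, info, sample_ids, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=cogburden",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  if (!is.null(info) && nrow(info) > 0)
    writeLines(sprintf("##contig=<ID=%s>", unique(info$chrom)), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample_ids), collapse = "\t"), con)
  if (is.null(dosage) || is.null(info) || nrow(info) == 0) return(invisible(path))
  gt_code <- c("0/0", "0/1", "1/1")
  n <- length(sample_ids)
  fixed <- paste(info$chrom, info$pos, info$variant_id, info$ref, info$alt,
                 ".", "PASS", ".", "GT", sep = "\t")
  if (methods::is(dosage, "sparseMatrix")) {
    # ultrarare regime: patch the few non-reference genotypes into an
    # all-reference template (each GT occupies a fixed 3-character slot)
    template <- paste(rep("0/0", n), collapse = "\t")
    trip <- Matrix::summary(methods::as(dosage, "CsparseMatrix"))
    by_var <- split(data.frame(i = trip$i, x = trip$x), trip$j)
    gts <- rep(template, nrow(info))
    for (v in names(by_var)) {
      jj <- as.integer(v)
      line <- template
      for (k in seq_len(nrow(by_var[[v]]))) {
        pos0 <- (by_var[[v]]$i[k] - 1L) * 4L + 1L
        substr(line, pos0, pos0 + 2L) <- gt_code[by_var[[v]]$x[k] + 1L]
      }
      gts[jj] <- line
    }
  } else {
    D <- as.matrix(dosage)
    gts <- vapply(seq_len(nrow(info)), function(v) {
      d <- D[, v]
      paste(ifelse(is.na(d), "./.", gt_code[d + 1L]), collapse = "\t")
    }, character(1))
  }
  writeLines(paste(fixed, gts, sep = "\t"), con)
  invisible(path)
}

#' Read a VCF into a sample x variant dosage matrix
#'
#' Thin wrapper over `vcfR::read.vcfR()`; alt-allele dosage is the count of
#' "1" alleles in the GT field, missing genotypes become NA.
#'
#' @param path VCF path.
#' @return List with `dosage` (samples x variants matrix) and `info`
#'   (variant_id, chrom, pos, ref, alt).
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- data.frame(variant_id = fix$ID, chrom = fix$CHROM,
                     pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count1 <- function(x) {
    out <- rep(NA_integer_, length(x))
    ok <- !is.na(x) & x != "./." & x != ".|."
    out[ok] <- vapply(strsplit(x[ok], "[/|]"),
                      function(a) sum(a == "1"), integer(1))
    out
  }
  dos <- apply(gt, 1, count1)
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = ncol(gt))
  rownames(dos) <- colnames(gt)
  colnames(dos) <- info$variant_id
  list(dosage = dos, info = info)
}
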