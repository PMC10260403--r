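#!/usr/bin/env Rscript
# Exome-wide rare coding-variant burden tests: for each functional class
# (PTV, MPC-tiered missense, synonymous), overall and stratified by gene
# LoF intolerance (pLI >= 0.9 vs < 0.9), regress the INT quantitative trait
# on the per-sample cumulative minor allele count with the standard
# covariates.

library(cogburden)

co <- read_cohort(file.path("results", "cohort"))
ann <- classify_variants(co$annotations)
X <- build_covariates(co$pheno$sex, co$pheno$age,
                      co$pheno[grep("^pc", names(co$pheno))], co$pheno$center)
y <- rank_int(co$pheno$trait_q)

classes <- c("PTV", "missense_t1", "missense_t2", "missense_t3", "synonymous")
strata <- list(all = NULL, pli_high = "high", pli_low = "low")

rows <- list()
for (cl in classes) {
  for (sn in names(strata)) {
    b <- suppressWarnings(
      build_burden(co$rare$dosage, ann, grouping = "exome", classes = cl,
                   pli_stratum = strata[[sn]]))
    if (b$units$carrier_count[1] == 0) next
    r <- linear_burden_test(as.numeric(b$burden[, 1]), y, X,
                            unit_id = paste(cl, sn, sep = "."))
    r$class <- cl
    r$stratum <- sn
    rows[[paste(cl, sn)]] <- r
  }
}
res <- do.call(rbind, rows)
res <- res[order(res$p), ]
dir.create("results", showWarnings = FALSE)
data.table::fwrite(res, file.path("results", "exome_burden.tsv"), sep = "\t")

cat("exome-wide burden tests:", nrow(res), "class x stratum units\n")
cat("strongest signals (deleterious classes should lead):\n")
print(head(res[, c("unit_id", "beta", "se", "p", "carrier_count")], 5),
      row.names = FALSE)
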