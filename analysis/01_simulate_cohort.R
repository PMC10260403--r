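#!/usr/bin/env Rscript
# Build the synthetic discovery cohort used by the downstream analyses:
# n = 20,000 samples, a 2,000-variant common polygenic background over 22
# chromosomes (h2 = 0.3), 400 genes carrying ultrarare coding variants, and
# five genes with injected large burden effects on the quantitative
# cognitive trait. A liability-threshold binary trait (prevalence 8.5%)
# stands in for a developmental-disorder outcome.

library(cogburden)

out_dir <- file.path("results", "cohort")

cfg <- sim_config(
  n_samples = 20000,
  n_common_variants = 2000,
  n_chromosomes = 22,
  n_genes = 400,
  carrier_rate = 1 / 400,
  polygenic_h2 = 0.3,
  # five large-effect genes plus a diffuse background of sixty genes with
  # small deleterious effects (the exome-wide burden signal)
  gene_effects = c(c(g0010 = -0.66, g0050 = -0.31, g0090 = -0.49,
                     g0170 = 0.45, g0330 = -0.55),
                   stats::setNames(rep(-0.08, 60), sprintf("g%04d", 201:260))),
  binary_prevalence = 0.085,
  seed = 2024)

cohort <- simulate_cohort(cfg)
write_cohort(cohort, out_dir, formats = "tsv")

cat("cohort written to", out_dir, "\n")
cat("samples:", nrow(cohort$pheno),
    " common variants:", ncol(cohort$common$dosage),
    " rare variants:", ncol(cohort$rare$dosage), "\n")
cat("quantitative trait variance:", round(var(cohort$pheno$trait_q), 3),
    " binary prevalence:", round(mean(cohort$pheno$trait_b), 4), "\n")
cat("genes with injected effects:",
    paste(names(cfg$gene_effects), collapse = ", "), "\n")
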