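# Shared small fixtures, built once per test run.

small_cohort <- local({
  co <- NULL
  function() {
    if (is.null(co)) {
      cfg <- sim_config(n_samples = 1500, n_common_variants = 300,
                        n_chromosomes = 8, n_genes = 40, carrier_rate = 1 / 60,
                        polygenic_h2 = 0.2, binary_prevalence = 0.2, seed = 101)
      co <<- simulate_cohort(cfg)
    }
    co
  }
})

cohort_covariates <- function(co) {
  build_covariates(co$pheno$sex, co$pheno$age,
                   co$pheno[grep("^pc", names(co$pheno))], co$pheno$center)
}

# Brute-force per-sample burden over qualifying variants (double loop).
brute_burden <- function(G, ann, genes = NULL, classes = NULL) {
  G <- as.matrix(G)
  out <- numeric(nrow(G))
  for (i in seq_len(nrow(G))) {
    for (j in seq_len(ncol(G))) {
      ok <- TRUE
      if (!is.null(genes)) ok <- ok && ann$gene[j] %in% genes
      if (!is.null(classes)) ok <- ok && ann$class[j] %in% classes
      if (ok && !is.na(G[i, j])) out[i] <- out[i] + G[i, j]
    }
  }
  out
}

# Brute-force BH q-values: q_i = min over j with p_(j) >= p_(i) of m p_(j) / j.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  ps <- p[o]
  for (i in seq_len(m)) q[i] <- min(pmin(1, m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}
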