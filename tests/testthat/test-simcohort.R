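test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(0), "n_samples")
  expect_error(sim_config(10, n_common_variants = -1), "non-negative")
  expect_error(sim_config(10, carrier_rate = 1.2), "proportion")
  expect_error(sim_config(10, class_mix = c(PTV = 0.5, missense_t1 = 0.1,
                                            missense_t2 = 0.1, missense_t3 = 0.1,
                                            synonymous = 0.1)), "sum to 1")
  expect_error(sim_config(10, polygenic_h2 = 1), "polygenic_h2")
  expect_error(sim_config(10, n_sibling_pairs = 6), "sibling")
})

test_that("same seed gives bit-identical cohorts", {
  cfg <- sim_config(n_samples = 300, n_common_variants = 50, n_chromosomes = 4,
                    n_genes = 10, carrier_rate = 1 / 30,
                    polygenic_h2 = 0.1, binary_prevalence = 0.3, seed = 9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$common$dosage, b$common$dosage)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$pheno, b$pheno)
})

test_that("common genotypes follow their generating allele frequencies", {
  # empirical MAF within 3 binomial SEs of the target for >= 99% of variants
  cfg <- sim_config(n_samples = 10000, n_common_variants = 200,
                    maf_range = c(0.2, 0.2), seed = 3)
  g <- simulate_common_genotypes(cfg)
  expect_true(all(g$dosage %in% 0:2))
  emp <- colMeans(g$dosage) / 2
  se3 <- 3 * sqrt(0.2 * 0.8 / (2 * 10000))
  expect_gte(mean(abs(emp - 0.2) <= se3), 0.99)
  # MAF fixed at 0.5: mean dosage near 1 by symmetry
  cfg5 <- sim_config(n_samples = 20000, n_common_variants = 20,
                     maf_range = c(0.5, 0.5), seed = 4)
  g5 <- simulate_common_genotypes(cfg5)
  expect_equal(mean(g5$dosage), 1.0, tolerance = 0.01)
  # contiguous chromosome blocks
  expect_true(!is.unsorted(g$info$chrom))
})

test_that("sibling pairs share roughly half their genome", {
  cfg <- sim_config(n_samples = 400, n_common_variants = 2000,
                    n_sibling_pairs = 200, maf_range = c(0.5, 0.5), seed = 6)
  g <- simulate_common_genotypes(cfg)
  s1 <- g$dosage[seq(1, 399, 2), ]
  s2 <- g$dosage[seq(2, 400, 2), ]
  r <- mean(vapply(seq_len(200), function(i) cor(s1[i, ], s2[i, ]), numeric(1)))
  expect_gt(r, 0.4)
  expect_lt(r, 0.6)
})

test_that("per-gene carrier counts are Binomial(n, carrier_rate)", {
  cfg <- sim_config(n_samples = 4000, n_genes = 100, carrier_rate = 1 / 100,
                    seed = 12)
  r <- simulate_rare_variants(cfg)
  ncar <- r$genes$n_carriers
  # chi-square goodness of fit against Binomial(4000, 1/100), binned tails
  brks <- c(-Inf, qbinom(c(0.2, 0.4, 0.6, 0.8), 4000, 1 / 100), Inf)
  obs <- table(cut(ncar, brks))
  pr <- diff(pbinom(c(-Inf, qbinom(c(0.2, 0.4, 0.6, 0.8), 4000, 1 / 100), Inf),
                    4000, 1 / 100))
  expect_gt(suppressWarnings(chisq.test(obs, p = pr / sum(pr))$p.value), 0.01)
  # every carrier holds a singleton het: in-cohort MAF = 1/(2n)
  expect_true(all(r$annotations$maf == 1 / 8000))
})

test_that("degenerate rare-variant settings behave", {
  cfg0 <- sim_config(n_samples = 100, n_genes = 5, carrier_rate = 0, seed = 2)
  r0 <- simulate_rare_variants(cfg0)
  expect_equal(ncol(r0$dosage), 0)
  expect_equal(r0$genes$n_carriers, rep(0L, 5))
  cfgp <- sim_config(n_samples = 200, n_genes = 5, carrier_rate = 1 / 10,
                     class_mix = c(PTV = 1, missense_t1 = 0, missense_t2 = 0,
                                   missense_t3 = 0, synonymous = 0), seed = 2)
  rp <- simulate_rare_variants(cfgp)
  expect_true(all(rp$annotations$consequence %in%
                    c("stop_gained", "frameshift_variant",
                      "splice_donor_variant", "splice_acceptor_variant")))
  expect_true(all(rp$annotations$lof_confidence == "HC"))
})

test_that("phenotype variance bookkeeping holds and null traits are null", {
  co <- small_cohort()
  expect_equal(var(co$pheno$trait_q), 1, tolerance = 0.05)
  # no gene effects, h2 = 0: trait independent of a gene burden
  cfg <- sim_config(n_samples = 5000, n_genes = 10, carrier_rate = 1 / 100,
                    polygenic_h2 = 0, seed = 31)
  co0 <- simulate_cohort(cfg)
  b <- build_burden(co0$rare$dosage, classify_variants(co0$annotations),
                    grouping = "gene")
  res <- linear_burden_test(as.numeric(b$burden[, 1]), co0$pheno$trait_q)
  expect_lt(abs(res$beta), 2 * res$se)
  # liability threshold: prevalence recovered
  expect_lt(abs(mean(small_cohort()$pheno$trait_b) - 0.2), 0.04)
  # excessive variance rejected
  cfgbad <- sim_config(n_samples = 500, n_genes = 2, carrier_rate = 0.5,
                       polygenic_h2 = 0.9,
                       gene_effects = c(g0001 = 1.5), seed = 1)
  expect_error(simulate_cohort(cfgbad), "exceeds 1")
})

test_that("an injected gene effect is recovered by the burden test", {
  # OLS sampling-distribution check: beta_hat within 2 SE of the truth
  cfg <- sim_config(n_samples = 50000, n_genes = 10, carrier_rate = 1 / 250,
                    polygenic_h2 = 0, gene_effects = c(g0003 = -0.5), seed = 77)
  co <- simulate_cohort(cfg)
  b <- build_burden(co$rare$dosage, classify_variants(co$annotations),
                    grouping = "gene")
  j <- which(b$units$unit_id == "g0003")
  res <- linear_burden_test(as.numeric(b$burden[, j]), co$pheno$trait_q)
  expect_lt(abs(res$beta - (-0.5)), 2 * res$se)
})

test_that("cohorts round-trip through write_cohort/read_cohort", {
  co <- simulate_cohort(sim_config(n_samples = 120, n_common_variants = 30,
                                   n_chromosomes = 3, n_genes = 8,
                                   carrier_rate = 1 / 20,
                                   binary_prevalence = 0.3, seed = 5))
  d <- withr::local_tempdir()
  write_cohort(co, d)
  co2 <- read_cohort(d)
  expect_equal(unname(co2$common$dosage), unname(co$common$dosage))
  expect_equal(co2$annotations$variant_id, co$annotations$variant_id)
  expect_equal(co2$annotations$mpc, co$annotations$mpc)
  expect_equal(co2$annotations$lof_confidence, co$annotations$lof_confidence)
  expect_equal(as.matrix(co2$rare$dosage), as.matrix(co$rare$dosage),
               ignore_attr = TRUE)
  expect_equal(co2$pheno$trait_q, co$pheno$trait_q)
  # VCF read-back agrees with the sparse dosage
  v <- read_vcf_dosage(file.path(d, "genotypes_rare.vcf"))
  expect_equal(unname(v$dosage[rownames(co$rare$dosage),
                               colnames(co$rare$dosage)]),
               unname(as.matrix(co$rare$dosage)), ignore_attr = TRUE)
  blocker <- withr::local_tempfile(lines = "x") # a file, not a directory
  expect_error(write_cohort(co, file.path(blocker, "sub")), "directory")
})

test_that("an empty cohort writes valid header-only files", {
  co <- simulate_phenotypes(sim_config(n_samples = 10, seed = 1))
  d <- withr::local_tempdir()
  write_cohort(co, d)
  co2 <- read_cohort(d)
  expect_null(co2$rare)
  expect_equal(nrow(co2$pheno), 10)
})
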