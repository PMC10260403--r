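test_that("PRS scoring equals the brute-force weighted allele sum", {
  set.seed(161)
  n <- 40; m <- 50
  G <- matrix(rbinom(n * m, 2, 0.3), n, m,
              dimnames = list(NULL, sprintf("v%03d", 1:m)))
  G[sample(n * m, 20)] <- NA
  # unambiguous alleles only, mixed ref/alt orientation
  info <- data.frame(variant_id = colnames(G),
                     ref = rep(c("A", "C"), length.out = m),
                     alt = rep(c("G", "T"), length.out = m))
  eff <- ifelse(runif(m) < 0.5, info$ref, info$alt)
  w <- data.frame(variant_id = colnames(G), effect_allele = eff,
                  weight = rnorm(m))
  s <- score_prs(G, info, w)
  # brute force with mean-imputation of missing dosages
  mu <- colMeans(G, na.rm = TRUE)
  brute <- numeric(n)
  for (i in 1:n) for (j in 1:m) {
    d <- G[i, j]; if (is.na(d)) d <- mu[j]
    if (eff[j] == info$ref[j]) d <- 2 - d
    brute[i] <- brute[i] + w$weight[j] * d
  }
  expect_equal(s, brute)
  # trivial cases
  w0 <- w; w0$weight <- 0
  expect_equal(score_prs(G, info, w0), rep(0, n))
  G1 <- matrix(2, 1, 1, dimnames = list(NULL, "v1"))
  i1 <- data.frame(variant_id = "v1", ref = "A", alt = "G")
  w1 <- data.frame(variant_id = "v1", effect_allele = "G", weight = 0.7)
  expect_equal(score_prs(G1, i1, w1), 1.4)
})

test_that("ambiguous and mismatched weight variants are dropped", {
  G <- matrix(c(0, 1, 2, 2, 1, 0), 3, 2,
              dimnames = list(NULL, c("amb", "bad")))
  info <- data.frame(variant_id = c("amb", "bad"),
                     ref = c("A", "C"), alt = c("T", "G"))
  w <- data.frame(variant_id = c("amb", "bad"),
                  effect_allele = c("A", "G"), weight = c(1, 1))
  # A/T is strand-ambiguous; C/G is too: nothing usable
  expect_error(suppressMessages(score_prs(G, info, w)), "no usable overlap")
  info2 <- data.frame(variant_id = c("amb", "bad"),
                      ref = c("A", "C"), alt = c("T", "T"))
  w2 <- data.frame(variant_id = c("amb", "bad"),
                   effect_allele = c("A", "C"), weight = c(1, 1))
  # ambiguous A/T dropped; the usable C/T variant scores on its ref allele
  expect_message(s <- score_prs(G, info2, w2), "1 weight variant")
  expect_equal(s, 2 - G[, "bad"], ignore_attr = TRUE)
})

test_that("carrier flags respect class, pLI and MAF boundaries", {
  ann <- data.frame(
    variant_id = sprintf("v%d", 1:6),
    gene = sprintf("G%d", 1:6),
    consequence = c("stop_gained", "missense_variant", "missense_variant",
                    "stop_gained", "missense_variant", "stop_gained"),
    lof_confidence = c("HC", NA, NA, "HC", NA, "HC"),
    mpc = c(NA, 2.5, 2.0, NA, 3.5, NA),
    pli = c(0.95, 0.95, 0.95, 0.5, 0.95, 0.95),
    maf = c(1e-6, 1e-6, 1e-6, 1e-6, 1e-6, 1e-5))
  ann <- classify_variants(ann)
  G <- diag(6); colnames(G) <- ann$variant_id
  fl <- carrier_flags(G, ann)
  # v1: qualifying PTV; v4 fails pLI; v6 fails MAF (strict <)
  expect_equal(fl$ptv_carrier, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  # v2: MPC 2.5 damaging; v3: MPC 2.0 not (> 2 strict); v5: tier 1 damaging
  expect_equal(fl$damaging_missense_carrier,
               c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE))
  # widening the pLI threshold never removes a carrier
  fl_wide <- carrier_flags(G, ann, pli_threshold = 0.4)
  expect_true(all(fl$ptv_carrier <= fl_wide$ptv_carrier))
  expect_true(all(fl$damaging_missense_carrier <=
                    fl_wide$damaging_missense_carrier))
  # non-strict comparison admits pli == threshold
  fl_ge <- carrier_flags(G, ann, pli_threshold = 0.95, pli_strict = FALSE)
  expect_true(fl_ge$ptv_carrier[1])
  fl_gt <- carrier_flags(G, ann, pli_threshold = 0.95, pli_strict = TRUE)
  expect_false(fl_gt$ptv_carrier[1])
})

test_that("joint model recovers injected conditional effects", {
  # effects of the magnitude reported for PRS / PTV / damaging missense
  set.seed(171)
  n <- 100000
  prs <- rnorm(n)
  ptv <- rbinom(n, 1, 0.004)
  dmis <- rbinom(n, 1, 0.02)
  y <- 0.116 * prs - 0.095 * ptv - 0.053 * dmis + rnorm(n, 0, sqrt(1 - 0.116^2))
  jm <- joint_model(y, prs, ptv, dmis)
  est <- jm$estimates
  truth <- c(prs = 0.116, ptv_carrier = -0.095,
             damaging_missense_carrier = -0.053)
  for (term in names(truth)) {
    row <- est[est$term == term, ]
    expect_lt(abs(row$beta - truth[[term]]), 2 * row$se)
  }
  expect_true(all(est$partial_r2 >= 0 & est$partial_r2 <= 1))
  expect_gt(est$partial_r2[est$term == "prs"], 0.01)
})

test_that("zero-effect predictors have vanishing partial R2", {
  set.seed(181)
  n <- 50000
  prs <- rnorm(n)
  ptv <- rbinom(n, 1, 0.01)
  dmis <- rbinom(n, 1, 0.01)
  y <- 0.2 * prs + rnorm(n)
  jm <- joint_model(y, prs, ptv, dmis)
  expect_lt(jm$estimates$partial_r2[jm$estimates$term == "ptv_carrier"], 1e-4)
  # flag with zero carriers is dropped with a warning
  expect_warning(jm0 <- joint_model(y, prs, ptv, rep(0, n)), "dropped")
  expect_false("damaging_missense_carrier" %in% jm0$estimates$term)
})

test_that("interaction p-values are uniform under an additive model", {
  set.seed(191)
  reps <- 400
  n <- 800
  pint <- matrix(NA_real_, reps, 2)
  for (i in seq_len(reps)) {
    prs <- rnorm(n)
    ptv <- rbinom(n, 1, 0.05)
    dmis <- rbinom(n, 1, 0.05)
    y <- 0.12 * prs - 0.1 * ptv - 0.05 * dmis + rnorm(n)
    jm <- joint_model(y, prs, ptv, dmis, interaction = TRUE)
    pint[i, ] <- jm$interactions$p
  }
  expect_gt(ks.test(pint[, 1], "punif")$p.value, 0.01)
  expect_gt(ks.test(pint[, 2], "punif")$p.value, 0.01)
})

test_that("additive generation gives additive R2 for orthogonalized predictors", {
  set.seed(201)
  n <- 60000
  prs <- rnorm(n)
  ptv <- rbinom(n, 1, 0.01)
  y <- 0.2 * prs - 0.3 * ptv + rnorm(n)
  jm <- joint_model(y, prs, ptv, rbinom(n, 1, 0.01))
  est <- jm$estimates
  expect_equal(jm$r2_full,
               sum(est$partial_r2), tolerance = 0.005)
})

test_that("quantile summaries group and summarize correctly", {
  set.seed(211)
  n <- 5000
  prs <- rnorm(n)
  flags <- data.frame(sample_id = 1:n,
                      ptv_carrier = rbinom(n, 1, 0.02) == 1,
                      damaging_missense_carrier = rbinom(n, 1, 0.05) == 1)
  # q = 50%: exactly two groups of near-equal size
  qs <- quantile_summary(prs, rnorm(n), flags, q = 0.5)
  sizes <- tapply(qs$n, qs$prs_group, sum)
  expect_equal(length(sizes), 2L)
  expect_lte(abs(diff(sizes)), 1)
  # null phenotype: medians near zero
  qs20 <- quantile_summary(prs, rnorm(n), flags, q = 0.2)
  nc <- qs20[qs20$stratum == "noncarrier", ]
  expect_true(all(abs(nc$median) < 2 * 1.253 / sqrt(nc$n)))
  # monotone PRS effect: non-carrier medians non-decreasing
  y <- 0.5 * prs + rnorm(n, 0, 0.3)
  qm <- quantile_summary(prs, y, flags, q = 0.2)
  med <- qm$median[qm$stratum == "noncarrier"][order(
    qm$prs_group[qm$stratum == "noncarrier"])]
  expect_true(all(diff(med) > 0))
  # top-10% binary split
  qt <- quantile_summary(prs, y, flags, top_binary = TRUE)
  expect_setequal(unique(as.character(qt$prs_group)), c("rest90", "top10"))
  expect_error(quantile_summary(prs, y, flags, q = 0.3), "evenly divide")
})
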