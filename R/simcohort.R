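#' Simulation configuration for a synthetic exome cohort
#'
#' Bundles and validates every parameter of the synthetic-cohort generator.
#' The generator emulates the statistical structure that rare-variant burden
#' analyses assume: a common-variant polygenic background spread over
#' chromosomes, ultrarare coding variants carried by a small number of
#' samples per gene with functional class labels (PTV, MPC-tiered missense,
#' synonymous) and gene-level pLI, standard cognitive-epidemiology
#' covariates (sex, age, principal components, recruitment centre), and
#' quantitative plus liability-threshold binary phenotypes with known
#' gene-level burden effects retained as truth.
#'
#' @param n_samples Number of samples.
#' @param n_common_variants Number of common variants (0 allowed; the
#'   polygenic component is then drawn directly from its normal law).
#' @param n_chromosomes Number of chromosomes common variants and genes are
#'   spread over (contiguous blocks). Default 22.
#' @param n_genes Number of genes carrying rare variants.
#' @param carrier_rate Per-gene probability that a sample carries a rare
#'   variant in the gene. Default 1/1900, the carrier rate observed for a
#'   LoF-tolerant gene in a large adult biobank.
#' @param maf_range Range common-variant minor allele frequencies are drawn
#'   from, default U(0.01, 0.5) (the common-variant QC floor excludes
#'   MAF < 1%).
#' @param class_mix Named proportions over variant classes
#'   \code{PTV, missense_t1, missense_t2, missense_t3, synonymous};
#'   must sum to 1. Defaults follow the relative abundance of rare PTV /
#'   missense / synonymous coding variants in large exome studies
#'   (7.1% / 59.4% / 33.5%), with the missense mass split 2% / 8% / 90%
#'   across MPC tiers 1-3.
#' @param pli_high_fraction Fraction of genes with pLI >= 0.9. Default 0.2.
#' @param polygenic_h2 Variance of the standardized liability explained by
#'   the polygenic component, in `[0, 1)`.
#' @param gene_effects Named numeric vector, gene id -> effect per rare
#'   allele on the standardized liability. NULL for no gene effects.
#' @param covariate_effects Optional numeric vector of effects on the
#'   liability for the standardized covariate columns
#'   (sex, age, age^2, sex:age, sex:age^2, PCs); NULL uses small defaults.
#' @param center_effect_sd SD of per-centre level effects. Default 0.02.
#' @param n_centers Number of recruitment-centre levels. Default 5.
#' @param n_pcs Number of simulated principal components. Default 20.
#' @param binary_prevalence Prevalence for the liability-threshold binary
#'   trait (NA to skip it).
#' @param n_sibling_pairs Number of sibling pairs among the samples (the
#'   first `2 * n_sibling_pairs` samples); siblings share parental common
#'   genotypes via Mendelian transmission, hence correlated polygenic
#'   components. Default 0 (unrelated cohort).
#' @param seed Integer seed; a fixed config is bit-reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples,
                       n_common_variants = 0L,
                       n_chromosomes = 22L,
                       n_genes = 0L,
                       carrier_rate = 1 / 1900,
                       maf_range = c(0.01, 0.5),
                       class_mix = c(PTV = 0.071, missense_t1 = 0.012,
                                     missense_t2 = 0.048, missense_t3 = 0.534,
                                     synonymous = 0.335),
                       pli_high_fraction = 0.2,
                       polygenic_h2 = 0,
                       gene_effects = NULL,
                       covariate_effects = NULL,
                       center_effect_sd = 0.02,
                       n_centers = 5L,
                       n_pcs = 20L,
                       binary_prevalence = NA_real_,
                       n_sibling_pairs = 0L,
                       seed = 1L) {
  stopifnot(length(n_samples) == 1L, n_samples >= 1)
  if (n_common_variants < 0 || n_genes < 0)
    stop("n_common_variants and n_genes must be non-negative")
  if (n_chromosomes < 1) stop("n_chromosomes must be positive")
  if (carrier_rate < 0 || carrier_rate > 1)
    stop("carrier_rate must be a proportion in [0, 1]")
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-8)
    stop("class_mix must be non-negative and sum to 1")
  req <- c("PTV", "missense_t1", "missense_t2", "missense_t3", "synonymous")
  if (!setequal(names(class_mix), req))
    stop("class_mix must be named over: ", paste(req, collapse = ", "))
  if (pli_high_fraction < 0 || pli_high_fraction > 1)
    stop("pli_high_fraction must be in [0, 1]")
  if (polygenic_h2 < 0 || polygenic_h2 >= 1)
    stop("polygenic_h2 must be in [0, 1)")
  if (!is.na(binary_prevalence) &&
      (binary_prevalence <= 0 || binary_prevalence >= 1))
    stop("binary_prevalence must be in (0, 1)")
  if (2L * n_sibling_pairs > n_samples)
    stop("more sibling-pair members than samples")
  cfg <- list(n_samples = as.integer(n_samples),
              n_common_variants = as.integer(n_common_variants),
              n_chromosomes = as.integer(n_chromosomes),
              n_genes = as.integer(n_genes),
              carrier_rate = carrier_rate,
              maf_range = maf_range,
              class_mix = class_mix[req],
              pli_high_fraction = pli_high_fraction,
              polygenic_h2 = polygenic_h2,
              gene_effects = gene_effects,
              covariate_effects = covariate_effects,
              center_effect_sd = center_effect_sd,
              n_centers = as.integer(n_centers),
              n_pcs = as.integer(n_pcs),
              binary_prevalence = binary_prevalence,
              n_sibling_pairs = as.integer(n_sibling_pairs),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

.sample_ids <- function(n) sprintf("S%06d", seq_len(n))

# Contiguous assignment of m items to k chromosome labels.
.contiguous_chrom <- function(m, k) {
  if (m == 0L) return(integer(0))
  sort(rep_len(seq_len(k), m))
}

#' Simulate common genotypes under Hardy-Weinberg equilibrium
#'
#' Draws per-variant minor allele frequencies from `config$maf_range` and
#' sample dosages in `{0, 1, 2}`. Variants are assigned to chromosomes in
#' contiguous blocks. When `config$n_sibling_pairs > 0`, the leading pairs
#' of samples are full siblings generated by drawing two parental genotypes
#' per variant and transmitting one allele from each parent to each sibling.
#'
#' @param config A [sim_config()].
#' @return List with `dosage` (samples x variants integer matrix) and
#'   `info` (data.frame: variant_id, chrom, pos, ref, alt, maf).
#' @export
simulate_common_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$n_common_variants
  n <- config$n_samples
  if (m < 1) stop("n_common_variants must be >= 1 to simulate common genotypes")
  set.seed(config$seed)
  maf <- runif(m, config$maf_range[1], config$maf_range[2])
  chrom <- .contiguous_chrom(m, config$n_chromosomes)
  nsib <- 2L * config$n_sibling_pairs
  nun <- n - nsib
  G <- matrix(0L, n, m)
  if (nun > 0) {
    G[(nsib + 1L):n, ] <- matrix(
      rbinom(nun * m, 2L, rep(maf, each = nun)), nun, m)
  }
  if (nsib > 0) {
    npair <- config$n_sibling_pairs
    # four parental alleles per pair per variant; each sib draws one
    # maternal and one paternal allele independently
    for (a in c("m1", "m2", "p1", "p2")) assign(a, matrix(
      rbinom(npair * m, 1L, rep(maf, each = npair)), npair, m))
    pick <- function(x1, x2) {
      u <- matrix(runif(npair * m) < 0.5, npair, m)
      ifelse(u, x1, x2)
    }
    s1 <- pick(m1, m2) + pick(p1, p2)
    s2 <- pick(m1, m2) + pick(p1, p2)
    G[seq(1L, nsib, by = 2L), ] <- s1
    G[seq(2L, nsib, by = 2L), ] <- s2
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  info <- data.frame(variant_id = sprintf("cv%06d", seq_len(m)),
                     chrom = chrom,
                     pos = ave(seq_len(m), chrom, FUN = seq_along) * 1000L,
                     ref = ref, alt = unname(alt), maf = maf,
                     stringsAsFactors = FALSE)
  dimnames(G) <- list(.sample_ids(n), info$variant_id)
  list(dosage = G, info = info)
}

#' Simulate ultrarare coding variants with class annotations
#'
#' Per gene, the number of carriers is Binomial(n_samples, carrier_rate) and
#' carriers are sampled without replacement; each carrier receives one
#' singleton heterozygous variant (the ultrarare regime). Each variant gets a
#' functional class drawn from `class_mix`, an MPC score consistent with its
#' missense tier, high-confidence LoF status for PTVs, and the pLI of its
#' gene. The in-cohort MAF (minor allele count / 2n) is recorded, so the
#' downstream rarity filter operates on frequencies that are meaningful at
#' any cohort size.
#'
#' @param config A [sim_config()].
#' @return List with `dosage` (sparse samples x variants dgCMatrix),
#'   `annotations` (data.frame: variant_id, chrom, pos, ref, alt, gene,
#'   consequence, lof_confidence, mpc, pli, maf), and `genes` (data.frame:
#'   gene, chrom, pli).
#' @export
simulate_rare_variants <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  ng <- config$n_genes
  if (ng < 1) stop("n_genes must be >= 1 to simulate rare variants")
  if (config$carrier_rate > 1) stop("carrier_rate must be <= 1")
  set.seed(config$seed + 1L)
  gene <- sprintf("g%04d", seq_len(ng))
  gchrom <- .contiguous_chrom(ng, config$n_chromosomes)
  high <- runif(ng) < config$pli_high_fraction
  pli <- ifelse(high, runif(ng, 0.9, 1), runif(ng, 0, 0.9))
  ncar <- rbinom(ng, n, config$carrier_rate)
  carriers <- lapply(ncar, function(k) if (k > 0) sample.int(n, k) else integer(0))
  nvar <- sum(ncar)
  vgene <- rep.int(seq_len(ng), ncar)
  i <- unlist(carriers, use.names = FALSE)
  dosage <- Matrix::sparseMatrix(i = i, j = seq_len(nvar), x = 1,
                                 dims = c(n, max(nvar, 0L)))
  cls <- if (nvar > 0)
    sample(names(config$class_mix), nvar, replace = TRUE,
           prob = config$class_mix) else character(0)
  consequence <- character(nvar)
  ptv_csq <- c("stop_gained", "frameshift_variant", "splice_donor_variant",
               "splice_acceptor_variant")
  consequence[cls == "PTV"] <- sample(ptv_csq, sum(cls == "PTV"), replace = TRUE)
  consequence[startsWith(cls, "missense")] <- "missense_variant"
  consequence[cls == "synonymous"] <- "synonymous_variant"
  mpc <- rep(NA_real_, nvar)
  mpc[cls == "missense_t1"] <- runif(sum(cls == "missense_t1"), 3, 6) # MPC > 3
  mpc[cls == "missense_t2"] <- runif(sum(cls == "missense_t2"), 2, 3) # 2 < MPC <= 3
  t3 <- which(cls == "missense_t3")
  # tier 3: low MPC or missing score, both map to tier 3
  has_mpc <- t3[runif(length(t3)) < 0.7]
  mpc[has_mpc] <- runif(length(has_mpc), 0, 2)
  lof <- ifelse(cls == "PTV", "HC", NA_character_)
  bases <- c("A", "C", "G", "T")
  ref <- if (nvar > 0) sample(bases, nvar, replace = TRUE) else character(0)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  ann <- data.frame(variant_id = sprintf("rv%06d", seq_len(nvar)),
                    chrom = gchrom[vgene],
                    pos = 5e6L + seq_len(nvar) * 10L,
                    ref = ref, alt = unname(alt),
                    gene = gene[vgene],
                    consequence = consequence,
                    lof_confidence = lof,
                    mpc = mpc,
                    pli = pli[vgene],
                    maf = if (nvar > 0) Matrix::colSums(dosage) / (2 * n) else numeric(0),
                    stringsAsFactors = FALSE)
  if (nvar > 0) dimnames(dosage) <- list(.sample_ids(n), ann$variant_id)
  list(dosage = dosage, annotations = ann,
       genes = data.frame(gene = gene, chrom = gchrom, pli = pli,
                          n_carriers = ncar, stringsAsFactors = FALSE))
}

# standardized covariate design used to inject covariate effects
.covariate_liability <- function(cov_df, config) {
  z <- function(x) as.numeric(scale(x))
  age_s <- z(cov_df$age)
  X <- cbind(sex = cov_df$sex - mean(cov_df$sex),
             age = age_s, age2 = z(age_s^2),
             sexage = z(cov_df$sex * age_s), sexage2 = z(cov_df$sex * age_s^2),
             as.matrix(cov_df[grep("^pc", names(cov_df))]))
  eff <- config$covariate_effects
  if (is.null(eff))
    eff <- c(0.08, -0.05, 0.01, 0, 0, rep(0.02, config$n_pcs))
  if (length(eff) != ncol(X))
    stop("covariate_effects must have length ", ncol(X))
  lin <- drop(X %*% eff)
  cen_eff <- rnorm(config$n_centers, 0, config$center_effect_sd)
  lin + cen_eff[as.integer(factor(cov_df$center))]
}

#' Simulate phenotypes on top of simulated genotypes
#'
#' Builds covariates (sex, age, PCs, recruitment centre) and a standardized
#' quantitative liability: covariate effects + polygenic component (variance
#' `polygenic_h2`; computed from common genotypes when present, otherwise
#' drawn directly) + per-gene burden effects + Gaussian noise scaled so the
#' total liability variance is 1. A binary trait is obtained by thresholding
#' the centred liability at `qnorm(1 - binary_prevalence)`.
#'
#' @param config A [sim_config()].
#' @param common Output of [simulate_common_genotypes()] or NULL.
#' @param rare Output of [simulate_rare_variants()] or NULL.
#' @return List of class `cohort` with elements `common`, `rare`,
#'   `annotations`, `pheno` (data.frame: sample_id, covariates, `trait_q`,
#'   and `trait_b` when a prevalence is configured) and `truth`
#'   (gene effects, polygenic component, liability pieces).
#' @export
simulate_phenotypes <- function(config, common = NULL, rare = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  set.seed(config$seed + 2L)
  cov_df <- data.frame(sample_id = .sample_ids(n),
                       sex = rbinom(n, 1L, 0.5),
                       age = round(runif(n, 40, 69)),
                       stringsAsFactors = FALSE)
  pcs <- matrix(rnorm(n * config$n_pcs), n, config$n_pcs)
  colnames(pcs) <- paste0("pc", seq_len(config$n_pcs))
  cov_df <- cbind(cov_df, as.data.frame(pcs))
  cov_df$center <- sample(LETTERS[seq_len(config$n_centers)], n, replace = TRUE)

  cov_lin <- .covariate_liability(cov_df, config)
  h2 <- config$polygenic_h2
  if (h2 > 0) {
    if (!is.null(common)) {
      u <- rnorm(ncol(common$dosage))
      graw <- drop(standardize_genotypes(common$dosage) %*% u)
      poly <- graw * sqrt(h2) / sd(graw)
    } else {
      poly <- rnorm(n, 0, sqrt(h2))
    }
  } else poly <- numeric(n)

  gen_part <- numeric(n)
  eff <- config$gene_effects
  if (!is.null(eff) && length(eff) > 0) {
    if (is.null(rare)) stop("gene_effects given but no rare genotypes")
    missing_g <- setdiff(names(eff), rare$genes$gene)
    if (length(missing_g) > 0)
      stop("gene_effects refer to unknown genes: ",
           paste(missing_g, collapse = ", "))
    for (g in names(eff)) {
      j <- which(rare$annotations$gene == g)
      if (length(j) > 0)
        gen_part <- gen_part + eff[[g]] * Matrix::rowSums(rare$dosage[, j, drop = FALSE])
    }
  }
  var_sys <- var(cov_lin) + h2 + var(gen_part)
  if (var_sys > 1)
    stop("polygenic_h2 plus covariate and gene-effect variance exceeds 1 (",
         signif(var_sys, 3), ")")
  noise <- rnorm(n, 0, sqrt(1 - var_sys))
  liab <- cov_lin + poly + gen_part + noise
  pheno <- cov_df
  pheno$trait_q <- liab
  if (!is.na(config$binary_prevalence)) {
    thr <- qnorm(1 - config$binary_prevalence)
    pheno$trait_b <- as.integer((liab - mean(cov_lin)) > thr)
  }
  out <- list(config = config,
              common = common,
              rare = rare,
              annotations = if (!is.null(rare)) rare$annotations else NULL,
              pheno = pheno,
              truth = list(gene_effects = eff, polygenic = poly,
                           covariate_liability = cov_lin))
  class(out) <- "cohort"
  out
}

#' Simulate a full synthetic cohort
#'
#' Convenience orchestration of [simulate_common_genotypes()],
#' [simulate_rare_variants()] and [simulate_phenotypes()].
#' @param config A [sim_config()].
#' @return A `cohort` list.
#' @export
simulate_cohort <- function(config) {
  common <- if (config$n_common_variants > 0) simulate_common_genotypes(config)
  rare <- if (config$n_genes > 0) simulate_rare_variants(config)
  simulate_phenotypes(config, common = common, rare = rare)
}

#' Simulate a binary trait from a logistic model given carrier status
#'
#' Used for replication-style analyses where a target odds ratio is injected
#' directly: `P(case) = plogis(qlogis(baseline_prev) + log(or) * carrier)`.
#'
#' @param carrier 0/1 (or logical) carrier indicator per sample.
#' @param or Target odds ratio for carriers.
#' @param baseline_prev Case prevalence among non-carriers.
#' @return Integer 0/1 outcome vector.
#' @export
simulate_binary_logistic <- function(carrier, or, baseline_prev) {
  stopifnot(or > 0, baseline_prev > 0, baseline_prev < 1)
  p <- plogis(qlogis(baseline_prev) + log(or) * as.numeric(carrier))
  rbinom(length(p), 1L, p)
}
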