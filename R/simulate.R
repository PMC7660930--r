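#' Simulation configuration
#'
#' Defines the linked genotype/annotation/expression/GWAS generative process
#' used throughout testing: LD-correlated dosages, annotation-enriched sparse
#' cis effects, and a trait mediated by genetically regulated expression.
#'
#' Defaults emulate a typical cis region: MAF uniform on \[0.05, 0.5\],
#' adjacent-SNP LD from an AR(1) Gaussian copula with correlation 0.3,
#' exponential(1) annotation values on one track, inclusion logits
#' `-2 + 2 * A` (about a third of SNPs causal in expectation), slab variance
#' ratio 0.01 against unit residual variance (per-gene heritability roughly
#' 0.1-0.3), and a mediated trait effect `kappa = 0.1` against unit trait
#' variance.
#'
#' @param n_train,n_gwas,n_ref Cohort sizes for training, GWAS, and the
#'   reference panel.
#' @param p Number of cis-SNPs.
#' @param m Number of annotation tracks.
#' @param maf_range Range of per-SNP minor allele frequencies.
#' @param ld_rho AR(1) adjacent-SNP latent correlation, in \[0, 1).
#' @param omega_true Length m + 1 inclusion-logit coefficients (intercept
#'   first).
#' @param sigma_beta2 Slab variance ratio; causal effects are
#'   `N(0, sigma_beta2 * sigma2)`.
#' @param sigma2 Residual expression variance.
#' @param kappa Effect of genetically regulated expression on the trait.
#' @param seed Integer seed; every generator is a pure function of
#'   `(config, seed)`.
#' @return A `tgen_sim_config` list.
#' @export
sim_config <- function(n_train = 300L, n_gwas = 5000L, n_ref = 500L,
                       p = 200L, m = 1L, maf_range = base::c(0.05, 0.5),
                       ld_rho = 0.3, omega_true = base::c(-2, 2),
                       sigma_beta2 = 0.01, sigma2 = 1, kappa = 0.1,
                       seed = 1L) {
  stopifnot(n_train > 0, n_gwas > 0, n_ref > 0, p > 0, m >= 0,
            ld_rho >= 0, ld_rho < 1, sigma_beta2 > 0, sigma2 > 0,
            length(omega_true) == m + 1,
            length(maf_range) == 2, maf_range[1] <= maf_range[2],
            maf_range[1] > 0, maf_range[2] <= 0.5)
  structure(list(n_train = as.integer(n_train), n_gwas = as.integer(n_gwas),
                 n_ref = as.integer(n_ref), p = as.integer(p),
                 m = as.integer(m), maf_range = maf_range, ld_rho = ld_rho,
                 omega_true = omega_true, sigma_beta2 = sigma_beta2,
                 sigma2 = sigma2, kappa = kappa, seed = as.integer(seed)),
            class = "tgen_sim_config")
}

# dosages for n individuals at the SNPs described by `snps` (maf + order),
# via two AR(1) latent-Gaussian haplotypes per individual thresholded at the
# allele frequency (Gaussian copula: Binomial(2, maf) marginals, adjacent LD)
draw_dosages <- function(n, maf, ld_rho) {
  p <- length(maf)
  thr <- qnorm(maf)
  hap <- function() {
    Z <- matrix(rnorm(n * p), n, p)
    if (ld_rho > 0 && p > 1) {
      for (j in 2:p) {
        Z[, j] <- ld_rho * Z[, j - 1] + sqrt(1 - ld_rho^2) * Z[, j]
      }
    }
    sweep(Z, 2, thr, "<") * 1
  }
  hap() + hap()
}

#' Simulate a genotype panel
#'
#' Dosages have Binomial(2, maf) marginals with adjacent-SNP LD induced by an
#' AR(1) Gaussian copula; positions are spaced within a synthetic 2 Mb cis
#' window on chromosome 1; alleles are drawn from non-complementary pairs so
#' the synthetic panel survives ambiguity filtering.
#'
#' @param config A [sim_config()].
#' @param n Number of individuals (default `config$n_train`).
#' @param seed Seed (default `config$seed`); same seed, same panel.
#' @return A [genotype_panel()].
#' @export
simulate_panel <- function(config, n = config$n_train, seed = config$seed) {
  withr::local_seed(seed)
  p <- config$p
  maf <- runif(p, config$maf_range[1], config$maf_range[2])
  pos <- sort(sample.int(2e6L, p)) + 1e6L
  pairs <- matrix(base::c("A", "G", "A", "C", "T", "G", "T", "C",
                          "G", "A", "C", "A", "G", "T", "C", "T"),
                  ncol = 2, byrow = TRUE)
  pick <- sample.int(nrow(pairs), p, replace = TRUE)
  snps <- tibble::tibble(snp_id = sprintf("snp_%04d", seq_len(p)),
                         chrom = "1", pos = pos,
                         ref = pairs[pick, 1], alt = pairs[pick, 2],
                         maf = maf)
  dos <- draw_dosages(n, maf, config$ld_rho)
  genotype_panel(dos, snps, sprintf("ind_%05d", seq_len(n)))
}

#' Simulate annotation values and annotation-enriched causal effects
#'
#' Annotation values are Exp(1) draws (non-negative, like fold enrichments);
#' the true inclusion probability of each SNP is
#' `pi_k = sigmoid(omega_0 + A_k . omega)`; causal indicators are Bernoulli
#' draws from `pi`, and causal effects are `N(0, sigma_beta2 * sigma2)`.
#'
#' @param panel A [genotype_panel()] (defines p and the centered dosages for
#'   the realized-heritability bookkeeping).
#' @param config A [sim_config()].
#' @param seed Seed (default `config$seed + 1`).
#' @return List with `annotation` (a [annotation_matrix()]) and `truth`
#'   (a `tgen_sim_truth`: `gamma_true`, `beta_true`, `pi_true`,
#'   `heritability_realized` — filled by [simulate_expression()]).
#' @export
simulate_annotated_effects <- function(panel, config, seed = config$seed + 1L) {
  withr::local_seed(seed)
  p <- n_snps(panel)
  m <- config$m
  A <- matrix(rexp(p * m), p, m,
              dimnames = list(NULL, if (m > 0) paste0("track_", seq_len(m))))
  pi_true <- drop(sigmoid(cbind(1, A) %*% config$omega_true))
  gamma_true <- runif(p) < pi_true
  beta_true <- numeric(p)
  beta_true[gamma_true] <- rnorm(sum(gamma_true),
                                 sd = sqrt(config$sigma_beta2 * config$sigma2))
  truth <- structure(list(gamma_true = gamma_true, beta_true = beta_true,
                          pi_true = pi_true,
                          heritability_realized = NA_real_),
                     class = "tgen_sim_truth")
  list(annotation = annotation_matrix(A), truth = truth)
}

#' Simulate adjusted expression from the causal model
#'
#' `Y = X_centered beta_true + N(0, sigma2)`; the realized heritability
#' `var(X beta) / var(Y)` is recorded on the returned truth object.
#'
#' @param panel Training [genotype_panel()].
#' @param truth A `tgen_sim_truth` from [simulate_annotated_effects()].
#' @param config A [sim_config()].
#' @param gene_id Label for the expression vector.
#' @param seed Seed (default `config$seed + 2`).
#' @return List with `expression` (a [expression_vector()]) and the updated
#'   `truth`.
#' @export
simulate_expression <- function(panel, truth, config, gene_id = "gene_1",
                                seed = config$seed + 2L) {
  withr::local_seed(seed)
  Xc <- scale(panel$dosages, center = TRUE, scale = FALSE)
  g <- drop(Xc %*% truth$beta_true)
  y <- g + rnorm(n_samples(panel), sd = sqrt(config$sigma2))
  truth$heritability_realized <- if (var(y) > 0) var(g) / var(y) else 0
  list(expression = expression_vector(gene_id, y, panel$sample_ids),
       truth = truth)
}

#' Simulate a GWAS cohort, its summary statistics, and a reference panel
#'
#' Draws an independent cohort of `n_gwas` individuals at the same SNPs
#' (same MAFs and LD process as `panel`), builds the trait
#' `T = kappa * (X_centered beta_true) + noise` with noise scaled so the
#' trait has unit variance, computes per-SNP z-scores as marginal-regression
#' t-statistics, and draws a reference panel of `n_ref` individuals from the
#' same process.
#'
#' @param panel Training [genotype_panel()] supplying SNP metadata.
#' @param truth A `tgen_sim_truth`.
#' @param config A [sim_config()].
#' @param seed Seed (default `config$seed + 3`).
#' @return List: `gwas` (a [gwas_summary()] with effect allele = alt),
#'   `reference` (a [genotype_panel()]), `gwas_panel`, `trait`.
#' @export
simulate_gwas <- function(panel, truth, config, seed = config$seed + 3L) {
  withr::local_seed(seed)
  snps <- panel$snps
  Xg <- draw_dosages(config$n_gwas, snps$maf, config$ld_rho)
  gwas_panel <- genotype_panel(Xg, snps,
                               sprintf("gwas_%05d", seq_len(config$n_gwas)))
  Xc <- scale(Xg, center = TRUE, scale = FALSE)
  g <- drop(Xc %*% truth$beta_true)
  sig_g <- config$kappa^2 * var(g)
  noise_var <- max(1 - sig_g, 0.05)
  trait <- config$kappa * g + rnorm(config$n_gwas, sd = sqrt(noise_var))
  z <- marginal_z(Xc, trait)
  gwas <- gwas_summary(tibble::tibble(snp_id = snps$snp_id, a1 = snps$alt,
                                      a2 = snps$ref, z = z),
                       n_gwas = config$n_gwas)
  Xr <- draw_dosages(config$n_ref, snps$maf, config$ld_rho)
  reference <- genotype_panel(Xr, snps,
                              sprintf("ref_%05d", seq_len(config$n_ref)))
  list(gwas = gwas, reference = reference, gwas_panel = gwas_panel,
       trait = trait)
}

# per-SNP marginal regression t-statistics of trait on centered dosage
marginal_z <- function(Xc, trait) {
  n <- length(trait)
  r <- suppressWarnings(cor(Xc, trait))
  r <- pmin(pmax(drop(r), -0.999999), 0.999999)
  r[is.na(r)] <- 0
  r * sqrt((n - 2) / (1 - r^2))
}

#' Simulate a complete linked dataset
#'
#' Convenience wrapper running [simulate_panel()],
#' [simulate_annotated_effects()], [simulate_expression()], and
#' [simulate_gwas()] with seeds derived from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List: `panel`, `annotation`, `truth`, `expression`, `gwas`,
#'   `reference`, `gwas_panel`, `trait`, `gene` (a [gene_info()] spanning the
#'   simulated window), `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  panel <- simulate_panel(config)
  ae <- simulate_annotated_effects(panel, config)
  ex <- simulate_expression(panel, ae$truth, config)
  gw <- simulate_gwas(panel, ex$truth, config)
  gene <- gene_info("gene_1", "1",
                    tss = min(panel$snps$pos), tes = max(panel$snps$pos))
  base::c(list(panel = panel, annotation = ae$annotation, truth = ex$truth,
               expression = ex$expression, gene = gene, config = config),
          gw)
}
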