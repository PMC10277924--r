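# Fixture builders shared across tests. All fixtures are generated in code
# under fixed seeds; nothing is read from disk.

# Small negative-binomial count matrix with optional planted group effect.
nb_counts <- function(n_genes, n_samples, seed = 1, mu_log = 4, disp = 0.15,
                      group = NULL, de_genes = integer(), lfc = 0) {
  set.seed(seed)
  base <- exp(rnorm(n_genes, mu_log, 1.2))
  mu <- matrix(base, n_genes, n_samples)
  if (!is.null(group) && length(de_genes))
    mu[de_genes, group == 1] <- mu[de_genes, group == 1] * 2^lfc
  cts <- matrix(rnbinom(n_genes * n_samples, mu = mu, size = 1 / disp),
                n_genes, n_samples)
  dimnames(cts) <- list(sprintf("g%04d", seq_len(n_genes)),
                        sprintf("s%03d", seq_len(n_samples)))
  cts
}

# Expression matrix with two correlated gene blocks plus independent genes.
block_expression <- function(block_sizes = c(20, 20), n_noise = 20,
                             n_samples = 50, within_r2 = 0.8, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_along(block_sizes), function(b) {
    f <- rnorm(n_samples)
    t(replicate(block_sizes[b],
                sqrt(within_r2) * f + sqrt(1 - within_r2) * rnorm(n_samples)))
  })
  expr <- do.call(rbind, c(rows, list(matrix(rnorm(n_noise * n_samples),
                                             n_noise, n_samples))))
  rownames(expr) <- sprintf("g%03d", seq_len(nrow(expr)))
  expr
}

# Harmonized IV effect table drawn under the two-sample MR model:
# beta_exposure observed around bx_true, beta_outcome around theta*bx_true
# (+ per-IV pleiotropy), with the given SEs.
iv_scenario <- function(bx_true, theta, se_x = 0.003, se_y = 0.02,
                        pleiotropy = 0, seed = 1) {
  set.seed(seed)
  J <- length(bx_true)
  data.frame(variant = sprintf("v%02d", seq_len(J)),
             effect_allele = "A", other_allele = "G",
             beta_exposure = rnorm(J, bx_true, se_x),
             se_exposure = rep(se_x, J),
             beta_outcome = rnorm(J, theta * bx_true + pleiotropy, se_y),
             se_outcome = rep(se_y, J),
             stringsAsFactors = FALSE)
}

# Summary statistics for a single region: one causal variant with the given
# z, remaining variants null; SEs constant.
region_stats <- function(n_var, causal_idx = NULL, z = 0, se = 0.1,
                         seed = 1, prefix = "v") {
  set.seed(seed)
  beta <- rnorm(n_var, 0, se)
  if (!is.null(causal_idx)) beta[causal_idx] <- z * se
  data.frame(variant = sprintf("%s%03d", prefix, seq_len(n_var)),
             beta = beta, se = rep(se, n_var), stringsAsFactors = FALSE)
}

# The standard covariate set used by the DE and regression stages.
covariate_names <- function() {
  c("age", "sex", "rin", "uniq_map_pct", "intronic_pct", "bias3")
}

# Phenotype table with prescribed grades (controls are all-zero rows).
grades_pheno <- function(steatosis, fibrosis, NASH) {
  n <- length(steatosis)
  data.frame(sample_id = sprintf("s%03d", seq_len(n)),
             steatosis = steatosis, fibrosis = fibrosis, NASH = NASH,
             stringsAsFactors = FALSE)
}
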