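small_config <- function(seed = 1, ...) {
  sim_config(n_samples = 80, n_genes_adipose = 120, n_genes_liver = 120,
             n_shared_genes = 100, n_variants = 40, seed = seed, ...)
}

test_that("identical seeds give bit-identical bundles; different seeds differ", {
  b1 <- simulate_study(small_config(seed = 5))
  b2 <- simulate_study(small_config(seed = 5))
  expect_identical(b1, b2)
  b3 <- simulate_study(small_config(seed = 6))
  expect_false(identical(b1$adipose_counts, b3$adipose_counts))
})

test_that("bundle pieces are mutually consistent", {
  cfg <- small_config(seed = 7)
  b <- simulate_study(cfg)
  ids <- b$pheno$sample_id
  expect_identical(colnames(b$adipose_counts), ids)
  expect_identical(colnames(b$liver_counts), ids)
  expect_identical(rownames(b$genotypes), ids)
  expect_equal(nrow(b$adipose_counts), cfg$n_genes_adipose)
  expect_equal(nrow(b$liver_counts), cfg$n_genes_liver)
  expect_equal(length(intersect(rownames(b$adipose_counts),
                                rownames(b$liver_counts))),
               cfg$n_shared_genes)
  expect_true(all(b$adipose_counts >= 0))
  expect_true(all(b$genotypes %in% 0:2))
  expect_true(all(b$exposure_stats$se > 0))
  # truth records exactly the planted configuration
  expect_identical(b$truth$planted_de, cfg$planted_de)
  expect_identical(b$truth$planted_sbc, cfg$planted_sbc)
  # grades are 0..3 and grade-0-in-all controls exist
  expect_true(all(unlist(b$pheno[, c("steatosis", "fibrosis", "NASH")]) %in% 0:3))
  expect_gt(sum(rowSums(b$pheno[, c("steatosis", "fibrosis", "NASH")]) == 0), 5)
})

test_that("contradictory plantings are rejected", {
  pd <- data.frame(gene = c("G00001", "G00001"),
                   tissue = c("adipose", "liver"),
                   trait = "steatosis", lfc = 1.5)
  expect_error(small_config(planted_de = pd, planted_sbc = "G00001"),
               "liver")
  expect_error(small_config(planted_sbc = "G00001"), "adipose-DE")
})

test_that("genotype generation matches its moments, LD and allele settings", {
  # MAF 0.5: mean dosage 1.0 within binomial tolerance at n = 10,000
  cfg <- sim_config(n_samples = 10000, n_genes_adipose = 10,
                    n_genes_liver = 10, n_shared_genes = 10,
                    n_variants = 10, maf_range = c(0.5, 0.5),
                    ld_copy_prob = 0, seed = 11)
  g <- simulate_genotypes(cfg)
  expect_true(all(abs(colMeans(g$dosages) - 1) < 0.05))
  # empirical allele frequency within 3 SE of the configured MAF
  maf_hat <- colMeans(g$dosages) / 2
  se3 <- 3 * sqrt(0.5 * 0.5 / (2 * 10000))
  expect_true(all(abs(maf_hat - 0.5) < se3 * 3))
  # copy probability 1: perfect within-block LD
  cfg2 <- sim_config(n_samples = 400, n_genes_adipose = 10,
                     n_genes_liver = 10, n_shared_genes = 10,
                     n_variants = 10, ld_block_size = 5, ld_copy_prob = 1,
                     seed = 12)
  g2 <- simulate_genotypes(cfg2)
  r2 <- ld_r2(g2$dosages[, 1:5])
  expect_true(all(r2 == 1))
  # palindromic fraction 0: no A/T or C/G records
  cfg3 <- small_config(seed = 13, palindromic_fraction = 0)
  g3 <- simulate_genotypes(cfg3)
  pal <- with(g3$variant_info,
              paste0(effect_allele, other_allele) %in%
                c("AT", "TA", "CG", "GC"))
  expect_false(any(pal))
  cfg4 <- small_config(seed = 13, palindromic_fraction = 1)
  g4 <- simulate_genotypes(cfg4)
  pal4 <- with(g4$variant_info,
               paste0(effect_allele, other_allele) %in%
                 c("AT", "TA", "CG", "GC"))
  expect_true(all(pal4))
})

test_that("null GWAS summary statistics are calibrated", {
  cfg <- sim_config(n_samples = 50, n_genes_adipose = 10, n_genes_liver = 10,
                    n_shared_genes = 10, n_variants = 1000, seed = 14)
  st <- simulate_gwas_summary(cfg, simulate_genotypes(cfg)$variant_info)
  # no true effects anywhere: essentially nothing at genome-wide threshold
  expect_equal(sum(st$exposure$p < 5e-8), 0)
  expect_gt(suppressWarnings(ks.test(st$exposure$p, "punif")$p.value), 0.01)
  # planted causal variant reaches genome-wide significance
  cfg2 <- sim_config(n_samples = 50, n_genes_adipose = 10,
                     n_genes_liver = 10, n_shared_genes = 10,
                     n_variants = 100, seed = 15,
                     planted_gwas = list(
                       exposure = list(causal = data.frame(
                         variant = "v00001", beta = 0.05), n_eff = 5e5),
                       outcome = list(causal = data.frame(
                         variant = character(), beta = numeric()),
                         n_eff = 5e5)),
                     theta_causal = 0.2)
  st2 <- simulate_gwas_summary(cfg2, simulate_genotypes(cfg2)$variant_info)
  expect_lt(st2$exposure$p[1], 5e-8)
  # outcome inherits theta * exposure effect at the shared causal variant
  expect_lt(st2$outcome$p[1], 1e-3)
  expect_gt(st2$outcome$beta[1] / st2$exposure$beta[1], 0)
})

test_that("planted DE effects reach downstream detection; the null stays quiet", {
  # planted adipose log2FC = 2 at n = 200 is recovered by the DE stage
  pd <- data.frame(gene = "G00005", tissue = "adipose", trait = "steatosis",
                   lfc = 2)
  cfg <- sim_config(n_samples = 200, n_genes_adipose = 300,
                    n_genes_liver = 300, n_shared_genes = 300,
                    planted_de = pd, n_variants = 20, seed = 16)
  b <- simulate_study(cfg)
  de <- run_de(b$adipose_counts, b$pheno, "steatosis", covariate_names())
  expect_lt(de$adj_p[de$gene == "G00005"], 0.05)
  expect_gt(de$logFC[de$gene == "G00005"], 1)
  # and the same gene is not DE in liver
  de_l <- run_de(b$liver_counts, b$pheno, "steatosis", covariate_names())
  expect_gt(de_l$adj_p[de_l$gene == "G00005"], 0.05)
})

test_that("an effect-free simulation yields near-zero DE discoveries", {
  fdr_hits <- vapply(1:6, function(s) {
    cfg <- sim_config(n_samples = 200, n_genes_adipose = 400,
                      n_genes_liver = 400, n_shared_genes = 400,
                      n_variants = 20, seed = 30 + s)
    b <- simulate_study(cfg)
    de <- run_de(b$adipose_counts, b$pheno, "steatosis", covariate_names())
    sum(de$adj_p < 0.05, na.rm = TRUE)
  }, numeric(1))
  # empirical FDR at a null: mean discoveries per run stay near zero
  expect_lte(mean(fdr_hits > 0), 0.5)
  expect_lte(mean(fdr_hits), 1)
})

test_that("count moments match the configured dispersion within tolerance", {
  cfg <- small_config(seed = 17)
  b <- simulate_study(cfg)
  cts <- b$adipose_counts
  # method-of-moments dispersion per gene: (var - mu) / mu^2
  mu <- rowMeans(cts); v <- apply(cts, 1, var)
  disp <- (v - mu) / mu^2
  disp <- disp[mu > 20]
  # covariate loadings add a little variance; allow a modest upward shift
  expect_gt(median(disp), 0.5 * cfg$nb_dispersion)
  expect_lt(median(disp), 3 * cfg$nb_dispersion)
})

test_that("written bundles round-trip through the plain-text formats", {
  b <- simulate_study(small_config(seed = 18))
  dir <- tempfile("bundle")
  files <- write_study_bundle(b, dir)
  expect_true(all(file.exists(file.path(
    dir, c("adipose_counts.tsv", "pheno.tsv", "gene_annotation.tsv",
           "genotypes.tsv", "variant_info.tsv", "exposure_stats.tsv")))))
  st <- read_summary_stats(file.path(dir, "exposure_stats.tsv"))
  expect_equal(st$beta, b$exposure_stats$beta, tolerance = 1e-12)
  expect_identical(names(st),
                   c("variant", "chrom", "pos", "effect_allele",
                     "other_allele", "beta", "se", "p"))
  cts <- as.matrix(utils::read.table(file.path(dir, "adipose_counts.tsv"),
                                     header = TRUE, sep = "\t",
                                     row.names = 1, check.names = FALSE))
  expect_equal(cts, b$adipose_counts)
  ann <- utils::read.table(file.path(dir, "gene_annotation.tsv"),
                           header = TRUE, sep = "\t")
  expect_equal(ann$start, b$annotation$start - 1)   # 0-based on disk
  unlink(dir, recursive = TRUE)
})
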