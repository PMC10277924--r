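# Synthetic study generator. Emulates the full input surface of a paired
# adipose/liver NAFLD cohort -- negative-binomial counts with planted
# tissue-specific DE, histology grades thresholded from a Gaussian
# liability that loads on serum triglycerides, genotype dosages with
# block-copy LD, planted cis-eQTLs, and analytically generated GWAS
# summary statistics with a planted causal exposure -> outcome effect --
# so every downstream stage can be scored against a known truth.

#' Build a simulation configuration
#'
#' Defaults describe a desk-scale cohort patterned on a bariatric-surgery
#' study population: ~250 individuals with paired adipose and liver
#' RNA-seq, histology grades for steatosis/fibrosis/NASH with case
#' fractions near 0.60/0.45/0.35 and grade-0-in-all controls, imputed
#' dosages for a few hundred variants, and biobank-scale (n_eff = 500,000)
#' GWAS summary statistics for the exposure (serum TG) and outcome
#' (NAFLD status) traits.
#'
#' @param n_samples cohort size, default 250.
#' @param n_genes_adipose,n_genes_liver genes per tissue, default 2000.
#' @param n_shared_genes genes common to both tissues, default 1600.
#' @param n_variants genotyped variants, default 400.
#' @param maf_range minor-allele-frequency range, default c(0.05, 0.5).
#' @param nb_dispersion shared negative-binomial dispersion, default 0.15.
#' @param planted_de data.frame \code{gene}, \code{tissue}
#'   ("adipose"/"liver"), \code{trait}, \code{lfc} (log2 fold change,
#'   cases vs controls).
#' @param planted_sbc gene ids guaranteed to pass every SBC filter
#'   (secreted, adipose TPM > 30, adipose/liver TPM ratio > 10); they must
#'   also be planted adipose-DE and must not be planted liver-DE.
#' @param planted_eqtl data.frame \code{variant}, \code{gene},
#'   \code{tissue}, \code{slope} (SD expression per allele).
#' @param planted_gwas list with elements \code{exposure} and
#'   \code{outcome}, each \code{list(causal = data.frame(variant, beta),
#'   n_eff = ...)}; outcome true effects are
#'   \code{theta_causal * exposure beta} at shared causal variants plus
#'   any direct outcome \code{causal} entries (pleiotropy scenarios).
#' @param theta_causal causal effect of exposure on outcome on the GWAS
#'   effect-size scale, default 0.163.
#' @param case_fractions named fractions of nonzero grades per trait.
#' @param ld_block_size variants per LD block, default 5.
#' @param ld_copy_prob per-haplotype probability that a block member
#'   copies the block anchor haplotype, default 0.8.
#' @param palindromic_fraction fraction of variants assigned A/T or C/G
#'   alleles, default 0.2.
#' @param seed master seed; all stage streams derive from it.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 250,
                       n_genes_adipose = 2000, n_genes_liver = 2000,
                       n_shared_genes = 1600, n_variants = 400,
                       maf_range = c(0.05, 0.5), nb_dispersion = 0.15,
                       planted_de = NULL, planted_sbc = character(),
                       planted_eqtl = NULL, planted_gwas = NULL,
                       theta_causal = 0.163,
                       case_fractions = c(steatosis = 0.60,
                                          fibrosis = 0.45, NASH = 0.35),
                       ld_block_size = 5, ld_copy_prob = 0.8,
                       palindromic_fraction = 0.2, seed = 1) {
  stopifnot(n_samples > 0, n_genes_adipose > 0, n_genes_liver > 0,
            n_shared_genes >= 0,
            n_shared_genes <= min(n_genes_adipose, n_genes_liver),
            n_variants >= 1, nb_dispersion > 0,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            ld_copy_prob >= 0, ld_copy_prob <= 1,
            palindromic_fraction >= 0, palindromic_fraction <= 1)
  if (is.null(planted_de))
    planted_de <- data.frame(gene = character(), tissue = character(),
                             trait = character(), lfc = numeric())
  if (is.null(planted_eqtl))
    planted_eqtl <- data.frame(variant = character(), gene = character(),
                               tissue = character(), slope = numeric())
  if (is.null(planted_gwas))
    planted_gwas <- list(
      exposure = list(causal = data.frame(variant = character(),
                                          beta = numeric()), n_eff = 5e5),
      outcome = list(causal = data.frame(variant = character(),
                                         beta = numeric()), n_eff = 5e5))
  liver_de <- planted_de$gene[planted_de$tissue == "liver"]
  if (length(intersect(planted_sbc, liver_de)))
    stop("planted SBC genes must not be planted DE in liver")
  if (length(planted_sbc)) {
    adi_de <- planted_de$gene[planted_de$tissue == "adipose"]
    if (!all(planted_sbc %in% adi_de))
      stop("planted SBC genes must be planted adipose-DE")
  }
  structure(list(n_samples = n_samples,
                 n_genes_adipose = n_genes_adipose,
                 n_genes_liver = n_genes_liver,
                 n_shared_genes = n_shared_genes,
                 n_variants = n_variants, maf_range = maf_range,
                 nb_dispersion = nb_dispersion, planted_de = planted_de,
                 planted_sbc = planted_sbc, planted_eqtl = planted_eqtl,
                 planted_gwas = planted_gwas, theta_causal = theta_causal,
                 case_fractions = case_fractions,
                 ld_block_size = ld_block_size,
                 ld_copy_prob = ld_copy_prob,
                 palindromic_fraction = palindromic_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

gene_ids <- function(config) {
  n_total <- config$n_genes_adipose + config$n_genes_liver -
    config$n_shared_genes
  sprintf("G%05d", seq_len(n_total))
}

# Gene annotation: shared genes first, then adipose-only, then liver-only.
# Genes are spaced 2.5 Mb apart across chromosomes so default +/-1 Mb cis
# windows do not overlap between genes, which keeps planted cis signals
# attributable to a single gene.
simulate_annotation <- function(config) {
  set.seed(stage_seed(config$seed, 11L))
  ids <- gene_ids(config)
  n <- length(ids)
  per_chrom <- 100L
  chrom <- paste0("chr", (seq_len(n) - 1L) %/% per_chrom + 1L)
  start <- as.numeric(((seq_len(n) - 1L) %% per_chrom)) * 2.5e6 + 1e6
  width <- round(stats::runif(n, 5e3, 5e4))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  secreted <- stats::runif(n) < 0.15
  adipose_tpm <- exp(stats::rnorm(n, log(8), 1.5))
  liver_tpm <- exp(stats::rnorm(n, log(8), 1.5))
  marker_set <- sample(c("none", "adipocyte", "preadipocyte", "hepatocyte",
                         "immune"), n, replace = TRUE,
                       prob = c(0.8, 0.05, 0.05, 0.05, 0.05))
  ann <- data.frame(gene = ids, chrom = chrom, start = start,
                    end = start + width, strand = strand,
                    secreted = secreted, adipose_tpm = adipose_tpm,
                    liver_tpm = liver_tpm, marker_set = marker_set,
                    stringsAsFactors = FALSE)
  # planted SBCs satisfy all annotation filters by construction
  sbc <- config$planted_sbc
  if (length(sbc)) {
    stopifnot(all(sbc %in% ids))
    idx <- match(sbc, ann$gene)
    ann$secreted[idx] <- TRUE
    ann$adipose_tpm[idx] <- stats::runif(length(idx), 40, 300)
    ann$liver_tpm[idx] <- ann$adipose_tpm[idx] /
      stats::runif(length(idx), 12, 40)
  }
  # truth exclusivity: no other gene satisfies the full annotation
  # conjunction, so the filter cascade's expected output is exactly the
  # planted list (liver TPM is raised until the ratio filter fails)
  other <- setdiff(ids, sbc)
  oi <- match(other, ann$gene)
  clash <- ann$secreted[oi] & ann$adipose_tpm[oi] > 30 &
    ann$adipose_tpm[oi] / pmax(ann$liver_tpm[oi], 1e-9) > 10
  ann$liver_tpm[oi[clash]] <- ann$adipose_tpm[oi[clash]] / 8
  ann
}

#' Simulate genotype dosages with block-copy LD
#'
#' Variants are organized in LD blocks of \code{ld_block_size}; every
#' block shares one MAF. The block anchor's two haplotypes are Bernoulli
#' draws; each other member copies each anchor haplotype with probability
#' \code{ld_copy_prob} (else redraws), giving tunable within-block r^2.
#' A configurable fraction of variants receives palindromic (A/T or C/G)
#' allele pairs. Variant positions cover the same chromosome span as the
#' gene annotation; variants named in \code{planted_eqtl} are placed
#' inside their target gene's body so they fall in its cis window.
#'
#' @param config a \code{\link{sim_config}}.
#' @param annotation optional annotation (regenerated if missing).
#' @return list with \code{dosages} (samples x variants, values 0..2) and
#'   \code{variant_info} (\code{variant}, \code{chrom}, \code{pos},
#'   \code{effect_allele}, \code{other_allele}, \code{maf}).
#' @export
simulate_genotypes <- function(config, annotation = NULL) {
  if (is.null(annotation)) annotation <- simulate_annotation(config)
  set.seed(stage_seed(config$seed, 23L))
  m <- config$n_variants; n <- config$n_samples
  vid <- sprintf("v%05d", seq_len(m))
  block <- (seq_len(m) - 1L) %/% config$ld_block_size
  maf_block <- stats::runif(max(block) + 1L,
                            config$maf_range[1], config$maf_range[2])
  maf <- maf_block[block + 1L]

  # positions: uniform over the annotated span, planted eQTL variants
  # pinned inside their gene body
  chrom_levels <- unique(annotation$chrom)
  chrom <- sample(chrom_levels, m, replace = TRUE)
  pos <- numeric(m)
  for (cl in chrom_levels) {
    sel <- chrom == cl
    span <- range(c(annotation$start[annotation$chrom == cl],
                    annotation$end[annotation$chrom == cl]))
    pos[sel] <- round(stats::runif(sum(sel), span[1] - 5e5, span[2] + 5e5))
  }
  pe <- config$planted_eqtl
  if (nrow(pe)) {
    stopifnot(all(pe$variant %in% vid), all(pe$gene %in% annotation$gene))
    for (i in seq_len(nrow(pe))) {
      j <- match(pe$variant[i], vid)
      k <- match(pe$gene[i], annotation$gene)
      chrom[j] <- annotation$chrom[k]
      pos[j] <- round((annotation$start[k] + annotation$end[k]) / 2)
    }
  }

  dos <- matrix(0L, n, m, dimnames = list(sprintf("S%04d", seq_len(n)), vid))
  h1a <- h2a <- NULL
  for (j in seq_len(m)) {
    anchor <- (j - 1L) %% config$ld_block_size == 0L
    if (anchor) {
      h1a <- stats::rbinom(n, 1L, maf[j])
      h2a <- stats::rbinom(n, 1L, maf[j])
      dos[, j] <- h1a + h2a
    } else {
      cp1 <- stats::runif(n) < config$ld_copy_prob
      cp2 <- stats::runif(n) < config$ld_copy_prob
      h1 <- ifelse(cp1, h1a, stats::rbinom(n, 1L, maf[j]))
      h2 <- ifelse(cp2, h2a, stats::rbinom(n, 1L, maf[j]))
      dos[, j] <- h1 + h2
    }
  }

  pal_pairs <- list(c("A", "T"), c("C", "G"))
  oth_pairs <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  is_pal <- stats::runif(m) < config$palindromic_fraction
  alle <- t(vapply(seq_len(m), function(j) {
    pr <- if (is_pal[j]) pal_pairs[[sample.int(2, 1)]]
          else oth_pairs[[sample.int(4, 1)]]
    if (stats::runif(1) < 0.5) pr else rev(pr)
  }, character(2)))
  vi <- data.frame(variant = vid, chrom = chrom, pos = pos,
                   effect_allele = alle[, 1], other_allele = alle[, 2],
                   maf = maf, stringsAsFactors = FALSE)
  list(dosages = dos, variant_info = vi)
}

#' Simulate GWAS summary statistics analytically
#'
#' Per variant, the estimate is drawn \code{beta_hat ~ N(true beta, se^2)}
#' with \code{se = 1/sqrt(2 maf (1-maf) n_eff)} (standardized-trait GWAS
#' of effective sample size \code{n_eff}); p-values are two-sided normal.
#' Outcome true effects are \code{theta_causal} times the exposure true
#' effects at shared causal variants, plus any direct outcome effects in
#' the configured architecture.
#'
#' @param config a \code{\link{sim_config}}.
#' @param variant_info variant metadata from
#'   \code{\link{simulate_genotypes}}.
#' @return list with \code{exposure} and \code{outcome} summary
#'   data.frames (\code{variant}, \code{chrom}, \code{pos},
#'   \code{effect_allele}, \code{other_allele}, \code{beta}, \code{se},
#'   \code{p}).
#' @export
simulate_gwas_summary <- function(config, variant_info) {
  set.seed(stage_seed(config$seed, 37L))
  arch <- config$planted_gwas
  m <- nrow(variant_info)
  true_x <- stats::setNames(rep(0, m), variant_info$variant)
  if (nrow(arch$exposure$causal))
    true_x[arch$exposure$causal$variant] <- arch$exposure$causal$beta
  true_y <- config$theta_causal * true_x
  if (nrow(arch$outcome$causal))
    true_y[arch$outcome$causal$variant] <-
      true_y[arch$outcome$causal$variant] + arch$outcome$causal$beta

  one <- function(true_beta, n_eff) {
    se <- 1 / sqrt(2 * variant_info$maf * (1 - variant_info$maf) * n_eff)
    beta <- stats::rnorm(m, true_beta, se)
    data.frame(variant = variant_info$variant, chrom = variant_info$chrom,
               pos = variant_info$pos,
               effect_allele = variant_info$effect_allele,
               other_allele = variant_info$other_allele,
               beta = beta, se = se,
               p = 2 * stats::pnorm(-abs(beta / se)),
               stringsAsFactors = FALSE)
  }
  list(exposure = one(true_x, arch$exposure$n_eff),
       outcome = one(true_y, arch$outcome$n_eff))
}

simulate_pheno <- function(config, dosages, variant_info) {
  set.seed(stage_seed(config$seed, 53L))
  n <- config$n_samples
  ids <- rownames(dosages)
  age <- round(stats::rnorm(n, 47, 9))
  sex <- stats::rbinom(n, 1L, 0.5)
  rin <- pmin(10, pmax(5, stats::rnorm(n, 8, 0.8)))
  uniq_map_pct <- pmin(99, stats::rnorm(n, 85, 4))
  intronic_pct <- pmax(1, stats::rnorm(n, 12, 3))
  bias3 <- stats::rnorm(n, 1.1, 0.15)

  # serum TG: genetic score from the exposure architecture plus noise
  gx <- config$planted_gwas$exposure$causal
  score <- rep(0, n)
  if (nrow(gx)) {
    for (i in seq_len(nrow(gx))) {
      v <- gx$variant[i]
      if (v %in% colnames(dosages)) {
        maf <- variant_info$maf[match(v, variant_info$variant)]
        gstd <- (dosages[, v] - 2 * maf) / sqrt(2 * maf * (1 - maf))
        score <- score + gx$beta[i] * gstd
      }
    }
  }
  z_tg <- score + stats::rnorm(n, 0, sqrt(max(1 - stats::var(score), 0.5)))
  z_tg <- as.numeric(scale(z_tg))
  serum_tg <- exp(0.2 + 0.45 * z_tg)   # mmol/L-like positive scale

  # NAFLD grades: shared liability plus a TG loading equal to the causal
  # effect on the GWAS scale, thresholded into grades 0..3
  L0 <- stats::rnorm(n)
  grades <- sapply(names(config$case_fractions), function(tr) {
    frac <- config$case_fractions[[tr]]
    lt <- sqrt(0.55) * L0 + config$theta_causal * z_tg +
      stats::rnorm(n, 0, sqrt(max(0.45 - config$theta_causal^2, 0.05)))
    thr0 <- stats::quantile(lt, 1 - frac)
    g <- integer(n)
    g[lt > thr0] <- 1L
    q2 <- stats::quantile(lt, 1 - frac / 2.5)
    q3 <- stats::quantile(lt, 1 - frac / 6)
    g[lt > q2] <- 2L
    g[lt > q3] <- 3L
    g
  })
  data.frame(sample_id = ids, steatosis = grades[, "steatosis"],
             fibrosis = grades[, "fibrosis"], NASH = grades[, "NASH"],
             serum_tg = serum_tg, age = age, sex = sex, rin = rin,
             uniq_map_pct = uniq_map_pct, intronic_pct = intronic_pct,
             bias3 = bias3, stringsAsFactors = FALSE)
}

simulate_counts <- function(config, tissue, genes, pheno, dosages,
                            variant_info, offset) {
  set.seed(stage_seed(config$seed, offset))
  n <- config$n_samples
  G <- length(genes)
  covars <- scale(as.matrix(pheno[, c("age", "sex", "rin", "uniq_map_pct",
                                      "intronic_pct", "bias3")]))
  base <- stats::rnorm(G, 5, 1.8)                   # log2 baseline
  # planted cis-regulated genes come from the well-expressed stratum:
  # regulation of a near-zero-count gene is not identifiable, so planting
  # one would make the configured truth unusable for scoring
  pe_genes <- unique(config$planted_eqtl$gene[
    config$planted_eqtl$tissue == tissue])
  pi <- match(pe_genes, genes)
  pi <- pi[!is.na(pi)]
  if (length(pi)) base[pi] <- stats::rnorm(length(pi), 7.5, 0.8)
  loadings <- matrix(stats::rnorm(G * ncol(covars), 0, 0.08), G)
  log2mu <- matrix(base, G, n) + loadings %*% t(covars)

  # planted DE: shift case means by the planted log2 fold change
  pd <- config$planted_de[config$planted_de$tissue == tissue, , drop = FALSE]
  for (i in seq_len(nrow(pd))) {
    g <- match(pd$gene[i], genes)
    if (is.na(g)) next
    case <- pheno[[pd$trait[i]]] > 0
    log2mu[g, case] <- log2mu[g, case] + pd$lfc[i]
  }
  # planted eQTLs: allele effect on the log2 scale calibrated so the
  # post-INT slope approximates the planted SD-per-allele value
  # (sd(log2 count) ~= sqrt(dispersion)/ln 2 at high counts)
  pe <- config$planted_eqtl[config$planted_eqtl$tissue == tissue, ,
                            drop = FALSE]
  sd_log2 <- sqrt(config$nb_dispersion) / log(2)
  for (i in seq_len(nrow(pe))) {
    g <- match(pe$gene[i], genes)
    if (is.na(g) || !(pe$variant[i] %in% colnames(dosages))) next
    log2mu[g, ] <- log2mu[g, ] +
      pe$slope[i] * sd_log2 * dosages[, pe$variant[i]]
  }

  libfac <- exp(stats::rnorm(n, 0, 0.2))
  mu <- t(t(2^log2mu) * libfac)
  counts <- matrix(stats::rnbinom(G * n, mu = mu,
                                  size = 1 / config$nb_dispersion), G, n)
  dimnames(counts) <- list(genes, pheno$sample_id)
  counts
}

#' Simulate a complete paired-tissue study
#'
#' Generates the whole input surface for the pipeline: annotation,
#' genotypes, phenotypes, adipose and liver count matrices, GWAS summary
#' statistics, and a truth record listing every planted effect. Identical
#' seeds give bit-identical bundles.
#'
#' @param config a \code{\link{sim_config}}.
#' @return object of class \code{study_bundle}: list with
#'   \code{adipose_counts}, \code{liver_counts}, \code{pheno},
#'   \code{annotation}, \code{genotypes}, \code{variant_info},
#'   \code{exposure_stats}, \code{outcome_stats}, \code{truth},
#'   \code{config}.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- gene_ids(config)
  shared <- ids[seq_len(config$n_shared_genes)]
  adipose_only <- ids[config$n_shared_genes +
                        seq_len(config$n_genes_adipose - config$n_shared_genes)]
  liver_only <- setdiff(ids, c(shared, adipose_only))
  genes_adipose <- c(shared, adipose_only)
  genes_liver <- c(shared, liver_only)

  planted_ids <- unique(c(config$planted_de$gene, config$planted_sbc,
                          config$planted_eqtl$gene))
  stopifnot(all(planted_ids %in% ids))
  ad_pl <- config$planted_de$gene[config$planted_de$tissue == "adipose"]
  stopifnot(all(ad_pl %in% genes_adipose))

  annotation <- simulate_annotation(config)
  geno <- simulate_genotypes(config, annotation)
  pheno <- simulate_pheno(config, geno$dosages, geno$variant_info)
  adipose_counts <- simulate_counts(config, "adipose", genes_adipose, pheno,
                                    geno$dosages, geno$variant_info, 71L)
  liver_counts <- simulate_counts(config, "liver", genes_liver, pheno,
                                  geno$dosages, geno$variant_info, 89L)
  gwas <- simulate_gwas_summary(config, geno$variant_info)

  truth <- list(planted_de = config$planted_de,
                planted_sbc = config$planted_sbc,
                planted_eqtl = config$planted_eqtl,
                planted_gwas = config$planted_gwas,
                theta_causal = config$theta_causal)
  structure(list(adipose_counts = adipose_counts,
                 liver_counts = liver_counts, pheno = pheno,
                 annotation = annotation, genotypes = geno$dosages,
                 variant_info = geno$variant_info,
                 exposure_stats = gwas$exposure,
                 outcome_stats = gwas$outcome,
                 truth = truth, config = config),
            class = "study_bundle")
}

#' Write a study bundle as plain-text tables
#'
#' Counts as gene x sample TSV, phenotypes and annotation as TSV
#' (BED-style half-open 0-based coordinates with a strand column),
#' genotype dosages and variant metadata as TSV, and summary statistics as
#' whitespace-delimited TSV with the conventional
#' \code{variant chrom pos effect_allele other_allele beta se p} header.
#'
#' @param bundle a \code{study_bundle}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_study_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f, rn = FALSE) {
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = rn, col.names = TRUE)
    file.path(dir, f)
  }
  ann <- bundle$annotation
  ann$start <- ann$start - 1   # to 0-based half-open on disk
  files <- c(
    w(bundle$adipose_counts, "adipose_counts.tsv", rn = TRUE),
    w(bundle$liver_counts, "liver_counts.tsv", rn = TRUE),
    w(bundle$pheno, "pheno.tsv"),
    w(ann, "gene_annotation.tsv"),
    w(bundle$genotypes, "genotypes.tsv", rn = TRUE),
    w(bundle$variant_info, "variant_info.tsv"),
    w(bundle$exposure_stats, "exposure_stats.tsv"),
    w(bundle$outcome_stats, "outcome_stats.tsv"))
  invisible(files)
}

#' Read GWAS summary statistics written by \code{write_study_bundle}
#' @param path TSV file with header
#'   \code{variant chrom pos effect_allele other_allele beta se p}.
#' @return data.frame of per-variant records.
#' @export
read_summary_stats <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
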