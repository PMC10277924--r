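# Genetic analysis: cis-eQTL mapping by per-pair linear regression, LD r^2,
# Wakefield approximate Bayes factors, posterior colocalization over the
# five sharing hypotheses, and an LD-mask pass for secondary signals.

#' Map cis-eQTLs by per-pair linear regression
#'
#' Tests every (gene, variant) pair where the variant lies within
#' \code{window} of the gene: by default of either annotated gene boundary;
#' \code{anchor = "end"} reproduces the literal "from the end of each gene"
#' reading (strand-aware: the end coordinate on + genes, the start on -).
#' Expression is regressed on allele dosage per pair; BH FDR is computed
#' over all tested pairs in the tissue. Monomorphic variants are skipped.
#'
#' @param expr corrected expression matrix, genes x samples (typically
#'   INT -> covariate PCs regressed out -> INT).
#' @param dosages samples x variants dosage matrix in [0, 2].
#' @param gene_coords data.frame \code{gene}, \code{chrom}, \code{start},
#'   \code{end}, \code{strand} (BED-style half-open 0-based).
#' @param variant_info data.frame \code{variant}, \code{chrom}, \code{pos}.
#' @param window cis window in bases, default 1e6.
#' @param anchor "both" (default) or "end".
#' @return data.frame \code{gene}, \code{variant}, \code{slope}, \code{se},
#'   \code{t}, \code{p}, \code{fdr} (BH over all tested pairs).
#' @export
map_cis_eqtls <- function(expr, dosages, gene_coords, variant_info,
                          window = 1e6, anchor = c("both", "end")) {
  anchor <- match.arg(anchor)
  stopifnot(window > 0, nrow(dosages) == ncol(expr))
  genes <- intersect(rownames(expr), gene_coords$gene)
  n <- nrow(dosages)
  res <- vector("list", length(genes))
  mono <- 0L
  for (i in seq_along(genes)) {
    g <- genes[i]
    gc <- gene_coords[gene_coords$gene == g, ][1, ]
    if (anchor == "both") {
      lo <- gc$start - window; hi <- gc$end + window
    } else {
      endpt <- if (identical(gc$strand, "-")) gc$start else gc$end
      lo <- endpt - window; hi <- endpt + window
    }
    vs <- variant_info$variant[variant_info$chrom == gc$chrom &
                                 variant_info$pos >= lo &
                                 variant_info$pos <= hi]
    vs <- intersect(vs, colnames(dosages))
    if (!length(vs)) next
    Xv <- dosages[, vs, drop = FALSE]
    poly <- apply(Xv, 2, stats::var) > 0
    mono <- mono + sum(!poly)
    vs <- vs[poly]
    if (!length(vs)) next
    Xc <- scale(Xv[, poly, drop = FALSE], scale = FALSE)
    yc <- expr[g, ] - mean(expr[g, ])
    sxx <- colSums(Xc^2)
    slope <- as.numeric(crossprod(Xc, yc)) / sxx
    rss <- pmax(sum(yc^2) - slope^2 * sxx, 0)
    se <- sqrt(rss / (n - 2) / sxx)
    tt <- slope / se
    res[[i]] <- data.frame(gene = g, variant = vs, slope = slope, se = se,
                           t = tt, p = 2 * stats::pt(-abs(tt), df = n - 2),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(data.frame(gene = character(), variant = character(),
                                      slope = numeric(), se = numeric(),
                                      t = numeric(), p = numeric(),
                                      fdr = numeric()))
  if (mono > 0L) message(mono, " monomorphic variant tests skipped")
  out$fdr <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Pairwise LD as squared Pearson correlation of dosages
#'
#' @param dosages samples x variants matrix; missing values handled
#'   pairwise-complete.
#' @param variants optional subset of variant ids (default all columns).
#' @return symmetric r^2 matrix; zero-variance variants give NA rows/cols.
#' @export
ld_r2 <- function(dosages, variants = NULL) {
  if (!is.null(variants)) dosages <- dosages[, variants, drop = FALSE]
  stopifnot(nrow(dosages) >= 2)
  r <- suppressWarnings(stats::cor(dosages, use = "pairwise.complete.obs"))
  r^2
}

#' Wakefield approximate Bayes factor (log scale)
#'
#' For a single-variant association with estimate \code{beta} and standard
#' error \code{se}, under a N(0, W) effect prior:
#' \code{log ABF = 0.5 * (log(1 - r) + r * z^2)} with \code{z = beta/se},
#' \code{r = W / (W + se^2)}, \code{W = prior_sd^2}.
#'
#' @param beta,se effect estimate and standard error (se > 0); vectorized.
#' @param prior_sd prior effect SD (0.15 for quantitative traits, 0.2 for
#'   binary, by convention).
#' @return log ABF (natural log).
#' @export
wakefield_abf <- function(beta, se, prior_sd = 0.15) {
  stopifnot(all(se > 0))
  z <- beta / se
  r <- prior_sd^2 / (prior_sd^2 + se^2)
  0.5 * (log(1 - r) + r * z^2)
}

#' Colocalization posteriors from summary statistics
#'
#' Enumerates the five hypotheses for a pair of traits over a shared
#' variant set (H0 no association; H1/H2 association with one trait;
#' H3 two distinct causal variants; H4 one shared causal variant), scoring
#' each configuration by Wakefield log ABFs and per-variant prior
#' probabilities p1, p2, p12. All sums run in log space.
#'
#' @param stats1,stats2 data.frames with columns \code{variant},
#'   \code{beta}, \code{se}; only shared variants are used.
#' @param p1,p2,p12 prior probabilities that a variant is causal for trait
#'   1 only, trait 2 only, or both.
#' @param prior_sd1,prior_sd2 ABF prior effect SDs per trait.
#' @return object of class \code{coloc_result}: list with \code{pp}
#'   (named PP0..PP4, summing to 1), \code{n_variants}, \code{lead1},
#'   \code{lead2} (max-|z| variants), \code{labf} (per-variant log ABFs).
#' @export
coloc_abf <- function(stats1, stats2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                      prior_sd1 = 0.15, prior_sd2 = 0.15) {
  shared <- intersect(stats1$variant, stats2$variant)
  if (length(shared) < 2L)
    warning("fewer than 2 shared variants; H3 cannot be represented")
  if (length(shared) == 0L) stop("no shared variants")
  s1 <- stats1[match(shared, stats1$variant), ]
  s2 <- stats2[match(shared, stats2$variant), ]
  l1 <- wakefield_abf(s1$beta, s1$se, prior_sd1)
  l2 <- wakefield_abf(s2$beta, s2$se, prior_sd2)
  S1 <- logsumexp(l1)
  S2 <- logsumexp(l2)
  S12 <- logsumexp(l1 + l2)
  h <- c(H0 = 0,
         H1 = log(p1) + S1,
         H2 = log(p2) + S2,
         H3 = if (length(shared) >= 2L)
           log(p1) + log(p2) + logdiffexp(S1 + S2, S12) else -Inf,
         H4 = log(p12) + S12)
  pp <- exp(h - logsumexp(h))
  names(pp) <- paste0("PP", 0:4)
  structure(list(pp = pp, n_variants = length(shared),
                 lead1 = shared[which.max(abs(s1$beta / s1$se))],
                 lead2 = shared[which.max(abs(s2$beta / s2$se))],
                 labf = data.frame(variant = shared, labf1 = l1, labf2 = l2),
                 priors = c(p1 = p1, p2 = p2, p12 = p12)),
            class = "coloc_result")
}

#' Mask variants linked to a lead signal
#'
#' Removes the lead variant and every variant with r^2 above
#' \code{r2_mask} to it, enabling a second colocalization pass on the
#' remaining variants to look for an independent secondary signal (a
#' simple stand-in for conditioning on the lead variant).
#'
#' @param stats summary-statistics data.frame with a \code{variant} column.
#' @param ld square r^2 matrix with variant dimnames.
#' @param lead lead variant id (must be in the LD matrix).
#' @param r2_mask removal threshold (strictly greater than); \code{0}
#'   removes every variant with any nonzero correlation to the lead.
#' @return \code{stats} restricted to unmasked variants.
#' @export
mask_second_signal <- function(stats, ld, lead, r2_mask = 0.2) {
  stopifnot(lead %in% rownames(ld))
  r2l <- ld[lead, ]
  drop <- names(r2l)[!is.na(r2l) & r2l > r2_mask]
  drop <- union(drop, lead)
  stats[!stats$variant %in% drop, , drop = FALSE]
}
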