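# Two-sample Mendelian randomization: instrument selection from aware-DE
# gene cis regions (eQTL presence, GWAS hit, colocalization, LD filters,
# strand-ambiguity removal), summary-statistics harmonization, and the
# Wald/IVW, Egger-regression and PRESSO-style global estimators.

is_palindromic <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns both traits' effect sizes to the exposure's effect allele.
#' Records whose outcome alleles are swapped relative to the exposure get
#' their outcome beta sign flipped and alleles swapped; incompatible allele
#' pairs are dropped; palindromic (A/T or C/G) variants cannot be strand
#' resolved from alleles alone and are dropped. Harmonizing already
#' harmonized data is the identity.
#'
#' @param exposure,outcome data.frames with columns \code{variant},
#'   \code{effect_allele}, \code{other_allele}, \code{beta}, \code{se}
#'   (and optionally \code{p}); matched on \code{variant}.
#' @return data.frame with \code{variant}, \code{effect_allele},
#'   \code{other_allele}, \code{beta_exposure}, \code{se_exposure},
#'   \code{beta_outcome}, \code{se_outcome}; attribute \code{dropped}
#'   names variants removed with the reason.
#' @export
harmonize <- function(exposure, outcome) {
  shared <- intersect(exposure$variant, outcome$variant)
  ex <- exposure[match(shared, exposure$variant), ]
  ou <- outcome[match(shared, outcome$variant), ]
  ea <- toupper(ex$effect_allele); oa <- toupper(ex$other_allele)
  eb <- toupper(ou$effect_allele); ob <- toupper(ou$other_allele)
  pal <- is_palindromic(ea, oa)
  aligned <- eb == ea & ob == oa
  swapped <- eb == oa & ob == ea
  bad <- !(aligned | swapped)
  beta_out <- ifelse(swapped, -ou$beta, ou$beta)
  keep <- !pal & !bad
  dropped <- data.frame(
    variant = shared[!keep],
    reason = ifelse(pal[!keep], "palindromic", "allele_mismatch"),
    stringsAsFactors = FALSE)
  out <- data.frame(variant = shared[keep],
                    effect_allele = ea[keep], other_allele = oa[keep],
                    beta_exposure = ex$beta[keep], se_exposure = ex$se[keep],
                    beta_outcome = beta_out[keep], se_outcome = ou$se[keep],
                    stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  out
}

#' Select instrumental variables from aware-DE gene cis regions
#'
#' The selection cascade, in order: (1) candidate regions = cis windows of
#' aware-DE genes holding at least one significant cis-eQTL (FDR below
#' \code{eqtl_fdr}) and at least one exposure GWAS hit
#' (p < \code{gwas_p}) that is not also an outcome GWAS hit
#' (outcome p >= \code{gwas_p}); (2) colocalization of the region's eQTL
#' and exposure GWAS signals, keeping regions with PP4 >= \code{pp4_min};
#' (3) IV candidates = the colocalized regions' significant eQTL variants;
#' (4) removal of candidates in LD (r^2 > \code{ld_max}) with any outcome
#' GWAS hit in the region's variant set; (5) LD pruning among candidates at
#' r^2 > \code{ld_max}, keeping per clump the variant with the smallest sum
#' of eQTL-p and exposure-GWAS-p ranks (ties by eQTL p, then variant id);
#' (6) removal of strand-ambiguous (A/T, C/G) variants. Exposure/outcome
#' effects are then harmonized.
#'
#' @param aware_genes character vector of aware-DE gene ids.
#' @param eqtls cis-eQTL table from \code{\link{map_cis_eqtls}} (with fdr).
#' @param exposure_stats,outcome_stats GWAS summary data.frames with
#'   columns \code{variant}, \code{chrom}, \code{pos},
#'   \code{effect_allele}, \code{other_allele}, \code{beta}, \code{se},
#'   \code{p}.
#' @param dosages samples x variants matrix used for LD.
#' @param gene_coords gene coordinate data.frame (as for eQTL mapping).
#' @param window cis window, default 1e6.
#' @param eqtl_fdr,gwas_p,pp4_min,ld_max cascade thresholds (defaults
#'   0.05, 5e-8, 0.8, 0.2).
#' @param prior_sd_eqtl,prior_sd_gwas coloc ABF prior SDs.
#' @param direction tag recorded in the result ("forward" or "reverse").
#' @return object of class \code{iv_set}: list with \code{ivs}
#'   (harmonized data.frame plus \code{gene} and \code{pp4}), \code{audit}
#'   (cascade step counts), \code{regions} (per-region diagnostics),
#'   \code{direction}, \code{failed} (TRUE when no IV survives).
#' @export
select_ivs <- function(aware_genes, eqtls, exposure_stats, outcome_stats,
                       dosages, gene_coords, window = 1e6,
                       eqtl_fdr = 0.05, gwas_p = 5e-8, pp4_min = 0.8,
                       ld_max = 0.2, prior_sd_eqtl = 0.15,
                       prior_sd_gwas = 0.15,
                       direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  audit <- list()
  region_of <- function(g) {
    gc <- gene_coords[gene_coords$gene == g, ][1, ]
    exposure_stats$variant[exposure_stats$chrom == gc$chrom &
                             exposure_stats$pos >= gc$start - window &
                             exposure_stats$pos <= gc$end + window]
  }
  audit$aware_genes <- length(aware_genes)

  regions <- list()
  for (g in intersect(aware_genes, gene_coords$gene)) {
    vs <- region_of(g)
    eq <- eqtls[eqtls$gene == g, ]
    sig_eq <- eq[!is.na(eq$fdr) & eq$fdr < eqtl_fdr, ]
    if (!nrow(sig_eq)) next
    ex <- exposure_stats[exposure_stats$variant %in% vs, ]
    ou <- outcome_stats[match(ex$variant, outcome_stats$variant), ]
    hit <- ex$p < gwas_p & (is.na(ou$p) | ou$p >= gwas_p)
    if (!any(hit, na.rm = TRUE)) next
    regions[[g]] <- list(gene = g, variants = vs, sig_eqtls = sig_eq,
                         exposure = ex, outcome = ou)
  }
  audit$candidate_regions <- length(regions)

  coloc_pass <- list()
  for (g in names(regions)) {
    rg <- regions[[g]]
    eq <- eqtls[eqtls$gene == g & eqtls$variant %in% rg$variants, ]
    e_stats <- data.frame(variant = eq$variant, beta = eq$slope, se = eq$se)
    g_stats <- rg$exposure[, c("variant", "beta", "se")]
    cl <- coloc_abf(e_stats, g_stats,
                    prior_sd1 = prior_sd_eqtl, prior_sd2 = prior_sd_gwas)
    regions[[g]]$pp4 <- unname(cl$pp["PP4"])
    if (cl$pp["PP4"] >= pp4_min) coloc_pass[[g]] <- regions[[g]]
  }
  audit$colocalized_regions <- length(coloc_pass)

  # candidate IVs: the colocalized regions' significant eQTL variants
  cand <- do.call(rbind, lapply(coloc_pass, function(rg) {
    sq <- rg$sig_eqtls[rg$sig_eqtls$variant %in% rg$exposure$variant, ]
    if (!nrow(sq)) return(NULL)
    data.frame(gene = rg$gene, variant = sq$variant, eqtl_p = sq$p,
               pp4 = rg$pp4,
               gwas_p = rg$exposure$p[match(sq$variant, rg$exposure$variant)],
               stringsAsFactors = FALSE)
  }))
  audit$iv_candidates <- if (is.null(cand)) 0L else nrow(cand)
  if (is.null(cand) || !nrow(cand)) {
    return(structure(list(ivs = NULL, audit = audit, regions = regions,
                          direction = direction, failed = TRUE),
                     class = "iv_set"))
  }

  # remove candidates in LD with outcome GWAS hits (within region sets)
  out_hits <- unique(unlist(lapply(coloc_pass, function(rg)
    rg$outcome$variant[!is.na(rg$outcome$p) & rg$outcome$p < gwas_p])))
  if (length(out_hits)) {
    both <- intersect(colnames(dosages), union(cand$variant, out_hits))
    r2 <- ld_r2(dosages, both)
    linked <- vapply(cand$variant, function(v) {
      oh <- setdiff(intersect(out_hits, both), v)
      length(oh) > 0 && any(r2[v, oh] > ld_max, na.rm = TRUE)
    }, logical(1))
    cand <- cand[!linked, , drop = FALSE]
  }
  audit$after_outcome_ld_filter <- nrow(cand)

  # LD prune among candidates, best (rank_eqtl_p + rank_gwas_p) kept
  if (nrow(cand) > 1L) {
    r2 <- ld_r2(dosages, cand$variant)
    score <- rank(cand$eqtl_p) + rank(cand$gwas_p)
    ord <- order(score, cand$eqtl_p, cand$variant)
    keep <- logical(nrow(cand))
    removed <- logical(nrow(cand))
    for (i in ord) {
      if (removed[i]) next
      keep[i] <- TRUE
      linked <- which(r2[cand$variant[i], cand$variant] > ld_max)
      removed[setdiff(linked, i)] <- TRUE
    }
    cand <- cand[keep, , drop = FALSE]
  }
  audit$after_ld_prune <- nrow(cand)

  # strand-ambiguous removal + harmonization
  ex <- exposure_stats[match(cand$variant, exposure_stats$variant), ]
  ou <- outcome_stats[match(cand$variant, outcome_stats$variant), ]
  harm <- harmonize(ex, ou)
  audit$final_ivs <- nrow(harm)
  if (nrow(harm) == 0L) {
    return(structure(list(ivs = NULL, audit = audit, regions = regions,
                          direction = direction, failed = TRUE),
                     class = "iv_set"))
  }
  harm$gene <- cand$gene[match(harm$variant, cand$variant)]
  harm$pp4 <- cand$pp4[match(harm$variant, cand$variant)]
  structure(list(ivs = harm, audit = audit, regions = regions,
                 direction = direction, failed = FALSE),
            class = "iv_set")
}

#' @export
print.iv_set <- function(x, ...) {
  cat("IV selection (", x$direction, " direction)\n", sep = "")
  for (nm in names(x$audit)) cat(sprintf("  %-26s %d\n", nm, x$audit[[nm]]))
  if (x$failed) cat("  FAILED: no valid instruments\n")
  invisible(x)
}

iv_frame <- function(ivset) {
  if (inherits(ivset, "iv_set")) {
    if (isTRUE(ivset$failed)) stop("IV set is in the failure state (no instruments)")
    ivset$ivs
  } else as.data.frame(ivset)
}

#' Inverse-variance-weighted MR estimate
#'
#' Fixed-effect IVW ratio estimate
#' \code{sum(bx by / sy^2) / sum(bx^2 / sy^2)} with
#' \code{SE = sum(bx^2 / sy^2)^(-1/2)}; for a single instrument this is the
#' Wald ratio \code{by/bx} with \code{SE = sy/|bx|}. Cochran's Q is
#' reported, and \code{random_effects = TRUE} inflates the SE by
#' \code{max(1, sqrt(Q/(J-1)))}.
#'
#' @param ivset an \code{iv_set} or a data.frame with columns
#'   \code{beta_exposure}, \code{se_exposure}, \code{beta_outcome},
#'   \code{se_outcome}.
#' @param random_effects multiplicative random-effects SE inflation.
#' @return object of class \code{mr_result}: list with \code{method},
#'   \code{estimate}, \code{se}, \code{p}, \code{ci} (95%), \code{Q},
#'   \code{Q_p}, \code{n_iv}.
#' @export
mr_ivw <- function(ivset, random_effects = FALSE) {
  iv <- iv_frame(ivset)
  J <- nrow(iv)
  stopifnot(J >= 1)
  bx <- iv$beta_exposure; by <- iv$beta_outcome; sy <- iv$se_outcome
  if (J == 1L && bx == 0) stop("single instrument with zero exposure effect")
  w <- 1 / sy^2
  est <- sum(bx * by * w) / sum(bx^2 * w)
  se <- 1 / sqrt(sum(bx^2 * w))
  Q <- sum(w * (by - est * bx)^2)
  Q_p <- if (J > 1) stats::pchisq(Q, df = J - 1, lower.tail = FALSE) else NA_real_
  if (random_effects && J > 1) se <- se * max(1, sqrt(Q / (J - 1)))
  z <- est / se
  structure(list(method = if (J == 1L) "wald" else "ivw",
                 estimate = est, se = se,
                 p = 2 * stats::pnorm(-abs(z)),
                 ci = est + c(-1, 1) * stats::qnorm(0.975) * se,
                 Q = Q, Q_p = Q_p, n_iv = J),
            class = "mr_result")
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with a
#' free intercept, after orienting every (bx, by) pair so bx >= 0 (the
#' InSIDE orientation). The slope is the causal estimate; a nonzero
#' intercept indicates directional pleiotropy. SEs are inflated by
#' \code{max(1, sqrt(RSS/(J-2)))}.
#'
#' @param ivset at least 3 instruments (see \code{\link{mr_ivw}} for the
#'   accepted forms).
#' @return \code{mr_result} with additional \code{intercept},
#'   \code{intercept_se}, \code{intercept_p}.
#' @export
mr_egger <- function(ivset) {
  iv <- iv_frame(ivset)
  J <- nrow(iv)
  if (J < 3L) stop("MR-Egger needs at least 3 instruments")
  flip <- sign(iv$beta_exposure)
  flip[flip == 0] <- 1
  bx <- iv$beta_exposure * flip
  by <- iv$beta_outcome * flip
  w <- 1 / iv$se_outcome^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X * w, X)
  coefs <- solve(XtWX, crossprod(X * w, by))
  res <- by - X %*% coefs
  rss <- sum(w * res^2)
  infl <- max(1, sqrt(rss / (J - 2)))
  covb <- solve(XtWX) * infl^2
  est <- coefs[2]; se <- sqrt(covb[2, 2])
  int <- coefs[1]; int_se <- sqrt(covb[1, 1])
  structure(list(method = "egger", estimate = est, se = se,
                 p = 2 * stats::pt(-abs(est / se), df = J - 2),
                 ci = est + c(-1, 1) * stats::qt(0.975, df = J - 2) * se,
                 intercept = int, intercept_se = int_se,
                 intercept_p = 2 * stats::pt(-abs(int / int_se), df = J - 2),
                 rss = rss, n_iv = J),
            class = "mr_result")
}

presso_rss <- function(bx, by, sy) {
  J <- length(bx)
  w <- 1 / sy^2
  r <- numeric(J)
  for (j in seq_len(J)) {
    est_j <- sum((bx * by * w)[-j]) / sum((bx^2 * w)[-j])
    r[j] <- w[j] * (by[j] - est_j * bx[j])^2
  }
  r
}

#' PRESSO-style global pleiotropy test and outlier detection
#'
#' Computes the observed leave-one-out residual sum of squares
#' \code{RSS = sum_j w_j (by_j - bx_j * est_(-j))^2} (w = 1/sy^2, est_(-j)
#' the IVW estimate excluding instrument j) and compares it to a parametric
#' bootstrap null drawing \code{by* ~ N(bx * est_(-j), sy^2)} and
#' \code{bx* ~ N(bx, sx^2)}. The global p is the proportion of simulated
#' RSS at or above the observed. Per-instrument outliers are flagged when
#' their observed residual exceeds the Bonferroni-adjusted quantile of its
#' simulated distribution.
#'
#' @param ivset at least 4 instruments.
#' @param n_sim bootstrap replicates, default 1000.
#' @param seed integer seed for the bootstrap.
#' @param outlier_alpha per-family outlier significance level (Bonferroni
#'   over instruments), default 0.05.
#' @return \code{mr_result} with \code{method = "presso"}: the IVW
#'   \code{estimate}/\code{se}/\code{p} plus \code{global_rss},
#'   \code{global_p}, \code{outliers} (logical per instrument),
#'   \code{outlier_p}.
#' @export
mr_presso <- function(ivset, n_sim = 1000, seed = 1, outlier_alpha = 0.05) {
  iv <- iv_frame(ivset)
  J <- nrow(iv)
  if (J < 4L) stop("the PRESSO global test needs at least 4 instruments")
  if (n_sim < 100) warning("n_sim < 100 gives a very coarse global p")
  bx <- iv$beta_exposure; by <- iv$beta_outcome
  sx <- iv$se_exposure; sy <- iv$se_outcome
  r_obs <- presso_rss(bx, by, sy)
  rss_obs <- sum(r_obs)
  # expected outcome effects under the no-pleiotropy model
  w <- 1 / sy^2
  est_loo <- vapply(seq_len(J), function(j)
    sum((bx * by * w)[-j]) / sum((bx^2 * w)[-j]), numeric(1))
  set.seed(seed)
  r_sim <- matrix(0, n_sim, J)
  for (b in seq_len(n_sim)) {
    bx_s <- stats::rnorm(J, bx, sx)
    by_s <- stats::rnorm(J, bx * est_loo, sy)
    r_sim[b, ] <- presso_rss(bx_s, by_s, sy)
  }
  rss_sim <- rowSums(r_sim)
  global_p <- mean(rss_sim >= rss_obs)
  outlier_p <- vapply(seq_len(J), function(j)
    mean(r_sim[, j] >= r_obs[j]), numeric(1))
  outliers <- outlier_p < outlier_alpha / J
  ivw <- mr_ivw(iv)
  structure(list(method = "presso", estimate = ivw$estimate, se = ivw$se,
                 p = ivw$p, ci = ivw$ci, n_iv = J,
                 global_rss = rss_obs, global_p = global_p,
                 outliers = outliers, outlier_p = outlier_p,
                 n_sim = n_sim, seed = seed),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR (%s): estimate %.4f (SE %.4f), p = %.3g, %d IVs\n",
              x$method, x$estimate, x$se, x$p, x$n_iv))
  if (!is.null(x$intercept))
    cat(sprintf("  Egger intercept %.4f (p = %.3g)\n",
                x$intercept, x$intercept_p))
  if (!is.null(x$global_p))
    cat(sprintf("  global test RSS %.3f, p = %.3g; %d outliers\n",
                x$global_rss, x$global_p, sum(x$outliers)))
  invisible(x)
}
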