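# Case-control differential expression with precision weights and
# empirical-Bayes moderated t statistics, cross-tissue "aware" DE sets,
# and hypergeometric over-representation.

#' Build a case-control design for one NAFLD trait
#'
#' Cases are samples with a nonzero histology grade for the tested trait;
#' controls are samples with grade zero in all three traits (steatosis,
#' fibrosis, NASH). Samples with grade zero for the tested trait but a
#' nonzero grade elsewhere are neither case nor control and are excluded.
#'
#' @param pheno data.frame with columns \code{sample_id}, \code{steatosis},
#'   \code{fibrosis}, \code{NASH} (integer grades 0-3) and any covariates.
#' @param trait one of "steatosis", "fibrosis", "NASH".
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @return object of class \code{case_control_design}: list with
#'   \code{trait}, \code{case_ids}, \code{control_ids}, \code{sample_ids}
#'   (cases then controls), \code{design} (model matrix with intercept,
#'   group indicator, covariates) and \code{coef} (name of the group
#'   column).
#' @export
build_case_control <- function(pheno, trait = c("steatosis", "fibrosis", "NASH"),
                               covariates = character()) {
  trait <- match.arg(trait)
  traits <- c("steatosis", "fibrosis", "NASH")
  stopifnot(all(traits %in% names(pheno)), "sample_id" %in% names(pheno))
  cases <- pheno$sample_id[pheno[[trait]] > 0]
  controls <- pheno$sample_id[rowSums(pheno[, traits, drop = FALSE] > 0) == 0]
  if (length(cases) == 0L) stop("no cases for trait ", trait)
  if (length(controls) == 0L) stop("no controls (grade zero in all traits)")
  ids <- c(cases, controls)
  grp <- c(rep(1L, length(cases)), rep(0L, length(controls)))
  ph <- pheno[match(ids, pheno$sample_id), , drop = FALSE]
  X <- cbind(`(Intercept)` = 1, case = grp)
  if (length(covariates)) {
    cv <- as.matrix(ph[, covariates, drop = FALSE])
    X <- cbind(X, cv)
  }
  rownames(X) <- ids
  structure(list(trait = trait, case_ids = cases, control_ids = controls,
                 sample_ids = ids, design = X, coef = "case"),
            class = "case_control_design")
}

#' Precision weights from the mean-variance trend
#'
#' Estimates the count-data mean-variance relationship and converts it to
#' per-observation inverse-variance weights, so that heteroscedastic log-CPM
#' values can enter an ordinary linear modeling pipeline. A lowess curve of
#' sqrt(residual SD) against average log2 count is fitted across genes; each
#' observation's predicted sqrt-SD is interpolated at its fitted log2 count
#' and the weight is the predicted SD^-4 (i.e. the inverse of the predicted
#' variance of the log-CPM value).
#'
#' @param counts integer matrix, genes x samples.
#' @param design model matrix, samples x coefficients.
#' @param lib_size library sizes; default column sums of \code{counts}.
#' @param factors optional TMM factors multiplying the library sizes.
#' @param span lowess span, default 0.5.
#' @return list with \code{E} (log2-CPM matrix), \code{weights}
#'   (same shape) and \code{trend} (the lowess curve).
#' @export
voom_weights <- function(counts, design, lib_size = NULL, factors = NULL,
                         span = 0.5) {
  stopifnot(is.matrix(counts), nrow(design) == ncol(counts))
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (!is.null(factors)) lib_size <- lib_size * factors
  y <- t(log2(t(counts + 0.5) / (lib_size + 1) * 1e6))
  qr_x <- qr(design)
  fit_res <- t(qr.resid(qr_x, t(y)))
  fit_vals <- y - fit_res
  df_resid <- ncol(y) - qr_x$rank
  sigma <- sqrt(rowSums(fit_res^2) / df_resid)
  # average log2 count per gene (log-CPM shifted back to the count scale)
  sx <- rowMeans(y) + mean(log2(lib_size + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  if (nrow(y) < 10L) {
    warning("fewer than 10 genes: using flat weights")
    w <- matrix(1, nrow(y), ncol(y), dimnames = dimnames(y))
    return(list(E = y, weights = w, trend = NULL))
  }
  lo <- stats::lowess(sx, sy, f = span)
  lof <- stats::approxfun(lo, rule = 2)
  fitted_count <- fit_vals + matrix(log2(lib_size + 1) - log2(1e6),
                                    nrow(y), ncol(y), byrow = TRUE)
  w <- lof(fitted_count)^-4
  dim(w) <- dim(y)
  dimnames(w) <- dimnames(y)
  list(E = y, weights = w, trend = lo)
}

# Moment-matching estimate of the scaled inverse chi-square prior
# (d0, s0^2) from gene-wise log sample variances. On the log scale,
# log s_g^2 | s0^2 has mean log(s0^2 d0 / d_g) + digamma(d_g/2) -
# digamma(d0/2) ... using the standard F-distribution moments:
#   E[z]   = log(s0^2) + digamma(d_g/2) - log(d_g/2)
#            - digamma(d0/2) + log(d0/2)
#   Var[z] = trigamma(d_g/2) + trigamma(d0/2)
# so d0 solves trigamma(d0/2) = var(z) - trigamma(d_g/2) (Newton on the
# monotone trigamma), and s0^2 follows from the mean equation.
estimate_variance_prior <- function(s2, df) {
  ok <- s2 > 0 & df > 0
  z <- log(s2[ok])
  dg <- df[ok]
  evar <- stats::var(z) - mean(trigamma(dg / 2))
  if (!is.finite(evar) || evar <= 0) {
    return(list(d0 = Inf, s02 = exp(mean(z) - mean(digamma(dg / 2) - log(dg / 2)))))
  }
  # invert trigamma by Newton iteration (monotone decreasing, convex)
  x <- 0.5 + 1 / evar
  for (i in 1:60) {
    delta <- trigamma(x) * (1 - trigamma(x) / evar) / psigamma(x, 2)
    x <- x + delta
    if (abs(delta) < 1e-10 * x) break
  }
  d0 <- 2 * x
  s02 <- exp(mean(z) - mean(digamma(dg / 2) - log(dg / 2)) +
               digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Weighted linear fit with empirical-Bayes moderated t statistics
#'
#' Fits a weighted OLS model per gene, shrinks residual variances toward a
#' common prior estimated by moment matching on log sample variances, and
#' tests one coefficient with a moderated t statistic on d0 + d_g degrees
#' of freedom. The posterior variance is
#' \code{(d0 * s0^2 + d_g * s_g^2) / (d0 + d_g)}.
#'
#' @param expr numeric matrix, genes x samples (typically log2-CPM).
#' @param design model matrix, samples x coefficients.
#' @param coef name or index of the tested coefficient.
#' @param weights optional matrix of observation weights (same shape as
#'   \code{expr}); default unweighted.
#' @return a \code{de_table} data.frame: \code{gene}, \code{logFC},
#'   \code{t}, \code{p}, \code{adj_p} (BH within the tested genes),
#'   \code{mean_expr}; attributes \code{d0} and \code{s02}.
#' @export
fit_moderated <- function(expr, design, coef = 2L, weights = NULL) {
  stopifnot(is.matrix(expr), nrow(design) == ncol(expr))
  qr0 <- qr(design)
  if (qr0$rank < ncol(design)) stop("design is rank deficient")
  G <- nrow(expr); n <- ncol(expr); p <- ncol(design)
  if (is.character(coef)) coef <- match(coef, colnames(design))
  beta <- numeric(G); s2 <- numeric(G); unscaled <- numeric(G)
  df_resid <- rep(n - p, G)
  if (is.null(weights)) {
    XtXi <- chol2inv(qr.R(qr0))
    bhat <- t(qr.coef(qr0, t(expr)))
    res <- t(qr.resid(qr0, t(expr)))
    beta <- bhat[, coef]
    s2 <- rowSums(res^2) / (n - p)
    unscaled <- rep(sqrt(XtXi[coef, coef]), G)
  } else {
    stopifnot(all(dim(weights) == dim(expr)), all(weights > 0))
    for (g in seq_len(G)) {
      sw <- sqrt(weights[g, ])
      qr_g <- qr(design * sw)
      bg <- qr.coef(qr_g, expr[g, ] * sw)
      rg <- qr.resid(qr_g, expr[g, ] * sw)
      beta[g] <- bg[coef]
      s2[g] <- sum(rg^2) / (n - p)
      unscaled[g] <- sqrt(chol2inv(qr.R(qr_g))[coef, coef])
    }
  }
  keep <- df_resid > 0 & is.finite(s2)
  if (any(!keep)) message(sum(!keep), " genes with zero residual df excluded")
  prior <- estimate_variance_prior(s2[keep], df_resid[keep])
  d0 <- prior$d0; s02 <- prior$s02
  s2_post <- if (is.finite(d0)) {
    (d0 * s02 + df_resid * s2) / (d0 + df_resid)
  } else rep(s02, G)
  tstat <- beta / (unscaled * sqrt(s2_post))
  df_total <- pmin(d0 + df_resid, G * (n - p))
  pval <- 2 * stats::pt(-abs(tstat), df = df_total)
  pval[!keep] <- NA_real_
  out <- data.frame(gene = rownames(expr) %||% as.character(seq_len(G)),
                    logFC = beta, t = tstat, p = pval,
                    adj_p = bh_adjust(pval),
                    mean_expr = rowMeans(expr),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  class(out) <- c("de_table", "data.frame")
  out
}

#' Run the full DE pipeline for one tissue and trait
#'
#' Convenience wrapper: expression filter, TMM factors, precision weights
#' and moderated fit for the case-control contrast of one trait.
#'
#' @param counts integer matrix, genes x samples (columns named by sample).
#' @param pheno phenotype data.frame (see \code{\link{build_case_control}}).
#' @param trait tested NAFLD trait.
#' @param covariates covariate column names in \code{pheno}.
#' @param min_nonzero_fraction expression filter threshold.
#' @return a \code{de_table} (see \code{\link{fit_moderated}}) with the
#'   design stored in attribute \code{design}.
#' @export
run_de <- function(counts, pheno, trait, covariates = character(),
                   min_nonzero_fraction = 0.9) {
  cc <- build_case_control(pheno, trait, covariates)
  cts <- counts[, cc$sample_ids, drop = FALSE]
  cts <- filter_expressed(cts, min_nonzero_fraction)
  f <- tmm_factors(cts)
  vw <- voom_weights(cts, cc$design, factors = f)
  de <- fit_moderated(vw$E, cc$design, coef = cc$coef, weights = vw$weights)
  attr(de, "design") <- cc
  de
}

#' Cross-tissue aware DE gene sets
#'
#' A gene is "aware DE" for tissue A if it is DE in A but not in tissue B.
#' Each tissue's DE set is the union over traits at the FDR cutoff. The
#' default removal rule is any-trait: a tissue-A DE gene is removed if it is
#' DE in tissue B for any of the three traits. \code{mode = "per_trait"}
#' restricts removal to the same trait.
#'
#' @param de_a,de_b named lists of \code{de_table}s, one per trait, for
#'   tissues A and B (same trait names).
#' @param fdr FDR cutoff, default 0.05.
#' @param mode "any_trait" (default) or "per_trait".
#' @return list with \code{aware} (character vector, union over traits),
#'   \code{per_trait} (list of per-trait aware sets), \code{de_a_union},
#'   \code{de_b_union}.
#' @export
aware_de_sets <- function(de_a, de_b, fdr = 0.05,
                          mode = c("any_trait", "per_trait")) {
  mode <- match.arg(mode)
  stopifnot(identical(sort(names(de_a)), sort(names(de_b))))
  sig <- function(tab) tab$gene[!is.na(tab$adj_p) & tab$adj_p < fdr]
  a_sets <- lapply(de_a, sig)
  b_sets <- lapply(de_b, sig)
  a_union <- unique(unlist(a_sets))
  b_union <- unique(unlist(b_sets))
  per_trait <- lapply(names(a_sets), function(tr) {
    drop <- if (mode == "any_trait") b_union else b_sets[[tr]]
    setdiff(a_sets[[tr]], drop)
  })
  names(per_trait) <- names(a_sets)
  aware <- if (mode == "any_trait") setdiff(a_union, b_union)
           else unique(unlist(per_trait))
  list(aware = aware, per_trait = per_trait,
       de_a_union = a_union, de_b_union = b_union)
}

#' Hypergeometric over-representation test
#'
#' Tests whether a hit set overlaps an annotation set more than expected by
#' chance, drawing without replacement from the universe:
#' p = P(X >= observed overlap).
#'
#' @param hits,annotation_set,universe character vectors of gene ids;
#'   \code{hits} and \code{annotation_set} must be subsets of
#'   \code{universe}.
#' @return list with \code{overlap}, \code{expected}, \code{fold} and
#'   \code{p}.
#' @export
hypergeometric_enrichment <- function(hits, annotation_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  hits <- unique(hits); annotation_set <- unique(annotation_set)
  stopifnot(all(hits %in% universe), all(annotation_set %in% universe))
  ov <- length(intersect(hits, annotation_set))
  expected <- length(hits) * length(annotation_set) / length(universe)
  p <- stats::phyper(ov - 1, length(annotation_set),
                     length(universe) - length(annotation_set),
                     length(hits), lower.tail = FALSE)
  list(overlap = ov, expected = expected,
       fold = if (expected > 0) ov / expected else NA_real_, p = p)
}

#' Restricted-gene-set DE without covariates
#'
#' The design used for knockdown or treatment experiments: two groups, no
#' covariates, genes prefiltered to those with a summed count above
#' \code{min_group_total} in at least one group (default; set
#' \code{group_rule = "both"} to require both), then restricted to
#' \code{gene_subset}. BH adjustment runs across the tested subset only.
#'
#' @param counts integer matrix, genes x samples.
#' @param groups factor/vector of two group labels, aligned to columns.
#' @param gene_subset character vector of genes to test.
#' @param min_group_total group-sum count threshold (strictly greater
#'   than), default 10.
#' @param group_rule "any" (default) or "both".
#' @return a \code{de_table} over the retained subset.
#' @export
de_restricted <- function(counts, groups, gene_subset, min_group_total = 10,
                          group_rule = c("any", "both")) {
  group_rule <- match.arg(group_rule)
  stopifnot(length(gene_subset) >= 1, length(unique(groups)) == 2L)
  missing <- setdiff(gene_subset, rownames(counts))
  if (length(missing)) {
    warning(length(missing), " subset genes absent from the matrix; skipped")
    gene_subset <- setdiff(gene_subset, missing)
  }
  g <- factor(groups)
  tot <- vapply(levels(g), function(lv)
    rowSums(counts[, g == lv, drop = FALSE]), numeric(nrow(counts)))
  pass <- if (group_rule == "any") apply(tot > min_group_total, 1, any)
          else apply(tot > min_group_total, 1, all)
  keep <- intersect(gene_subset, rownames(counts)[pass])
  cts <- counts[keep, , drop = FALSE]
  design <- cbind(`(Intercept)` = 1, group = as.integer(g == levels(g)[2]))
  f <- tmm_factors(counts)   # factors from the full matrix, as usual
  vw <- voom_weights(cts, design, lib_size = colSums(counts), factors = f)
  fit_moderated(vw$E, design, coef = "group", weights = vw$weights)
}
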