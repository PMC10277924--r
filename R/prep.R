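# Expression preprocessing: expression filter, TMM scaling factors, log-CPM,
# rank-based inverse normal transform, covariate residualization, and
# expression principal components (stand-in for PEER factors).

#' Filter genes by fraction of samples with nonzero counts
#'
#' Keeps genes with a nonzero count in at least \code{ceiling(fraction * n)}
#' samples. Genes expressed in only a minority of samples have bimodal,
#' zero-inflated distributions that rank-based normalisation cannot repair,
#' so they are removed before network and DE analysis.
#'
#' @param counts integer matrix, genes x samples, with dimnames.
#' @param min_nonzero_fraction required fraction of samples with count > 0,
#'   in (0, 1]. Default 0.9.
#' @return the filtered count matrix (possibly zero rows, with a message).
#' @export
filter_expressed <- function(counts, min_nonzero_fraction = 0.9) {
  stopifnot(is.matrix(counts),
            min_nonzero_fraction > 0, min_nonzero_fraction <= 1)
  need <- ceiling(min_nonzero_fraction * ncol(counts))
  keep <- rowSums(counts > 0) >= need
  if (!any(keep)) message("filter_expressed: no genes pass the filter")
  counts[keep, , drop = FALSE]
}

#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Between-sample normalization for count matrices. The reference sample is
#' the one whose 75th-percentile count fraction is closest to the mean across
#' samples. For each sample, gene-wise log-ratios (M) and average log
#' abundances (A) against the reference are computed over genes nonzero in
#' both; the most extreme 30% of M from each tail and 5% of A from each tail
#' are trimmed; the factor is 2 to the precision-weighted mean of the
#' remaining M values. Factors are rescaled to geometric mean 1.
#'
#' @param counts integer matrix, genes x samples.
#' @param logratio_trim,abundance_trim tail-trim fractions for M and A.
#' @return named numeric vector of positive scaling factors, one per sample.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, abundance_trim = 0.05) {
  stopifnot(is.matrix(counts), ncol(counts) >= 2)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("every sample needs a positive library size")
  frac <- sweep(counts, 2, lib, "/")
  f75 <- apply(frac, 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(f75 - mean(f75)))

  one_factor <- function(j) {
    x <- counts[, j]; xr <- counts[, ref]
    keep <- x > 0 & xr > 0
    if (!any(keep)) {
      warning("sample ", j, " shares no nonzero genes with the reference; factor set to 1")
      return(1)
    }
    px <- x[keep] / lib[j]; pr <- xr[keep] / lib[ref]
    M <- log2(px / pr)
    A <- 0.5 * log2(px * pr)
    # asymptotic delta-method variance of M, used as inverse weights
    v <- (lib[j] - x[keep]) / (lib[j] * x[keep]) +
         (lib[ref] - xr[keep]) / (lib[ref] * xr[keep])
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abundance_trim) + 1; hiA <- n + 1 - loA
    keep2 <- rank(M, ties.method = "first") >= loM &
             rank(M, ties.method = "first") <= hiM &
             rank(A, ties.method = "first") >= loA &
             rank(A, ties.method = "first") <= hiA
    if (!any(keep2)) return(1)
    2^(sum(M[keep2] / v[keep2]) / sum(1 / v[keep2]))
  }

  f <- vapply(seq_len(ncol(counts)), one_factor, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' Log2 counts per million with a prior count
#'
#' \code{log2((count + prior) / (libsize * factor + 2 * prior) * 1e6)}.
#' The prior keeps zero counts finite; the doubled prior in the denominator
#' keeps the transform consistent as library size grows.
#'
#' @param counts integer matrix, genes x samples.
#' @param factors per-sample TMM factors (default all 1).
#' @param prior_count pseudo-count, default 0.5.
#' @return numeric matrix of log2-CPM values with a \code{transform}
#'   attribute.
#' @export
log_cpm <- function(counts, factors = NULL, prior_count = 0.5) {
  stopifnot(is.matrix(counts))
  lib <- colSums(counts)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  stopifnot(length(factors) == ncol(counts))
  eff <- lib * factors
  out <- log2(sweep(counts + prior_count, 2, eff + 2 * prior_count, "/") * 1e6)
  attr(out, "transform") <- if (all(factors == 1)) "cpm" else "log_cpm_tmm"
  out
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles of their (tie-averaged) ranks:
#' \code{qnorm((rank - c) / (n - 2c + 1))} with the Blom constant c = 3/8.
#' Any monotone transform of the input yields the identical output.
#'
#' @param x numeric vector, length >= 2.
#' @param c offset constant; default 3/8 (Blom).
#' @return numeric vector with mean approximately 0 and SD approximately 1.
#' @export
inverse_normal_transform <- function(x, c = 3 / 8) {
  stopifnot(length(x) >= 2)
  if (length(unique(x[!is.na(x)])) <= 1L) {
    warning("constant vector: inverse normal transform returns zeros")
    return(rep(0, length(x)))
  }
  n <- sum(!is.na(x))
  r <- rank(x, ties.method = "average", na.last = "keep")
  stats::qnorm((r - c) / (n - 2 * c + 1))
}

#' Residualize expression against covariates
#'
#' Replaces each gene (row) by its OLS residuals against an intercept plus
#' the covariate columns, optionally followed by a second inverse normal
#' transform per gene (the convention used before network construction and
#' eQTL mapping, so gene distributions stay normal after adjustment).
#'
#' @param expr numeric matrix, genes x samples.
#' @param covariates numeric matrix or data.frame, samples x covariates.
#' @param second_int if TRUE, apply \code{\link{inverse_normal_transform}}
#'   to every gene after residualization.
#' @return matrix of the same shape; rows are orthogonal to the design
#'   when \code{second_int = FALSE}.
#' @export
residualize <- function(expr, covariates, second_int = FALSE) {
  stopifnot(is.matrix(expr))
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  stopifnot(nrow(X) == ncol(expr))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  res <- t(qr.resid(qr_x, t(expr)))
  dimnames(res) <- dimnames(expr)
  if (second_int) {
    res <- t(apply(res, 1, inverse_normal_transform))
    dimnames(res) <- dimnames(expr)
  }
  attr(res, "transform") <- "residualized"
  res
}

#' Principal components of an expression matrix
#'
#' Top-k PC scores of the gene-standardized matrix, used as data-driven
#' expression covariates (the role PEER factors play for eQTL mapping).
#' Sign convention: within each component, the gene loading with the largest
#' magnitude is made positive, so scores are reproducible across runs.
#'
#' @param expr numeric matrix, genes x samples.
#' @param k number of components, k < min(genes, samples).
#' @return samples x k matrix of scores, with a \code{var_explained}
#'   attribute giving each component's variance share.
#' @export
expression_pcs <- function(expr, k) {
  stopifnot(is.matrix(expr), k >= 1, k < min(dim(expr)))
  Z <- t(scale(t(expr)))           # standardize genes
  Z[!is.finite(Z)] <- 0            # constant genes contribute nothing
  sv <- svd(t(Z), nu = k, nv = k)  # samples x genes
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], nrow = k)
  for (j in seq_len(k)) {
    load_j <- sv$v[, j]
    if (load_j[which.max(abs(load_j))] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- colnames(expr)
  colnames(scores) <- paste0("PC", seq_len(k))
  attr(scores, "var_explained") <- (sv$d^2 / sum(sv$d^2))[seq_len(k)]
  scores
}
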