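# Weighted co-expression networks: soft-threshold choice, topological
# overlap, module detection by static tree cut, eigengenes, module merging,
# and Bonferroni-controlled correlation tables.

#' Soft-threshold diagnostics
#'
#' For each candidate power beta, builds the unsigned adjacency
#' \code{|cor(x_i, x_j)|^beta}, computes each gene's connectivity
#' \code{k_i = sum_j a_ij}, and summarizes scale-free fit as the signed r^2
#' of log10 p(k) against log10 k over equal-count connectivity bins
#' (positive when the slope is negative, as a scale-free network requires).
#'
#' @param expr numeric matrix, genes x samples (>= 20 genes).
#' @param powers integer vector of candidate soft powers.
#' @param n_bins number of connectivity bins, default 10.
#' @return data.frame with \code{power}, \code{sft_r2},
#'   \code{mean_connectivity}.
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, n_bins = 10) {
  stopifnot(is.matrix(expr), nrow(expr) >= 20)
  ac <- abs(stats::cor(t(expr)))
  diag(ac) <- 0
  out <- lapply(powers, function(b) {
    a <- ac^b
    k <- rowSums(a)
    data.frame(power = b, sft_r2 = scale_free_r2(k, n_bins),
               mean_connectivity = mean(k))
  })
  do.call(rbind, out)
}

# Scale-free fit index: bin connectivity, regress log10 frequency on
# log10 mean connectivity per bin; the index is r^2 signed positive when
# the slope is negative (the direction a scale-free degree law requires).
scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(NA_real_)
  bins <- cut(k, breaks = n_bins)
  kmean <- tapply(k, bins, mean)
  cnt <- tapply(k, bins, length)
  ok <- !is.na(kmean) & !is.na(cnt) & cnt > 0
  x <- log10(kmean[ok]); y <- log10(cnt[ok] / sum(cnt[ok]))
  if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  r <- stats::cor(x, y)
  unname(-sign(r) * r^2)
}

#' Unsigned adjacency matrix
#' @param expr genes x samples matrix.
#' @param power soft-threshold power.
#' @return genes x genes adjacency \code{|cor|^power} with zero diagonal.
#' @export
adjacency_matrix <- function(expr, power) {
  a <- abs(stats::cor(t(expr)))^power
  diag(a) <- 0
  a
}

#' Topological overlap matrix
#'
#' \code{TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)}
#' for i != j, with unit diagonal; genes overlap topologically when they
#' share neighbours, not only when directly connected. The dissimilarity
#' 1 - TOM is the clustering input for module detection.
#'
#' @param adjacency symmetric matrix with entries in [0, 1] (diagonal
#'   ignored, treated as zero).
#' @return the TOM similarity matrix.
#' @export
tom_similarity <- function(adjacency) {
  stopifnot(is.matrix(adjacency))
  if (max(abs(adjacency - t(adjacency))) > 1e-10) stop("adjacency must be symmetric")
  a <- adjacency
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect modules by average-linkage clustering of the TOM dissimilarity
#'
#' Genes are clustered with average linkage on 1 - TOM and branches are cut
#' at a static height expressed as a fraction of the dendrogram's maximum
#' merge height. Clusters smaller than \code{min_module_size} are relabeled
#' "grey" (unassigned). Module labels "M1", "M2", ... are ordered by
#' decreasing size.
#'
#' @param diss_tom square dissimilarity matrix (1 - TOM).
#' @param min_module_size minimum cluster size, default 30.
#' @param cut_height fraction of the maximum merge height at which to cut,
#'   default 0.99.
#' @return named character vector gene -> module label ("grey" =
#'   unassigned), with the \code{hclust} tree in attribute \code{tree}.
#' @export
detect_modules <- function(diss_tom, min_module_size = 30, cut_height = 0.99) {
  stopifnot(is.matrix(diss_tom), nrow(diss_tom) == ncol(diss_tom))
  tree <- stats::hclust(stats::as.dist(diss_tom), method = "average")
  h <- cut_height * max(tree$height)
  raw <- stats::cutree(tree, h = h)
  sizes <- table(raw)
  big <- names(sizes)[sizes >= min_module_size]
  lab <- rep("grey", length(raw))
  if (length(big)) {
    ord <- big[order(-sizes[big], as.integer(big))]
    for (i in seq_along(ord)) lab[raw == as.integer(ord[i])] <- paste0("M", i)
  }
  names(lab) <- rownames(diss_tom) %||% as.character(seq_len(nrow(diss_tom)))
  attr(lab, "tree") <- tree
  lab
}

#' Module eigengene
#'
#' First right singular vector of the gene-standardized module submatrix:
#' the sample profile capturing the largest share of the module's expression
#' variance. The sign is oriented so the eigengene correlates positively
#' with the module's mean standardized expression.
#'
#' @param expr genes x samples matrix.
#' @param genes character vector of module member gene ids.
#' @return unit-norm numeric vector over samples with attributes
#'   \code{var_explained} and \code{kME} (per-member Pearson correlation
#'   with the eigengene).
#' @export
module_eigengene <- function(expr, genes) {
  stopifnot(length(genes) >= 1, all(genes %in% rownames(expr)))
  sub <- expr[genes, , drop = FALSE]
  z <- t(scale(t(sub)))
  z[!is.finite(z)] <- 0
  if (length(genes) == 1L) {
    v <- z[1, ]
    v <- v / sqrt(sum(v^2))
    attr(v, "var_explained") <- 1
    attr(v, "kME") <- stats::setNames(1, genes)
    return(v)
  }
  sv <- svd(z, nu = 1, nv = 1)
  v <- sv$v[, 1]
  if (stats::cor(v, colMeans(z)) < 0) v <- -v
  names(v) <- colnames(expr)
  attr(v, "var_explained") <- sv$d[1]^2 / sum(sv$d^2)
  attr(v, "kME") <- apply(sub, 1, stats::cor, y = v)
  v
}

#' Merge modules with correlated eigengenes
#'
#' Clusters module eigengenes with average linkage on 1 - cor, merges
#' clusters joined below \code{merge_height}, recomputes eigengenes and
#' iterates to a fixed point.
#'
#' @param expr genes x samples matrix.
#' @param assignment gene -> module label vector ("grey" kept aside).
#' @param merge_height eigengene dissimilarity below which modules merge
#'   (e.g. 0.10 merges modules with eigengene correlation > 0.90).
#' @param max_iter safety cap on merge iterations.
#' @return updated assignment vector with eigengene matrix (samples x
#'   modules) in attribute \code{eigengenes}.
#' @export
merge_modules <- function(expr, assignment, merge_height, max_iter = 10) {
  stopifnot(merge_height >= 0, merge_height <= 1)
  lab <- assignment
  for (it in seq_len(max_iter)) {
    mods <- setdiff(unique(lab), "grey")
    if (length(mods) <= 1L) break
    me <- vapply(mods, function(m)
      as.numeric(module_eigengene(expr, names(lab)[lab == m])),
      numeric(ncol(expr)))
    d <- 1 - stats::cor(me)
    tree <- stats::hclust(stats::as.dist(d), method = "average")
    grps <- stats::cutree(tree, h = merge_height)
    if (max(grps) == length(mods)) break   # nothing merged: fixed point
    for (gidx in unique(grps)) {
      members <- mods[grps == gidx]
      if (length(members) > 1L) lab[lab %in% members] <- members[1]
    }
  }
  mods <- setdiff(unique(lab), "grey")
  # relabel by size for a stable output convention
  sizes <- table(lab[lab != "grey"])
  ord <- names(sizes)[order(-sizes, names(sizes))]
  new <- lab
  for (i in seq_along(ord)) new[lab == ord[i]] <- paste0("M", i)
  me <- vapply(paste0("M", seq_along(ord)), function(m)
    as.numeric(module_eigengene(expr, names(new)[new == m])),
    numeric(ncol(expr)))
  rownames(me) <- colnames(expr)
  attr(new, "eigengenes") <- me
  new
}

#' Pairwise Pearson correlations with Bonferroni control
#'
#' Correlates every column of X with every column of Y (samples in rows),
#' tests each with the t transform \code{t = R sqrt((n-2)/(1-R^2))}, and
#' flags pairs significant after Bonferroni correction over the family of
#' all tested pairs. Zero-variance profiles are excluded and flagged.
#'
#' @param X,Y numeric matrices, samples x profiles, same row count.
#'   If \code{Y} is NULL, all within-X pairs (i < j) are tested.
#' @param alpha family-wise error rate, default 0.05.
#' @return data.frame \code{x}, \code{y}, \code{r}, \code{p},
#'   \code{significant}; attribute \code{excluded} lists zero-variance
#'   profiles.
#' @export
correlate_bonferroni <- function(X, Y = NULL, alpha = 0.05) {
  X <- as.matrix(X)
  self <- is.null(Y)
  Y <- if (self) X else as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  n <- nrow(X)
  sdx <- apply(X, 2, stats::sd); sdy <- apply(Y, 2, stats::sd)
  excluded <- c(colnames(X)[sdx == 0], if (!self) colnames(Y)[sdy == 0])
  Xk <- X[, sdx > 0, drop = FALSE]; Yk <- Y[, sdy > 0, drop = FALSE]
  R <- stats::cor(Xk, Yk)
  idx <- if (self) which(upper.tri(R), arr.ind = TRUE)
         else as.matrix(expand.grid(row = seq_len(ncol(Xk)),
                                    col = seq_len(ncol(Yk))))
  r <- R[idx]
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(r) >= 1] <- 0
  m <- length(r)
  out <- data.frame(
    x = (colnames(Xk) %||% as.character(seq_len(ncol(Xk))))[idx[, 1]],
    y = (colnames(Yk) %||% as.character(seq_len(ncol(Yk))))[idx[, 2]],
    r = r, p = p, significant = p < alpha / m,
    stringsAsFactors = FALSE)
  attr(out, "excluded") <- unique(excluded)
  attr(out, "n_tests") <- m
  out
}
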