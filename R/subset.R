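# Exhaustive best-subset selection of candidate genes explaining NAFLD
# trait variance, BIC model choice, and a permutation null drawn from the
# expressed-gene universe.

rss_of <- function(y, X) {
  fit <- stats::lm.fit(cbind(1, X), y)
  sum(fit$residuals^2)
}

#' Exhaustive best-subset regression with BIC choice
#'
#' Enumerates every subset of the candidate pool up to \code{max_size},
#' finds the RSS-minimizing subset of each size, and picks the overall
#' winner by BIC = n log(RSS/n) + (k+1) log(n) (intercept counted in the
#' parameter count). Ties are broken lexicographically by gene id.
#'
#' @param y numeric response (trait grade treated as numeric).
#' @param X numeric matrix, samples x candidate genes (at most 20
#'   candidates; exhaustive enumeration is 2^p).
#' @param max_size largest subset size searched; default \code{ncol(X)}.
#' @return object of class \code{subset_result}: list with \code{chosen}
#'   (gene ids), \code{r2}, \code{by_size} (data.frame \code{size},
#'   \code{genes}, \code{rss}, \code{bic}), \code{bic}, \code{n}.
#' @export
best_subset_search <- function(y, X, max_size = ncol(X)) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), ncol(X) <= 20)
  genes <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  colnames(X) <- genes
  n <- length(y)
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    warning("collinear candidates; least-squares fits may be degenerate")
  tss <- sum((y - mean(y))^2)
  rows <- list(data.frame(size = 0L, genes = "", rss = tss,
                          bic = n * log(tss / n) + 1 * log(n),
                          stringsAsFactors = FALSE))
  for (k in seq_len(min(max_size, ncol(X)))) {
    combos <- utils::combn(genes, k, simplify = FALSE)
    # lexicographic order of combos is combn's order for sorted gene names;
    # scanning sorted candidates with strict improvement keeps the first
    # (lexicographically smallest) subset on ties
    combos <- combos[order(vapply(combos, paste, "", collapse = "\r"))]
    best_rss <- Inf; best_set <- NULL
    for (cs in combos) {
      r <- rss_of(y, X[, cs, drop = FALSE])
      if (r < best_rss - 1e-12) { best_rss <- r; best_set <- cs }
    }
    rows[[k + 1L]] <- data.frame(
      size = k, genes = paste(best_set, collapse = ","), rss = best_rss,
      bic = n * log(best_rss / n) + (k + 1) * log(n),
      stringsAsFactors = FALSE)
  }
  by_size <- do.call(rbind, rows)
  win <- which.min(by_size$bic)
  chosen <- if (by_size$size[win] == 0L) character(0)
            else strsplit(by_size$genes[win], ",")[[1]]
  r2 <- 1 - by_size$rss[win] / tss
  structure(list(chosen = chosen, r2 = r2, by_size = by_size,
                 bic = by_size$bic[win], n = n),
            class = "subset_result")
}

#' Variance explained by a gene subset after covariate adjustment
#'
#' Coefficient of determination of the OLS fit of the response on the
#' subset after both response and predictors are residualized against the
#' covariates (so the r^2 quantifies variance explained beyond them).
#'
#' @param y numeric response.
#' @param X samples x genes matrix for the subset.
#' @param covariates optional samples x covariates matrix.
#' @return r^2 in [0, 1].
#' @export
r2_explained <- function(y, X, covariates = NULL) {
  X <- as.matrix(X)
  if (nrow(X) <= ncol(X)) stop("need more samples than predictors")
  if (!is.null(covariates)) {
    C <- cbind(1, as.matrix(covariates))
    qc <- qr(C)
    y <- qr.resid(qc, y)
    X <- qr.resid(qc, X)
  }
  fit <- stats::lm.fit(cbind(1, X), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Permutation p-value for a best-subset model
#'
#' Draws B random gene sets of the model's size from the expressed-gene
#' universe, fits each by OLS on the identical (residualized) design, and
#' reports the proportion of random models whose r^2 strictly exceeds the
#' observed one. The add-one-smoothed estimate (B+1 denominator) and the
#' non-strict (>=) version are reported alongside.
#'
#' @param r2_obs observed r^2 of the chosen model.
#' @param y numeric response.
#' @param universe samples x genes matrix of all expressed genes eligible
#'   for random draws.
#' @param m subset size (number of genes per random draw).
#' @param B number of permutations (default 10000; 100000 reproduces the
#'   original analysis scale).
#' @param covariates optional covariate matrix residualized out of both
#'   sides, exactly as for the observed model.
#' @param seed integer seed, recorded in the result.
#' @return list with \code{p} (strict >), \code{p_geq}, \code{p_smoothed},
#'   \code{B}, \code{m}, \code{seed}, \code{r2_obs}.
#' @export
permutation_pvalue <- function(r2_obs, y, universe, m, B = 10000,
                               covariates = NULL, seed = 1) {
  universe <- as.matrix(universe)
  stopifnot(ncol(universe) >= m, m >= 1)
  if (B < 100) warning("B < 100 gives a very coarse p-value resolution")
  if (!is.null(covariates)) {
    C <- cbind(1, as.matrix(covariates))
    qc <- qr(C)
    y <- qr.resid(qc, y)
    universe <- qr.resid(qc, universe)
  }
  yc <- y - mean(y)
  tss <- sum(yc^2)
  set.seed(seed)
  r2_perm <- numeric(B)
  for (b in seq_len(B)) {
    cols <- sample.int(ncol(universe), m)
    fit <- stats::lm.fit(cbind(1, universe[, cols, drop = FALSE]), y)
    r2_perm[b] <- 1 - sum(fit$residuals^2) / tss
  }
  list(p = mean(r2_perm > r2_obs),
       p_geq = mean(r2_perm >= r2_obs),
       p_smoothed = (sum(r2_perm > r2_obs) + 1) / (B + 1),
       B = B, m = m, seed = seed, r2_obs = r2_obs)
}
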