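# Added-value regression comparison: does a gene's adipose expression
# improve the explanation of NAFLD status over serum triglycerides alone?

#' Logistic regression fit
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares (the \code{stats::glm} binomial fitter), returning coefficients
#' and the maximized log-likelihood. Separable data are caught by the
#' fitter's convergence guards and reported with a warning but finite
#' output.
#'
#' @param y binary response in {0, 1}.
#' @param design model matrix including the intercept column.
#' @return list with \code{coef}, \code{loglik}, \code{fitted},
#'   \code{converged}, \code{n}.
#' @export
logistic_fit <- function(y, design) {
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  design <- as.matrix(design)
  if (qr(design)$rank < ncol(design)) stop("design is rank deficient")
  fit <- withCallingHandlers(
    stats::glm.fit(design, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-10,
                                                maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warning("separable data: coefficient estimates are unstable",
                call. = FALSE)
      invokeRestart("muffleWarning")
    })
  mu <- fit$fitted.values
  ll <- sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
  list(coef = fit$coefficients, loglik = ll, fitted = mu,
       converged = fit$converged, n = length(y))
}

#' Nagelkerke pseudo-r-squared
#'
#' \code{R2 = (1 - (L0/L1)^(2/n)) / (1 - L0^(2/n))} with L0, L1 the null
#' and fitted model likelihoods (not logs). Rescales the Cox-Snell R2 to
#' a [0, 1] range.
#'
#' @param loglik0,loglik1 log-likelihoods of the null and fitted models
#'   (loglik1 >= loglik0 for nested fits).
#' @param n sample size.
#' @return pseudo-r-squared in [0, 1].
#' @export
nagelkerke_r2 <- function(loglik0, loglik1, n) {
  if (loglik1 < loglik0 - 1e-8)
    stop("fitted model has lower likelihood than the null (not nested?)")
  cox_snell <- 1 - exp(2 / n * (loglik0 - loglik1))
  max_r2 <- 1 - exp(2 / n * loglik0)
  if (max_r2 <= 0) return(0)
  cox_snell / max_r2
}

#' Area under the ROC curve by the rank (Mann-Whitney) formula
#'
#' \code{AUC = U / (n1 n0)} where U counts case-control score pairs with
#' the case scored higher, ties counted one half.
#'
#' @param scores numeric predictions.
#' @param y binary labels in {0, 1}; both classes must be present.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, y) {
  stopifnot(length(scores) == length(y), all(y %in% c(0, 1)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Compare base and gene-augmented models for a NAFLD trait
#'
#' Fits the base model (log10 serum TG + covariates) and the augmented
#' model (base + INT-transformed gene expression in CPM) to the binary
#' trait status, both as logistic and as linear regressions, and reports
#' Nagelkerke pseudo-r2, AUC, and linear (adjusted) r2 for each.
#'
#' @param status binary trait status vector (e.g. nonzero grade).
#' @param serum_tg raw serum TG measurements (log10-transformed
#'   internally).
#' @param gene_cpm the candidate gene's expression in CPM
#'   (inverse-normal-transformed internally).
#' @param covariates optional samples x covariates matrix.
#' @return object of class \code{model_comparison}: list with \code{base}
#'   and \code{augmented} (each: \code{pseudo_r2}, \code{auc},
#'   \code{r2_linear}, \code{adj_r2_linear}, \code{loglik}), and
#'   \code{delta} (augmented minus base for each metric).
#' @export
compare_models <- function(status, serum_tg, gene_cpm, covariates = NULL) {
  stopifnot(all(status %in% c(0, 1)), all(serum_tg > 0))
  tg <- log10(serum_tg)
  ge <- inverse_normal_transform(gene_cpm)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  X0 <- cbind(`(Intercept)` = 1, tg = tg, C)
  X1 <- cbind(X0, gene = ge)
  Xnull <- X0[, 1, drop = FALSE]

  f_null <- logistic_fit(status, Xnull)
  one <- function(X) {
    fl <- logistic_fit(status, X)
    lin <- stats::lm.fit(X, status)
    n <- length(status); p <- ncol(X) - 1
    r2 <- 1 - sum(lin$residuals^2) / sum((status - mean(status))^2)
    list(pseudo_r2 = nagelkerke_r2(f_null$loglik, fl$loglik, n),
         auc = roc_auc(fl$fitted, status),
         r2_linear = r2,
         adj_r2_linear = 1 - (1 - r2) * (n - 1) / (n - p - 1),
         loglik = fl$loglik)
  }
  base <- one(X0)
  aug <- one(X1)
  structure(list(base = base, augmented = aug,
                 delta = list(pseudo_r2 = aug$pseudo_r2 - base$pseudo_r2,
                              auc = aug$auc - base$auc,
                              r2_linear = aug$r2_linear - base$r2_linear)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("base:      pseudo-r2 %.3f  AUC %.3f  linear r2 %.3f\n",
              x$base$pseudo_r2, x$base$auc, x$base$r2_linear))
  cat(sprintf("augmented: pseudo-r2 %.3f  AUC %.3f  linear r2 %.3f\n",
              x$augmented$pseudo_r2, x$augmented$auc, x$augmented$r2_linear))
  cat(sprintf("delta:     pseudo-r2 %+.3f  AUC %+.3f\n",
              x$delta$pseudo_r2, x$delta$auc))
  invisible(x)
}
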