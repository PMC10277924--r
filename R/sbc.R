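# Serum-biomarker-candidate (SBC) filter cascade and SBC correlation
# structure. An SBC is an adipose "aware" DE gene that encodes a secreted
# protein, is well expressed in adipose tissue, and is strongly
# adipose-enriched relative to liver.

#' Apply the SBC filter cascade
#'
#' Sequential filters over the adipose aware-DE gene list:
#' (1) the aware-DE input; (2) secreted-protein flag; (3) adipose median
#' TPM strictly greater than \code{tpm_min}; (4) adipose/liver median TPM
#' ratio strictly greater than \code{ratio_min}. A liver median TPM of 0
#' with positive adipose TPM passes the ratio filter (infinite ratio) and
#' is logged. Genes missing from the annotation fail conservatively and
#' land in a distinct audit bucket.
#'
#' @param aware_de character vector of aware-DE gene ids.
#' @param annotation data.frame with columns \code{gene}, \code{secreted}
#'   (logical), \code{adipose_tpm}, \code{liver_tpm}.
#' @param tpm_min adipose median TPM threshold, default 30 (strict ">").
#' @param ratio_min adipose/liver TPM ratio threshold, default 10
#'   (strict ">").
#' @return object of class \code{filter_audit}: list with \code{audit}
#'   (data.frame \code{filter}, \code{n_in}, \code{n_out},
#'   \code{removed}), \code{sbc} (final gene list),
#'   \code{missing_annotation}, \code{zero_liver_tpm}.
#' @export
apply_sbc_filters <- function(aware_de, annotation, tpm_min = 30,
                              ratio_min = 10) {
  stopifnot(all(c("gene", "secreted", "adipose_tpm", "liver_tpm") %in%
                  names(annotation)))
  aware_de <- unique(aware_de)
  missing <- setdiff(aware_de, annotation$gene)
  if (length(missing))
    message(length(missing), " aware-DE genes missing annotation; treated as failing")
  ann <- annotation[match(aware_de, annotation$gene), , drop = FALSE]

  steps <- list(
    secreted = function(g) {
      ok <- !is.na(ann$secreted) & ann$secreted
      g[g %in% aware_de[ok]]
    },
    adipose_tpm = function(g) {
      ok <- !is.na(ann$adipose_tpm) & ann$adipose_tpm > tpm_min
      g[g %in% aware_de[ok]]
    },
    tpm_ratio = function(g) {
      ratio <- ifelse(ann$liver_tpm == 0,
                      ifelse(ann$adipose_tpm > 0, Inf, NA_real_),
                      ann$adipose_tpm / ann$liver_tpm)
      ok <- !is.na(ratio) & ratio > ratio_min
      g[g %in% aware_de[ok]]
    })

  current <- setdiff(aware_de, missing)
  audit <- data.frame(filter = "aware_de_input",
                      n_in = length(aware_de),
                      n_out = length(current),
                      removed = I(list(missing)),
                      stringsAsFactors = FALSE)
  for (nm in names(steps)) {
    nxt <- steps[[nm]](current)
    audit <- rbind(audit, data.frame(
      filter = nm, n_in = length(current), n_out = length(nxt),
      removed = I(list(setdiff(current, nxt))), stringsAsFactors = FALSE))
    current <- nxt
  }
  zero_liver <- current[ann$liver_tpm[match(current, aware_de)] == 0]
  if (length(zero_liver))
    message(length(zero_liver),
            " retained genes have liver TPM 0 (ratio treated as infinite)")
  structure(list(audit = audit, sbc = current,
                 missing_annotation = missing,
                 zero_liver_tpm = zero_liver),
            class = "filter_audit")
}

#' @export
print.filter_audit <- function(x, ...) {
  cat("SBC filter cascade\n")
  for (i in seq_len(nrow(x$audit)))
    cat(sprintf("  %-16s %4d -> %4d\n", x$audit$filter[i],
                x$audit$n_in[i], x$audit$n_out[i]))
  cat("final SBCs:", if (length(x$sbc)) paste(x$sbc, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Pairwise SBC correlation structure
#'
#' All pairwise Pearson correlations between SBC gene expression profiles
#' with Bonferroni flags, gene order given by rank on the first principal
#' component of the SBC expression matrix, and correlation blocks defined
#' as connected components of the significant-positive-correlation graph.
#'
#' @param expr numeric matrix, SBC genes x samples (log-CPM), >= 2 genes.
#' @param alpha family-wise error rate for the Bonferroni flags.
#' @return list with \code{correlations} (the pair table),
#'   \code{gene_order} (PC1-rank order), \code{blocks} (list of gene-id
#'   vectors, singletons included).
#' @export
sbc_correlation_blocks <- function(expr, alpha = 0.05) {
  stopifnot(is.matrix(expr), nrow(expr) >= 2)
  genes <- rownames(expr) %||% as.character(seq_len(nrow(expr)))
  rownames(expr) <- genes
  tab <- correlate_bonferroni(t(expr), alpha = alpha)
  z <- t(scale(t(expr)))
  z[!is.finite(z)] <- 0
  sv <- svd(z, nu = 1, nv = 1)
  load1 <- sv$u[, 1]
  if (load1[which.max(abs(load1))] < 0) load1 <- -load1
  gene_order <- genes[order(load1, decreasing = TRUE)]
  # connected components of the significant positive-correlation graph
  edges <- tab[tab$significant & tab$r > 0, c("x", "y")]
  gi <- stats::setNames(seq_along(genes), genes)
  parent <- seq_along(genes)
  findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(edges)) for (e in seq_len(nrow(edges))) {
    a <- findp(gi[[edges$x[e]]]); b <- findp(gi[[edges$y[e]]])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_along(genes), findp, integer(1))
  blocks <- split(genes, roots)
  blocks <- blocks[order(-lengths(blocks))]
  names(blocks) <- NULL
  list(correlations = tab, gene_order = gene_order, blocks = blocks)
}
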