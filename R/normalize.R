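#' Log2 counts-per-million with a prior count
#'
#' Computes `log2((count + prior) / (library_size + 2 * prior) * 1e6)`.
#' By default the library size is the column sum of the count matrix; an
#' explicit `lib_size` (for example a TMM effective library size, as used
#' by [run_de()]) overrides it. The prior count keeps zeros finite and
#' shrinks log fold changes of lowly expressed genes. Libraries with zero
#' total counts are dropped with a warning.
#'
#' @param gene_counts Genes x libraries count matrix.
#' @param prior_count Prior count added to every observation (default 0.5).
#' @param lib_size Optional per-library sizes (defaults to column sums).
#' @return Real matrix of log2-CPM values, genes x libraries.
#' @export
normalize_logcpm <- function(gene_counts, prior_count = 0.5,
                             lib_size = NULL) {
  counts <- as.matrix(gene_counts)
  if (is.null(lib_size)) lib_size <- colSums(counts)
  if (length(lib_size) != ncol(counts))
    stop("'lib_size' must have one entry per library")
  if (any(lib_size == 0)) {
    warning("dropping ", sum(lib_size == 0), " librar(y/ies) with zero counts")
    counts <- counts[, lib_size > 0, drop = FALSE]
    lib_size <- lib_size[lib_size > 0]
  }
  log2(sweep(counts + prior_count, 2, lib_size + 2 * prior_count, "/") * 1e6)
}

#' Filter genes by minimum expression
#'
#' Keeps genes whose CPM exceeds `min_cpm` in at least a fraction
#' `min_fraction` of libraries; the customary guard against fitting models
#' to genes with essentially no counts.
#'
#' @param gene_counts Genes x libraries count matrix.
#' @param min_cpm CPM threshold (default 1).
#' @param min_fraction Minimum fraction of libraries above threshold
#'   (default 0.05).
#' @return Character vector of retained gene ids (row names).
#' @export
filter_genes <- function(gene_counts, min_cpm = 1, min_fraction = 0.05) {
  counts <- as.matrix(gene_counts)
  lib_size <- colSums(counts)
  lib_size[lib_size == 0] <- NA_real_
  cpm <- sweep(counts, 2, lib_size, "/") * 1e6
  keep <- rowMeans(cpm > min_cpm, na.rm = TRUE) >= min_fraction
  rownames(counts)[keep]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjustment: with `m` p-values sorted increasingly,
#' the adjusted value of the `i`-th is `min_k>=i (m / k) * p_(k)`, capped at
#' 1; ranks are preserved and the output is returned in the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (no `NA`s).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03))
adjust_bh <- function(p) {
  if (!is.numeric(p)) stop("'p' must be numeric")
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  pmin(1, cummin(m / (m:1) * p[o]))[order(o)]
}

#' Classify genes by effect size and adjusted significance
#'
#' Applies the screening cutoffs: a gene is `up` when `logFC > lfc_cut` and
#' `p_adj < alpha`, `down` when `logFC < -lfc_cut` and `p_adj < alpha`,
#' and `ns` otherwise.
#'
#' @param results data.frame with columns `logFC` and `p_adj` (e.g. from
#'   [run_de()]).
#' @param lfc_cut Absolute log2 fold-change cutoff (default 0.5).
#' @param alpha Adjusted p-value threshold (default 0.001).
#' @return `results` with a `de_class` factor column
#'   (`up`/`down`/`ns`) appended or replaced.
#' @export
classify_de <- function(results, lfc_cut = 0.5, alpha = 0.001) {
  if (!all(c("logFC", "p_adj") %in% names(results)))
    stop("'results' must carry 'logFC' and 'p_adj' columns")
  cls <- rep("ns", nrow(results))
  cls[results$logFC > lfc_cut & results$p_adj < alpha] <- "up"
  cls[results$logFC < -lfc_cut & results$p_adj < alpha] <- "down"
  results$de_class <- factor(cls, levels = c("up", "down", "ns"))
  results
}
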