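#' Assemble an effect matrix from per-virus DE results
#'
#' Aligns the log2 fold-change vectors of one coefficient per virus on the
#' intersection-by-pair of tested genes (genes are matched by id; pairs are
#' correlated on their shared genes).
#'
#' @param results_list Named list of [run_de()] result data.frames (names
#'   are virus labels).
#' @param coefficient Which coefficient to extract (default `"virus"`;
#'   `"sexmale:virus"` gives the interaction effects).
#' @return Numeric matrix genes x viruses (union of gene ids, `NA` where a
#'   gene was not tested for a virus).
#' @export
effect_matrix <- function(results_list, coefficient = "virus") {
  if (is.null(names(results_list)) || any(!nzchar(names(results_list))))
    stop("'results_list' must be a named list (names = virus labels)")
  cols <- lapply(results_list, function(r) {
    r <- r[r$coefficient == coefficient, , drop = FALSE]
    stats::setNames(r$logFC, r$gene_id)
  })
  genes <- sort(unique(unlist(lapply(cols, names))))
  em <- matrix(NA_real_, length(genes), length(cols),
               dimnames = list(genes, names(results_list)))
  for (v in names(cols)) em[names(cols[[v]]), v] <- cols[[v]]
  em
}

#' Correlate estimated expression changes across viruses
#'
#' Pairwise correlation of log2 fold-change columns on the genes shared by
#' each pair, with the p-value from the t-transform of `r` on `n - 2`
#' degrees of freedom. Entries whose p-value fails `alpha` are masked
#' (`NA`) in the returned `masked` matrix, mirroring the convention of
#' reporting only significant correlations. Pearson is the default;
#' Spearman (rank) correlation is available since screening reports vary
#' in which they quote.
#'
#' @param em Effect matrix (genes x columns), e.g. from [effect_matrix()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param alpha Significance threshold for the mask (default 0.001).
#' @param min_genes Minimum shared genes per pair (default 3); pairs below
#'   it are reported as `NA` with `n` recorded.
#' @return List of class `effect_correlation`: `r` (correlation matrix,
#'   unit diagonal), `p`, `n` (shared genes per pair), `masked` (`r` with
#'   non-significant entries `NA`), `method`, `alpha`, and `pairs` (long
#'   data.frame: `a`, `b`, `r`, `n`, `p`, `significant`).
#' @export
correlate_effects <- function(em, method = c("pearson", "spearman"),
                              alpha = 0.001, min_genes = 3) {
  method <- match.arg(method)
  em <- as.matrix(em)
  k <- ncol(em)
  if (k < 2) stop("need at least two effect columns")
  labs <- colnames(em)
  r <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  p <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  nmat <- matrix(0L, k, k, dimnames = list(labs, labs))
  diag(r) <- 1; diag(p) <- 0
  pairs <- list()
  for (i in seq_len(k)) for (j in seq_len(i - 1L)) {
    ok <- stats::complete.cases(em[, c(i, j)])
    n <- sum(ok)
    nmat[i, j] <- nmat[j, i] <- n
    rij <- pij <- NA_real_
    if (n >= min_genes) {
      x <- em[ok, i]; y <- em[ok, j]
      if (method == "spearman") { x <- rank(x); y <- rank(y) }
      if (stats::sd(x) > 0 && stats::sd(y) > 0) {
        rij <- stats::cor(x, y)
        tt <- rij * sqrt((n - 2) / max(1 - rij^2, .Machine$double.eps))
        pij <- 2 * stats::pt(-abs(tt), n - 2)
      }
    }
    r[i, j] <- r[j, i] <- rij
    p[i, j] <- p[j, i] <- pij
    pairs[[length(pairs) + 1L]] <- data.frame(
      a = labs[j], b = labs[i], r = rij, n = n, p = pij,
      significant = !is.na(pij) && pij < alpha, stringsAsFactors = FALSE)
  }
  masked <- r
  masked[!is.na(p) & p >= alpha] <- NA_real_
  structure(list(r = r, p = p, n = nmat, masked = masked, method = method,
                 alpha = alpha, pairs = do.call(rbind, pairs)),
            class = "effect_correlation")
}

#' @export
print.effect_correlation <- function(x, ...) {
  cat(sprintf("effect_correlation (%s, alpha %g):\n", x$method, x$alpha))
  print(round(x$r, 3))
  invisible(x)
}

#' Volcano-plot table from DE results
#'
#' One row per gene per coefficient with the quantities a volcano plot
#' needs: `logFC`, `-log10(p_adj)` (capped for adjusted p-values of zero)
#' and the up/down/ns class.
#'
#' @param results A [run_de()] result data.frame.
#' @param cap Maximum `-log10(p_adj)` reported (default 300).
#' @return data.frame: `gene_id`, `coefficient`, `logFC`, `neg_log10_padj`,
#'   `de_class`.
#' @export
volcano_table <- function(results, cap = 300) {
  if (nrow(results) == 0)
    return(data.frame(gene_id = character(0), coefficient = character(0),
                      logFC = numeric(0), neg_log10_padj = numeric(0),
                      de_class = factor(character(0),
                                        levels = c("up", "down", "ns"))))
  if (!all(c("gene_id", "coefficient", "logFC", "p_adj", "de_class") %in%
           names(results)))
    stop("'results' must be a run_de() result table")
  data.frame(gene_id = results$gene_id, coefficient = results$coefficient,
             logFC = results$logFC,
             neg_log10_padj = pmin(-log10(results$p_adj), cap),
             de_class = results$de_class, stringsAsFactors = FALSE)
}
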