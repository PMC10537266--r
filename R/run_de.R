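#' Per-virus differential expression across all genes
#'
#' Runs the whole per-virus analysis: restricts libraries and builds the
#' design with [build_design()], filters lowly expressed genes
#' ([filter_genes()]), computes log2-CPM ([normalize_logcpm()]), fits every
#' gene's mixed (or OLS) model ([fit_gene_model()]), optionally moderates
#' the residual variances across genes ([moderate_variances()]), adjusts
#' p-values within each coefficient by Benjamini-Hochberg ([adjust_bh()])
#' and classifies genes by the effect-size/significance cutoffs
#' ([classify_de()]).
#'
#' Library sizes are TMM-normalised by default (`norm = "tmm"`, via
#' \pkg{edgeR}'s trimmed mean of M-values): when expression changes are not
#' balanced between up- and down-regulation, plain CPM shifts every
#' unchanged gene in the opposite direction (composition bias), which
#' biases null genes away from zero; effective library sizes remove this.
#'
#' With moderation, each coefficient's standard error is rescaled by the
#' square root of the posterior-to-raw variance ratio and the prior
#' degrees of freedom are added to the per-coefficient df before the
#' t-tail is taken.
#'
#' @param gene_counts Genes x libraries count matrix.
#' @param meta Metadata data.frame (see [build_design()]).
#' @param calls An `infection_calls` object or logical matrix.
#' @param virus Virus label to analyse.
#' @param moderation Apply empirical-Bayes variance moderation
#'   (default `TRUE`).
#' @param lfc_cut,alpha Classification cutoffs (defaults 0.5 and 0.001).
#' @param min_cpm,min_fraction Expression-filter settings
#'   (see [filter_genes()]).
#' @param prior_count Prior count for log-CPM.
#' @param norm `"tmm"` (default; effective library sizes) or `"none"`
#'   (raw column totals).
#' @return data.frame with one row per gene and non-intercept coefficient:
#'   `gene_id`, `coefficient`, `logFC`, `se`, `stat`, `df`, `p`, `p_adj`,
#'   `de_class`; attributes `design` (the `de_design`), `summary`
#'   (up/down/ns counts per coefficient), `skipped` (genes not fitted,
#'   with reasons) and `moderation` (prior df and scale, if applied).
#' @export
run_de <- function(gene_counts, meta, calls, virus, moderation = TRUE,
                   lfc_cut = 0.5, alpha = 0.001, min_cpm = 1,
                   min_fraction = 0.05, prior_count = 0.5,
                   norm = c("tmm", "none")) {
  norm <- match.arg(norm)
  design <- build_design(meta, calls, virus)
  counts <- as.matrix(gene_counts)[, design$libraries, drop = FALSE]
  keep <- filter_genes(counts, min_cpm = min_cpm,
                       min_fraction = min_fraction)
  if (length(keep) == 0) stop("no genes pass the expression filter")
  lib_size <- colSums(counts)
  if (norm == "tmm")
    lib_size <- lib_size *
      edgeR::calcNormFactors(counts[keep, , drop = FALSE],
                             lib.size = lib_size)
  expr <- normalize_logcpm(counts[keep, , drop = FALSE],
                           prior_count = prior_count, lib_size = lib_size)

  prep <- .prep_mixed(design$X, design$group)
  # rotate all genes at once; rows = libraries (rotated), cols = genes
  Yt <- if (prep$mixed) crossprod(prep$Q, t(expr)) else t(expr)

  fits <- vector("list", length(keep))
  skipped <- character(0)
  for (g in seq_along(keep)) {
    f <- tryCatch(.fit_gene_prepared(Yt[, g], prep), error = function(e) e)
    if (inherits(f, "error")) {
      skipped <- c(skipped, stats::setNames(conditionMessage(f), keep[g]))
      next
    }
    fits[[g]] <- f
  }
  fitted <- !vapply(fits, is.null, logical(1))
  if (!any(fitted)) stop("no gene could be fitted: ", skipped[1])
  genes <- keep[fitted]
  fits <- fits[fitted]

  sigma2 <- vapply(fits, attr, numeric(1), "sigma2")
  df_res <- vapply(fits, attr, numeric(1), "df_residual")
  mod <- NULL
  if (moderation && length(genes) >= 10) {
    mod <- tryCatch(moderate_variances(sigma2, df_res),
                    warning = function(w) { warning(w); NULL },
                    error = function(e) NULL)
  }

  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    f <- f[f$coefficient != "(Intercept)", , drop = FALSE]
    if (!is.null(mod)) {
      scale <- sqrt(mod$var_post[i] / sigma2[i])
      f$se <- f$se * scale
      f$stat <- f$logFC / f$se
      f$df <- f$df + min(mod$df_prior, 1e6)
      f$p <- 2 * stats::pt(-abs(f$stat), f$df)
    }
    cbind(gene_id = genes[i], f, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- NA_real_
  for (co in unique(res$coefficient)) {
    sel <- res$coefficient == co
    res$p_adj[sel] <- adjust_bh(res$p[sel])
  }
  res <- classify_de(res, lfc_cut = lfc_cut, alpha = alpha)
  rownames(res) <- NULL

  summ <- as.data.frame(table(coefficient = res$coefficient,
                              de_class = res$de_class))
  attr(res, "design") <- design
  attr(res, "summary") <- summ
  attr(res, "skipped") <- skipped
  if (!is.null(mod))
    attr(res, "moderation") <- list(df_prior = mod$df_prior,
                                    var_prior = mod$var_prior)
  res
}
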