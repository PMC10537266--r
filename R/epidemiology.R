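#' Per-project virus prevalence with exact binomial confidence intervals
#'
#' Prevalence is the fraction of a project's libraries called positive for
#' a virus. Intervals are Clopper-Pearson (exact beta-quantile) bounds,
#' which keep at least nominal coverage even for a single positive library.
#'
#' @param calls An `infection_calls` object from [call_infections()] (or a
#'   logical libraries x viruses matrix).
#' @param meta Metadata data.frame with `library_id` and `project`.
#' @param level Confidence level (default 0.95).
#' @param include_zero Keep (project, virus) rows with zero positives
#'   (default `FALSE`).
#' @return data.frame: `project`, `virus`, `k` (positives), `n`
#'   (libraries), `p_hat`, `ci_low`, `ci_high`, `level`.
#' @export
#' @examples
#' calls <- matrix(c(TRUE, TRUE, FALSE, FALSE), 4, 1,
#'                 dimnames = list(paste0("lib", 1:4), "DAV"))
#' meta <- data.frame(library_id = paste0("lib", 1:4), project = "P1")
#' estimate_prevalence(calls, meta)
estimate_prevalence <- function(calls, meta, level = 0.95,
                                include_zero = FALSE) {
  present <- if (inherits(calls, "infection_calls")) calls$present else
    as.matrix(calls)
  meta <- .align_meta(meta, rownames(present))
  a <- (1 - level) / 2
  out <- list()
  for (p in unique(meta$project)) {
    idx <- which(meta$project == p)
    n <- length(idx)
    if (n == 0) { warning("project ", p, " has no libraries; skipped"); next }
    for (v in colnames(present)) {
      k <- sum(present[idx, v])
      if (k == 0 && !include_zero) next
      ci_low <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
      ci_high <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
      out[[length(out) + 1L]] <- data.frame(
        project = p, virus = v, k = k, n = n, p_hat = k / n,
        ci_low = ci_low, ci_high = ci_high, level = level,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(project = character(0), virus = character(0),
                      k = integer(0), n = integer(0), p_hat = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      level = numeric(0)))
  do.call(rbind, out)
}

#' Cross-tabulate two viruses' presence calls within a project
#'
#' @param calls An `infection_calls` object or logical matrix.
#' @param meta Metadata with `library_id` and `project`.
#' @param virus_a,virus_b Virus labels (columns of the call matrix).
#' @param project Project whose libraries are tabulated.
#' @return List of class `coinfection_table`: `project`, `virus_a`,
#'   `virus_b`, `n11` (both), `n10` (A only), `n01` (B only), `n00`
#'   (neither).
#' @export
coinfection_table <- function(calls, meta, virus_a, virus_b, project) {
  present <- if (inherits(calls, "infection_calls")) calls$present else
    as.matrix(calls)
  for (v in c(virus_a, virus_b))
    if (!v %in% colnames(present))
      stop("virus '", v, "' is not a column of the call matrix")
  meta <- .align_meta(meta, rownames(present))
  idx <- which(meta$project == project)
  if (length(idx) == 0) stop("project '", project, "' has no libraries")
  a <- present[idx, virus_a]
  b <- present[idx, virus_b]
  structure(list(project = project, virus_a = virus_a, virus_b = virus_b,
                 n11 = sum(a & b), n10 = sum(a & !b),
                 n01 = sum(!a & b), n00 = sum(!a & !b)),
            class = "coinfection_table")
}

#' @export
print.coinfection_table <- function(x, ...) {
  cat(sprintf("coinfection_table (%s): %s x %s\n", x$project, x$virus_a,
              x$virus_b))
  cat(sprintf("  both %d | %s only %d | %s only %d | neither %d\n",
              x$n11, x$virus_a, x$n10, x$virus_b, x$n01, x$n00))
  invisible(x)
}

# log point probability of a 2x2 table with fixed margins, via log-gamma
.log_dhyper2x2 <- function(n11, r1, c1, n) {
  lchoose2 <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)
  lchoose2(c1, n11) + lchoose2(n - c1, r1 - n11) - lchoose2(n, r1)
}

#' Exact test of association on a 2x2 contingency table
#'
#' Computes the exact conditional (hypergeometric) test with both margins
#' fixed, from first principles via log-gamma factorials (stable to
#' n ~ thousands). The two-sided p-value follows the point-probability
#' ("minimum-likelihood") rule: the sum of the probabilities of all tables
#' with the same margins whose point probability does not exceed that of
#' the observed table (within a relative tolerance of 1e-7 for ties);
#' `two_sided = "doubling"` instead doubles the smaller tail (capped at 1).
#' The odds ratio reported is the sample odds ratio `n11*n00 / (n10*n01)`
#' (`Inf` when a denominator cell is zero and the numerator cells are
#' positive; `NaN` when both numerator and denominator vanish).
#'
#' @param table A [coinfection_table()] or a list/vector with elements
#'   `n11`, `n10`, `n01`, `n00`.
#' @param alternative `"two.sided"` (default), `"greater"` (positive
#'   association, large `n11`) or `"less"`.
#' @param two_sided Rule for the two-sided p-value: `"minlik"` (default) or
#'   `"doubling"`.
#' @return List of class `exact_test`: `p_value`, `odds_ratio`,
#'   `alternative`.
#' @export
#' @examples
#' fisher_exact(list(n11 = 4, n10 = 6, n01 = 27, n00 = 741))$p_value
fisher_exact <- function(table, alternative = c("two.sided", "greater",
                                                "less"),
                         two_sided = c("minlik", "doubling")) {
  alternative <- match.arg(alternative)
  two_sided <- match.arg(two_sided)
  cells <- c(table$n11, table$n10, table$n01, table$n00)
  if (length(cells) != 4 || anyNA(cells))
    stop("'table' must provide n11, n10, n01 and n00")
  if (any(cells < 0) || any(cells != round(cells)))
    stop("table cells must be non-negative integers")
  n11 <- cells[1]; n10 <- cells[2]; n01 <- cells[3]; n00 <- cells[4]
  r1 <- n11 + n10          # margin: virus A positives
  c1 <- n11 + n01          # margin: virus B positives
  n <- sum(cells)
  odds_ratio <- (n11 * n00) / (n10 * n01)

  if (n == 0 || r1 == 0 || c1 == 0 || r1 == n || c1 == n) {
    # degenerate margins: only one table is possible
    return(structure(list(p_value = 1, odds_ratio = odds_ratio,
                          alternative = alternative),
                     class = "exact_test"))
  }
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  logp <- .log_dhyper2x2(support, r1, c1, n)
  logp <- logp - max(logp)                # normalise for stability
  prob <- exp(logp); prob <- prob / sum(prob)
  obs <- which(support == n11)
  p_value <- switch(alternative,
    greater = sum(prob[support >= n11]),
    less = sum(prob[support <= n11]),
    two.sided = if (two_sided == "minlik") {
      sum(prob[prob <= prob[obs] * (1 + 1e-7)])
    } else {
      min(1, 2 * min(sum(prob[support >= n11]), sum(prob[support <= n11])))
    })
  p_value <- min(1, max(p_value, prob[obs]))   # p >= P(observed) > 0
  structure(list(p_value = p_value, odds_ratio = odds_ratio,
                 alternative = alternative),
            class = "exact_test")
}

#' @export
print.exact_test <- function(x, ...) {
  cat(sprintf("exact 2x2 test (%s): p = %.4g, sample odds ratio = %.4g\n",
              x$alternative, x$p_value, x$odds_ratio))
  invisible(x)
}

#' Scan all virus pairs in every project for co-infection association
#'
#' For each project with at least two called viruses, every unordered virus
#' pair is cross-tabulated and tested with [fisher_exact()]. Mirroring the
#' screening convention, results are flagged at the raw `alpha` threshold
#' with **no** multiple-testing correction; interpret flags accordingly.
#'
#' @param calls An `infection_calls` object or logical matrix.
#' @param meta Metadata with `library_id` and `project`.
#' @param alpha Significance threshold on the raw p-value (default 0.01).
#' @param min_positive Only viruses with at least this many positive
#'   libraries in the project are paired (default 1).
#' @return data.frame: `project`, `virus_a`, `virus_b`, `n11`, `n10`,
#'   `n01`, `n00`, `odds_ratio`, `p_value`, `significant`.
#' @export
coinfection_scan <- function(calls, meta, alpha = 0.01, min_positive = 1) {
  present <- if (inherits(calls, "infection_calls")) calls$present else
    as.matrix(calls)
  meta <- .align_meta(meta, rownames(present))
  out <- list()
  for (p in unique(meta$project)) {
    idx <- which(meta$project == p)
    pos <- colSums(present[idx, , drop = FALSE])
    vs <- names(pos)[pos >= min_positive]
    if (length(vs) < 2) next
    for (i in seq_along(vs)) for (j in seq_len(i - 1L)) {
      tb <- coinfection_table(present, meta, vs[j], vs[i], p)
      ft <- fisher_exact(tb)
      out[[length(out) + 1L]] <- data.frame(
        project = p, virus_a = vs[j], virus_b = vs[i],
        n11 = tb$n11, n10 = tb$n10, n01 = tb$n01, n00 = tb$n00,
        odds_ratio = ft$odds_ratio, p_value = ft$p_value,
        significant = ft$p_value < alpha, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(project = character(0), virus_a = character(0),
                      virus_b = character(0), n11 = integer(0),
                      n10 = integer(0), n01 = integer(0), n00 = integer(0),
                      odds_ratio = numeric(0), p_value = numeric(0),
                      significant = logical(0)))
  do.call(rbind, out)
}
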