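#' Call virus presence/absence from read counts
#'
#' A virus is called present in a library when its read count reaches both
#' thresholds: at least `rel_threshold` (default 1%) of the highest read
#' count observed for that virus, and at least `abs_threshold` reads
#' (default 150). The relative rule guards against index-hopped reads from
#' a heavily infected lane-mate; the absolute floor removes residual
#' low-level noise. By default the per-virus maximum is taken within each
#' project (`scope = "project"`); `scope = "pooled"` uses the global
#' maximum across all libraries. Raw read counts are used throughout (no
#' library-size normalisation).
#'
#' @param vc A [virus_count_matrix] (or a bare libraries x viruses count
#'   matrix).
#' @param meta Optional metadata data.frame with `library_id` and `project`;
#'   required for `scope = "project"` when `vc` covers several projects.
#'   If omitted, all libraries are treated as one project.
#' @param rel_threshold Fraction of the per-virus maximum (default 0.01).
#' @param abs_threshold Minimum read count (default 150).
#' @param scope `"project"` (per-virus maximum within each project) or
#'   `"pooled"` (global maximum).
#' @return An object of class `infection_calls`: list with `present`
#'   (logical libraries x viruses matrix), `rel_threshold`,
#'   `abs_threshold`, `per_virus_max` (projects x viruses matrix of the
#'   maxima used) and `scope`.
#' @export
#' @examples
#' counts <- cbind(DAV = c(10000, 150, 99), nora = c(0, 20000, 180))
#' rownames(counts) <- paste0("lib", 1:3)
#' call_infections(counts)$present
call_infections <- function(vc, meta = NULL, rel_threshold = 0.01,
                            abs_threshold = 150,
                            scope = c("project", "pooled")) {
  scope <- match.arg(scope)
  counts <- if (inherits(vc, "virus_count_matrix")) vc$counts else as.matrix(vc)
  if (rel_threshold < 0 || rel_threshold > 1)
    stop("'rel_threshold' must lie in [0, 1]")
  if (abs_threshold < 0) stop("'abs_threshold' must be non-negative")
  if (nrow(counts) == 0 || ncol(counts) == 0) {
    return(structure(list(
      present = matrix(logical(0), nrow(counts), ncol(counts),
                       dimnames = dimnames(counts)),
      rel_threshold = rel_threshold, abs_threshold = abs_threshold,
      per_virus_max = NULL, scope = scope), class = "infection_calls"))
  }
  if (is.null(meta) || scope == "pooled") {
    project <- rep("all", nrow(counts))
  } else {
    meta <- .align_meta(meta, rownames(counts))
    project <- meta$project
  }
  projects <- unique(project)
  per_virus_max <- matrix(0, length(projects), ncol(counts),
                          dimnames = list(projects, colnames(counts)))
  present <- matrix(FALSE, nrow(counts), ncol(counts),
                    dimnames = dimnames(counts))
  for (p in projects) {
    idx <- which(project == p)
    mx <- apply(counts[idx, , drop = FALSE], 2, max)
    per_virus_max[p, ] <- mx
    thr <- pmax(rel_threshold * mx, abs_threshold)
    present[idx, ] <- sweep(counts[idx, , drop = FALSE], 2, thr, ">=")
  }
  structure(list(present = present, rel_threshold = rel_threshold,
                 abs_threshold = abs_threshold,
                 per_virus_max = per_virus_max, scope = scope),
            class = "infection_calls")
}

#' @export
print.infection_calls <- function(x, ...) {
  cat(sprintf(
    "infection_calls: %d libraries x %d viruses (rel %.3g, abs %g, %s scope)\n",
    nrow(x$present), ncol(x$present), x$rel_threshold, x$abs_threshold,
    x$scope))
  if (ncol(x$present))
    cat("  positives per virus:",
        paste(sprintf("%s=%d", colnames(x$present), colSums(x$present)),
              collapse = ", "), "\n")
  invisible(x)
}

#' Choose the absolute read floor from duplicate-sample discordance
#'
#' For every candidate absolute threshold, all libraries are re-called with
#' [call_infections()] and the discordance — the fraction of
#' (duplicate pair, virus) combinations whose two members receive different
#' calls — is computed. The smallest candidate attaining the minimum
#' discordance is returned (ties broken toward the smallest threshold to
#' retain sensitivity).
#'
#' @param vc A [virus_count_matrix] or count matrix.
#' @param meta Metadata data.frame with `library_id`, `project` and
#'   `duplicate_id` (non-`NA` for members of a duplicate pair).
#' @param candidate_thresholds Numeric vector of candidate floors.
#' @param rel_threshold,scope Passed to [call_infections()].
#' @return List: `abs_threshold` (chosen), `profile` (data.frame of
#'   candidate vs discordance and discordant-combination counts),
#'   `n_pairs`.
#' @export
select_abs_threshold <- function(vc, meta,
                                 candidate_thresholds = c(10, 25, 50, 100,
                                                          150, 200, 300, 500),
                                 rel_threshold = 0.01,
                                 scope = c("project", "pooled")) {
  scope <- match.arg(scope)
  .check_meta(meta, need = c("library_id", "project", "duplicate_id"))
  counts <- if (inherits(vc, "virus_count_matrix")) vc$counts else as.matrix(vc)
  meta_al <- .align_meta(meta, rownames(counts))
  dup <- meta_al$duplicate_id
  pairs <- split(seq_len(nrow(counts)), dup)   # NA labels are dropped
  pairs <- Filter(function(p) length(p) == 2L, pairs)
  if (length(pairs) == 0)
    stop("no duplicate pairs in the metadata; cannot tune the absolute ",
         "threshold - use the default of 150 reads")
  candidate_thresholds <- sort(unique(candidate_thresholds))
  n_comb <- length(pairs) * ncol(counts)
  prof <- data.frame(abs_threshold = candidate_thresholds,
                     n_discordant = NA_integer_,
                     discordance = NA_real_)
  for (i in seq_along(candidate_thresholds)) {
    calls <- call_infections(vc, meta_al, rel_threshold = rel_threshold,
                             abs_threshold = candidate_thresholds[i],
                             scope = scope)$present
    nd <- sum(vapply(pairs, function(p)
      sum(calls[p[1], ] != calls[p[2], ]), integer(1)))
    prof$n_discordant[i] <- nd
    prof$discordance[i] <- nd / n_comb
  }
  best <- prof$abs_threshold[which.min(prof$discordance)]  # smallest at min
  list(abs_threshold = best, profile = prof, n_pairs = length(pairs))
}

#' Flag virus sets whose counts point to a common contamination source
#'
#' Viruses whose per-library read counts are almost perfectly correlated
#' across many libraries are unlikely to represent independent infections;
#' they typically share a single contaminating source (for example an
#' unreported cell-culture library on the same flow cell). Pairwise Pearson
#' correlations are computed on `log1p`-transformed counts (counts span
#' several orders of magnitude), a graph is formed over virus pairs with
#' `r >= r_min`, and its connected components of size >= 2 are reported.
#'
#' @param vc A [virus_count_matrix] or count matrix (>= 3 libraries).
#' @param r_min Correlation threshold (default 0.95).
#' @return List: `clusters` (list of character vectors of virus labels),
#'   `correlations` (virus x virus Pearson matrix on log1p counts),
#'   `excluded` (viruses with constant counts, dropped with a warning).
#' @export
flag_contaminant_clusters <- function(vc, r_min = 0.95) {
  counts <- if (inherits(vc, "virus_count_matrix")) vc$counts else as.matrix(vc)
  if (nrow(counts) < 3)
    stop("at least 3 libraries are needed to assess correlation")
  lc <- log1p(counts)
  sds <- apply(lc, 2, stats::sd)
  excluded <- colnames(lc)[sds == 0]
  if (length(excluded))
    warning("constant count column(s) excluded from clustering: ",
            paste(excluded, collapse = ", "))
  lc <- lc[, sds > 0, drop = FALSE]
  v <- colnames(lc)
  if (length(v) < 2)
    return(list(clusters = list(),
                correlations = if (length(v)) stats::cor(lc) else NULL,
                excluded = excluded))
  cm <- stats::cor(lc)
  # union-find over the r >= r_min graph
  parent <- seq_along(v)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_along(v)) for (j in seq_len(i - 1L)) {
    if (cm[i, j] >= r_min) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_along(v), find, integer(1))
  groups <- split(v, comp)
  clusters <- unname(Filter(function(g) length(g) >= 2, groups))
  list(clusters = clusters, correlations = cm, excluded = excluded)
}
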