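#' Virus read-count matrix
#'
#' A light container pairing the libraries x viruses read-count matrix with
#' each library's total usable read count. Row names are library ids,
#' column names virus labels.
#'
#' @param counts Integer matrix, libraries x viruses, non-negative.
#' @param total_reads Numeric vector of per-library total reads, one per
#'   row of `counts`; every virus count must be at most the library total.
#' @return An object of class `virus_count_matrix` with elements `counts`
#'   and `total_reads`.
#' @export
virus_count_matrix <- function(counts, total_reads) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' needs library row names and virus column names")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must contain non-negative integers")
  if (length(total_reads) != nrow(counts))
    stop("'total_reads' must have one entry per library")
  if (is.null(names(total_reads))) names(total_reads) <- rownames(counts)
  if (!identical(names(total_reads), rownames(counts)))
    total_reads <- total_reads[rownames(counts)]
  if (anyNA(total_reads) || any(total_reads < 0))
    stop("'total_reads' must be non-negative and cover every library")
  if (any(counts > total_reads))
    stop("virus counts cannot exceed a library's total reads")
  structure(list(counts = counts, total_reads = total_reads),
            class = "virus_count_matrix")
}

#' @export
print.virus_count_matrix <- function(x, ...) {
  cat(sprintf("virus_count_matrix: %d libraries x %d viruses\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  viruses: %s\n", paste(colnames(x$counts), collapse = ", ")))
  cat(sprintf("  per-virus max counts: %s\n",
              paste(apply(x$counts, 2, max), collapse = ", ")))
  invisible(x)
}

# shared validation for the metadata table
.check_meta <- function(meta, need = c("library_id", "project")) {
  if (!is.data.frame(meta))
    stop("'meta' must be a data.frame")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols))
    stop("metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(meta$library_id))
    stop("metadata 'library_id' values must be unique")
  meta
}

# align a metadata table to a set of library ids, preserving that order
.align_meta <- function(meta, library_ids) {
  .check_meta(meta)
  if (!all(library_ids %in% meta$library_id))
    stop("metadata is missing entries for some libraries in the count data")
  meta[match(library_ids, meta$library_id), , drop = FALSE]
}
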