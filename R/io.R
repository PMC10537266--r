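#' Read and write the pipeline's tab-separated artefacts
#'
#' All tabular I/O is tab-separated with a header row. The gene-count
#' table follows the featureCounts layout (a `Geneid` column, then one
#' column per library); the virus-count table has a `library_id` column,
#' one column per virus, and a final `total_reads` column.
#'
#' @param path File path.
#' @return `read_meta()` a data.frame; `read_virus_counts()` a
#'   [virus_count_matrix]; `read_gene_counts()` a genes x libraries integer
#'   matrix.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_meta <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  .check_meta(meta)
  meta
}

#' @rdname pipeline_io
#' @param meta Metadata data.frame.
#' @export
write_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_virus_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"library_id" %in% names(tab) || !"total_reads" %in% names(tab))
    stop("virus-count table needs 'library_id' and 'total_reads' columns")
  viruses <- setdiff(names(tab), c("library_id", "total_reads"))
  counts <- as.matrix(tab[viruses])
  rownames(counts) <- tab$library_id
  virus_count_matrix(counts, stats::setNames(tab$total_reads,
                                             tab$library_id))
}

#' @rdname pipeline_io
#' @param vc A [virus_count_matrix].
#' @export
write_virus_counts <- function(vc, path) {
  tab <- data.frame(library_id = rownames(vc$counts), vc$counts,
                    total_reads = vc$total_reads, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_gene_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"Geneid" %in% names(tab))
    stop("gene-count table needs a 'Geneid' first column ",
         "(featureCounts layout)")
  counts <- as.matrix(tab[setdiff(names(tab), "Geneid")])
  rownames(counts) <- tab$Geneid
  storage.mode(counts) <- "integer"
  counts
}

#' @rdname pipeline_io
#' @param gene_counts Genes x libraries matrix.
#' @export
write_gene_counts <- function(gene_counts, path) {
  tab <- data.frame(Geneid = rownames(gene_counts), gene_counts,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @param calls An `infection_calls` object.
#' @export
write_calls <- function(calls, path) {
  present <- if (inherits(calls, "infection_calls")) calls$present else
    as.matrix(calls)
  tab <- data.frame(library_id = rownames(present), present,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_calls <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"library_id" %in% names(tab))
    stop("calls table needs a 'library_id' column")
  m <- as.matrix(tab[setdiff(names(tab), "library_id")])
  storage.mode(m) <- "logical"
  rownames(m) <- tab$library_id
  m
}
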