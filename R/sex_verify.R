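#' Sex-specific marker genes of Drosophila melanogaster
#'
#' FlyBase gene identifiers of the male-specific and female-specific genes
#' used to verify the reported sex of each sequencing library. The
#' female-specific set comprises the five yolk/chorion-class genes; the
#' male-specific set the accessory-gland/testis-limited genes customarily
#' used for this check.
#'
#' @format Character vectors of FlyBase gene ids.
#' @name sex_markers
NULL

#' @rdname sex_markers
#' @export
dmel_male_markers <- c(
  "FBgn0011669", "FBgn0011694", "FBgn0046294", "FBgn0053340",
  "FBgn0250832", "FBgn0259795", "FBgn0259971", "FBgn0259975",
  "FBgn0262099", "FBgn0262623", "FBgn0270925")

#' @rdname sex_markers
#' @export
dmel_female_markers <- c(
  "FBgn0000355", "FBgn0000356", "FBgn0000358", "FBgn0000359",
  "FBgn0000360")

#' Verify library sex from sex-specific marker genes
#'
#' Classifies each library as male, female or ambiguous by comparing the
#' CPM-normalised sums of male-specific and female-specific marker gene
#' counts. A library is called male when the male-marker sum is at least
#' `margin` times the female-marker sum (and positive), female in the
#' reverse case, and ambiguous otherwise (including when both sums are
#' zero). Reported metadata sex is not consulted; this is the independent
#' check used to catch mislabelled libraries before estimating the
#' barcode-switching rate.
#'
#' @param gene_counts Genes x libraries count matrix with gene ids as row
#'   names.
#' @param male_markers,female_markers Character vectors of marker gene ids;
#'   markers absent from the matrix are dropped with a warning, and an
#'   error is raised if an entire panel is missing.
#' @param margin Fold-difference required to call a sex (default 2).
#' @return Named character vector (`"male"`, `"female"` or `"ambiguous"`),
#'   one entry per library, with attributes `male_cpm` and `female_cpm`
#'   carrying the normalised marker sums.
#' @export
#' @examples
#' counts <- rbind(m1 = c(500, 0), f1 = c(0, 300), g1 = c(1000, 1000))
#' colnames(counts) <- c("libA", "libB")
#' verify_sex(counts, "m1", "f1")
verify_sex <- function(gene_counts,
                       male_markers = dmel_male_markers,
                       female_markers = dmel_female_markers,
                       margin = 2) {
  gene_counts <- as.matrix(gene_counts)
  if (is.null(rownames(gene_counts)))
    stop("'gene_counts' needs gene ids as row names")
  if (length(male_markers) == 0 || length(female_markers) == 0)
    stop("marker lists must be non-empty")
  mm <- intersect(male_markers, rownames(gene_counts))
  fm <- intersect(female_markers, rownames(gene_counts))
  dropped <- length(male_markers) + length(female_markers) -
    length(mm) - length(fm)
  if (dropped > 0)
    warning(sprintf("%d marker gene(s) absent from the matrix were dropped",
                    dropped))
  if (length(mm) == 0 && length(fm) == 0)
    stop("none of the marker genes are present in the count matrix")
  if (length(mm) == 0 || length(fm) == 0)
    stop("an entire marker panel is missing from the count matrix; ",
         "sex cannot be verified")

  lib_size <- colSums(gene_counts)
  lib_size[lib_size == 0] <- NA_real_
  male_cpm <- colSums(gene_counts[mm, , drop = FALSE]) / lib_size * 1e6
  female_cpm <- colSums(gene_counts[fm, , drop = FALSE]) / lib_size * 1e6
  male_cpm[is.na(male_cpm)] <- 0
  female_cpm[is.na(female_cpm)] <- 0

  call <- rep("ambiguous", ncol(gene_counts))
  call[male_cpm > 0 & male_cpm >= margin * female_cpm] <- "male"
  call[female_cpm > 0 & female_cpm >= margin * male_cpm] <- "female"
  names(call) <- colnames(gene_counts)
  attr(call, "male_cpm") <- male_cpm
  attr(call, "female_cpm") <- female_cpm
  call
}

#' Estimate the barcode-switching (index-hopping) rate from marker genes
#'
#' Reads from strictly sex-limited genes observed in libraries of the
#' *other* (verified) sex can only have arrived by index hopping, so they
#' estimate the switching rate. Two estimates are returned:
#'
#' * `rate_raw`: wrong-sex marker reads divided by all marker reads, with a
#'   Clopper-Pearson binomial interval. Under a uniform within-lane hop
#'   model this ratio estimates `hop_rate` times the average fraction of a
#'   source library's lane-mates that are of the opposite sex, so on
#'   mixed-sex lanes it understates the per-read hop rate.
#' * `rate` (primary): the exposure-corrected estimate, wrong-sex reads
#'   divided by the summed *exposure*
#'   `sum over lanes, panels of (panel reads on lane) * (opposite-sex
#'   lane-mates) / (lane size - 1)` — consistent for the per-read hop rate
#'   itself — with an exact Poisson interval on the wrong-sex read count.
#'
#' @param gene_counts Genes x libraries count matrix.
#' @param verified_sex Named vector of `"male"`/`"female"`/`"ambiguous"`
#'   calls as returned by [verify_sex()]; ambiguous libraries are excluded.
#' @param female_markers,male_markers Marker gene id vectors.
#' @param lanes Named character vector of lane labels per library (or a
#'   metadata data.frame with `library_id` and `lane` columns).
#' @param level Confidence level (default 0.95).
#' @return List of class `switching_rate`: `rate`, `ci` (corrected,
#'   primary), `rate_raw`, `ci_raw`, `n_wrong`, `n_total`, `exposure`,
#'   `per_lane` (data.frame), and `estimable` — `FALSE` when no lane holds
#'   verified libraries of both sexes (single-sex projects), in which case
#'   the rates are `NA`.
#' @export
estimate_switching_rate <- function(gene_counts, verified_sex,
                                    female_markers, male_markers, lanes,
                                    level = 0.95) {
  gene_counts <- as.matrix(gene_counts)
  if (is.data.frame(lanes)) {
    .check_meta(lanes, need = c("library_id", "lane"))
    lanes <- stats::setNames(lanes$lane, lanes$library_id)
  }
  libs <- colnames(gene_counts)
  if (!all(libs %in% names(verified_sex)) || !all(libs %in% names(lanes)))
    stop("'verified_sex' and 'lanes' must cover every library")
  verified_sex <- verified_sex[libs]
  lanes <- lanes[libs]
  mm <- intersect(male_markers, rownames(gene_counts))
  fm <- intersect(female_markers, rownames(gene_counts))
  if (length(mm) == 0 || length(fm) == 0)
    stop("both marker panels must be present in the count matrix")

  keep <- verified_sex %in% c("male", "female")
  res_lane <- list()
  n_wrong <- 0; n_total <- 0; exposure <- 0
  for (ln in unique(lanes[keep])) {
    idx <- which(lanes == ln & keep)
    s_all <- sum(lanes == ln)          # hop recipients include all lane-mates
    males <- idx[verified_sex[idx] == "male"]
    females <- idx[verified_sex[idx] == "female"]
    m_reads <- sum(gene_counts[mm, idx, drop = FALSE])
    f_reads <- sum(gene_counts[fm, idx, drop = FALSE])
    wrong <- sum(gene_counts[fm, males, drop = FALSE]) +
      sum(gene_counts[mm, females, drop = FALSE])
    expo <- if (s_all >= 2)
      f_reads * length(males) / (s_all - 1) +
      m_reads * length(females) / (s_all - 1) else 0
    res_lane[[ln]] <- data.frame(
      lane = ln, n_male = length(males), n_female = length(females),
      n_wrong = wrong, n_total = m_reads + f_reads, exposure = expo,
      estimable = length(males) > 0 && length(females) > 0,
      stringsAsFactors = FALSE)
    if (length(males) > 0 && length(females) > 0) {
      n_wrong <- n_wrong + wrong
      n_total <- n_total + m_reads + f_reads
      exposure <- exposure + expo
    }
  }
  per_lane <- do.call(rbind, res_lane)
  estimable <- n_total > 0 && exposure > 0

  a <- (1 - level) / 2
  if (estimable) {
    rate_raw <- n_wrong / n_total
    ci_raw <- c(
      if (n_wrong == 0) 0 else stats::qbeta(a, n_wrong, n_total - n_wrong + 1),
      if (n_wrong == n_total) 1 else
        stats::qbeta(1 - a, n_wrong + 1, n_total - n_wrong))
    rate <- n_wrong / exposure
    # exact Poisson interval on the wrong-sex count, scaled by exposure
    ci <- c(if (n_wrong == 0) 0 else stats::qgamma(a, n_wrong) / exposure,
            stats::qgamma(1 - a, n_wrong + 1) / exposure)
  } else {
    rate <- rate_raw <- NA_real_
    ci <- ci_raw <- c(NA_real_, NA_real_)
  }
  structure(list(rate = rate, ci = ci, rate_raw = rate_raw, ci_raw = ci_raw,
                 n_wrong = n_wrong, n_total = n_total, exposure = exposure,
                 per_lane = per_lane, level = level, estimable = estimable),
            class = "switching_rate")
}

#' @export
print.switching_rate <- function(x, ...) {
  if (!x$estimable) {
    cat("switching_rate: not estimable (no lane with verified libraries of",
        "both sexes)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "switching_rate: %.3g (%d%% CI %.3g-%.3g), from %d wrong-sex of %d marker reads\n",
    x$rate, round(100 * x$level), x$ci[1], x$ci[2], x$n_wrong, x$n_total))
  cat(sprintf("  raw wrong-sex fraction: %.3g (CI %.3g-%.3g)\n",
              x$rate_raw, x$ci_raw[1], x$ci_raw[2]))
  invisible(x)
}
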