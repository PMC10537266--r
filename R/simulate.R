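#' Simulate a multi-project virus-infected RNA-seq experiment
#'
#' Generates the four artefacts the screening pipeline consumes, with full
#' ground truth: a library metadata table, a [virus_count_matrix], a host
#' gene-count matrix and a truth object recording the planted infections and
#' effect sizes. All randomness derives deterministically from
#' `config$seed`; each stage (design, viral counts, gene counts, duplicate
#' re-sampling) uses its own sub-seed so partial re-runs are reproducible.
#'
#' Libraries are laid out round-robin across lanes within each project, with
#' alternating sexes and cycling genotype/tissue labels, so every lane mixes
#' strata (index hopping acts within a lane). Infection status is an
#' independent Bernoulli draw per library and virus at the configured
#' prevalence. Duplicate pairs share the stratum and infection status of
#' their source library, and the duplicate's counts are Poisson re-draws
#' around the source's counts (a technical re-sample).
#'
#' @param config A [sim_config()] object.
#' @return A list with components:
#' \describe{
#'   \item{meta}{data.frame: `library_id`, `project`, `genotype`, `tissue`,
#'     `lane`, `sex` (simulated truth, reported as-is), `duplicate_id`
#'     (`NA` for unpaired libraries).}
#'   \item{virus_counts}{a [virus_count_matrix].}
#'   \item{gene_counts}{integer matrix, genes x libraries, with marker genes
#'     first (row names `markerM*`, `markerF*`, then `gene*`).}
#'   \item{truth}{list: `infection_status` (logical libraries x viruses),
#'     `true_logfc` (genes x coefficients matrix, log2; zero rows for
#'     unaffected genes; columns `sex`, `virus_<label>`,
#'     `sex:virus_<label>`), `hop_rate`, `group_intercepts` (named, log2),
#'     `male_markers`, `female_markers`, `lib_size`.}
#' }
#' @export
#' @examples
#' sim <- simulate_experiment(sim_config(n_projects = 1,
#'   libraries_per_project = 12, n_genes = 60, seed = 7))
#' dim(sim$gene_counts)
#' colSums(sim$truth$infection_status)
simulate_experiment <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("'config' must be built with sim_config()")
  cfg <- config

  ## -- design: strata, lanes, sexes, duplicates ---------------------------
  set.seed(cfg$seed)
  n_lib <- cfg$n_projects * cfg$libraries_per_project
  project <- rep(sprintf("PRJ%02d", seq_len(cfg$n_projects)),
                 each = cfg$libraries_per_project)
  within <- rep(seq_len(cfg$libraries_per_project), cfg$n_projects)
  library_id <- sprintf("%s_L%04d", project, within)
  # lanes cycle fastest, then sex alternates per lane-cycle, then genotype
  # per two cycles: every lane carries both sexes and genotypes are
  # sex-balanced (index hopping needs mixed lanes to be detectable)
  lane <- sprintf("%s_lane%d", project,
                  ((within - 1L) %% cfg$lanes_per_project) + 1L)
  sex <- ifelse(((within - 1L) %/% cfg$lanes_per_project) %% 2L == 0L,
                "male", "female")
  genotype <- sprintf("geno%02d",
                      ((within - 1L) %/% (2L * cfg$lanes_per_project)) %%
                        cfg$genotypes_per_project + 1L)
  tissue <- cfg$tissues[((within - 1L) %% length(cfg$tissues)) + 1L]

  meta <- data.frame(library_id = library_id, project = project,
                     genotype = genotype, tissue = tissue, lane = lane,
                     sex = sex, duplicate_id = NA_character_,
                     stringsAsFactors = FALSE)

  # duplicate pairs: in each project the first 2k libraries form k pairs;
  # the second member inherits the first member's stratum and status
  dup_source <- integer(0)
  dup_copy <- integer(0)
  if (cfg$n_duplicate_pairs > 0) {
    for (p in seq_len(cfg$n_projects)) {
      off <- (p - 1L) * cfg$libraries_per_project
      for (k in seq_len(cfg$n_duplicate_pairs)) {
        i <- off + 2L * k - 1L
        j <- off + 2L * k
        id <- sprintf("%s_dup%02d", meta$project[i], k)
        meta$duplicate_id[c(i, j)] <- id
        meta$sex[j] <- meta$sex[i]
        meta$genotype[j] <- meta$genotype[i]
        meta$tissue[j] <- meta$tissue[i]
        dup_source <- c(dup_source, i)
        dup_copy <- c(dup_copy, j)
      }
    }
  }

  ## -- infection status ---------------------------------------------------
  viruses <- names(cfg$viruses)
  status <- matrix(FALSE, n_lib, length(viruses),
                   dimnames = list(library_id, viruses))
  for (v in viruses)
    status[, v] <- stats::rbinom(n_lib, 1L, cfg$viruses[[v]]) == 1L
  status[dup_copy, ] <- status[dup_source, , drop = FALSE]

  lib_size <- stats::rlnorm(n_lib, log(cfg$lib_size_mean),
                            cfg$lib_size_sdlog)
  names(lib_size) <- library_id

  ## -- viral read counts --------------------------------------------------
  vcounts <- simulate_virus_counts(status, lane, cfg$hop_rate,
                                   titer_mean = cfg$infected_titer_mean,
                                   titer_sdlog = cfg$titer_sdlog,
                                   seed = cfg$seed + 1L)
  if (length(dup_copy)) {
    set.seed(cfg$seed + 3L)
    for (m in seq_along(dup_copy))
      vcounts[dup_copy[m], ] <-
        stats::rpois(ncol(vcounts), vcounts[dup_source[m], ])
  }

  ## -- gene counts --------------------------------------------------------
  gs <- simulate_gene_counts(meta, status, cfg$effect_model,
                             cfg$nb_dispersion,
                             marker_spec = list(
                               n_male = cfg$n_marker_male,
                               n_female = cfg$n_marker_female,
                               leakage = cfg$marker_leakage),
                             seed = cfg$seed + 2L,
                             n_genes = cfg$n_genes,
                             sex_effect = cfg$sex_effect,
                             group_sd = cfg$group_sd,
                             lib_size = lib_size,
                             hop_rate = cfg$hop_rate)
  gene_counts <- gs$counts
  if (length(dup_copy)) {
    set.seed(cfg$seed + 4L)
    for (m in seq_along(dup_copy))
      gene_counts[, dup_copy[m]] <-
        stats::rpois(nrow(gene_counts), gene_counts[, dup_source[m]])
  }

  total_reads <- colSums(gene_counts) + rowSums(vcounts)
  vc <- virus_count_matrix(vcounts, total_reads)

  truth <- list(infection_status = status,
                true_logfc = gs$true_logfc,
                hop_rate = cfg$hop_rate,
                group_intercepts = gs$group_intercepts,
                male_markers = gs$male_markers,
                female_markers = gs$female_markers,
                lib_size = lib_size)

  list(meta = meta, virus_counts = vc, gene_counts = gene_counts,
       truth = truth)
}

#' Simulate viral read counts with index hopping across lane-mates
#'
#' Truly infected libraries draw a log-normal read count (median
#' `titer_mean`, log-sd `titer_sdlog`). Index hopping then deposits reads
#' into each *uninfected* library sharing a lane: with `T` viral reads of a
#' virus on a lane of size `s`, each uninfected lane-mate receives a
#' Poisson count with mean `hop_rate * T / (s - 1)` (a fraction `hop_rate`
#' of reads relocating uniformly over the `s - 1` other libraries).
#'
#' @param status Logical matrix, libraries x viruses (row names = library
#'   ids), `TRUE` where the library is truly infected.
#' @param lanes Character vector of lane labels, one per library (row of
#'   `status`); hopping only acts within a lane.
#' @param hop_rate Per-read relocation rate in `[0, 1)`.
#' @param titer_mean,titer_sdlog Log-normal titre parameters for infected
#'   libraries.
#' @param seed Integer seed.
#' @return Integer matrix, libraries x viruses.
#' @export
simulate_virus_counts <- function(status, lanes, hop_rate,
                                  titer_mean = 5e4, titer_sdlog = 1.5,
                                  seed = 1L) {
  status <- as.matrix(status)
  if (length(lanes) != nrow(status))
    stop("'lanes' must have one entry per library (row of 'status')")
  if (hop_rate < 0 || hop_rate >= 1)
    stop("'hop_rate' must lie in [0, 1)")
  set.seed(seed)
  n <- nrow(status)
  counts <- matrix(0, n, ncol(status), dimnames = dimnames(status))
  # infected titres (drawn column-wise so the stream is reproducible)
  for (v in seq_len(ncol(status))) {
    inf <- which(status[, v])
    if (length(inf))
      counts[inf, v] <- pmax(1, round(stats::rlnorm(
        length(inf), log(titer_mean), titer_sdlog)))
  }
  # hopped reads into uninfected lane-mates
  if (hop_rate > 0) {
    for (ln in unique(lanes)) {
      idx <- which(lanes == ln)
      s <- length(idx)
      if (s < 2L) next
      for (v in seq_len(ncol(status))) {
        lane_total <- sum(counts[idx, v])
        if (lane_total == 0) next
        uninf <- idx[!status[idx, v]]
        if (length(uninf))
          counts[uninf, v] <- counts[uninf, v] +
            stats::rpois(length(uninf), hop_rate * lane_total / (s - 1))
      }
    }
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate host gene counts with planted sex, virus and interaction effects
#'
#' Gene counts are negative-binomial with log2 mean
#' `baseline + sex effect + sum(virus effects) + sum(sex:virus effects) +
#' group intercept + log2(library size)`. Marker genes express only in the
#' matching sex; with `marker_spec$leakage`, wrong-sex libraries receive
#' hopped marker reads under the same within-lane hop model as viral reads.
#'
#' @param meta Metadata data.frame as produced by [simulate_experiment()]
#'   (columns `library_id`, `project`, `genotype`, `tissue`, `lane`, `sex`).
#' @param infection_status Logical libraries x viruses matrix.
#' @param effects Per-virus effect list as held in `sim_config()$effect_model`.
#' @param nb_dispersion Negative-binomial dispersion (0 = Poisson).
#' @param marker_spec List: `n_male`, `n_female`, `leakage` (logical).
#' @param seed Integer seed.
#' @param n_genes Total number of genes, marker genes included.
#' @param sex_effect List with `logfc`, `frac_affected`.
#' @param group_sd Random-intercept sd (log2).
#' @param lib_size Named per-library size vector (reads).
#' @param hop_rate Hop rate used for marker leakage.
#' @return List: `counts` (genes x libraries integer matrix), `true_logfc`
#'   (genes x coefficients, log2), `group_intercepts`, `male_markers`,
#'   `female_markers`.
#' @export
simulate_gene_counts <- function(meta, infection_status, effects,
                                 nb_dispersion, marker_spec, seed = 1L,
                                 n_genes = 2000L,
                                 sex_effect = list(logfc = 1,
                                                   frac_affected = 0.1),
                                 group_sd = 0.5, lib_size = NULL,
                                 hop_rate = 0) {
  .check_meta(meta, need = c("library_id", "project", "genotype",
                             "tissue", "lane", "sex"))
  n_lib <- nrow(meta)
  viruses <- colnames(infection_status)
  set.seed(seed)
  if (is.null(lib_size)) {
    lib_size <- stats::rlnorm(n_lib, log(5e6), 0.3)
    names(lib_size) <- meta$library_id
  }

  n_mm <- marker_spec$n_male
  n_fm <- marker_spec$n_female
  male_markers <- if (n_mm) sprintf("markerM%02d", seq_len(n_mm)) else character(0)
  female_markers <- if (n_fm) sprintf("markerF%02d", seq_len(n_fm)) else character(0)
  # markers first, then ordinary genes
  if (n_mm + n_fm >= n_genes)
    stop("'n_genes' must exceed the number of marker genes")
  n_plain <- n_genes - n_mm - n_fm
  gene_ids <- c(male_markers, female_markers,
                sprintf("gene%05d", seq_len(n_plain)))
  marker_rows <- seq_len(n_mm + n_fm)

  # baseline relative expression: log-normal weights, markers pinned to a
  # solidly detectable level (~100 CPM) so sex calls and the switching-rate
  # estimate have signal
  w <- stats::rlnorm(n_genes, 0, 1.5)
  if (length(marker_rows)) w[marker_rows] <- stats::quantile(w, 0.9)
  p <- w / sum(w)

  coef_names <- c("sex", paste0("virus_", viruses),
                  paste0("sex:virus_", viruses))
  true_logfc <- matrix(0, n_genes, length(coef_names),
                       dimnames = list(gene_ids, coef_names))
  plain <- setdiff(seq_len(n_genes), marker_rows)
  pick <- function(frac) {
    k <- round(frac * length(plain))
    if (k == 0) return(integer(0))
    sample(plain, k)
  }
  signed <- function(idx, lfc)
    ifelse(seq_along(idx) %% 2L == 1L, lfc, -lfc)
  sx <- pick(sex_effect$frac_affected)
  true_logfc[sx, "sex"] <- signed(sx, sex_effect$logfc)
  for (v in viruses) {
    iv <- pick(effects[[v]]$frac_affected)
    true_logfc[iv, paste0("virus_", v)] <- signed(iv, effects[[v]]$logfc)
    ii <- pick(effects[[v]]$frac_interaction)
    true_logfc[ii, paste0("sex:virus_", v)] <-
      signed(ii, effects[[v]]$interaction_logfc)
  }

  group <- interaction(meta$project, meta$genotype, meta$tissue, drop = TRUE)
  group_intercepts <- stats::rnorm(nlevels(group), 0, group_sd)
  names(group_intercepts) <- levels(group)

  is_male <- meta$sex == "male"
  # log2 linear predictor per gene x library
  eta <- matrix(0, n_genes, n_lib)
  eta <- eta + outer(true_logfc[, "sex"], as.numeric(is_male))
  for (v in viruses) {
    infv <- as.numeric(infection_status[meta$library_id, v])
    eta <- eta + outer(true_logfc[, paste0("virus_", v)], infv)
    eta <- eta + outer(true_logfc[, paste0("sex:virus_", v)],
                       infv * as.numeric(is_male))
  }
  eta <- eta + matrix(group_intercepts[as.character(group)], n_genes,
                      n_lib, byrow = TRUE)
  mu <- p * 2^eta
  mu <- sweep(mu, 2, lib_size[meta$library_id], "*")
  # sex-limit the markers
  if (n_mm) mu[seq_len(n_mm), !is_male] <- 0
  if (n_fm) mu[n_mm + seq_len(n_fm), is_male] <- 0

  counts <- matrix(0L, n_genes, n_lib,
                   dimnames = list(gene_ids, meta$library_id))
  pos <- mu > 0
  if (nb_dispersion > 0) {
    counts[pos] <- stats::rnbinom(sum(pos), mu = mu[pos],
                                  size = 1 / nb_dispersion)
  } else {
    counts[pos] <- stats::rpois(sum(pos), mu[pos])
  }

  # marker leakage: hop model applied to each marker gene within each lane
  if (isTRUE(marker_spec$leakage) && hop_rate > 0 && length(marker_rows)) {
    for (ln in unique(meta$lane)) {
      idx <- which(meta$lane == ln)
      s <- length(idx)
      if (s < 2L) next
      for (g in marker_rows) {
        lane_total <- sum(counts[g, idx])
        if (lane_total == 0) next
        wrong <- if (g <= n_mm) idx[!is_male[idx]] else idx[is_male[idx]]
        if (length(wrong))
          counts[g, wrong] <- counts[g, wrong] +
            stats::rpois(length(wrong), hop_rate * lane_total / (s - 1))
      }
    }
  }
  storage.mode(counts) <- "integer"

  list(counts = counts, true_logfc = true_logfc,
       group_intercepts = group_intercepts,
       male_markers = male_markers, female_markers = female_markers)
}
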