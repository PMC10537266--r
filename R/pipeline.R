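#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end screen in one validated object.
#' Exactly one input mode must be given: `sim` (a [sim_config()], synthetic
#' mode) or `inputs` (paths to the three real-input TSVs). Thresholds
#' default to the screening conventions: 1% relative, 150-read floor,
#' raw co-infection alpha 0.01, |logFC| cutoff 0.5, adjusted-p cutoff
#' 0.001.
#'
#' @param outdir Output directory (created if missing).
#' @param sim Optional [sim_config()] for synthetic mode.
#' @param inputs Optional named list with `meta`, `virus_counts`,
#'   `gene_counts` file paths.
#' @param rel_threshold,abs_threshold Presence/absence thresholds.
#' @param tune_abs If `TRUE`, choose the absolute floor with
#'   [select_abs_threshold()] (needs duplicate pairs).
#' @param candidate_thresholds Candidate floors for tuning.
#' @param scope `"project"` or `"pooled"` for the relative rule.
#' @param coinfection_alpha Raw significance threshold of the co-infection
#'   scan.
#' @param prevalence_level Confidence level of prevalence intervals.
#' @param lfc_cut,de_alpha DE classification cutoffs.
#' @param moderation Empirical-Bayes variance moderation in DE.
#' @param de_viruses Viruses to analyse for DE (`NULL` = every virus with
#'   at least one positive call).
#' @param stages Character subset of
#'   `c("call", "prevalence", "coinfection", "de", "correlate")`.
#' @param male_markers,female_markers Marker gene ids for sex verification
#'   (`NULL` = auto-detect simulated `markerM*`/`markerF*` rows, falling
#'   back to the *D. melanogaster* FlyBase panels).
#' @param seed Integer seed (used by the simulation stage).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, sim = NULL, inputs = NULL,
                            rel_threshold = 0.01, abs_threshold = 150,
                            tune_abs = FALSE,
                            candidate_thresholds = c(10, 25, 50, 100, 150,
                                                     200, 300, 500),
                            scope = c("project", "pooled"),
                            coinfection_alpha = 0.01,
                            prevalence_level = 0.95,
                            lfc_cut = 0.5, de_alpha = 0.001,
                            moderation = TRUE, de_viruses = NULL,
                            stages = c("call", "prevalence", "coinfection",
                                       "de", "correlate"),
                            male_markers = NULL, female_markers = NULL,
                            seed = 1L) {
  scope <- match.arg(scope)
  if (is.null(sim) == is.null(inputs))
    stop("provide exactly one of 'sim' (synthetic mode) or 'inputs' ",
         "(real-input paths)")
  if (!is.null(sim) && !inherits(sim, "sim_config"))
    stop("'sim' must be a sim_config() object")
  if (!is.null(inputs)) {
    need <- c("meta", "virus_counts", "gene_counts")
    if (!all(need %in% names(inputs)))
      stop("'inputs' must name files: ", paste(need, collapse = ", "))
  }
  all_stages <- c("call", "prevalence", "coinfection", "de", "correlate")
  stages <- if (length(stages))
    match.arg(stages, all_stages, several.ok = TRUE) else character(0)
  structure(list(outdir = outdir, sim = sim, inputs = inputs,
                 rel_threshold = rel_threshold,
                 abs_threshold = abs_threshold, tune_abs = tune_abs,
                 candidate_thresholds = candidate_thresholds,
                 scope = scope, coinfection_alpha = coinfection_alpha,
                 prevalence_level = prevalence_level, lfc_cut = lfc_cut,
                 de_alpha = de_alpha, moderation = moderation,
                 de_viruses = de_viruses, stages = stages,
                 male_markers = male_markers,
                 female_markers = female_markers,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Build a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `simulate:` mapping holds [sim_config()] arguments. `overrides` (e.g.
#' from command-line flags) take precedence over file values.
#'
#' @param path YAML file path.
#' @param overrides Named list overriding file values.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw <- utils::modifyList(raw, overrides)
  if (!is.null(raw$simulate)) {
    sim_args <- raw$simulate
    if (!is.null(sim_args$viruses))
      sim_args$viruses <- unlist(sim_args$viruses)
    raw$sim <- do.call(sim_config, sim_args)
    raw$simulate <- NULL
  }
  do.call(pipeline_config, raw)
}

#' Run the full screening pipeline
#'
#' Executes the enabled stages in dependency order — simulate (synthetic
#' mode) or load inputs, verify sex and estimate the switching rate, call
#' infections (optionally tuning the absolute floor from duplicates), flag
#' contaminant clusters, estimate prevalence, scan co-infections, run
#' per-virus differential expression, and correlate effects — writing each
#' stage's TSV/JSON outputs under `cfg$outdir` and a `manifest.json`
#' recording every parameter, output file (with MD5 checksum), warning and
#' stage timing. Re-running with the same configuration and seed
#' reproduces identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (!inherits(cfg, "pipeline_config"))
    stop("'cfg' must be a pipeline_config() object")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  warnings_log <- character(0)
  timings <- list()
  say <- function(...) if (!quiet) message(sprintf(...))
  note_warn <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stage <- function(name, f) {
    t0 <- proc.time()[["elapsed"]]
    say("[%s] running", name)
    res <- withCallingHandlers(f(), warning = note_warn)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  out_path <- function(name) {
    p <- file.path(cfg$outdir, name)
    outputs <<- c(outputs, p)
    p
  }

  ## -- inputs -------------------------------------------------------------
  if (!is.null(cfg$sim)) {
    sim <- stage("simulate", function() simulate_experiment(cfg$sim))
    meta <- sim$meta; vc <- sim$virus_counts; gene_counts <- sim$gene_counts
    write_meta(meta, out_path("meta.tsv"))
    write_virus_counts(vc, out_path("virus_counts.tsv"))
    write_gene_counts(gene_counts, out_path("gene_counts.tsv"))
    truth_out <- sim$truth
    truth_out$infection_status <-
      as.data.frame(truth_out$infection_status)
    truth_out$true_logfc <- as.data.frame(truth_out$true_logfc)
    jsonlite::write_json(truth_out, out_path("truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  } else {
    meta <- read_meta(cfg$inputs$meta)
    vc <- read_virus_counts(cfg$inputs$virus_counts)
    gene_counts <- read_gene_counts(cfg$inputs$gene_counts)
    sim <- NULL
  }

  ## -- sex verification & switching rate ----------------------------------
  mm <- cfg$male_markers; fm <- cfg$female_markers
  if (is.null(mm)) {
    mm <- grep("^markerM", rownames(gene_counts), value = TRUE)
    if (!length(mm)) mm <- intersect(dmel_male_markers,
                                     rownames(gene_counts))
  }
  if (is.null(fm)) {
    fm <- grep("^markerF", rownames(gene_counts), value = TRUE)
    if (!length(fm)) fm <- intersect(dmel_female_markers,
                                     rownames(gene_counts))
  }
  sex_verified <- NULL; switching <- NULL
  if (length(mm) && length(fm)) {
    sex_verified <- stage("verify_sex", function()
      verify_sex(gene_counts, mm, fm))
    meta$sex_verified <- unname(sex_verified[meta$library_id])
    if ("lane" %in% names(meta))
      switching <- stage("switching_rate", function()
        estimate_switching_rate(gene_counts, sex_verified, fm, mm, meta))
  }

  manifest <- list(
    parameters = list(rel_threshold = cfg$rel_threshold,
                      abs_threshold = cfg$abs_threshold,
                      scope = cfg$scope,
                      coinfection_alpha = cfg$coinfection_alpha,
                      prevalence_level = cfg$prevalence_level,
                      lfc_cut = cfg$lfc_cut, de_alpha = cfg$de_alpha,
                      moderation = cfg$moderation, seed = cfg$seed),
    mode = if (is.null(cfg$sim)) "real" else "synthetic",
    stages = cfg$stages)

  ## -- calling ------------------------------------------------------------
  calls <- NULL
  if ("call" %in% cfg$stages) {
    abs_thr <- cfg$abs_threshold
    tuning <- NULL
    if (cfg$tune_abs) {
      tuning <- stage("tune_abs", function()
        select_abs_threshold(vc, meta,
                             candidate_thresholds = cfg$candidate_thresholds,
                             rel_threshold = cfg$rel_threshold,
                             scope = cfg$scope))
      abs_thr <- tuning$abs_threshold
      manifest$parameters$abs_threshold <- abs_thr
      manifest$threshold_tuning <- tuning$profile
    }
    calls <- stage("call", function()
      call_infections(vc, meta, rel_threshold = cfg$rel_threshold,
                      abs_threshold = abs_thr, scope = cfg$scope))
    write_calls(calls, out_path("calls.tsv"))
    clusters <- stage("contaminant_clusters", function()
      flag_contaminant_clusters(vc))
    diag <- list(rel_threshold = cfg$rel_threshold,
                 abs_threshold = abs_thr,
                 positives_per_virus = as.list(colSums(calls$present)),
                 contaminant_clusters = clusters$clusters)
    if (!is.null(switching) && switching$estimable)
      diag$switching_rate <- list(rate = switching$rate,
                                  ci = switching$ci,
                                  rate_raw = switching$rate_raw,
                                  n_wrong = switching$n_wrong,
                                  n_total = switching$n_total)
    jsonlite::write_json(diag, out_path("calling_diagnostics.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  needs_calls <- intersect(c("prevalence", "coinfection", "de", "correlate"),
                           cfg$stages)
  if (length(needs_calls) && is.null(calls))
    stop("stage '", needs_calls[1],
         "' requires the 'call' stage output, which is not enabled")

  ## -- epidemiology -------------------------------------------------------
  if ("prevalence" %in% cfg$stages) {
    prev <- stage("prevalence", function()
      estimate_prevalence(calls, meta, level = cfg$prevalence_level))
    utils::write.table(prev, out_path("prevalence.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if ("coinfection" %in% cfg$stages) {
    coinf <- stage("coinfection", function()
      coinfection_scan(calls, meta, alpha = cfg$coinfection_alpha))
    utils::write.table(coinf, out_path("coinfection.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  ## -- differential expression -------------------------------------------
  de_results <- list()
  if ("de" %in% cfg$stages) {
    viruses <- cfg$de_viruses
    if (is.null(viruses))
      viruses <- colnames(calls$present)[colSums(calls$present) > 0]
    for (v in viruses) {
      res <- stage(paste0("de_", v), function()
        run_de(gene_counts, meta, calls, v, moderation = cfg$moderation,
               lfc_cut = cfg$lfc_cut, alpha = cfg$de_alpha))
      de_results[[v]] <- res
      utils::write.table(res, out_path(sprintf("de_%s.tsv", v)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(volcano_table(res),
                         out_path(sprintf("volcano_%s.tsv", v)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    summ <- lapply(de_results, function(r) {
      s <- attr(r, "summary")
      stats::setNames(lapply(split(s$Freq, s$coefficient), function(fr)
        stats::setNames(as.list(fr), levels(s$de_class))),
        levels(factor(s$coefficient)))
    })
    jsonlite::write_json(list(genes_tested = lapply(de_results, function(r)
      length(unique(r$gene_id))), class_counts = summ),
      out_path("de_summary.json"), auto_unbox = TRUE, digits = NA)
  }

  ## -- correlation report -------------------------------------------------
  if ("correlate" %in% cfg$stages && length(de_results) >= 2) {
    for (co in c("virus", "sexmale:virus")) {
      have <- Filter(function(r) co %in% r$coefficient, de_results)
      if (length(have) < 2) next
      em <- effect_matrix(have, coefficient = co)
      ec <- stage(paste0("correlate_", co), function()
        correlate_effects(em, alpha = cfg$de_alpha))
      tag <- if (co == "virus") "virus" else "interaction"
      utils::write.table(ec$pairs,
                         out_path(sprintf("correlation_%s.tsv", tag)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  ## -- recovery report (synthetic mode) -----------------------------------
  if (!is.null(sim) && length(de_results)) {
    recov <- lapply(names(de_results), function(v) {
      res <- de_results[[v]]
      res <- res[res$coefficient == "virus", , drop = FALSE]
      truth <- sim$truth$true_logfc[, paste0("virus_", v)]
      shared <- intersect(res$gene_id, names(truth))
      est <- stats::setNames(res$logFC, res$gene_id)[shared]
      tru <- truth[shared]
      aff <- tru != 0
      list(virus = v, n_genes = length(shared),
           mae_affected = if (any(aff)) mean(abs(est[aff] - tru[aff])) else NA,
           mean_bias_affected = if (any(aff))
             mean((est[aff] - tru[aff]) * sign(tru[aff])) else NA,
           null_fpr_p05 = mean(stats::setNames(res$p, res$gene_id)[
             shared][!aff] < 0.05))
    })
    jsonlite::write_json(recov, out_path("recovery_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest$outputs <- lapply(stats::setNames(outputs, basename(outputs)),
                             function(p)
                               list(path = p,
                                    md5 = unname(tools::md5sum(p))))
  manifest$warnings <- warnings_log
  manifest$timings_s <- timings
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete: %d output file(s) in %s", length(outputs),
      cfg$outdir)
  invisible(manifest)
}
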