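#' Configuration for the synthetic multi-project RNA-seq experiment
#'
#' Builds and validates the configuration driving [simulate_experiment()].
#' The generator emulates the structure of a virus screen across several
#' published sequencing projects: libraries are stratified by project,
#' genotype, tissue, lane and sex; some libraries are truly infected by each
#' virus; infected libraries carry large (log-normal) viral read counts while
#' their uninfected lane-mates receive a small Poisson number of
#' index-hopped reads; host gene counts are negative-binomial with planted
#' log2 fold changes for sex, virus and sex:virus terms plus a normal random
#' intercept per dataset-genotype-tissue group.
#'
#' @param n_projects Number of sequencing projects (datasets).
#' @param libraries_per_project Libraries in each project.
#' @param lanes_per_project Sequencing lanes per project; libraries are
#'   spread round-robin across lanes, so every lane mixes sexes and
#'   genotypes (index hopping only moves reads within a lane).
#' @param genotypes_per_project Distinct genotype labels per project.
#' @param tissues Character vector of tissue labels cycled across libraries.
#' @param viruses Named numeric vector of per-virus true prevalence in
#'   `[0, 1]`, applied in every project (names are the virus labels).
#' @param hop_rate Index-hopping rate in `[0, 1)`: the expected fraction of
#'   a library's reads that relocate, uniformly, to its lane-mates.
#' @param infected_titer_mean Median viral read count of a truly infected
#'   library (counts are log-normal with this median and `titer_sdlog`).
#' @param titer_sdlog Log-scale standard deviation of infected titres; the
#'   default spans the orders-of-magnitude spread seen in real screens.
#' @param n_genes Number of host genes (marker genes included).
#' @param n_marker_male,n_marker_female Number of male-specific and
#'   female-specific marker genes (defaults 12 and 5, the usual
#'   *D. melanogaster* sex-verification panel size).
#' @param nb_dispersion Negative-binomial dispersion of gene counts
#'   (`variance = mu + dispersion * mu^2`); `0` gives Poisson counts.
#' @param effect_model Either a single list recycled for every virus, or a
#'   named list (one entry per virus) of lists with elements `logfc`
#'   (absolute planted log2 fold change of the virus main effect),
#'   `frac_affected` (fraction of non-marker genes affected; half up, half
#'   down), `interaction_logfc` and `frac_interaction` (same for the
#'   sex:virus interaction).
#' @param sex_effect List with `logfc` and `frac_affected` for the sex main
#'   effect (male relative to female).
#' @param group_sd Standard deviation (log2 scale) of the random intercept
#'   shared by each project-genotype-tissue group.
#' @param lib_size_mean Median library size in reads (log-normal with
#'   `lib_size_sdlog`).
#' @param lib_size_sdlog Log-scale sd of library sizes.
#' @param marker_leakage If `TRUE`, marker-gene reads leak into wrong-sex
#'   lane-mates at `hop_rate` under the same hop model as viral reads, so
#'   the switching-rate estimator has signal; if `FALSE`, markers are
#'   strictly sex-limited.
#' @param n_duplicate_pairs Number of duplicate (technical re-sample) pairs
#'   to plant; the second member of each pair shares the first member's
#'   stratum and infection status and its counts are re-drawn around the
#'   first member's counts.
#' @param seed Integer seed; identical configurations produce bit-identical
#'   simulated data.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_experiment()]
#' @export
#' @examples
#' cfg <- sim_config(n_projects = 1, libraries_per_project = 20,
#'                   n_genes = 50, seed = 42)
#' cfg$viruses
sim_config <- function(n_projects = 2,
                       libraries_per_project = 100,
                       lanes_per_project = 2,
                       genotypes_per_project = 4,
                       tissues = "whole",
                       viruses = c(DAV = 0.3, nora = 0.2),
                       hop_rate = 0.002,
                       infected_titer_mean = 5e4,
                       titer_sdlog = 1.5,
                       n_genes = 2000,
                       n_marker_male = 12,
                       n_marker_female = 5,
                       nb_dispersion = 0.2,
                       effect_model = list(logfc = 1, frac_affected = 0.1,
                                           interaction_logfc = 1,
                                           frac_interaction = 0.05),
                       sex_effect = list(logfc = 1, frac_affected = 0.1),
                       group_sd = 0.5,
                       lib_size_mean = 5e6,
                       lib_size_sdlog = 0.3,
                       marker_leakage = TRUE,
                       n_duplicate_pairs = 0,
                       seed = 1L) {
  bad <- function(field, msg)
    stop(sprintf("invalid sim_config field '%s': %s", field, msg),
         call. = FALSE)
  chk_count <- function(x, field, min = 1) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
        x != round(x))
      bad(field, sprintf("must be a single integer >= %d", min))
  }
  chk_count(n_projects, "n_projects")
  chk_count(libraries_per_project, "libraries_per_project")
  chk_count(lanes_per_project, "lanes_per_project")
  chk_count(genotypes_per_project, "genotypes_per_project")
  chk_count(n_genes, "n_genes")
  chk_count(n_marker_male, "n_marker_male", min = 0)
  chk_count(n_marker_female, "n_marker_female", min = 0)
  chk_count(n_duplicate_pairs, "n_duplicate_pairs", min = 0)
  if (n_marker_male + n_marker_female >= n_genes)
    bad("n_genes", "must exceed the number of marker genes")
  if (!is.character(tissues) || length(tissues) < 1L)
    bad("tissues", "must be a non-empty character vector")
  if (!is.numeric(viruses) || length(viruses) < 1L ||
      is.null(names(viruses)) || any(!nzchar(names(viruses))) ||
      anyDuplicated(names(viruses)))
    bad("viruses", "must be a named numeric vector with unique names")
  if (any(viruses < 0 | viruses > 1))
    bad("viruses", "prevalences must lie in [0, 1]")
  if (!is.numeric(hop_rate) || length(hop_rate) != 1L ||
      hop_rate < 0 || hop_rate >= 1)
    bad("hop_rate", "must be a single value in [0, 1)")
  chk_pos <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
      bad(field, "must be a single positive number")
  }
  chk_pos(infected_titer_mean, "infected_titer_mean")
  chk_pos(titer_sdlog, "titer_sdlog")
  chk_pos(lib_size_mean, "lib_size_mean")
  chk_pos(lib_size_sdlog, "lib_size_sdlog")
  if (!is.numeric(nb_dispersion) || length(nb_dispersion) != 1L ||
      nb_dispersion < 0)
    bad("nb_dispersion", "must be a single non-negative number")
  if (!is.numeric(group_sd) || length(group_sd) != 1L || group_sd < 0)
    bad("group_sd", "must be a single non-negative number")
  if (!is.logical(marker_leakage) || length(marker_leakage) != 1L)
    bad("marker_leakage", "must be TRUE or FALSE")
  if (2 * n_duplicate_pairs > libraries_per_project)
    bad("n_duplicate_pairs",
        "needs at most libraries_per_project / 2 pairs")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != round(seed) || abs(seed) >= 2^31 - 16)
    bad("seed", "must be a single integer of magnitude below 2^31 - 16")

  effect_model <- .expand_effect_model(effect_model, names(viruses), bad)
  if (!is.list(sex_effect) ||
      !all(c("logfc", "frac_affected") %in% names(sex_effect)))
    bad("sex_effect", "must be a list with 'logfc' and 'frac_affected'")
  if (sex_effect$frac_affected < 0 || sex_effect$frac_affected > 1)
    bad("sex_effect", "'frac_affected' must lie in [0, 1]")

  structure(list(
    n_projects = as.integer(n_projects),
    libraries_per_project = as.integer(libraries_per_project),
    lanes_per_project = as.integer(lanes_per_project),
    genotypes_per_project = as.integer(genotypes_per_project),
    tissues = tissues,
    viruses = viruses,
    hop_rate = hop_rate,
    infected_titer_mean = infected_titer_mean,
    titer_sdlog = titer_sdlog,
    n_genes = as.integer(n_genes),
    n_marker_male = as.integer(n_marker_male),
    n_marker_female = as.integer(n_marker_female),
    nb_dispersion = nb_dispersion,
    effect_model = effect_model,
    sex_effect = sex_effect,
    group_sd = group_sd,
    lib_size_mean = lib_size_mean,
    lib_size_sdlog = lib_size_sdlog,
    marker_leakage = marker_leakage,
    n_duplicate_pairs = as.integer(n_duplicate_pairs),
    seed = as.integer(seed)
  ), class = "sim_config")
}

# recycle a single effect spec across viruses; validate each entry
.expand_effect_model <- function(effect_model, virus_names, bad) {
  needed <- c("logfc", "frac_affected", "interaction_logfc",
              "frac_interaction")
  if (!is.list(effect_model)) bad("effect_model", "must be a list")
  one <- function(e, label) {
    if (!is.list(e) || !all(needed %in% names(e)))
      bad("effect_model",
          sprintf("entry '%s' needs fields %s", label,
                  paste(needed, collapse = ", ")))
    if (e$frac_affected < 0 || e$frac_affected > 1 ||
        e$frac_interaction < 0 || e$frac_interaction > 1)
      bad("effect_model", "affected fractions must lie in [0, 1]")
    e[needed]
  }
  if (all(needed %in% names(effect_model))) {
    em <- rep(list(one(effect_model, "shared")), length(virus_names))
    names(em) <- virus_names
    return(em)
  }
  if (!setequal(names(effect_model), virus_names))
    bad("effect_model",
        "per-virus list must have exactly one entry per virus")
  em <- lapply(virus_names, function(v) one(effect_model[[v]], v))
  names(em) <- virus_names
  em
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d project(s) x %d libraries, %d lane(s)/project, %d genes\n",
    x$n_projects, x$libraries_per_project, x$lanes_per_project, x$n_genes))
  cat(sprintf("  viruses: %s\n",
              paste(sprintf("%s (prev %.2f)", names(x$viruses), x$viruses),
                    collapse = ", ")))
  cat(sprintf("  hop_rate %.4g, titer median %.3g reads, NB dispersion %.3g\n",
              x$hop_rate, x$infected_titer_mean, x$nb_dispersion))
  cat(sprintf("  markers: %d male / %d female (leakage %s), seed %d\n",
              x$n_marker_male, x$n_marker_female,
              ifelse(x$marker_leakage, "on", "off"), x$seed))
  invisible(x)
}
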