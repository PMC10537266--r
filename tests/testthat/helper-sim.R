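# shared small fixtures, built in code

# a small two-project experiment with duplicates; cached per test file
tiny_sim <- function(seed = 11, ...) {
  simulate_experiment(sim_config(
    n_projects = 2, libraries_per_project = 40, lanes_per_project = 2,
    n_genes = 300, viruses = c(DAV = 0.3, nora = 0.2),
    n_duplicate_pairs = 3, seed = seed, ...))
}

sim_markers <- function(sim, which = c("male", "female")) {
  which <- match.arg(which)
  pat <- if (which == "male") "^markerM" else "^markerF"
  grep(pat, rownames(sim$gene_counts), value = TRUE)
}

# brute-force re-evaluation of the presence/absence rule, independent of
# call_infections' vectorised implementation
brute_calls <- function(counts, project, rel = 0.01, abs_thr = 150) {
  out <- matrix(FALSE, nrow(counts), ncol(counts),
                dimnames = dimnames(counts))
  for (p in unique(project)) for (v in seq_len(ncol(counts))) {
    idx <- which(project == p)
    mx <- max(counts[idx, v])
    for (i in idx)
      out[i, v] <- counts[i, v] >= rel * mx && counts[i, v] >= abs_thr
  }
  out
}
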