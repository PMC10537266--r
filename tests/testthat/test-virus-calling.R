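test_that("sex verification applies the fold-margin rule on CPM sums", {
  counts <- cbind(
    male_only = c(m1 = 500, f1 = 0, g1 = 1000),
    both_zero = c(m1 = 0, f1 = 0, g1 = 1000),
    below_margin = c(m1 = 150, f1 = 100, g1 = 1000),
    female_clear = c(m1 = 0, f1 = 400, g1 = 1000))
  sex <- verify_sex(counts, "m1", "f1")
  expect_identical(unname(c(sex)),
                   c("male", "ambiguous", "ambiguous", "female"))
})

test_that("missing markers are dropped with a warning; absent panels error", {
  counts <- rbind(m1 = c(10, 0), f1 = c(0, 10), g = c(5, 5))
  colnames(counts) <- c("a", "b")
  expect_warning(verify_sex(counts, c("m1", "mX"), "f1"), "absent")
  expect_error(suppressWarnings(verify_sex(counts, "zz", "yy")),
               "none of the marker genes")
  expect_error(suppressWarnings(verify_sex(counts, "m1", "yy")), "panel")
})

test_that("presence calls follow the relative-and-floor rule exactly", {
  counts <- cbind(DAV = c(10000, 150, 99), nora = c(20000, 180, 0))
  rownames(counts) <- paste0("lib", 1:3)
  calls <- call_infections(counts)$present
  # 150 reads = 1.5% of the 10,000 max and >= floor -> present
  expect_true(calls["lib2", "DAV"])
  expect_false(calls["lib3", "DAV"])            # 99 < 150-read floor
  # 180 reads >= floor but only 0.9% of the 20,000 max -> absent
  expect_false(calls["lib2", "nora"])
  expect_true(calls["lib1", "DAV"] && calls["lib1", "nora"])
})

test_that("viruses whose maximum is below the floor give all-absent columns", {
  counts <- cbind(v = c(10, 120, 40))
  rownames(counts) <- paste0("l", 1:3)
  expect_false(any(call_infections(counts)$present))
  empty <- call_infections(counts[0, , drop = FALSE])
  expect_identical(dim(empty$present), c(0L, 1L))
})

test_that("calls match a brute-force rule evaluation on random matrices", {
  set.seed(101)
  for (i in 1:100) {
    counts <- matrix(rpois(50 * 5, exp(runif(250, 0, 10))), 50, 5,
                     dimnames = list(paste0("l", 1:50), paste0("v", 1:5)))
    project <- sample(c("P1", "P2"), 50, replace = TRUE)
    meta <- data.frame(library_id = rownames(counts), project = project)
    got <- call_infections(counts, meta)$present
    expect_identical(got, brute_calls(counts, project))
  }
})

test_that("increasing a count never turns a present call absent", {
  set.seed(7)
  counts <- matrix(rpois(60, 3000), 20, 3,
                   dimnames = list(paste0("l", 1:20), paste0("v", 1:3)))
  base <- call_infections(counts)$present
  for (k in 1:30) {
    i <- sample(20, 1); j <- sample(3, 1)
    bumped <- counts
    bumped[i, j] <- bumped[i, j] + sample(1:5000, 1)
    after <- call_infections(bumped)$present
    # the bumped library keeps (or gains) its call
    expect_true(!base[i, j] || after[i, j])
  }
  # and the maximum library is always present when the max >= floor
  mx_lib <- apply(counts, 2, which.max)
  calls <- call_infections(counts)$present
  for (j in 1:3)
    if (max(counts[, j]) >= 150) expect_true(calls[mx_lib[j], j])
})

test_that("threshold selection minimises duplicate discordance, smallest wins ties", {
  # duplicates with identical counts: zero discordance everywhere
  counts <- cbind(v = c(10000, 10000, 300, 300))
  rownames(counts) <- paste0("l", 1:4)
  meta <- data.frame(library_id = rownames(counts), project = "P",
                     duplicate_id = c("d1", "d1", "d2", "d2"))
  sel <- select_abs_threshold(counts, meta,
                              candidate_thresholds = c(50, 150, 500))
  expect_true(all(sel$profile$discordance == 0))
  expect_identical(sel$abs_threshold, 50)

  # hand-evaluated pair: 10 vs 200 reads, virus max 10,000
  counts2 <- cbind(v = c(10000, 10, 200))
  rownames(counts2) <- paste0("l", 1:3)
  meta2 <- data.frame(library_id = rownames(counts2), project = "P",
                      duplicate_id = c(NA, "d1", "d1"))
  sel2 <- select_abs_threshold(counts2, meta2,
                               candidate_thresholds = c(100, 150, 300))
  # at 100 and 150 only the 200-read side passes (discordant);
  # at 300 neither passes (concordant) -> 300 chosen
  expect_identical(sel2$profile$n_discordant, c(1L, 1L, 0L))
  expect_identical(sel2$abs_threshold, 300)

  expect_error(select_abs_threshold(
    counts, transform(meta, duplicate_id = NA), c(50)), "150")
})

test_that("tuned threshold removes hop-only positives but keeps real infections", {
  sim <- simulate_experiment(sim_config(
    n_projects = 1, libraries_per_project = 60, lanes_per_project = 2,
    n_genes = 60, viruses = c(DAV = 0.3, nora = 0.3), hop_rate = 0.002,
    infected_titer_mean = 1e5, titer_sdlog = 0.5,
    n_duplicate_pairs = 10, seed = 31))
  sel <- select_abs_threshold(sim$virus_counts, sim$meta)
  calls <- call_infections(sim$virus_counts, sim$meta,
                           abs_threshold = sel$abs_threshold)$present
  truth <- sim$truth$infection_status
  counts <- sim$virus_counts$counts
  # every planted infection with titre >= 10x the chosen floor is retained
  strong <- truth & counts >= 10 * sel$abs_threshold
  expect_true(all(calls[strong]))
  # >= 95% of hop-only (uninfected, nonzero) entries are rejected
  hop_only <- !truth & counts > 0
  expect_gte(sum(hop_only), 10)
  expect_gte(mean(!calls[hop_only]), 0.95)
})

test_that("default thresholds give full sensitivity at high titres and <1% false positives", {
  sim <- simulate_experiment(sim_config(
    n_projects = 2, libraries_per_project = 50, lanes_per_project = 2,
    n_genes = 40, viruses = c(DAV = 0.3, nora = 0.2), hop_rate = 0.002,
    infected_titer_mean = 1e5, titer_sdlog = 0.5, seed = 17))
  calls <- call_infections(sim$virus_counts, sim$meta)$present
  truth <- sim$truth$infection_status
  high <- truth & sim$virus_counts$counts >= 1e4
  expect_gte(sum(high), 20)
  expect_identical(sum(calls[high]), sum(high))      # sensitivity 1
  expect_lt(mean(calls[!truth]), 0.01)               # FPR < 1%
})

test_that("contaminant clustering groups proportional columns and skips constants", {
  set.seed(5)
  base <- rpois(100, 800)
  counts <- cbind(A = base, B = base, C = 3L * base,
                  D = rpois(100, 800), E = rpois(100, 800),
                  K = rep(0L, 100))
  rownames(counts) <- paste0("l", 1:100)
  expect_warning(res <- flag_contaminant_clusters(counts), "constant")
  expect_identical(res$excluded, "K")
  expect_length(res$clusters, 1)
  expect_setequal(res$clusters[[1]], c("A", "B", "C"))   # A = B = 3C
  expect_equal(res$correlations["A", "B"], 1)
  # independent columns stay unclustered across seeds
  for (s in 1:10) {
    set.seed(s)
    ind <- cbind(X = rpois(100, 500), Y = rpois(100, 500),
                 Z = rpois(100, 500))
    rownames(ind) <- paste0("l", 1:100)
    expect_length(flag_contaminant_clusters(ind)$clusters, 0)
  }
  expect_error(flag_contaminant_clusters(counts[1:2, ]), "3 libraries")
})

test_that("switching rate is the wrong-sex read fraction with exposure correction", {
  # 2 males + 2 females on one lane; marker reads set by hand
  counts <- rbind(
    mk = c(5000, 5000, 5, 5),     # male marker, 5 reads leaked into females
    fk = c(0, 0, 5000, 5000),     # female marker, no leakage
    g1 = c(1e6, 1e6, 1e6, 1e6))
  colnames(counts) <- paste0("l", 1:4)
  sex <- setNames(c("male", "male", "female", "female"), colnames(counts))
  lanes <- setNames(rep("lane1", 4), colnames(counts))
  est <- estimate_switching_rate(counts, sex, "fk", "mk", lanes)
  expect_true(est$estimable)
  expect_identical(est$n_wrong, 10)
  expect_identical(est$n_total, 20010)
  expect_equal(est$rate_raw, 10 / 20010)
  # exposure: each panel has 10010 reads (mk) / 10000 (fk), 2 opposite-sex
  # recipients of 3 lane-mates
  expect_equal(est$exposure, (10010 + 10000) * 2 / 3)
  expect_equal(est$rate, 10 / ((10010 + 10000) * 2 / 3))
  expect_true(est$ci[1] <= est$rate && est$rate <= est$ci[2])

  # no wrong-sex reads -> rate 0
  counts0 <- counts; counts0["mk", 3:4] <- 0
  est0 <- estimate_switching_rate(counts0, sex, "fk", "mk", lanes)
  expect_identical(est0$rate_raw, 0)
  expect_identical(est0$ci[1], 0)

  # single-sex data -> flagged inestimable
  sex1 <- setNames(rep("male", 4), colnames(counts))
  est1 <- estimate_switching_rate(counts, sex1, "fk", "mk", lanes)
  expect_false(est1$estimable)
  expect_true(is.na(est1$rate))
})

test_that("a planted hop rate is recovered inside its confidence interval", {
  hits <- 0; n_sim <- 25
  for (s in seq_len(n_sim)) {
    sim <- simulate_experiment(sim_config(
      n_projects = 1, libraries_per_project = 40, lanes_per_project = 2,
      n_genes = 150, hop_rate = 0.002, seed = 400 + s))
    sx <- verify_sex(sim$gene_counts, sim_markers(sim, "male"),
                     sim_markers(sim, "female"))
    est <- estimate_switching_rate(sim$gene_counts, sx,
                                   sim_markers(sim, "female"),
                                   sim_markers(sim, "male"), sim$meta)
    if (est$ci[1] <= 0.002 && 0.002 <= est$ci[2]) hits <- hits + 1
  }
  expect_gte(hits, ceiling(0.8 * n_sim))   # ~95% nominal coverage
})
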