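test_that("log-CPM round-trips to the normalised counts", {
  set.seed(3)
  counts <- matrix(rpois(200, 50), 20, 10,
                   dimnames = list(paste0("g", 1:20), paste0("l", 1:10)))
  lcpm <- normalize_logcpm(counts, prior_count = 0.5)
  back <- 2^lcpm
  expected <- sweep(counts + 0.5, 2, colSums(counts) + 1, "/") * 1e6
  expect_equal(back, expected, tolerance = 1e-12)
  # proportional libraries give identical log-CPM columns
  two <- cbind(a = counts[, 1], b = 3L * counts[, 1])
  lc2 <- normalize_logcpm(two, prior_count = 0)
  expect_equal(lc2[, 1], lc2[, 2], tolerance = 1e-12)
  # a zero count at prior 0.5 in a library of 1e6 reads: log2 ~ -1
  one <- matrix(c(0, 1e6), 2, 1, dimnames = list(c("z", "big"), "l"))
  expect_equal(normalize_logcpm(one)["z", 1], log2(0.5 / (1e6 + 1) * 1e6),
               tolerance = 1e-12)
})

test_that("the expression filter keeps exactly the genes passing the CPM rule", {
  set.seed(4)
  counts <- matrix(rpois(300, 10), 30, 10,
                   dimnames = list(paste0("g", 1:30), paste0("l", 1:10)))
  counts[1, ] <- 0L                         # all-zero gene
  counts[2, ] <- 5000L                      # strongly expressed gene
  kept <- filter_genes(counts, min_cpm = 1, min_fraction = 0.05)
  expect_false("g1" %in% kept)
  expect_true("g2" %in% kept)
  cpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
  brute <- rownames(counts)[rowMeans(cpm > 1) >= 0.05]
  expect_identical(kept, brute)
})

test_that("design building applies the term-dropping rules", {
  meta <- data.frame(
    library_id = paste0("l", 1:12),
    project = rep(c("P1", "P2"), each = 6),
    genotype = rep(c("g1", "g2"), 6),
    tissue = "whole",
    sex = rep(c("male", "female"), 6))
  pres <- matrix(FALSE, 12, 1, dimnames = list(meta$library_id, "DAV"))
  # virus in both sexes and both projects: full model, grouped
  pres[c(1, 2, 7, 8), 1] <- TRUE
  d <- build_design(meta, pres, "DAV")
  expect_identical(d$terms, c("sex", "virus", "sex:virus"))
  expect_false(is.null(d$group))
  expect_identical(nlevels(d$group), 4L)   # project x genotype
  # virus only in males of a mixed-sex project: virus term only
  pres2 <- pres; pres2[, 1] <- FALSE; pres2[c(1, 3, 7), 1] <- TRUE
  d2 <- build_design(meta, pres2, "DAV")
  expect_identical(d2$terms, "virus")
  # one project, one genotype, one tissue: no random intercept
  meta3 <- meta[1:6, ]; meta3$genotype <- "g1"
  pres3 <- pres[1:6, , drop = FALSE]
  d3 <- build_design(meta3, pres3, "DAV")
  expect_null(d3$group)
  # never-called virus errors
  expect_error(build_design(meta, pres & FALSE, "DAV"), "never called")
  # restriction to projects where the virus occurs
  pres4 <- pres; pres4[7:8, 1] <- FALSE
  d4 <- build_design(meta, pres4, "DAV")
  expect_true(all(grepl("^l([1-6])$", d4$libraries)))
})

test_that("constant expression yields zero effect estimates", {
  X <- cbind("(Intercept)" = 1, virus = rep(c(0, 1), each = 10))
  fit <- fit_gene_model(rep(5, 20), X)
  expect_equal(fit$logFC[fit$coefficient == "virus"], 0)
})

test_that("an unreplicated two-group OLS fit reproduces the classical t-test", {
  set.seed(11)
  g <- rep(c(0, 1), each = 12)
  y <- rnorm(24) + 0.7 * g
  X <- cbind("(Intercept)" = 1, virus = g)
  fit <- fit_gene_model(y, X)
  ref <- t.test(y[g == 1], y[g == 0], var.equal = TRUE)
  row <- fit[fit$coefficient == "virus", ]
  expect_equal(row$logFC, mean(y[g == 1]) - mean(y[g == 0]),
               tolerance = 1e-12)
  expect_equal(row$p, ref$p.value, tolerance = 1e-12)
  expect_equal(row$df, 22)
})

test_that("the REML fit agrees with lmerTest (Satterthwaite) as oracle", {
  skip_if_not_installed("lmerTest")
  set.seed(13)
  for (rep in 1:3) {
    n <- 48
    g <- factor(sample(rep(1:6, each = 8)))
    sex <- factor(rep(c("female", "male"), n / 2),
                  levels = c("female", "male"))
    vir <- rbinom(n, 1, 0.4)
    y <- 0.4 * (sex == "male") + 0.9 * vir +
      rnorm(6, 0, 0.6)[g] + rnorm(n, 0, 0.8)
    X <- cbind("(Intercept)" = 1, sexmale = as.numeric(sex == "male"),
               virus = vir,
               "sexmale:virus" = as.numeric(sex == "male") * vir)
    mine <- fit_gene_model(y, X, g)
    ref <- suppressMessages(
      lmerTest::lmer(y ~ sex * vir + (1 | g), REML = TRUE))
    rs <- coef(summary(ref))
    expect_equal(mine$logFC, unname(rs[, "Estimate"]), tolerance = 1e-4)
    expect_equal(mine$se, unname(rs[, "Std. Error"]), tolerance = 1e-4)
    expect_equal(mine$df, unname(rs[, "df"]), tolerance = 0.05)
    expect_equal(mine$p, unname(rs[, "Pr(>|t|)"]), tolerance = 1e-3)
  }
})

test_that("zero group variance collapses to the OLS fit", {
  set.seed(17)
  g <- factor(rep(1:4, each = 10))
  X <- cbind("(Intercept)" = 1, virus = rep(c(0, 1), 20))
  y <- rnorm(40) + 0.5 * X[, 2]
  y <- y - ave(y, g) + mean(y)           # force equal group means
  mixed <- fit_gene_model(y, X, g)
  plain <- fit_gene_model(y, X)
  expect_equal(mixed$logFC, plain$logFC, tolerance = 1e-6)
  expect_equal(attr(mixed, "lambda"), 0)
})

test_that("variance moderation matches its closed forms and limma as oracle", {
  skip_if_not_installed("limma")
  set.seed(19)
  s2 <- rchisq(800, 10) / 10 * 0.4
  mine <- moderate_variances(s2, 10)
  ref <- limma::squeezeVar(s2, 10)
  expect_equal(mine$df_prior, ref$df.prior, tolerance = 1e-6)
  expect_equal(mine$var_prior, ref$var.prior, tolerance = 1e-6)
  expect_equal(mine$var_post, ref$var.post, tolerance = 1e-8)
  # equal variances are left untouched (degenerate distribution)
  expect_warning(eq <- moderate_variances(rep(0.5, 50), 8), "degenerate")
  expect_equal(eq$var_post, rep(0.5, 50))
  expect_error(moderate_variances(s2[1:5], 10), "at least 10")
})

test_that("moderation recovers planted prior hyperparameters", {
  set.seed(23)
  d0 <- 8; s0 <- 0.25; n <- 5000; d <- 6
  true_var <- d0 * s0 / rchisq(n, d0)          # scaled inverse chi-square
  s2 <- true_var * rchisq(n, d) / d
  est <- moderate_variances(s2, d)
  expect_lt(abs(est$df_prior - d0) / d0, 0.2)
  expect_lt(abs(est$var_prior - s0) / s0, 0.2)
})

test_that("BH adjustment equals the reference step-up on random vectors", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(adjust_bh(0.42), 0.42)
  expect_error(adjust_bh(c(0.1, 1.2)), "0, 1")
  set.seed(29)
  for (i in 1:200) {
    p <- runif(sample(1:80, 1))
    expect_equal(adjust_bh(p), p.adjust(p, "BH"), tolerance = 1e-14)
  }
  # permutation equivariance
  p <- runif(30); perm <- sample(30)
  expect_equal(adjust_bh(p)[perm], adjust_bh(p[perm]))
})

test_that("DE classification applies the logFC and adjusted-p cutoffs", {
  res <- data.frame(logFC = c(0.6, 0.6, -2, 0.4, -0.5),
                    p_adj = c(5e-4, 0.01, 1e-6, 1e-6, 1e-6))
  cls <- classify_de(res)$de_class
  expect_identical(as.character(cls), c("up", "ns", "down", "ns", "ns"))
})

test_that("null data produce calibrated raw p-values for the virus term", {
  sim <- simulate_experiment(sim_config(
    n_projects = 1, libraries_per_project = 100, n_genes = 400,
    viruses = c(DAV = 0.4), hop_rate = 0,
    effect_model = list(logfc = 0, frac_affected = 0,
                        interaction_logfc = 0, frac_interaction = 0),
    sex_effect = list(logfc = 0, frac_affected = 0), seed = 47))
  calls <- sim$truth$infection_status
  res <- run_de(sim$gene_counts, sim$meta, calls, "DAV",
                moderation = FALSE)
  pv <- res$p[res$coefficient == "virus"]
  fpr <- mean(pv < 0.05)
  se <- sqrt(0.05 * 0.95 / length(pv))
  expect_lt(abs(fpr - 0.05), 3 * se + 0.01)
})

test_that("run_de output is complete, reproducible and internally consistent", {
  sim <- tiny_sim(seed = 51)
  calls <- call_infections(sim$virus_counts, sim$meta)
  res1 <- run_de(sim$gene_counts, sim$meta, calls, "DAV")
  res2 <- run_de(sim$gene_counts, sim$meta, calls, "DAV")
  expect_identical(res1, res2)
  expect_setequal(unique(res1$coefficient),
                  c("sexmale", "virus", "sexmale:virus"))
  # BH within coefficient, classification rule holds
  for (co in unique(res1$coefficient)) {
    sub <- res1[res1$coefficient == co, ]
    expect_equal(sub$p_adj, adjust_bh(sub$p))
    expect_identical(sub$de_class == "up",
                     sub$logFC > 0.5 & sub$p_adj < 0.001)
  }
})
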