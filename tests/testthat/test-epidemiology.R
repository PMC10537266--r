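make_calls <- function(pos_a, pos_b, both, n, va = "A", vb = "B",
                       project = "P1") {
  stopifnot(both <= pos_a, both <= pos_b)
  pres <- matrix(FALSE, n, 2,
                 dimnames = list(sprintf("l%04d", 1:n), c(va, vb)))
  pres[seq_len(pos_a), 1] <- TRUE
  pres[c(seq_len(both), pos_a + seq_len(pos_b - both)), 2] <- TRUE
  meta <- data.frame(library_id = rownames(pres), project = project)
  list(present = pres, meta = meta)
}

test_that("prevalence estimates reproduce screening worked examples", {
  x <- make_calls(10, 31, 4, 778)
  prev <- estimate_prevalence(x$present, x$meta)
  dav <- prev[prev$virus == "A", ]
  expect_identical(dav$k, 10L)
  expect_equal(round(100 * dav$p_hat, 1), 1.3)
  y <- make_calls(39, 5, 2, 396)
  prev2 <- estimate_prevalence(y$present, y$meta)
  expect_equal(round(100 * prev2$p_hat[prev2$virus == "A"], 1), 9.8)
})

test_that("prevalence intervals are Clopper-Pearson, checked against binom.test", {
  x <- make_calls(39, 10, 3, 396)
  prev <- estimate_prevalence(x$present, x$meta)
  for (i in seq_len(nrow(prev))) {
    ref <- binom.test(prev$k[i], prev$n[i])$conf.int
    expect_equal(prev$ci_low[i], ref[1], tolerance = 1e-12)
    expect_equal(prev$ci_high[i], ref[2], tolerance = 1e-12)
  }
  expect_true(all(prev$ci_low <= prev$p_hat & prev$p_hat <= prev$ci_high))
  # zero positives: lower bound 0, row only with include_zero
  z <- make_calls(0, 1, 0, 100)
  prev0 <- estimate_prevalence(z$present, z$meta, include_zero = TRUE)
  a <- prev0[prev0$virus == "A", ]
  expect_identical(a$k, 0L)
  expect_identical(a$ci_low, 0)
})

test_that("prevalence interval coverage is at least nominal", {
  set.seed(19)
  cover <- 0; nsim <- 2000
  for (i in seq_len(nsim)) {
    k <- rbinom(1, 100, 0.05)
    lo <- if (k == 0) 0 else qbeta(0.025, k, 100 - k + 1)
    hi <- if (k == 100) 1 else qbeta(0.975, k + 1, 100 - k)
    cover <- cover + (lo <= 0.05 && 0.05 <= hi)
  }
  expect_gte(cover / nsim, 0.95)
})

test_that("coinfection tables cross-tabulate calls and sum to the project total", {
  x <- make_calls(10, 31, 4, 778)
  tb <- coinfection_table(x$present, x$meta, "A", "B", "P1")
  expect_identical(c(tb$n11, tb$n10, tb$n01, tb$n00), c(4L, 6L, 27L, 741L))
  expect_identical(tb$n11 + tb$n10 + tb$n01 + tb$n00, 778L)
  expect_error(coinfection_table(x$present, x$meta, "A", "Z", "P1"), "Z")
  # random matrices against a brute-force tally
  set.seed(23)
  for (i in 1:20) {
    pres <- matrix(runif(60) < 0.3, 30, 2,
                   dimnames = list(paste0("l", 1:30), c("A", "B")))
    meta <- data.frame(library_id = rownames(pres), project = "P")
    tb <- coinfection_table(pres, meta, "A", "B", "P")
    expect_identical(tb$n11, sum(pres[, 1] & pres[, 2]))
    expect_identical(tb$n00, sum(!pres[, 1] & !pres[, 2]))
  }
})

test_that("exact test handles degenerate and symmetric tables", {
  expect_equal(fisher_exact(list(n11 = 1, n10 = 1, n01 = 1, n00 = 1))$p_value, 1)
  expect_equal(fisher_exact(list(n11 = 0, n10 = 0, n01 = 5, n00 = 5))$p_value, 1)
  expect_error(fisher_exact(list(n11 = -1, n10 = 1, n01 = 1, n00 = 1)),
               "non-negative")
  # odds ratio conventions
  expect_identical(fisher_exact(list(n11 = 3, n10 = 0, n01 = 2, n00 = 4))$odds_ratio, Inf)
  expect_equal(fisher_exact(list(n11 = 4, n10 = 2, n01 = 2, n00 = 4))$odds_ratio, 4)
})

test_that("exact test is invariant to transposition and label swaps", {
  set.seed(31)
  for (i in 1:50) {
    cells <- rpois(4, 6)
    p1 <- fisher_exact(list(n11 = cells[1], n10 = cells[2],
                            n01 = cells[3], n00 = cells[4]))$p_value
    # swap rows with columns (transpose)
    p2 <- fisher_exact(list(n11 = cells[1], n10 = cells[3],
                            n01 = cells[2], n00 = cells[4]))$p_value
    # relabel both viruses (swap presence/absence of both)
    p3 <- fisher_exact(list(n11 = cells[4], n10 = cells[3],
                            n01 = cells[2], n00 = cells[1]))$p_value
    expect_equal(p1, p2, tolerance = 1e-12)
    expect_equal(p1, p3, tolerance = 1e-12)
  }
})

test_that("exact test matches the reference enumeration on random tables", {
  set.seed(37)
  for (i in 1:500) {
    cells <- rpois(4, sample(c(2, 5, 12), 1))
    mine <- fisher_exact(list(n11 = cells[1], n10 = cells[2],
                              n01 = cells[3], n00 = cells[4]))
    ref <- fisher.test(matrix(cells, 2, byrow = TRUE))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
  # one-sided tails against phyper
  tb <- list(n11 = 8, n10 = 4, n01 = 3, n00 = 10)
  expect_equal(fisher_exact(tb, alternative = "greater")$p_value,
               phyper(7, 11, 14, 12, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(fisher_exact(tb, alternative = "less")$p_value,
               phyper(8, 11, 14, 12), tolerance = 1e-12)
})

test_that("exact p-values stay in (0, 1] and are conservative under the null", {
  set.seed(41)
  flags <- 0; nsim <- 400; alpha <- 0.05
  for (i in seq_len(nsim)) {
    a <- rbinom(500, 1, 0.1) == 1
    b <- rbinom(500, 1, 0.2) == 1
    p <- fisher_exact(list(n11 = sum(a & b), n10 = sum(a & !b),
                           n01 = sum(!a & b), n00 = sum(!a & !b)))$p_value
    expect_gt(p, 0); expect_lte(p, 1)
    flags <- flags + (p < alpha)
  }
  se <- sqrt(alpha * (1 - alpha) / nsim)
  expect_lte(flags / nsim, alpha + 3 * se)   # conservative, never anti-
  expect_gte(flags / nsim, alpha / 5)        # ...but not vacuously so
})

test_that("the co-infection scan tests every pair and flags at raw alpha", {
  x <- make_calls(24, 39, 7, 396, va = "DAV", vb = "Thika")
  scan <- coinfection_scan(x$present, x$meta, alpha = 0.01)
  expect_identical(nrow(scan), 1L)
  expect_true(scan$significant)
  expect_equal(signif(scan$p_value, 1), 5e-3)
  # single called virus -> empty result
  solo <- x$present[, 1, drop = FALSE]
  expect_identical(nrow(coinfection_scan(solo, x$meta)), 0L)
  # three viruses -> three pairs
  pres3 <- cbind(x$present, C = rep(c(TRUE, FALSE), length.out = 396))
  expect_identical(nrow(coinfection_scan(pres3, x$meta)), 3L)
})
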