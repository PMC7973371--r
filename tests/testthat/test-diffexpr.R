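test_that("low-count filter keeps genes meeting the threshold in enough samples", {
  # 8 samples, smallest group 4: >= 10 reads in exactly 4 samples is kept,
  # in exactly 3 is removed; all-zero genes always go
  cts <- rbind(
    kept    = c(12, 11, 10, 10, 0, 0, 0, 0),
    removed = c(12, 11, 10, 9, 0, 0, 0, 0),
    zero    = rep(0, 8),
    high    = rep(50, 8))
  colnames(cts) <- sprintf("s%d", 1:8)
  smp <- data.frame(sample_id = colnames(cts),
                    condition = rep(c("disease", "control"), each = 4),
                    timepoint = 15, replicate = rep(1:4, 2))
  x <- counts_table(cts, smp)
  f <- filter_low_counts(x, min_count = 10)
  expect_setequal(rownames(f$counts), c("kept", "high"))
  expect_equal(ncol(f$counts), 8L)

  # min_count = 0 is vacuous
  f0 <- filter_low_counts(x, min_count = 0)
  expect_equal(rownames(f0$counts), rownames(cts))
})

test_that("counts table validation rejects bad input", {
  cts <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  smp <- data.frame(sample_id = c("s1", "s2"), condition = c("disease", "control"),
                    timepoint = 10, replicate = 1)
  expect_silent(counts_table(cts, smp))
  bad <- cts; bad[1, 2] <- -1
  expect_error(counts_table(bad, smp), "g1.*s2")
  expect_error(counts_table(cts, smp[1, , drop = FALSE]), "s2")
  dup <- rbind(cts, cts); rownames(dup) <- c("g1", "g1", "g2", "g2")
  expect_error(counts_table(dup, smp), "duplicate")
})

test_that("identical disease and control columns yield zero fold changes and no calls", {
  set.seed(3)
  base <- matrix(rnbinom(200 * 4, mu = 100, size = 10), 200, 4)
  cts <- cbind(base, base)
  rownames(cts) <- sprintf("g%03d", 1:200)
  colnames(cts) <- sprintf("s%d", 1:8)
  smp <- data.frame(sample_id = colnames(cts),
                    condition = rep(c("disease", "control"), each = 4),
                    timepoint = 15, replicate = rep(1:4, 2))
  de <- test_differential(counts_table(cts, smp), 15)
  expect_true(all(de$log2fc == 0))
  expect_true(all(de$call == "ns"))
  expect_true(all(de$p == 1))
})

test_that("null simulations control the false-call rate at FDR 0.01", {
  called <- 0L
  total <- 0L
  for (seed in 1:20) {
    x <- toy_counts(mu_d = numeric(0), mu_c = numeric(0), extra_null = 2000,
                    seed = 5000 + seed)
    de <- test_differential(x, 15)
    called <- called + sum(de$call != "ns")
    total <- total + nrow(de)
  }
  expect_lte(called / total, 0.025)
})

test_that("a strongly planted gene is detected with high power", {
  # log2fc = +3 at mu = 500, phi = 0.1, 4 vs 4: Monte-Carlo over 500
  # independent replicates of the planted gene
  hits <- 0L
  for (seed in 1:5) {
    x <- toy_counts(mu_d = rep(500 * 8, 100), mu_c = rep(500, 100),
                    extra_null = 400, seed = 300 + seed)
    de <- test_differential(x, 15)
    hits <- hits + sum(de$call[1:100] == "induced")
  }
  expect_gte(hits / 500, 0.95)
})

test_that("results are invariant to gene row order", {
  x <- toy_counts(mu_d = c(800, 100), mu_c = c(100, 100), extra_null = 50, seed = 11)
  de1 <- test_differential(x, 15)
  perm <- sample(nrow(x$counts))
  xp <- counts_table(x$counts[perm, ], x$samples)
  de2 <- test_differential(xp, 15)
  de2 <- de2[match(de1$gene, de2$gene), ]
  expect_equal(de1$p, de2$p)
  expect_equal(de1$fdr, de2$fdr)
  expect_equal(de1$call, de2$call)
})

test_that("BH adjustment matches hand-worked and closed-form references", {
  expect_equal(adjust_bh(0.04), 0.04)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(c(1, 1)), c(1, 1))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(8)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjust_bh(p), oracle_bh(p))
  }
})

test_that("fdr is never below p and calls respect both thresholds", {
  x <- toy_counts(mu_d = c(2000, 400, 150), mu_c = c(100, 100, 100),
                  extra_null = 300, seed = 21)
  de <- test_differential(x, 15)
  expect_true(all(de$fdr >= de$p - 1e-12))
  ind <- de$call == "induced"
  expect_true(all(de$fdr[ind] < 0.01 & de$log2fc[ind] >= 1))
  rep_ <- de$call == "repressed"
  expect_true(all(de$fdr[rep_] < 0.01 & de$log2fc[rep_] <= -1))
})

test_that("external DE tables are accepted in place of the built-in test", {
  de <- data.frame(gene = c("a", "b"), log2fc = c(2.5, 0.2),
                   p = c(1e-6, 0.4), fdr = c(2e-6, 0.5))
  out <- call_de_table(de, timepoint = 10)
  expect_equal(out$call, c("induced", "ns"))
  bad <- de; bad$fdr[1] <- 1e-9
  expect_error(call_de_table(bad, timepoint = 10), "fdr")
})
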