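test_that("low-count filter is inclusive at the threshold", {
  m <- matrix(c(rep(20, 6),       # mean exactly 20 -> removed
                c(21, 20, 21, 20, 21, 20),  # mean 20.5 -> retained
                rep(0, 6)),       # all zero -> removed
              nrow = 3, byrow = TRUE,
              dimnames = list(c("at", "above", "zero"), paste0("s", 1:6)))
  x <- count_matrix(m, tiny_counts()$meta)
  f <- filter_low_counts(x)
  expect_identical(rownames(f$counts), "above")
  expect_setequal(attr(f, "removed"), c("at", "zero"))
  expect_error(filter_low_counts(count_matrix(m[0, , drop = FALSE],
                                              tiny_counts()$meta)), "empty")
})

test_that("median-of-ratios size factors behave on canonical fixtures", {
  set.seed(3)
  base <- matrix(rpois(50 * 4, 100), 50, 4,
                 dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  expect_equal(unname(size_factors(cbind(base[, 1], base[, 1], base[, 1]))),
               rep(1, 3))
  doubled <- base
  doubled[, 2] <- base[, 2] * 2
  sf <- size_factors(doubled)
  # brute-force median-of-ratios oracle
  ref <- exp(rowMeans(log(doubled)))
  oracle <- apply(doubled, 2, function(col) median(col / ref))
  expect_equal(unname(sf), unname(oracle))
  expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 0.05)
  expect_equal(unname(size_factors(base[, 1, drop = FALSE])), 1)
  allzero <- base; allzero[, 1] <- 0
  expect_error(size_factors(allzero), "no gene positive")
})

test_that("BH adjustment matches hand computation and stays monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  for (i in 1:25) {
    p <- runif(sample(1:80, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_brute(p))
    expect_true(all(diff(sort(adj)[order(order(sort(p)))]) >= -1e-12))
    expect_true(all(adj >= p))
  }
})

test_that("DEG status thresholds are strict on |log2FC|, inclusive on FDR", {
  expect_equal(call_deg_status(1.0, 0.001), "ns")
  expect_equal(call_deg_status(-1.2, 0.05), "down")
  expect_equal(call_deg_status(2.0, 0.06), "ns")
  expect_equal(call_deg_status(1.0001, 0.05), "up")
  expect_error(call_deg_status(Inf, 0.01), "finite")
  # exhaustive and mutually exclusive over a grid
  g <- expand.grid(lfc = seq(-3, 3, by = 0.25), fdr = seq(0, 1, by = 0.05))
  st <- call_deg_status(g$lfc, g$fdr)
  expect_true(all(st %in% c("up", "down", "ns")))
  expect_equal(sum(st == "up"), sum(g$lfc > 1 & g$fdr <= 0.05))
  expect_equal(sum(st == "down"), sum(g$lfc < -1 & g$fdr <= 0.05))
})

test_that("NB Wald contrast is calibrated on nulls and recovers planted effects", {
  # identical groups, large counts: p-values near-uniform
  cfg <- sim_config(seed = 42, n_genes = 2000, timepoints = c(0, 14),
                    n_replicates = 10, baseline_meanlog = log(2000),
                    baseline_sdlog = 0.3, program_fractions = c(late_up = 0))
  s <- simulate_timecourse_counts(cfg)
  res <- test_contrast(filter_low_counts(s$counts), 14)
  expect_gt(stats::ks.test(res$p, "punif")$p.value, 0.01)

  # planted 4-fold increase, dispersion 0.02, baseline 1000:
  # median estimated log2FC within +/- 0.2 of 2
  cfg2 <- sim_config(seed = 43, n_genes = 600, timepoints = c(0, 14),
                     baseline_meanlog = log(1000), baseline_sdlog = 0,
                     dispersion = 0.02, effect_size = 2,
                     program_fractions = c(late_up = 0.05, late_down = 0.05))
  s2 <- simulate_timecourse_counts(cfg2)
  d2 <- call_degs(s2$counts)
  up <- s2$truth$gene_id[s2$truth$program == "late" & s2$truth$direction == 1]
  expect_lt(abs(median(d2$log2FC[d2$gene_id %in% up & d2$timepoint == 14]) - 2),
            0.2)

  # gene removed by the filter yields no result row
  expect_false(any(attr(d2, "removed") %in% d2$gene_id))

  expect_error(test_contrast(tiny_counts(), 7), "replicates")
})

test_that("log2FC estimation is equivariant to doubling one group", {
  # noiseless fixture: exact integer counts, zero dispersion
  m0 <- matrix(rep(c(100, 200, 400, 800), each = 6), nrow = 4, byrow = TRUE,
               dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  meta <- tiny_counts()$meta
  x1 <- count_matrix(m0, meta)
  m2 <- m0
  m2[, meta$timepoint == 14] <- m0[, meta$timepoint == 14] * 2
  x2 <- count_matrix(m2, meta)
  sf1 <- setNames(rep(1, 6), colnames(m0))
  r1 <- test_contrast(x1, 14, sf = sf1)
  r2 <- test_contrast(x2, 14, sf = sf1)
  expect_equal(median(r2$log2FC - r1$log2FC), 1, tolerance = 0.1)
})

test_that("FPKM ratio log2FC follows the closed form", {
  expect_equal(fpkm_log2fc(8, 2, 0), 2)
  expect_equal(fpkm_log2fc(7.3, 7.3, 0), 0)
  expect_error(fpkm_log2fc(5, 0, 0), "mock")
  expect_equal(fpkm_log2fc(5, 0, 1), log2(6))
  expect_error(fpkm_log2fc(-1, 2, 0), ">= 0")
})
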