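test_that("config validation rejects impossible worlds", {
  expect_error(sim_config(program_fractions = c(late_up = 0.7, late_down = 0.5)),
               "sum")
  expect_error(sim_config(coreg_correlation = 1.5), "correlation")
  expect_error(sim_config(n_replicates = 0), "replicate")
  expect_error(sim_config(timepoints = c(1, 7)), "reference")
  expect_error(sim_config(expansion_spec = list(list(family = "PR-2", size = 40))),
               "exceeds family size")
})

test_that("all three generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 99, n_genes = 60)
  a <- simulate_timecourse_counts(cfg)
  b <- simulate_timecourse_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)

  ha <- simulate_hormone_pair(cfg)
  hb <- simulate_hormone_pair(cfg)
  expect_identical(ha$sa$counts, hb$sa$counts)
  expect_identical(ha$ja$counts, hb$ja$counts)

  fa <- simulate_family_structure(cfg)
  fb <- simulate_family_structure(cfg)
  expect_identical(fa$newick, fb$newick)
  expect_identical(as.data.frame(fa$catalog), as.data.frame(fb$catalog))

  # different seed changes the draws
  c2 <- simulate_timecourse_counts(sim_config(seed = 100, n_genes = 60))
  expect_false(identical(a$counts$counts, c2$counts$counts))
})

test_that("null counts match NB(mu, alpha) moments within 3 SE", {
  n <- 10000
  cfg <- sim_config(seed = 5, n_genes = n, baseline_meanlog = log(400),
                    baseline_sdlog = 0, dispersion = 0.1,
                    timepoints = c(0, 1), n_replicates = 1,
                    size_factor_range = c(1, 1),
                    program_fractions = c(late_up = 0))
  sim <- simulate_timecourse_counts(cfg)
  x <- as.numeric(sim$counts$counts[, 1])
  mu <- 400; alpha <- 0.1
  v <- mu + alpha * mu^2
  se_mean <- sqrt(v / n)
  expect_lt(abs(mean(x) - mu), 3 * se_mean)
  # SE of the sample variance via the NB kurtosis-free bound 2v^2/(n-1) is
  # optimistic for skewed counts; use the moment-based SE from the data
  se_var <- stats::sd((x - mean(x))^2) / sqrt(n)
  expect_lt(abs(stats::var(x) - v), 3 * se_var)
})

test_that("planted programs are realized exactly in the expected-value profile", {
  cfg <- sim_config(seed = 8, n_genes = 200)
  sim <- simulate_timecourse_counts(cfg)
  tr <- sim$truth
  lfc <- as.matrix(tr[grep("^lfc_", names(tr))])
  active <- lfc != 0
  windows <- list(early = c("lfc_1", "lfc_7"), late = c("lfc_14", "lfc_22"),
                  sustained = c("lfc_1", "lfc_7", "lfc_14", "lfc_22"),
                  none = character(0))
  for (i in seq_len(nrow(tr))) {
    expect_setequal(colnames(lfc)[active[i, ]], windows[[tr$program[i]]])
    if (tr$program[i] != "none") {
      expect_true(all(sign(lfc[i, active[i, ]]) == tr$direction[i]))
      expect_true(all(abs(lfc[i, active[i, ]]) == cfg$effect_size))
    }
  }
  # fraction bookkeeping: planted counts are the rounded fractions
  expect_equal(sum(tr$program != "none"),
               sum(round(cfg$program_fractions * cfg$n_genes)))
})

test_that("hormone pair plants the configured co-regulation structure", {
  cfg <- sim_config(seed = 21, n_genes = 500, coreg_correlation = 1)
  h <- simulate_hormone_pair(cfg)
  co <- h$truth[h$truth$hormone_program == "co_regulated", ]
  # rho = 1 makes the planted SA and JA effects identical
  expect_equal(cor(co$true_sa, co$true_ja), 1)
  rec <- h$truth[h$truth$hormone_program == "reciprocal", ]
  expect_true(all(sign(rec$true_sa) == -sign(rec$true_ja)))
  sa_only <- h$truth[h$truth$hormone_program == "sa_only", ]
  expect_true(all(sa_only$true_ja == 0))
  expect_true(all(abs(sa_only$true_sa) > 0))
})

test_that("family structure plants expansions and arrays as specified", {
  cfg <- sim_config(seed = 31)
  fs <- simulate_family_structure(cfg)
  # one 3-tip clade in PR-2, one 20-tip clade in PR-15/16, nothing else
  ex2 <- detect_expansions(fs$trees[["PR-2"]], "Mes", family = "PR-2")
  expect_equal(nrow(ex2), 1)
  expect_equal(ex2$size, 3)
  ex15 <- detect_expansions(fs$trees[["PR-15/16"]], "Mes", family = "PR-15/16")
  expect_equal(ex15$size, 20)
  truth2 <- fs$truth[!is.na(fs$truth$expansion) & fs$truth$family == "PR-2", ]
  expect_equal(ex2$members, paste(sort(truth2$gene_id), collapse = ","))

  # a 2-tip focal clade is below the minimum size: no expansion
  cfg2 <- sim_config(seed = 31,
                     families = list(list(label = "PR-4", size = 5)),
                     expansion_spec = list(list(family = "PR-4", size = 2)),
                     cluster_spec = list())
  fs2 <- simulate_family_structure(cfg2)
  expect_equal(nrow(detect_expansions(fs2$trees[[1]], "Mes")), 0)
})
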