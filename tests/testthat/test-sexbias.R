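test_that("ratio histograms bin correctly and conserve gene counts", {
  rec <- tibble::tibble(chromosome = "chr2", mean_expr = 5,
                        mf_ratio = c(1.013, 1.019, 0.999, 1.02))
  h <- ratio_histogram(rec, bin_width = 0.02)
  expect_equal(h$n[h$bin_start == 1.00], 2)     # 1.013 and 1.019 in [1.00, 1.02)
  expect_equal(h$n[h$bin_start == 0.98], 1)
  expect_equal(h$n[h$bin_start == 1.02], 1)     # boundary value starts a new bin
  expect_equal(sum(h$n), 4)

  same <- tibble::tibble(chromosome = "X", mean_expr = 2, mf_ratio = rep(0.97, 9))
  expect_equal(nrow(ratio_histogram(same)), 1)

  set.seed(81)
  rec2 <- tibble::tibble(chromosome = sample(c("X", "chr2"), 60, TRUE),
                         mean_expr = runif(60, 0, 10),
                         mf_ratio = c(rlnorm(55, 0, 0.3), rep(NA, 5)))
  h2 <- ratio_histogram(rec2, threshold = 2)
  kept <- rec2[rec2$mean_expr >= 2, ]
  expect_equal(sum(h2$n), sum(!is.na(kept$mf_ratio)))
  expect_equal(attr(h2, "n_undefined"), sum(is.na(kept$mf_ratio)))
  # permutation invariance
  h3 <- ratio_histogram(rec2[sample(60), ], threshold = 2)
  expect_equal(as.data.frame(h3), as.data.frame(h2))
})

test_that("BH q-values reproduce the step-up rule", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_qvalues(0.37), 0.37)
  set.seed(91)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_qvalues(p), oracle_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("bias classification applies the q and fold rules jointly", {
  ann <- ann_tbl(paste0("g", 1:5), c("X", "chr2", "chr3", "chr2", "X"))
  e <- expr_tbl(ann$gene_id,
                M = c(1.6, 1.4, 0.5, 1.0, 2.0),
                F = c(1.0, 1.0, 1.0, 1.0, 0.0))
  q <- tibble::tibble(gene_id = ann$gene_id,
                      q_value = c(0.001, 0.001, 0.5, 0.9, 0.0001))
  rec <- classify_bias(e, ann, "M", "F", external_q = q)
  expect_equal(rec$bias_class,
               c("male_biased",    # fold 1.6, q 0.001
                 "unbiased",       # fold 1.4 fails the 1.5x rule
                 "unbiased",       # fold 0.5 but q 0.5 fails
                 "unbiased",
                 "male_biased"))   # zero female expression, significant q
  expect_true(is.na(rec$mf_fold[5]))
  # each gene gets exactly one class
  expect_true(all(table(rec$gene_id) == 1))
  expect_true(all(rec$bias_class %in%
                    c("male_biased", "female_biased", "unbiased", "undefined")))

  # female-biased side
  ef <- expr_tbl(ann$gene_id, M = c(0.5, 1, 1, 1, 1), F = rep(1, 5))
  recf <- classify_bias(ef, ann, "M", "F",
                        external_q = tibble::tibble(gene_id = ann$gene_id,
                                                    q_value = rep(1e-4, 5)))
  expect_equal(recf$bias_class[1], "female_biased")

  expect_error(classify_bias(e, ann, "M", "F"), ">= 2 replicates")
})

test_that("the in-house moderated test recovers strongly sex-biased genes", {
  sim <- simulate_dataset(sim_config(
    n_genes = c(chr2 = 1000, chr3 = 800, X = 250),
    sex_bias = list(male_fraction = 0.08, female_fraction = 0.08,
                    effect_law = list(meanlog2 = 2.5, sdlog2 = 0.5)),
    samples = sim_samples(3), seed = 13))
  expr <- normalize_rpkm(sim$counts, sim$annotation, "uq")
  rec <- classify_bias(expr, sim$annotation, c("M1", "M2", "M3"),
                       c("F1", "F2", "F3"))
  truth <- sim$truth
  planted <- sum(truth$bias_class != "unbiased" & truth$active)
  found <- sum(rec$bias_class %in% c("male_biased", "female_biased"))
  expect_gt(found, 0.5 * planted)
  expect_lt(found, 1.5 * planted)
  # direction agrees for confidently called active genes
  both <- dplyr::inner_join(rec, truth, by = "gene_id")
  called <- both[both$bias_class.x %in% c("male_biased", "female_biased") &
                   both$active, ]
  expect_gt(mean(called$bias_class.x == called$bias_class.y), 0.95)
})

test_that("Fisher enrichment matches exhaustive enumeration and flags degeneracy", {
  enr <- fisher_enrichment(records_from_table(3, 1, 1, 3))
  expect_equal(enr$p_value, 0.4857, tolerance = 1e-3)
  expect_equal(enr$p_value, oracle_fisher_p(enr$table), tolerance = 1e-10)
  expect_equal(enr$odds_ratio, 9)

  prop <- fisher_enrichment(records_from_table(2, 4, 3, 6))
  expect_equal(prop$p_value, 1.0)

  set.seed(101)
  for (i in 1:40) {
    repeat {
      cell <- as.vector(stats::rmultinom(1, sample(8:60, 1), rep(0.25, 4)))
      if (sum(cell[c(1, 3)]) > 0 && sum(cell[c(2, 4)]) > 0) break
    }
    got <- fisher_enrichment(records_from_table(cell[1], cell[2], cell[3], cell[4]))
    expect_equal(got$p_value, oracle_fisher_p(got$table), tolerance = 1e-10)
  }

  degen <- fisher_enrichment(records_from_table(0, 3, 2, 3))
  expect_equal(degen$note, "degenerate_odds_ratio")
  expect_error(fisher_enrichment(records_from_table(0, 0, 0, 0)), "no sex-biased")

  td <- tidy(enr)
  expect_equal(sum(td$n), 8)
  gl <- glance(enr)
  expect_equal(gl$n_biased, 8)
})

test_that("rank-sum set comparison is exact for small sets and honest for ties", {
  same <- compare_ratio_sets(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1.0)
  expect_equal(same$method, "exact_enumeration")

  sep <- compare_ratio_sets(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$statistic, 0)
  expect_equal(sep$p_value, 0.1)            # 2 / choose(6, 3)

  set.seed(111)
  big <- compare_ratio_sets(rnorm(30), rnorm(30) + 1)
  expect_equal(big$method, "normal_approximation")
  expect_lt(big$p_value, 0.01)
  expect_error(compare_ratio_sets(1, c(1, 2)), "at least 2")
})

test_that("replicate correlations are Spearman with mid-ranked ties", {
  e <- expr_tbl(paste0("g", 1:6), a = c(1, 2, 3, 4, 5, 6),
                b = c(6, 5, 4, 3, 2, 1), c = c(2, 4, 6, 8, 10, 12))
  rho <- replicate_correlation(e)
  expect_equal(rho["a", "a"], 1)
  expect_equal(rho["a", "b"], -1)
  expect_equal(rho["a", "c"], 1)

  set.seed(121)
  x <- rnorm(50)
  y <- x + rnorm(50)
  e2 <- expr_tbl(sprintf("g%02d", 1:50), a = x, b = y)
  expect_equal(replicate_correlation(e2)["a", "b"], oracle_spearman(x, y),
               tolerance = 1e-10)

  const <- expr_tbl(paste0("g", 1:4), a = 1:4, b = rep(2, 4))
  expect_true(is.na(replicate_correlation(const)["a", "b"]))
})
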