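test_that("threshold selection is inclusive, monotone and scope-aware", {
  e <- expr_tbl(paste0("g", 1:4), a = c(0, 0.5, 1, 5), b = c(2, 2, 0, 0))
  expect_equal(select_genes(e, 0)$a, paste0("g", 1:4))
  expect_equal(select_genes(e, 1)$a, c("g3", "g4"))        # 0.5 excluded at 1.0
  expect_true("g3" %in% select_genes(e, 1)$a)              # boundary included
  expect_equal(select_genes(e, 1, "mean_over_samples"), c("g1", "g2", "g4"))
  # raising the threshold never adds genes
  sets <- lapply(c(0, 0.5, 1, 2, 5), function(th) select_genes(e, th)$a)
  for (i in seq_along(sets)[-1]) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("chromosome ratios equal hand medians and an independent oracle", {
  ann <- ann_tbl(paste0("g", 1:7), c(rep("X", 3), rep("chr2", 2), rep("chr3", 2)))
  e <- expr_tbl(ann$gene_id, s = c(2, 4, 6, 2, 4, 6, 8))
  r <- chrom_ratio(e, ann, "s", "X:A")
  expect_equal(r$estimate, 4 / 5)            # median{2,4,6} / median{2,4,6,8}
  expect_equal(r$n_num, 3)
  expect_equal(r$n_den, 4)

  ident <- chrom_ratio(e, ann, "s", numerator = c("chr2", "chr3"),
                       denominator = c("chr2", "chr3"))
  expect_equal(ident$estimate, 1.0)

  # global rescaling cancels
  e2 <- dplyr::mutate(e, s = s * 13.7)
  expect_equal(chrom_ratio(e2, ann, "s", "X:A")$estimate, r$estimate)

  set.seed(31)
  for (i in 1:50) {
    fx <- random_ratio_fixture(12)
    got <- chrom_ratio(fx$expr, fx$ann, "s1", "X:A")$estimate
    v <- fx$expr$s1
    want <- oracle_median(v[fx$ann$chromosome == "X"]) /
      oracle_median(v[fx$ann$chromosome %in% c("chr2", "chr3")])
    expect_equal(got, want, tolerance = 1e-12)
    got32 <- chrom_ratio(fx$expr, fx$ann, "s1", "chr3:2")$estimate
    want32 <- oracle_median(v[fx$ann$chromosome == "chr3"]) /
      oracle_median(v[fx$ann$chromosome == "chr2"])
    expect_equal(got32, want32, tolerance = 1e-12)
  }
})

test_that("undefined ratios are flagged with reasons, never silent", {
  ann <- ann_tbl(paste0("g", 1:3), c("X", "chr2", "chr3"))
  e <- expr_tbl(ann$gene_id, s = c(0.1, 5, 6))
  r <- chrom_ratio(e, ann, "s", "X:A", threshold = 1)
  expect_true(is.na(r$estimate))
  expect_equal(r$note, "empty_gene_set")

  zero <- expr_tbl(ann$gene_id, s = c(1, 0, 0))
  rz <- chrom_ratio(zero, ann, "s", "X:A")
  expect_true(is.na(rz$estimate))
  expect_equal(rz$note, "zero_denominator_median")
})

test_that("male:female methods agree with composed oracles and each other", {
  ann <- ann_tbl(paste0("g", 1:6), c("X", "X", "chr2", "chr2", "chr3", "chr3"))
  e <- expr_tbl(ann$gene_id, M1 = c(2, 4, 1, 3, 5, 7), M2 = c(2, 4, 1, 3, 5, 7),
                F1 = c(2, 4, 1, 3, 5, 7), F2 = c(2, 4, 1, 3, 5, 7))
  m1 <- mf_ratio_method1(e, ann, c("M1", "M2"), c("F1", "F2"))
  m2 <- mf_ratio_method2(e, ann, c("M1", "M2"), c("F1", "F2"))
  expect_equal(m1$estimate, 1.0)
  expect_equal(m2$estimate, 1.0)

  # doubling male X relative to a compensated baseline doubles Method 1
  e_up <- dplyr::mutate(e, M1 = M1 * ifelse(ann$chromosome == "X", 2, 1),
                        M2 = M2 * ifelse(ann$chromosome == "X", 2, 1))
  expect_equal(mf_ratio_method1(e_up, ann, c("M1", "M2"), c("F1", "F2"))$estimate, 2.0)

  # per-gene ratio example: X M:F {1.0, 0.8, 1.2}, autosomes all 1.0
  ann3 <- ann_tbl(paste0("g", 1:6), c("X", "X", "X", "chr2", "chr3", "chr2"))
  em <- expr_tbl(ann3$gene_id, M = c(1, 0.8, 1.2, 1, 1, 1), F = rep(1, 6))
  expect_equal(mf_ratio_method2(em, ann3, "M", "F")$estimate, 1.0)

  set.seed(41)
  for (i in 1:30) {
    fx <- random_ratio_fixture(30, n_samples = 2)
    names(fx$expr) <- c("gene_id", "M", "F")
    ch <- fx$ann$chromosome
    m <- fx$expr$M
    f <- fx$expr$F
    want1 <- (oracle_median(m[ch == "X"]) / oracle_median(m[ch != "X"])) /
      (oracle_median(f[ch == "X"]) / oracle_median(f[ch != "X"]))
    got1 <- mf_ratio_method1(fx$expr, fx$ann, "M", "F")$estimate
    expect_equal(got1, want1, tolerance = 1e-12)
    r <- m / f
    want2 <- oracle_median(r[ch == "X"]) / oracle_median(r[ch != "X"])
    got2 <- mf_ratio_method2(fx$expr, fx$ann, "M", "F")$estimate
    expect_equal(got2, want2, tolerance = 1e-12)
  }

  # genes with zero female expression are excluded and counted
  ez <- expr_tbl(ann3$gene_id, M = c(1, 1, 1, 1, 1, 1), F = c(0, 1, 1, 1, 1, 1))
  r2 <- mf_ratio_method2(ez, ann3, "M", "F")
  expect_equal(r2$n_undefined, 1)
  expect_equal(r2$n_num, 2)
})

test_that("stratified bootstrap is degenerate-exact, deterministic and honest", {
  ann <- ann_tbl(paste0("g", 1:9), rep(c("X", "chr2", "chr3"), each = 3))
  e <- expr_tbl(ann$gene_id, s = rep(c(2, 4, 4), each = 3))
  r <- chrom_ratio(e, ann, "s", "X:A", n_boot = 200, seed = 1)
  expect_equal(r$estimate, 0.5)
  expect_equal(r$ci_low, 0.5)               # constant strata: CI collapses
  expect_equal(r$ci_high, 0.5)

  fx <- random_ratio_fixture(24)
  a <- chrom_ratio(fx$expr, fx$ann, "s1", "X:A", n_boot = 500, seed = 99)
  b <- chrom_ratio(fx$expr, fx$ann, "s1", "X:A", n_boot = 500, seed = 99)
  expect_identical(a, b)
  expect_true(a$ci_low <= a$estimate && a$estimate <= a$ci_high)

  expect_warning(chrom_ratio(fx$expr, fx$ann, "s1", "X:A", n_boot = 50, seed = 1),
                 "n_boot < 100")
})

test_that("decile analysis partitions genes evenly and respects identity", {
  # 20 genes -> 10 deciles of exactly 2 genes (one X + one autosome each)
  ann <- ann_tbl(sprintf("g%02d", 1:20), rep(c("X", "chr2"), 10))
  lev <- rep(2^(0:9), each = 2)             # increasing expression by pair
  e <- expr_tbl(ann$gene_id, M = lev, F = lev)
  d <- decile_analysis(e, ann, "M", "F", n_boot = 0)
  expect_equal(d$decile, 1:10)
  expect_equal(d$n_num + d$n_den, rep(2L, 10))
  expect_equal(d$estimate, rep(1, 10))      # male = female everywhere
})

test_that("expressed fractions count thresholded genes per chromosome", {
  ann <- ann_tbl(sprintf("g%02d", 1:14), c(rep("X", 10), rep("chr2", 4)))
  e <- expr_tbl(ann$gene_id, s = c(rep(5, 4), rep(0.1, 6), 5, 5, 0.1, 0.1))
  f <- expressed_fraction(e, ann, threshold = 1)
  expect_equal(f$fraction[f$chromosome == "X"], 0.4)
  expect_equal(f$fraction[f$chromosome == "chr2"], 0.5)
  f0 <- expressed_fraction(e, ann, threshold = 0)
  expect_true(all(f0$fraction == 1))

  set.seed(51)
  fx <- random_ratio_fixture(40)
  got <- expressed_fraction(fx$expr, fx$ann, threshold = 3)
  for (ch in unique(fx$ann$chromosome)) {
    v <- fx$expr$s1[fx$ann$chromosome == ch]
    expect_equal(got$fraction[got$chromosome == ch], sum(v >= 3) / length(v))
  }
})
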