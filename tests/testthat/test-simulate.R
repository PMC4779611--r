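test_that("identical config and seed reproduce the data set exactly", {
  cfg <- sim_config(n_genes = c(chr2 = 60, chr3 = 50, X = 30, unplaced = 5),
                    samples = sim_samples(2), seed = 77)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)
  # different seed -> different draw
  c2 <- simulate_dataset(sim_config(n_genes = c(chr2 = 60, chr3 = 50, X = 30,
                                                unplaced = 5),
                                    samples = sim_samples(2), seed = 78))
  expect_false(identical(a$counts, c2$counts))
})

test_that("presets encode the canonical compensation scenarios", {
  expect_equal(sim_preset("no_compensation")$compensation_c, 0.5)
  expect_equal(sim_preset("pupae_complete")$compensation_c, 1.0)
  expect_equal(sim_preset("larvae_female_high")$female_x_factor, 1.3)
  tl <- sim_preset("testes_like")
  expect_equal(tl$compensation_c, 0.5)
  expect_equal(unique(tl$samples$sex), "male")
  expect_gt(tl$expr_law$inactive_fraction[["X"]],
            tl$expr_law$inactive_fraction[["chr2"]])
  expect_identical(sim_preset("pupae_complete"), sim_preset("pupae_complete"))
  expect_error(sim_preset("bogus"), "unknown preset")
})

test_that("config validation rejects inconsistent settings before output", {
  expect_error(sim_config(compensation_c = 2), "compensation_c")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(samples = sim_samples(0)), "non-empty")
  expect_error(sim_config(sex_bias = list(male_fraction = 1.2,
                                          female_fraction = 0,
                                          effect_law = list(meanlog2 = 1,
                                                            sdlog2 = 0.1))),
               "fractions")
})

test_that("the noise-free limit returns rounded expected counts", {
  cfg <- sim_config(n_genes = c(chr2 = 40, chr3 = 40, X = 20),
                    dispersion = 0, lib_jitter = 0,
                    samples = sim_samples(1), seed = 9)
  sim <- simulate_dataset(cfg)
  mu_male <- sim$truth$baseline * (sim$annotation$exonic_length / 1000) *
    sim$truth$male_mult * 2                       # 2e6 reads -> x2 per kb
  expect_equal(sim$counts$M1, floor(mu_male + 0.5))
  mu_female <- sim$truth$baseline * (sim$annotation$exonic_length / 1000) *
    sim$truth$female_mult * 2
  expect_equal(sim$counts$F1, floor(mu_female + 0.5))
})

test_that("truth, annotation and counts rows correspond one-to-one", {
  sim <- simulate_dataset(sim_preset("pupae_complete", seed = 3))
  expect_identical(sim$truth$gene_id, sim$annotation$gene_id)
  expect_identical(sim$counts$gene_id, sim$annotation$gene_id)
  expect_identical(sim$truth$chromosome, sim$annotation$chromosome)
  expect_true(all(sim$annotation$exonic_length >= 200))
  expect_true(all(sim$annotation$end <= rep(
    sim$config$chrom_lengths[sim$annotation$chromosome])))
  # genes sorted by start within chromosome
  by_chr <- split(sim$annotation$start, sim$annotation$chromosome)
  expect_true(all(vapply(by_chr, function(s) !is.unsorted(s), logical(1))))
  # X multipliers carry the compensation factor
  expect_true(all(sim$truth$male_mult[sim$truth$chromosome == "X" &
                                        sim$truth$bias_class == "unbiased"] == 1))
})

test_that("planted compensation factors are recovered end to end", {
  sim <- simulate_dataset(sim_config(samples = sim_samples(3),
                                     compensation_c = 0.5, seed = 19))
  expr <- normalize_rpkm(sim$counts, sim$annotation, "uq")
  info <- sim$samples
  male <- chrom_ratio(
    dplyr::bind_cols(expr["gene_id"],
                     male = average_samples_for_test(expr, c("M1", "M2", "M3"))),
    sim$annotation, "male", "X:A", threshold = 1)
  expect_gt(male$estimate, 0.43)
  expect_lt(male$estimate, 0.57)
  female <- chrom_ratio(
    dplyr::bind_cols(expr["gene_id"],
                     female = average_samples_for_test(expr, c("F1", "F2", "F3"))),
    sim$annotation, "female", "X:A", threshold = 1)
  expect_gt(female$estimate, 0.93)
  expect_lt(female$estimate, 1.07)
  # chr3:2 stays inside the natural-variation band with a coherent CI
  cc <- chrom_ratio(
    dplyr::bind_cols(expr["gene_id"],
                     male = average_samples_for_test(expr, c("M1", "M2", "M3"))),
    sim$annotation, "male", "chr3:2", threshold = 1, n_boot = 1000, seed = 4)
  expect_gt(cc$estimate, 0.93)
  expect_lt(cc$estimate, 1.07)
  expect_true(cc$ci_low <= cc$estimate && cc$estimate <= cc$ci_high)
})

test_that("RPKM cancels a planted length-chromosome confound", {
  sim <- simulate_dataset(sim_config(n_genes = c(chr2 = 300, chr3 = 300, X = 120),
                                     samples = sim_samples(1, "male"),
                                     dispersion = 0, lib_jitter = 0, seed = 29))
  base <- chrom_ratio(normalize_rpkm(sim$counts, sim$annotation, "total"),
                      sim$annotation, "M1", "X:A", threshold = 1)
  # quadruple X gene lengths and scale their expected counts alike
  onx <- sim$annotation$chromosome == "X"
  ann2 <- sim$annotation
  ann2$exonic_length <- as.integer(ann2$exonic_length * ifelse(onx, 4L, 1L))
  cnt2 <- sim$counts
  cnt2$M1 <- as.integer(cnt2$M1 * ifelse(onx, 4L, 1L))
  confounded <- chrom_ratio(normalize_rpkm(cnt2, ann2, "total"),
                            ann2, "M1", "X:A", threshold = 1)
  expect_equal(confounded$estimate, base$estimate, tolerance = 0.02)
})

test_that("simulated data round-trip through the on-disk dialects", {
  sim <- simulate_dataset(sim_config(n_genes = c(chr2 = 30, chr3 = 25, X = 15),
                                     samples = sim_samples(2), seed = 31))
  dir <- withr::local_tempdir()
  write_sim_dataset(sim, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "annotation.tsv", "annotation.gff3", "counts.tsv", "samples.tsv",
    "truth.tsv", "config.json")))))
  cnt <- read_counts_tsv(file.path(dir, "counts.tsv"))
  expect_equal(as.data.frame(cnt), as.data.frame(sim$counts))
  ann <- read_annotation_tsv(file.path(dir, "annotation.tsv"))
  expect_equal(ann$exonic_length, sim$annotation$exonic_length)
  smp <- read_sample_sheet(file.path(dir, "samples.tsv"))
  expect_equal(smp$sample_id, sim$samples$sample_id)
})
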