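# Small in-code fixtures and independent oracles shared across test files.

# Flat annotation without exon structure.
ann_tbl <- function(gene_id, chromosome, start = NULL, end = NULL,
                    exonic_length = 1000L) {
  n <- length(gene_id)
  start <- start %||% seq(1, by = 10000, length.out = n)
  end <- end %||% (start + 4999)
  tibble::tibble(gene_id = gene_id, chromosome = chromosome,
                 start = as.integer(start), end = as.integer(end),
                 strand = "+", exonic_length = as.integer(rep_len(exonic_length, n)))
}

# Expression tibble from named sample vectors.
expr_tbl <- function(gene_id, ...) {
  tibble::tibble(gene_id = gene_id, ...)
}

`%||%` <- rlang::`%||%`

# Random gene table on the three chromosomes, for oracle comparisons.
random_ratio_fixture <- function(n = 12, n_samples = 1) {
  chrom <- sample(c("chr2", "chr3", "X"), n, replace = TRUE)
  # guarantee each chromosome is populated
  chrom[1:3] <- c("chr2", "chr3", "X")
  ann <- ann_tbl(sprintf("g%03d", seq_len(n)), chrom)
  expr <- tibble::tibble(gene_id = ann$gene_id)
  for (j in seq_len(n_samples)) {
    expr[[paste0("s", j)]] <- round(stats::rlnorm(n, log(5), 1), 4)
  }
  list(ann = ann, expr = expr)
}

# Independent medians: explicit order-statistic definition.
oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))

# Exhaustive two-sided Fisher p (minimum-likelihood convention) by
# enumerating the hypergeometric support of a 2x2 table.
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(a_range, function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  }, numeric(1))
  p_obs <- probs[a_range == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force Benjamini-Hochberg step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(p[o][i:m] * m / (i:m)))
  }
  q
}

# Brute-force per-replicate SSD via the double loop.
oracle_ssd <- function(x) {
  R <- ncol(x)
  vapply(seq_len(R), function(r) {
    tot <- 0
    for (rp in seq_len(R)) {
      if (rp != r) tot <- tot + sum((x[, r] - x[, rp])^2)
    }
    tot
  }, numeric(1))
}

# Records tibble for fisher_enrichment() from a 2x2 count table
# (rows X/autosome, cols male-/female-biased).
records_from_table <- function(a, b, c, d) {
  tibble::tibble(
    chromosome = rep(c("X", "X", "chr2", "chr2"), times = c(a, b, c, d)),
    bias_class = rep(c("male_biased", "female_biased",
                       "male_biased", "female_biased"), times = c(a, b, c, d)))
}

average_samples_for_test <- function(expr, samples) {
  rowMeans(as.matrix(expr[, samples]))
}

write_gff3 <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gff3",
                                .local_envir = parent.frame())
  writeLines(c("##gff-version 3", lines), path)
  path
}
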