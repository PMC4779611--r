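#' Convert read counts to RPKM (total-count normalization)
#'
#' RPKM(g, s) = count(g, s) / (exonic length of g in kb x library size of s in
#' millions of reads). Library sizes default to the per-sample column sums of
#' the count matrix, i.e. total mapped reads assigned to genes.
#'
#' @param counts Counts tibble (`gene_id` first column, integer samples).
#' @param annotation Annotation tibble supplying `exonic_length` per gene.
#' @param library_sizes Optional named numeric vector of reads per sample;
#'   `NULL` uses column sums.
#' @return Expression tibble of RPKM values with attribute
#'   `rpkm_method = "total"`.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = "g1", s1 = 100L)
#' ann <- tibble::tibble(gene_id = "g1", chromosome = "chr2", start = 1L,
#'                       end = 2000L, strand = "+", exonic_length = 2000L)
#' rpkm_total(counts, ann, library_sizes = c(s1 = 1e7))$s1 # 5.0
rpkm_total <- function(counts, annotation, library_sizes = NULL) {
  m <- expr_matrix(counts)
  idx <- match(rownames(m), annotation$gene_id)
  if (anyNA(idx)) {
    rlang::abort(paste0("no exonic length for gene(s): ",
                        paste(utils::head(rownames(m)[is.na(idx)], 10), collapse = ", ")))
  }
  len_kb <- annotation$exonic_length[idx] / 1000
  if (any(len_kb <= 0)) rlang::abort("exonic lengths must be positive")
  if (is.null(library_sizes)) {
    library_sizes <- colSums(m)
  } else {
    check <- setdiff(colnames(m), names(library_sizes))
    if (length(check) > 0) {
      rlang::abort(paste0("library_sizes missing sample(s): ", paste(check, collapse = ", ")))
    }
    library_sizes <- library_sizes[colnames(m)]
  }
  if (any(library_sizes <= 0)) {
    rlang::abort(paste0("zero or negative library size for sample(s): ",
                        paste(colnames(m)[library_sizes <= 0], collapse = ", ")))
  }
  out <- sweep(m / len_kb, 2, library_sizes / 1e6, "/")
  set_expr_method(matrix_tbl(out), "total")
}

#' Quantile rescaling of an RPKM matrix (upper-quartile / median normalization)
#'
#' Replaces the total-count library-size scale with a per-sample quantile of
#' the expressed (positive) RPKM values: each sample is multiplied by
#' `G / Q_s`, where `Q_s` is the `q`-quantile of its positive values and `G`
#' the geometric mean of the `Q_s` over samples, so the output stays on a
#' common RPKM-like scale. `q = 0.75` is upper-quartile normalization;
#' `q = 0.5` is median normalization. Quantiles use linear interpolation
#' between order statistics (h = (n-1)q + 1, R type 7).
#'
#' @param expr Expression tibble produced by [rpkm_total()].
#' @param q Quantile in (0, 1); default 0.75.
#' @return Expression tibble with `rpkm_method` set to `"upper_quartile"`
#'   (q = 0.75), `"median_scaled"` (q = 0.5) or `"quantile"` otherwise.
#' @export
rescale_quantile <- function(expr, q = 0.75) {
  if (!identical(expr_method(expr), "total")) {
    rlang::abort("rescale_quantile() expects an RPKM matrix from rpkm_total()")
  }
  stopifnot(q > 0, q < 1)
  m <- expr_matrix(expr)
  qs <- vapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    v <- v[v > 0]
    if (length(v) == 0) {
      rlang::abort(paste0("sample with all-zero expression: ", colnames(m)[j]))
    }
    stats::quantile(v, q, names = FALSE, type = 7)
  }, numeric(1))
  out <- sweep(m, 2, geom_mean(qs) / qs, "*")
  method <- if (q == 0.75) "upper_quartile" else if (q == 0.5) "median_scaled" else "quantile"
  set_expr_method(matrix_tbl(out), method)
}

#' Counts to normalized RPKM in one step
#'
#' Convenience wrapper: [rpkm_total()] followed by [rescale_quantile()] for the
#' upper-quartile (`"uq"`) and median (`"median"`) methods.
#'
#' @inheritParams rpkm_total
#' @param method `"uq"` (default), `"total"` or `"median"`.
#' @return Expression tibble of normalized RPKM values.
#' @export
normalize_rpkm <- function(counts, annotation, method = c("uq", "total", "median"),
                           library_sizes = NULL) {
  method <- match.arg(method)
  expr <- rpkm_total(counts, annotation, library_sizes)
  switch(method,
         total = expr,
         uq = rescale_quantile(expr, 0.75),
         median = rescale_quantile(expr, 0.5))
}

#' Downsample a count matrix to a common depth (binomial thinning)
#'
#' Each count is replaced by a Binomial(count, target_depth / column sum)
#' draw, the count-level analogue of resampling reads to a lower sequencing
#' depth: expected RPKM is unchanged while sampling noise matches the
#' shallower depth.
#'
#' @param counts Counts tibble.
#' @param target_depth Target reads per sample; must not exceed any column sum.
#' @param seed Optional integer seed for reproducibility.
#' @return Thinned counts tibble.
#' @export
downsample_counts <- function(counts, target_depth, seed = NULL) {
  m <- expr_matrix(counts)
  depths <- colSums(m)
  if (any(target_depth > depths)) {
    rlang::abort(paste0("target_depth exceeds column sum for sample(s): ",
                        paste(colnames(m)[target_depth > depths], collapse = ", ")))
  }
  p <- target_depth / depths
  out <- with_seed_if(seed, {
    vapply(seq_len(ncol(m)), function(j) {
      stats::rbinom(nrow(m), size = as.integer(m[, j]), prob = p[j])
    }, numeric(nrow(m)))
  })
  dimnames(out) <- dimnames(m)
  matrix_tbl(out)
}

#' Per-gene MA values for a pair of samples
#'
#' M = log2((a + pc) / (b + pc)), A = 0.5 log2((a + pc)(b + pc)); the standard
#' diagnostic for between-sample normalization bias.
#'
#' @param expr Expression (or count) tibble.
#' @param sample_a,sample_b Sample column names.
#' @param pseudocount Positive offset guarding against log of zero. 1 is
#'   conventional for counts, 0.01 for RPKM.
#' @return Tibble with columns `gene_id`, `A`, `M` in matrix order.
#' @export
ma_values <- function(expr, sample_a, sample_b, pseudocount = 0.01) {
  stopifnot(pseudocount > 0)
  check_samples_present(expr, c(sample_a, sample_b))
  a <- expr[[sample_a]] + pseudocount
  b <- expr[[sample_b]] + pseudocount
  tibble::tibble(gene_id = expr$gene_id,
                 A = 0.5 * log2(a * b),
                 M = log2(a / b))
}
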