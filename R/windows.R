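window_starts <- function(chrom_length, window, step) {
  stopifnot(window >= step, step > 0)
  seq(1, chrom_length, by = step)
}

gene_positions <- function(annotation, assign = c("midpoint", "start")) {
  assign <- match.arg(assign)
  if (assign == "midpoint") floor((annotation$start + annotation$end) / 2)
  else annotation$start
}

#' Sliding-window density of expressed genes along a chromosome
#'
#' Counts, within a window sliding along the chromosome, the genes expressed
#' at or above each threshold. Windows start at 1, 1 + step, ... and a gene
#' belongs to a window when its midpoint (rounded down; configurable via
#' `assign`) lies inside it. Trailing windows extending past the chromosome
#' end are emitted and flagged `partial`.
#'
#' @param expr Expression tibble (values averaged over `samples`).
#' @param annotation Annotation tibble.
#' @param chromosome Chromosome to profile (default `"X"`).
#' @param window,step Window size and step in bp (defaults 1 Mb / 100 kb).
#' @param thresholds Minimum-RPKM thresholds to count at.
#' @param samples Samples whose mean expression is used (default: all).
#' @param chrom_length Chromosome length in bp; default: the last gene end.
#' @param assign Gene-to-window assignment rule.
#' @return Long tibble: `chromosome`, `window_start`, `window_end`, `partial`,
#'   `threshold`, `n_genes`; classed `xa_window_profile`.
#' @export
window_density <- function(expr, annotation, chromosome = "X", window = 1e6,
                           step = 1e5, thresholds = c(0, 0.1, 0.25, 0.5, 1),
                           samples = NULL, chrom_length = NULL,
                           assign = c("midpoint", "start")) {
  ann <- dplyr::filter(annotation, .data$chromosome == !!chromosome)
  if (nrow(ann) == 0) {
    rlang::warn(paste0("no genes on chromosome ", chromosome))
    return(empty_window_profile())
  }
  samples <- samples %||% sample_cols(expr)
  v <- average_samples(expr, samples)
  names(v) <- expr$gene_id
  pos <- gene_positions(ann, assign)
  val <- v[ann$gene_id]
  chrom_length <- chrom_length %||% max(ann$end)
  starts <- window_starts(chrom_length, window, step)
  ends <- starts + window - 1
  out <- purrr::map_dfr(thresholds, function(th) {
    expressed_pos <- pos[!is.na(val) & val >= th]
    tibble::tibble(
      chromosome = chromosome,
      window_start = starts, window_end = ends,
      partial = ends > chrom_length,
      threshold = th,
      n_genes = vapply(seq_along(starts), function(i) {
        sum(expressed_pos >= starts[i] & expressed_pos <= ends[i])
      }, integer(1)))
  })
  class(out) <- c("xa_window_profile", class(out))
  out
}

empty_window_profile <- function() {
  out <- tibble::tibble(chromosome = character(), window_start = numeric(),
                        window_end = numeric(), partial = logical(),
                        threshold = numeric(), n_genes = integer())
  class(out) <- c("xa_window_profile", class(out))
  out
}

#' Sliding-window X:A expression ratios
#'
#' For each window along the X chromosome: the median expression of the
#' expressed X-linked genes whose midpoints fall in the window, divided by the
#' median expression of all expressed autosomal genes. With several samples,
#' per-sample window ratios are computed against per-sample autosomal medians
#' and then combined (`combine`). Windows with fewer than `min_genes`
#' expressed genes (in any contributing sample) are flagged undefined rather
#' than reported as noise.
#'
#' @inheritParams window_density
#' @param threshold Minimum RPKM for a gene to count as expressed.
#' @param min_genes Minimum expressed window genes for a defined ratio.
#' @param autosomes Denominator chromosome labels.
#' @param combine How per-sample window ratios are combined.
#' @return Tibble: window coordinates, `n_window_genes_used`,
#'   `window_xa_ratio` (NA when flagged), `note`; classed `xa_window_profile`.
#' @export
window_xa <- function(expr, annotation, chromosome = "X", window = 1e6,
                      step = 1e5, threshold = 1, min_genes = 5,
                      samples = NULL, chrom_length = NULL,
                      autosomes = c("chr2", "chr3"),
                      assign = c("midpoint", "start"),
                      combine = c("mean", "median")) {
  combine <- match.arg(combine)
  samples <- samples %||% sample_cols(expr)
  check_samples_present(expr, samples)
  ann_x <- dplyr::filter(annotation, .data$chromosome == !!chromosome)
  if (nrow(ann_x) == 0) {
    rlang::warn(paste0("no genes on chromosome ", chromosome))
    return(empty_window_profile())
  }
  chrom <- gene_chromosomes(expr, annotation)
  pos <- gene_positions(ann_x, assign)
  x_idx <- match(ann_x$gene_id, expr$gene_id)
  chrom_length <- chrom_length %||% max(ann_x$end)
  starts <- window_starts(chrom_length, window, step)
  ends <- starts + window - 1

  per_sample <- lapply(samples, function(s) {
    v <- expr[[s]]
    a <- v[chrom %in% autosomes & v >= threshold]
    if (length(a) == 0 || stats::median(a) == 0) {
      rlang::abort("autosomal median is zero or no expressed autosomal genes")
    }
    a_med <- stats::median(a)
    xv <- v[x_idx]
    keep <- !is.na(xv) & xv >= threshold
    list(pos = pos[keep], val = xv[keep], a_med = a_med)
  })

  rows <- purrr::map_dfr(seq_along(starts), function(i) {
    per_win <- lapply(per_sample, function(ps) {
      inw <- ps$pos >= starts[i] & ps$pos <= ends[i]
      list(n = sum(inw),
           ratio = if (sum(inw) >= min_genes) stats::median(ps$val[inw]) / ps$a_med
                   else NA_real_)
    })
    ns <- vapply(per_win, `[[`, integer(1), "n")
    ratios <- vapply(per_win, `[[`, numeric(1), "ratio")
    defined <- all(is.finite(ratios))
    tibble::tibble(
      chromosome = chromosome,
      window_start = starts[i], window_end = ends[i],
      partial = ends[i] > chrom_length,
      threshold = threshold,
      n_window_genes_used = min(ns),
      window_xa_ratio = if (defined) {
        if (combine == "mean") mean(ratios) else stats::median(ratios)
      } else NA_real_,
      note = if (defined) NA_character_ else "too_few_expressed_genes")
  })
  class(rows) <- c("xa_window_profile", class(rows))
  rows
}

#' Correlation between window gene density and X:A ratio departure
#'
#' Pearson correlation between the number of genes used in each window and
#' the departure of the window X:A ratio from unity, measured as
#' |log2(ratio)|; the p-value comes from the standard t transform. A negative
#' correlation indicates that strong X:A departures concentrate in gene-poor
#' windows.
#'
#' @param profile Output of [window_xa()].
#' @return One-row tibble: `r`, `p_value`, `n_windows`, `note`.
#' @export
density_departure_correlation <- function(profile) {
  ok <- is.finite(profile$window_xa_ratio) & profile$window_xa_ratio > 0
  n <- sum(ok)
  if (n < 3) rlang::abort("need at least 3 defined windows")
  count <- profile$n_window_genes_used[ok]
  departure <- abs(log2(profile$window_xa_ratio[ok]))
  if (stats::sd(count) == 0 || stats::sd(departure) == 0) {
    return(tibble::tibble(r = NA_real_, p_value = NA_real_, n_windows = n,
                          note = "zero_variance"))
  }
  ct <- stats::cor.test(count, departure, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n_windows = n,
                 note = NA_character_)
}
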