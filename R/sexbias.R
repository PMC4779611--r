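#' Per-gene male:female expression ratios
#'
#' Replicate-averaged male and female expression and their per-gene ratio.
#' Genes with zero female expression have an undefined ratio (`NA`) and carry
#' a `direction` flag instead.
#'
#' @inheritParams mf_ratio_method1
#' @return Tibble: `gene_id`, `chromosome`, `male_expr`, `female_expr`,
#'   `mean_expr`, `mf_ratio`, `direction` (`male`/`female`/`none` for
#'   undefined-ratio genes, `NA` otherwise).
#' @export
mf_gene_ratios <- function(expr, annotation, male_samples, female_samples) {
  mf_gene_table(expr, annotation, male_samples, female_samples) |>
    dplyr::mutate(direction = dplyr::case_when(
      !is.na(.data$mf_ratio) ~ NA_character_,
      .data$male_expr > 0 ~ "male",
      TRUE ~ "none"))
}

#' Histogram of per-gene male:female ratios
#'
#' Bins per-gene male:female ratios into half-open intervals
#' `[k w, (k+1) w)` of width `bin_width` (default 0.02), optionally restricted
#' to a chromosome set and to genes whose mean expression meets `threshold`.
#' Genes with undefined ratios are excluded and counted in the
#' `n_undefined` attribute.
#'
#' @param records Tibble from [mf_gene_ratios()] (or any tibble with
#'   `chromosome`, `mean_expr`, `mf_ratio`).
#' @param chromosomes Chromosome labels to keep (default: all).
#' @param threshold Minimum mean expression.
#' @param bin_width Bin width on the ratio scale.
#' @return Tibble `bin_start`, `bin_end`, `n`; attribute `n_undefined`.
#' @export
ratio_histogram <- function(records, chromosomes = NULL, threshold = 0,
                            bin_width = 0.02) {
  stopifnot(bin_width > 0)
  keep <- records$mean_expr >= threshold
  if (!is.null(chromosomes)) keep <- keep & records$chromosome %in% chromosomes
  r <- records$mf_ratio[keep]
  n_undefined <- sum(is.na(r))
  r <- r[!is.na(r)]
  if (length(r) == 0) {
    out <- tibble::tibble(bin_start = numeric(), bin_end = numeric(), n = integer())
    attr(out, "n_undefined") <- n_undefined
    return(out)
  }
  k <- floor(r / bin_width)
  counts <- table(k)
  kk <- as.numeric(names(counts))
  out <- tibble::tibble(bin_start = kk * bin_width,
                        bin_end = (kk + 1) * bin_width,
                        n = as.integer(counts))
  attr(out, "n_undefined") <- n_undefined
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_(i) = min_(j >= i) p_(j) m / j`, capped at 1 and
#' returned in input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values.
#' @export
bh_qvalues <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    rlang::abort("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Classify genes as male-biased, female-biased or unbiased
#'
#' A gene is sex-biased when it is significant (q-value below `q_cut`) and its
#' male:female fold change clears `fold_cut` (male-biased: ratio
#' `>= fold_cut`; female-biased: `<= 1/fold_cut`; the default 1.5 encodes a
#' "fold change above 50%" rule). q-values are taken from `external_q` when
#' supplied (e.g. from an external differential-expression run); otherwise a
#' moderated two-sample test (limma) on `log2(RPKM + pseudocount)` across
#' replicates supplies p-values, adjusted by [bh_qvalues()]. Genes with zero
#' female but positive male expression have an undefined fold and are
#' classified by the q-rule with direction male; genes silent in both sexes
#' are `undefined`.
#'
#' @inheritParams mf_ratio_method1
#' @param q_cut Significance cutoff on the q-value (default 0.005).
#' @param fold_cut Fold-change cutoff (default 1.5).
#' @param external_q Optional tibble `gene_id`, `q_value` taking precedence
#'   over the in-house test.
#' @param pseudocount Offset added before the log transform.
#' @return Tibble of per-gene records: `gene_id`, `chromosome`, `mf_fold`,
#'   `p_value`, `q_value`, `bias_class`.
#' @export
classify_bias <- function(expr, annotation, male_samples, female_samples,
                          q_cut = 0.005, fold_cut = 1.5, external_q = NULL,
                          pseudocount = 0.01) {
  stopifnot(fold_cut > 1)
  tab <- mf_gene_ratios(expr, annotation, male_samples, female_samples)
  if (is.null(external_q)) {
    if (length(male_samples) < 2 || length(female_samples) < 2) {
      rlang::abort("in-house test needs >= 2 replicates per sex; supply external_q otherwise")
    }
    m <- log2(expr_matrix(expr)[, c(male_samples, female_samples), drop = FALSE] +
                pseudocount)
    design <- cbind(intercept = 1,
                    male = rep(c(1, 0), c(length(male_samples), length(female_samples))))
    # near-silent genes have almost-zero log variance; limma offsets them and
    # warns, which is expected here rather than actionable
    fit <- withCallingHandlers(
      limma::eBayes(limma::lmFit(m, design), trend = TRUE, robust = TRUE),
      warning = function(w) {
        if (grepl("very small variances", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    p <- fit$p.value[, "male"]
    q <- bh_qvalues(p)
  } else {
    idx <- match(tab$gene_id, external_q$gene_id)
    if (anyNA(idx)) {
      rlang::abort("external_q does not cover every gene in the matrix")
    }
    p <- rep(NA_real_, nrow(tab))
    q <- external_q$q_value[idx]
  }
  tab$p_value <- unname(p)
  tab$q_value <- unname(q)
  tab |>
    dplyr::mutate(
      mf_fold = .data$mf_ratio,
      bias_class = dplyr::case_when(
        .data$male_expr == 0 & .data$female_expr == 0 ~ "undefined",
        is.na(.data$mf_fold) & .data$q_value < q_cut ~ "male_biased",
        is.na(.data$mf_fold) ~ "unbiased",
        .data$q_value < q_cut & .data$mf_fold >= fold_cut ~ "male_biased",
        .data$q_value < q_cut & .data$mf_fold <= 1 / fold_cut ~ "female_biased",
        TRUE ~ "unbiased")) |>
    dplyr::select("gene_id", "chromosome", "male_expr", "female_expr",
                  "mf_fold", "p_value", "q_value", "bias_class")
}

#' Fisher's exact test for X-linkage of sex-biased genes
#'
#' Builds the 2x2 table of biased genes (rows: X / autosome; columns:
#' male-biased / female-biased; unbiased genes excluded) and tests
#' independence of bias direction and chromosomal location with a two-sided
#' Fisher's exact test (minimum-likelihood convention: the p-value sums
#' hypergeometric probabilities no larger than the observed table's). Under
#' the null, male- and female-biased genes are distributed between the X and
#' the autosomes in the same proportions.
#'
#' @param records Output of [classify_bias()].
#' @param x_chromosome Label of the X chromosome.
#' @return An object of class `xa_enrichment`: list with `table` (2x2 matrix),
#'   `odds_ratio` (sample odds ratio ad/bc; `Inf`/`NaN` flagged in `note`),
#'   `p_value`, `n_biased`. Has [generics::tidy()] and [generics::glance()]
#'   methods.
#' @export
fisher_enrichment <- function(records, x_chromosome = "X") {
  biased <- dplyr::filter(records, .data$bias_class %in% c("male_biased", "female_biased"))
  if (nrow(biased) == 0) rlang::abort("no sex-biased genes; cannot test enrichment")
  tab <- table(
    factor(ifelse(biased$chromosome == x_chromosome, "X", "autosome"),
           levels = c("X", "autosome")),
    factor(biased$bias_class, levels = c("male_biased", "female_biased")))
  tab <- matrix(as.integer(tab), 2, 2, dimnames = dimnames(tab))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  note <- if (!is.finite(or) || or == 0) "degenerate_odds_ratio" else NA_character_
  structure(list(table = tab, odds_ratio = or, p_value = p,
                 n_biased = nrow(biased), note = note),
            class = "xa_enrichment")
}

#' @export
print.xa_enrichment <- function(x, ...) {
  cat("Sex-bias X-linkage enrichment (Fisher's exact test)\n")
  print(x$table)
  cat(sprintf("odds ratio (ad/bc) = %.4g, two-sided p = %.4g, n biased = %d\n",
              x$odds_ratio, x$p_value, x$n_biased))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.xa_enrichment <- function(x, ...) {
  tibble::as_tibble(as.data.frame(as.table(x$table), stringsAsFactors = FALSE)) |>
    rlang::set_names(c("location", "bias_class", "n"))
}

#' @export
glance.xa_enrichment <- function(x, ...) {
  tibble::tibble(odds_ratio = x$odds_ratio, p_value = x$p_value,
                 n_biased = x$n_biased, note = x$note)
}

#' Compare two sets of expression ratios (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum comparison of two ratio sets
#' (e.g. the same genes' male:female ratios at two developmental time
#' points). Below a combined size of 20 the null distribution of U is
#' enumerated exactly over all group assignments (mid-ranks for ties);
#' otherwise the normal approximation with tie correction is used.
#'
#' @param x,y Numeric vectors of ratios (each of length >= 2).
#' @param exact_below Combined-size bound for exact enumeration.
#' @return One-row tibble: `statistic` (U for `x`), `p_value`, `median_x`,
#'   `median_y`, `method`.
#' @export
compare_ratio_sets <- function(x, y, exact_below = 20) {
  if (length(x) < 2 || length(y) < 2) {
    rlang::abort("each ratio set needs at least 2 values")
  }
  m <- length(x)
  n <- length(y)
  pooled_ranks <- rank(c(x, y))
  u_obs <- sum(pooled_ranks[seq_len(m)]) - m * (m + 1) / 2
  if (m + n < exact_below) {
    dev_obs <- abs(u_obs - m * n / 2)
    combos <- utils::combn(m + n, m)
    u_all <- colSums(matrix(pooled_ranks[combos], nrow = m)) - m * (m + 1) / 2
    p <- mean(abs(u_all - m * n / 2) >= dev_obs - 1e-9)
    method <- "exact_enumeration"
  } else {
    p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    method <- "normal_approximation"
  }
  tibble::tibble(statistic = u_obs, p_value = p,
                 median_x = stats::median(x), median_y = stats::median(y),
                 method = method)
}

#' Pairwise Spearman correlation of replicate samples
#'
#' Spearman rank correlation (ties mid-ranked) on per-gene expression between
#' every pair of samples; the standard replicate-agreement check. Constant
#' columns yield `NA` for their pairs.
#'
#' @param expr Expression tibble.
#' @param samples Samples to correlate (default: all).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
replicate_correlation <- function(expr, samples = NULL) {
  samples <- samples %||% sample_cols(expr)
  if (length(samples) < 2) rlang::abort("need at least 2 samples")
  m <- expr_matrix(expr)[, samples, drop = FALSE]
  suppressWarnings(out <- stats::cor(m, method = "spearman"))
  diag(out) <- 1
  out
}
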