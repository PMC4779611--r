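#' Select genes above a minimum-expression threshold
#'
#' Gene filtering for the threshold sweep. With `scope = "per_sample"` a gene
#' is selected for each sample in which its value is `>= threshold` (the
#' boundary is inclusive, matching a ">= RPKM" sweep); with
#' `scope = "mean_over_samples"` one shared set is returned, selecting genes
#' whose mean over the designated samples is `>= threshold`. A threshold of 0
#' keeps every gene, active or not.
#'
#' @param expr Expression tibble.
#' @param threshold Minimum RPKM, `>= 0`.
#' @param scope `"per_sample"` or `"mean_over_samples"`.
#' @param samples Sample columns to consider (default: all).
#' @return `per_sample`: named list of gene-id character vectors, one per
#'   sample; `mean_over_samples`: a single character vector.
#' @export
select_genes <- function(expr, threshold,
                         scope = c("per_sample", "mean_over_samples"),
                         samples = NULL) {
  scope <- match.arg(scope)
  stopifnot(threshold >= 0)
  samples <- samples %||% sample_cols(expr)
  check_samples_present(expr, samples)
  if (scope == "mean_over_samples") {
    v <- average_samples(expr, samples)
    return(expr$gene_id[v >= threshold])
  }
  out <- lapply(samples, function(s) expr$gene_id[expr[[s]] >= threshold])
  names(out) <- samples
  out
}

# ---- stratified bootstrap engine ----------------------------------------
#
# `strata` is a named list (one element per chromosome stratum); each stratum
# is a list of equal-length numeric vectors (e.g. v, or m and f). One bootstrap
# replicate resamples gene indices with replacement independently within each
# stratum, preserving stratum sizes. Under "shared" resampling the same index
# multiset is applied to every vector of a stratum, so the paired male/female
# structure of a contrast is preserved; "independent" draws a separate index
# multiset per vector.
boot_ratio_ci <- function(strata, stat_fn, n_boot, level = 0.95, seed = NULL,
                          resample = c("shared", "independent")) {
  resample <- match.arg(resample)
  if (n_boot < 100) rlang::warn("n_boot < 100: bootstrap CI will be unstable")
  note <- NA_character_
  if (any(vapply(strata, function(s) length(s[[1]]), integer(1)) == 1)) {
    note <- "stratum_of_size_1"
  }
  reps <- with_seed_if(seed, {
    vapply(seq_len(n_boot), function(b) {
      res <- lapply(strata, function(s) {
        n <- length(s[[1]])
        if (resample == "shared") {
          i <- sample.int(n, n, replace = TRUE)
          lapply(s, function(v) v[i])
        } else {
          lapply(s, function(v) v[sample.int(n, n, replace = TRUE)])
        }
      })
      stat_fn(res)
    }, numeric(1))
  })
  ok <- is.finite(reps)
  if (!all(ok)) note <- paste(stats::na.omit(c(note, "undefined_replicates")), collapse = ";")
  if (!any(ok)) return(list(ci_low = NA_real_, ci_high = NA_real_, note = note))
  alpha <- (1 - level) / 2
  ci <- stats::quantile(reps[ok], c(alpha, 1 - alpha), names = FALSE, type = 7)
  list(ci_low = ci[1], ci_high = ci[2], note = note)
}

safe_median_ratio <- function(num, den) {
  if (length(num) == 0 || length(den) == 0) return(NA_real_)
  md <- stats::median(den)
  if (md == 0) return(NA_real_)
  stats::median(num) / md
}

chrom_sets <- function(ratio_type = c("X:A", "chr3:2")) {
  ratio_type <- match.arg(ratio_type)
  if (ratio_type == "X:A") {
    list(numerator = "X", denominator = c("chr2", "chr3"))
  } else {
    list(numerator = "chr3", denominator = "chr2")
  }
}

ratio_row <- function(ratio_type, sex_or_contrast, threshold, estimate,
                      ci_low = NA_real_, ci_high = NA_real_, n_num = 0L,
                      n_den = 0L, n_boot = 0L, seed = NA_integer_,
                      note = NA_character_) {
  tibble::tibble(ratio_type = ratio_type, sex_or_contrast = sex_or_contrast,
                 threshold = threshold, estimate = estimate, ci_low = ci_low,
                 ci_high = ci_high, n_num = as.integer(n_num),
                 n_den = as.integer(n_den), n_boot = as.integer(n_boot),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 note = note)
}

#' Median chromosome-ratio of expression within one sample
#'
#' The core dosage-compensation statistic: the ratio of the median expression
#' of numerator-chromosome genes to the median expression of
#' denominator-chromosome genes, among genes at or above a minimum-expression
#' threshold in this sample. `"X:A"` compares the X against both autosomes
#' pooled; `"chr3:2"` compares the two autosomes and serves as the natural
#' between-chromosome variation control. With `n_boot > 0` a 95% (or `level`)
#' percentile bootstrap CI is attached, resampling genes with replacement
#' independently within each chromosome stratum.
#'
#' @param expr Expression tibble.
#' @param annotation Annotation tibble.
#' @param sample Sample column to analyse.
#' @param ratio_type `"X:A"` or `"chr3:2"`, or override `numerator` /
#'   `denominator` with chromosome label sets directly.
#' @param threshold Minimum RPKM (inclusive).
#' @param numerator,denominator Chromosome label sets; default from
#'   `ratio_type`.
#' @param n_boot Bootstrap replicates (0 = point estimate only).
#' @param level CI level.
#' @param seed Optional integer seed for the bootstrap.
#' @return One-row tibble: `ratio_type`, `sex_or_contrast` (the sample name),
#'   `threshold`, `estimate`, `ci_low`, `ci_high`, `n_num`, `n_den`, `n_boot`,
#'   `seed`, `note`. Undefined ratios (empty gene set, zero denominator
#'   median) are returned as `NA` estimates with an explanatory `note`,
#'   never silently.
#' @export
chrom_ratio <- function(expr, annotation, sample, ratio_type = "X:A",
                        threshold = 0, numerator = NULL, denominator = NULL,
                        n_boot = 0, level = 0.95, seed = NULL) {
  if (is.null(numerator) || is.null(denominator)) {
    sets <- chrom_sets(ratio_type)
    numerator <- numerator %||% sets$numerator
    denominator <- denominator %||% sets$denominator
  }
  check_samples_present(expr, sample)
  chrom <- gene_chromosomes(expr, annotation)
  v <- expr[[sample]]
  keep <- v >= threshold & chrom %in% c(numerator, denominator)
  v <- v[keep]
  ch <- chrom[keep]

  num <- v[ch %in% numerator]
  den <- v[ch %in% denominator]
  est <- safe_median_ratio(num, den)
  note <- if (length(num) == 0 || length(den) == 0) {
    "empty_gene_set"
  } else if (stats::median(den) == 0) {
    "zero_denominator_median"
  } else NA_character_

  row <- ratio_row(ratio_type, sample, threshold, est, n_num = length(num),
                   n_den = length(den), n_boot = n_boot, seed = seed, note = note)
  if (n_boot > 0 && is.finite(est)) {
    strata <- lapply(split(v, ch), function(x) list(v = x))
    stat <- function(s) {
      vs <- lapply(s, `[[`, "v")
      nn <- unlist(vs[names(vs) %in% numerator], use.names = FALSE)
      dd <- unlist(vs[names(vs) %in% denominator], use.names = FALSE)
      safe_median_ratio(nn, dd)
    }
    ci <- boot_ratio_ci(strata, stat, n_boot, level, seed)
    row$ci_low <- ci$ci_low
    row$ci_high <- ci$ci_high
    row$note <- paste(stats::na.omit(c(row$note, ci$note)), collapse = ";") %0na%
      row$note
  }
  row
}

`%0na%` <- function(x, fallback) if (identical(x, "")) fallback else x

# Replicate-averaged male and female expression with the mean-expression
# threshold rule used for male:female contrasts and deciles.
mf_gene_table <- function(expr, annotation, male_samples, female_samples) {
  stopifnot(length(male_samples) >= 1, length(female_samples) >= 1)
  m <- average_samples(expr, male_samples)
  f <- average_samples(expr, female_samples)
  tibble::tibble(
    gene_id = expr$gene_id,
    chromosome = gene_chromosomes(expr, annotation),
    male_expr = m, female_expr = f,
    mean_expr = (m + f) / 2,
    mf_ratio = ifelse(f > 0, m / f, NA_real_))
}

#' Male:female chromosome-ratio comparison, Method 1
#'
#' Method 1 compares the sexes at the chromosome level: the X:A (or chr3:2)
#' ratio is computed on the replicate-averaged expression of each sex
#' separately, and the male ratio is divided by the female ratio. Genes enter
#' the comparison when the mean of their male and female average expression is
#' at or above `threshold`; the same gene set is used for both sexes.
#'
#' @inheritParams chrom_ratio
#' @param male_samples,female_samples Sample columns per sex (replicates are
#'   averaged).
#' @param resample Bootstrap resampling of the paired male/female values:
#'   `"shared"` (default) applies one resampled gene multiset per stratum to
#'   both sexes, preserving pairing; `"independent"` resamples each sex
#'   separately.
#' @return One-row RatioEstimate tibble (`sex_or_contrast = "male_vs_female"`).
#' @export
mf_ratio_method1 <- function(expr, annotation, male_samples, female_samples,
                             ratio_type = "X:A", threshold = 0, n_boot = 0,
                             level = 0.95, seed = NULL,
                             resample = c("shared", "independent")) {
  resample <- match.arg(resample)
  sets <- chrom_sets(ratio_type)
  tab <- mf_gene_table(expr, annotation, male_samples, female_samples) |>
    dplyr::filter(.data$mean_expr >= threshold,
                  .data$chromosome %in% c(sets$numerator, sets$denominator))

  stat_of <- function(m_by, f_by) {
    rm_ <- safe_median_ratio(
      unlist(m_by[names(m_by) %in% sets$numerator], use.names = FALSE),
      unlist(m_by[names(m_by) %in% sets$denominator], use.names = FALSE))
    rf_ <- safe_median_ratio(
      unlist(f_by[names(f_by) %in% sets$numerator], use.names = FALSE),
      unlist(f_by[names(f_by) %in% sets$denominator], use.names = FALSE))
    if (!is.finite(rm_) || !is.finite(rf_) || rf_ == 0) NA_real_ else rm_ / rf_
  }

  m_by <- split(tab$male_expr, tab$chromosome)
  f_by <- split(tab$female_expr, tab$chromosome)
  est <- stat_of(m_by, f_by)
  n_num <- sum(tab$chromosome %in% sets$numerator)
  n_den <- sum(tab$chromosome %in% sets$denominator)
  note <- if (!is.finite(est)) "undefined_component_ratio" else NA_character_
  label <- paste0("M:F-", ratio_type)
  row <- ratio_row(label, "male_vs_female", threshold, est, n_num = n_num,
                   n_den = n_den, n_boot = n_boot, seed = seed, note = note)
  if (n_boot > 0 && is.finite(est)) {
    strata <- lapply(split(tab[, c("male_expr", "female_expr")], tab$chromosome),
                     function(d) list(m = d$male_expr, f = d$female_expr))
    stat <- function(s) {
      stat_of(lapply(s, `[[`, "m"), lapply(s, `[[`, "f"))
    }
    ci <- boot_ratio_ci(strata, stat, n_boot, level, seed, resample)
    row$ci_low <- ci$ci_low
    row$ci_high <- ci$ci_high
    row$note <- paste(stats::na.omit(c(row$note, ci$note)), collapse = ";") %0na%
      row$note
  }
  row
}

# Method 2 core on a prepared gene table; shared with decile_analysis().
mf2_estimate <- function(tab, sets, threshold, n_boot, level, seed, label,
                         resample = "shared") {
  tab <- dplyr::filter(tab, .data$mean_expr >= threshold,
                       .data$chromosome %in% c(sets$numerator, sets$denominator))
  n_undefined <- sum(is.na(tab$mf_ratio))
  tab <- dplyr::filter(tab, !is.na(.data$mf_ratio))
  num <- tab$mf_ratio[tab$chromosome %in% sets$numerator]
  den <- tab$mf_ratio[tab$chromosome %in% sets$denominator]
  est <- safe_median_ratio(num, den)
  note <- if (length(num) == 0 || length(den) == 0) {
    "empty_gene_set"
  } else if (!is.finite(est)) "zero_denominator_median" else NA_character_
  row <- ratio_row(label, "male_vs_female", threshold, est, n_num = length(num),
                   n_den = length(den), n_boot = n_boot, seed = seed, note = note)
  row$n_undefined <- as.integer(n_undefined)
  if (n_boot > 0 && is.finite(est)) {
    strata <- lapply(split(tab$mf_ratio, tab$chromosome), function(x) list(r = x))
    stat <- function(s) {
      rs <- lapply(s, `[[`, "r")
      safe_median_ratio(
        unlist(rs[names(rs) %in% sets$numerator], use.names = FALSE),
        unlist(rs[names(rs) %in% sets$denominator], use.names = FALSE))
    }
    ci <- boot_ratio_ci(strata, stat, n_boot, level, seed, resample)
    row$ci_low <- ci$ci_low
    row$ci_high <- ci$ci_high
    row$note <- paste(stats::na.omit(c(row$note, ci$note)), collapse = ";") %0na%
      row$note
  }
  row
}

#' Male:female chromosome-ratio comparison, Method 2
#'
#' Method 2 compares the sexes at the gene level: a male:female expression
#' ratio is computed for every gene (replicate-averaged; genes with zero
#' female expression are excluded and counted in `n_undefined`), and the
#' statistic is the median of these per-gene ratios over the numerator
#' chromosome divided by the median over the denominator chromosome(s).
#'
#' @inheritParams mf_ratio_method1
#' @return One-row RatioEstimate tibble with an extra `n_undefined` column.
#' @export
mf_ratio_method2 <- function(expr, annotation, male_samples, female_samples,
                             ratio_type = "X:A", threshold = 0, n_boot = 0,
                             level = 0.95, seed = NULL,
                             resample = c("shared", "independent")) {
  resample <- match.arg(resample)
  sets <- chrom_sets(ratio_type)
  tab <- mf_gene_table(expr, annotation, male_samples, female_samples)
  mf2_estimate(tab, sets, threshold, n_boot, level, seed,
               paste0("M:F-", ratio_type), resample)
}

#' Method 2 male:female ratios by expression decile
#'
#' Genes are ranked by the mean of male and female replicate-averaged
#' expression and split into 10 equal-count bins (any remainder is spread over
#' the lowest bins); decile 1 holds the least-expressed genes. Within each
#' decile the Method 2 male:female ratio and its stratified bootstrap CI are
#' computed. Deciles in which a required chromosome stratum is empty are
#' flagged undefined.
#'
#' @inheritParams mf_ratio_method1
#' @param n_boot Bootstrap replicates per decile.
#' @return Tibble of RatioEstimate rows with a leading `decile` column.
#' @export
decile_analysis <- function(expr, annotation, male_samples, female_samples,
                            ratio_type = "X:A", n_boot = 1000, level = 0.95,
                            seed = NULL) {
  sets <- chrom_sets(ratio_type)
  tab <- mf_gene_table(expr, annotation, male_samples, female_samples)
  tab <- tab[order(tab$mean_expr), , drop = FALSE]
  n <- nrow(tab)
  if (n < 10) rlang::abort("decile analysis needs at least 10 genes")
  sizes <- rep(n %/% 10, 10) + (seq_len(10) <= n %% 10)
  tab$decile <- rep(seq_len(10), times = sizes)
  with_seed_if(seed, {
    purrr::map_dfr(seq_len(10), function(d) {
      row <- mf2_estimate(tab[tab$decile == d, , drop = FALSE], sets,
                          threshold = 0, n_boot = n_boot, level = level,
                          seed = NULL, label = paste0("M:F-", ratio_type))
      row$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
      dplyr::bind_cols(tibble::tibble(decile = d), row)
    })
  })
}

#' Fraction of genes expressed per chromosome
#'
#' For each chromosome, the fraction of genes whose expression (averaged over
#' `samples`) is at or above `threshold`.
#'
#' @inheritParams chrom_ratio
#' @param samples Samples to average (default: all).
#' @return Tibble: `chromosome`, `n_genes`, `n_expressed`, `fraction`.
#' @export
expressed_fraction <- function(expr, annotation, threshold = 1, samples = NULL) {
  stopifnot(threshold >= 0)
  samples <- samples %||% sample_cols(expr)
  v <- average_samples(expr, samples)
  tibble::tibble(chromosome = gene_chromosomes(expr, annotation), expressed = v >= threshold) |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::summarise(n_genes = dplyr::n(), n_expressed = sum(.data$expressed),
                     fraction = mean(.data$expressed), .groups = "drop")
}

#' Default minimum-expression threshold grid
#'
#' The sweep runs from 0 RPKM (all genes) to highly expressed genes only
#' (>= 40); bootstrap CIs are reported for thresholds between 0.2 and 15,
#' outside which they become meaninglessly wide.
#' @return Numeric vector of thresholds.
#' @export
default_threshold_grid <- function() c(0, 0.2, 0.5, 1, 2, 3, 4, 5, 6, 8, 10, 15, 20, 30, 40)

#' Threshold sweep of within-sex chromosome ratios
#'
#' Computes X:A and chr3:2 median-expression ratios on the replicate-averaged
#' expression of each sex across a grid of minimum-expression thresholds, with
#' stratified bootstrap CIs attached for thresholds inside `ci_range`.
#'
#' @inheritParams chrom_ratio
#' @param sample_info Sample sheet tibble (`sample_id`, `sex`, ...); only
#'   samples present in `expr` are used.
#' @param thresholds Threshold grid.
#' @param ratio_types Ratio types to compute.
#' @param ci_range Thresholds within `[ci_range[1], ci_range[2]]` get CIs.
#' @param n_boot,level,seed Bootstrap settings.
#' @return Tibble of RatioEstimate rows with a `sex` column, classed
#'   `xa_ratio_sweep` for [autoplot.xa_ratio_sweep()].
#' @export
ratio_sweep <- function(expr, annotation, sample_info,
                        thresholds = default_threshold_grid(),
                        ratio_types = c("X:A", "chr3:2"),
                        ci_range = c(0.2, 15), n_boot = 10000, level = 0.95,
                        seed = NULL) {
  sample_info <- dplyr::filter(sample_info, .data$sample_id %in% sample_cols(expr))
  sexes <- split(sample_info$sample_id, sample_info$sex)
  avg <- tibble::tibble(gene_id = expr$gene_id)
  for (sx in names(sexes)) avg[[sx]] <- average_samples(expr, sexes[[sx]])
  out <- with_seed_if(seed, {
    purrr::map_dfr(names(sexes), function(sx) {
      purrr::map_dfr(ratio_types, function(rt) {
        purrr::map_dfr(thresholds, function(th) {
          nb <- if (th >= ci_range[1] && th <= ci_range[2]) n_boot else 0
          row <- chrom_ratio(avg, annotation, sx, ratio_type = rt,
                             threshold = th, n_boot = nb, level = level)
          row$sex_or_contrast <- sx
          row
        })
      })
    })
  })
  out$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  class(out) <- c("xa_ratio_sweep", class(out))
  out
}

#' Threshold sweep of male:female ratios (Method 1 or 2)
#'
#' @inheritParams ratio_sweep
#' @param method 1 or 2, the male:female comparison method.
#' @return Tibble of RatioEstimate rows, classed `xa_ratio_sweep`.
#' @export
mf_sweep <- function(expr, annotation, sample_info,
                     thresholds = default_threshold_grid(),
                     ratio_types = c("X:A", "chr3:2"), method = 2,
                     ci_range = c(0.2, 15), n_boot = 10000, level = 0.95,
                     seed = NULL) {
  stopifnot(method %in% c(1, 2))
  sample_info <- dplyr::filter(sample_info, .data$sample_id %in% sample_cols(expr))
  sexes <- split(sample_info$sample_id, sample_info$sex)
  if (!all(c("male", "female") %in% names(sexes))) {
    rlang::abort("mf_sweep needs both male and female samples")
  }
  fn <- if (method == 1) mf_ratio_method1 else mf_ratio_method2
  out <- with_seed_if(seed, {
    purrr::map_dfr(ratio_types, function(rt) {
      purrr::map_dfr(thresholds, function(th) {
        nb <- if (th >= ci_range[1] && th <= ci_range[2]) n_boot else 0
        fn(expr, annotation, sexes$male, sexes$female, ratio_type = rt,
           threshold = th, n_boot = nb, level = level)
      })
    })
  })
  out$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  out$method <- as.integer(method)
  class(out) <- c("xa_ratio_sweep", class(out))
  out
}
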