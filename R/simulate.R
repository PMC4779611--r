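#' Build a sample sheet for simulation
#'
#' @param n_rep Replicates per sex.
#' @param sexes Sexes to include.
#' @param stage Developmental stage label.
#' @param time_points Optional vector of time points (hours), one per
#'   replicate, mirroring designs where time points are treated as replicates
#'   of a stage.
#' @return Sample-sheet tibble (`sample_id`, `sex`, `stage`, `time_point`,
#'   `replicate`).
#' @export
sim_samples <- function(n_rep = 3, sexes = c("male", "female"), stage = "pupa",
                        time_points = NULL) {
  purrr::map_dfr(sexes, function(sx) {
    tibble::tibble(
      sample_id = paste0(toupper(substr(sx, 1, 1)), seq_len(n_rep)),
      sex = sx, stage = stage,
      time_point = if (is.null(time_points)) NA_real_ else time_points[seq_len(n_rep)],
      replicate = seq_len(n_rep))
  })
}

per_chrom <- function(x, chroms) {
  if (length(x) == 1 && is.null(names(x))) {
    return(stats::setNames(rep(x, length(chroms)), chroms))
  }
  out <- stats::setNames(rep(0, length(chroms)), chroms)
  out[names(x)] <- x
  out
}

#' Configuration for the synthetic RNA-seq count simulator
#'
#' The simulator emulates a genome with chromosomes chr2, chr3, X (plus an
#' unplaced scaffold bin): gene positions uniform along each chromosome,
#' exon-union lengths log-normal (median 1.5 kb), per-gene baseline expression
#' log-normal with a configurable inactive-gene fraction, negative-binomial
#' counts with library-size jitter, a male-X compensation factor
#' (`compensation_c` = 1 complete compensation, 0.5 absent), an optional
#' female-X multiplier, configurable per-chromosome fractions of sex-biased
#' genes, and an optional divergent replicate. Gene counts default to roughly
#' 1/10 of the *A. gambiae* gene complement, with chromosome lengths scaled
#' alike so gene density is preserved.
#'
#' @param n_genes Named integer vector of genes per chromosome.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param length_law `list(meanlog, sdlog)` for exon-union lengths.
#' @param expr_law `list(meanlog, sdlog, inactive_fraction, inactive_meanlog,
#'   inactive_sdlog)`; `inactive_fraction` may be a scalar or named
#'   per-chromosome vector.
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives the deterministic limit where counts
#'   equal their rounded expectations.
#' @param lib_size Mean reads per sample.
#' @param lib_jitter Relative half-width of the uniform library-size jitter.
#' @param lib_sizes Optional explicit named per-sample library sizes
#'   (overrides `lib_size`/`lib_jitter`).
#' @param samples Sample sheet, e.g. from [sim_samples()].
#' @param compensation_c Male-X multiplicative factor in `[0.25, 1.5]`.
#' @param female_x_factor Female-X multiplier (default 1; values above 1 model
#'   female-X overexpression).
#' @param sex_bias `list(male_fraction, female_fraction, effect_law =
#'   list(meanlog2, sdlog2))`; fractions scalar or per-chromosome.
#' @param outlier_replicate Optional `list(sample_id, fraction, fold)`
#'   perturbing one replicate multiplicatively on a random gene subset.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_genes = c(chr2 = 860, chr3 = 760, X = 110, unplaced = 20),
                       chrom_lengths = c(chr2 = 10e6, chr3 = 9e6, X = 2.5e6,
                                         unplaced = 1e6),
                       length_law = list(meanlog = log(1500), sdlog = 0.6),
                       expr_law = list(meanlog = log(15), sdlog = 0.1,
                                       inactive_fraction = 0.1,
                                       inactive_meanlog = log(0.05),
                                       inactive_sdlog = 0.5),
                       dispersion = 0.1,
                       lib_size = 2e6, lib_jitter = 0.2, lib_sizes = NULL,
                       samples = sim_samples(),
                       compensation_c = 1.0, female_x_factor = 1.0,
                       sex_bias = list(male_fraction = 0, female_fraction = 0,
                                       effect_law = list(meanlog2 = 2.5,
                                                         sdlog2 = 0.5)),
                       outlier_replicate = NULL, seed = 1L) {
  chroms <- names(n_genes)
  cfg <- list(n_genes = n_genes, chrom_lengths = chrom_lengths[chroms],
              length_law = length_law, expr_law = expr_law,
              dispersion = dispersion, lib_size = lib_size,
              lib_jitter = lib_jitter, lib_sizes = lib_sizes,
              samples = samples, compensation_c = compensation_c,
              female_x_factor = female_x_factor, sex_bias = sex_bias,
              outlier_replicate = outlier_replicate, seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  chroms <- names(cfg$n_genes)
  if (is.null(chroms) || anyNA(cfg$chrom_lengths)) {
    rlang::abort("n_genes and chrom_lengths must be named per chromosome")
  }
  if (nrow(cfg$samples) == 0) rlang::abort("samples must be non-empty")
  if (anyDuplicated(cfg$samples$sample_id)) rlang::abort("duplicate sample_ids")
  if (cfg$dispersion < 0) rlang::abort("dispersion must be >= 0")
  if (cfg$compensation_c < 0.25 || cfg$compensation_c > 1.5) {
    rlang::abort("compensation_c must lie in [0.25, 1.5]")
  }
  fr <- c(per_chrom(cfg$expr_law$inactive_fraction, chroms),
          per_chrom(cfg$sex_bias$male_fraction, chroms),
          per_chrom(cfg$sex_bias$female_fraction, chroms))
  if (any(fr < 0 | fr > 1)) rlang::abort("fractions must lie in [0, 1]")
  if (!is.null(cfg$lib_sizes) && any(cfg$lib_sizes <= 0)) {
    rlang::abort("lib_sizes must be positive")
  }
  if (cfg$lib_size <= 0) rlang::abort("lib_size must be positive")
  invisible(cfg)
}

# Random exon structure totalling `exonic_length` bp within the chromosome.
# Plain data.frame construction: this runs once per gene.
exon_df <- function(start, end) {
  structure(list(start = as.integer(start), end = as.integer(end)),
            class = "data.frame", row.names = seq_along(start))
}

sim_gene_structure <- function(n, exonic_lengths, chrom_length) {
  ks <- sample.int(4, n, replace = TRUE)
  starts0 <- stats::runif(n)
  lapply(seq_len(n), function(i) {
    len <- exonic_lengths[i]
    k <- ks[i]
    cuts <- sort(sample.int(len - 1, k - 1))
    exon_len <- diff(c(0, cuts, len))
    gaps <- if (k > 1) round_half_up(stats::runif(k - 1, 50, 1000)) else numeric(0)
    span <- len + sum(gaps)
    start <- 1 + floor(starts0[i] * max(chrom_length - span, 1))
    ex_start <- start + cumsum(c(0, exon_len[-k] + gaps))
    list(start = start, end = start + span - 1,
         exons = exon_df(ex_start, ex_start + exon_len - 1))
  })
}

#' Simulate an annotated RNA-seq count data set with known compensation status
#'
#' Draws a genome, per-gene baselines, sex-bias assignments and
#' negative-binomial counts according to a [sim_config()]. The expected count
#' is `baseline x length_kb x sex/chromosome multiplier x library factor`, so
#' RPKM normalization recovers the baselines up to the compensation and bias
#' multipliers; the returned truth table makes every planted effect checkable.
#'
#' @param config A [sim_config()].
#' @return List with elements `annotation` (tibble with `exons` list-column),
#'   `counts`, `samples`, `truth` (per-gene ground truth) and `config`.
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  chroms <- names(config$n_genes)
  withr::with_seed(config$seed, {
    inact <- per_chrom(config$expr_law$inactive_fraction, chroms)
    mfrac <- per_chrom(config$sex_bias$male_fraction, chroms)
    ffrac <- per_chrom(config$sex_bias$female_fraction, chroms)
    eff <- config$sex_bias$effect_law

    ann_list <- list()
    truth_list <- list()
    for (ch in chroms) {
      n <- config$n_genes[[ch]]
      if (n == 0) next
      exonic <- pmax(200, round_half_up(
        stats::rlnorm(n, config$length_law$meanlog, config$length_law$sdlog)))
      structure <- sim_gene_structure(n, exonic, config$chrom_lengths[[ch]])
      start <- vapply(structure, `[[`, numeric(1), "start")
      ord <- order(start)
      structure <- structure[ord]
      exonic <- exonic[ord]
      gene_id <- sprintf("%s_g%04d", ch, seq_len(n))

      active <- stats::runif(n) >= inact[[ch]]
      baseline <- ifelse(
        active,
        stats::rlnorm(n, config$expr_law$meanlog, config$expr_law$sdlog),
        stats::rlnorm(n, config$expr_law$inactive_meanlog,
                      config$expr_law$inactive_sdlog))
      u <- stats::runif(n)
      bias_class <- ifelse(u < mfrac[[ch]], "male_biased",
                           ifelse(u < mfrac[[ch]] + ffrac[[ch]],
                                  "female_biased", "unbiased"))
      effect <- ifelse(bias_class == "unbiased", 1,
                       2^stats::rnorm(n, eff$meanlog2, eff$sdlog2))
      male_mult <- ifelse(bias_class == "male_biased", effect, 1)
      female_mult <- ifelse(bias_class == "female_biased", effect, 1)
      if (ch == "X") {
        male_mult <- male_mult * config$compensation_c
        female_mult <- female_mult * config$female_x_factor
      }
      ann_list[[ch]] <- tibble::tibble(
        gene_id = gene_id, chromosome = ch,
        start = as.integer(vapply(structure, `[[`, numeric(1), "start")),
        end = as.integer(vapply(structure, `[[`, numeric(1), "end")),
        strand = sample(c("+", "-"), n, replace = TRUE),
        exonic_length = as.integer(exonic),
        exons = lapply(structure, `[[`, "exons"))
      truth_list[[ch]] <- tibble::tibble(
        gene_id = gene_id, chromosome = ch, active = active,
        baseline = baseline, bias_class = bias_class, effect = effect,
        male_mult = male_mult, female_mult = female_mult)
    }
    annotation <- dplyr::bind_rows(ann_list)
    truth <- dplyr::bind_rows(truth_list)
    truth$exonic_length <- annotation$exonic_length
    truth$start <- annotation$start
    truth$end <- annotation$end

    smp <- config$samples
    n_s <- nrow(smp)
    lib <- config$lib_sizes %||%
      stats::setNames(config$lib_size *
                        stats::runif(n_s, 1 - config$lib_jitter,
                                     1 + config$lib_jitter),
                      smp$sample_id)
    lib <- lib[smp$sample_id]

    len_kb <- annotation$exonic_length / 1000
    mult <- cbind(male = truth$male_mult, female = truth$female_mult)
    mu <- vapply(seq_len(n_s), function(j) {
      truth$baseline * len_kb * mult[, smp$sex[j]] * (lib[j] / 1e6)
    }, numeric(nrow(annotation)))
    dimnames(mu) <- list(annotation$gene_id, smp$sample_id)

    out_rep <- config$outlier_replicate
    if (!is.null(out_rep)) {
      if (!out_rep$sample_id %in% smp$sample_id) {
        rlang::abort("outlier_replicate sample_id not in sample sheet")
      }
      idx <- sample.int(nrow(mu), round_half_up(out_rep$fraction * nrow(mu)))
      mu[idx, out_rep$sample_id] <- mu[idx, out_rep$sample_id] * out_rep$fold
      truth$outlier_gene <- seq_len(nrow(truth)) %in% idx
    }

    counts <- if (config$dispersion > 0) {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
             nrow = nrow(mu), dimnames = dimnames(mu))
    } else {
      round_half_up(mu)
    }
    storage.mode(counts) <- "integer"

    list(annotation = annotation,
         counts = matrix_tbl(counts),
         samples = smp,
         truth = truth,
         config = config)
  })
}

#' Named simulation presets for canonical compensation scenarios
#'
#' * `pupae_complete`: complete compensation (c = 1), three time-point
#'   replicates per sex treated as replicates of the pupal stage.
#' * `larvae_female_high`: complete male compensation with female-X
#'   overexpression (`female_x_factor = 1.3`, an illustrative magnitude),
#'   three larval replicates per sex.
#' * `no_compensation`: c = 0.5, otherwise as `pupae_complete`.
#' * `testes_like`: c = 0.5, a single male sample, and a reduced fraction of
#'   expressed X-linked genes.
#'
#' @param name Preset name.
#' @param seed Seed stored in the returned config.
#' @return A [sim_config()].
#' @export
sim_preset <- function(name = c("pupae_complete", "larvae_female_high",
                                "no_compensation", "testes_like"),
                       seed = 1L) {
  if (!is.character(name) || !name[1] %in%
      c("pupae_complete", "larvae_female_high", "no_compensation", "testes_like")) {
    rlang::abort(paste0("unknown preset; available: pupae_complete, ",
                        "larvae_female_high, no_compensation, testes_like"))
  }
  name <- match.arg(name)
  switch(
    name,
    pupae_complete = sim_config(
      samples = sim_samples(3, stage = "pupa", time_points = c(4, 10, 20)),
      seed = seed),
    larvae_female_high = sim_config(
      samples = sim_samples(3, stage = "larva"),
      female_x_factor = 1.3, seed = seed),
    no_compensation = sim_config(
      samples = sim_samples(3, stage = "pupa", time_points = c(4, 10, 20)),
      compensation_c = 0.5, seed = seed),
    testes_like = sim_config(
      samples = sim_samples(1, sexes = "male", stage = "pupa"),
      compensation_c = 0.5,
      expr_law = list(meanlog = log(15), sdlog = 0.1,
                      inactive_fraction = c(chr2 = 0.1, chr3 = 0.1, X = 0.55,
                                            unplaced = 0.1),
                      inactive_meanlog = log(0.05), inactive_sdlog = 0.5),
      seed = seed))
}

#' Write a simulated data set to disk in the pipeline's input dialects
#'
#' Emits the annotation (TSV and GFF3), count matrix, sample sheet and ground
#' truth as tab-separated files plus the configuration as JSON.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_annotation_tsv(sim$annotation, file.path(dir, "annotation.tsv"))
  write_annotation_gff3(sim$annotation, file.path(dir, "annotation.gff3"))
  write_counts_tsv(sim$counts, file.path(dir, "counts.tsv"))
  write_sample_sheet(sim$samples, file.path(dir, "samples.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  cfg <- sim$config
  cfg$samples <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(dir)
}
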