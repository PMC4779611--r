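#' Configuration for an end-to-end pipeline run
#'
#' Collects inputs (objects or file paths) and stage settings. A run is
#' reproducible from its config plus inputs: the config (minus the in-memory
#' objects) is serialized alongside every output.
#'
#' @param counts Counts tibble or path to a count TSV.
#' @param annotation Annotation tibble or path to an annotation TSV/GFF3.
#' @param samples Sample sheet tibble or path to a sample-sheet TSV.
#' @param out_dir Output directory.
#' @param norm_method Normalization: `"uq"`, `"total"` or `"median"`.
#' @param thresholds Threshold grid for the ratio sweep.
#' @param ci_range Threshold range over which bootstrap CIs are computed.
#' @param n_boot,level Bootstrap settings.
#' @param window,step,window_threshold,min_genes Sliding-window settings.
#' @param q_cut,fold_cut Sex-bias classification cutoffs.
#' @param qc_n_perm,qc_alpha Replicate-QC settings.
#' @param seed Integer master seed for every stochastic stage.
#' @return A `run_config` list.
#' @export
run_config <- function(counts, annotation, samples, out_dir,
                       norm_method = "uq",
                       thresholds = default_threshold_grid(),
                       ci_range = c(0.2, 15), n_boot = 10000, level = 0.95,
                       window = 1e6, step = 1e5, window_threshold = 1,
                       min_genes = 5, q_cut = 0.005, fold_cut = 1.5,
                       qc_n_perm = 10000, qc_alpha = 0.001, seed = 1L) {
  structure(list(counts = counts, annotation = annotation, samples = samples,
                 out_dir = out_dir, norm_method = norm_method,
                 thresholds = thresholds, ci_range = ci_range,
                 n_boot = n_boot, level = level, window = window, step = step,
                 window_threshold = window_threshold, min_genes = min_genes,
                 q_cut = q_cut, fold_cut = fold_cut, qc_n_perm = qc_n_perm,
                 qc_alpha = qc_alpha, seed = as.integer(seed)),
            class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

load_input <- function(x, reader) if (is.character(x)) reader(x) else x

read_annotation_any <- function(path) {
  if (grepl("\\.gff3?$", path)) read_annotation_gff3(path) else read_annotation_tsv(path)
}

#' Run the full dosage-compensation analysis pipeline
#'
#' Stages, in order: input loading and chromosome filtering; RPKM
#' normalization; replicate QC (permutation test on the SSD statistic, per
#' sex/stage replicate group); within-sex X:A and chr3:2 threshold sweeps
#' with bootstrap CIs plus Method 1 and Method 2 male:female sweeps; sliding
#' window X profiles; sex-bias classification and X-linkage enrichment. When
#' QC flags divergent replicates, ratio tables are written both with all
#' replicates and with the flagged ones excluded. All outputs are new files
#' under `out_dir`; a JSON manifest records settings, seeds and output
#' checksums. Runs are deterministic given config + seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the manifest and key result tibbles.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character(0)

  counts <- run_stage("input", load_input(config$counts, read_counts_tsv))
  annotation <- run_stage("input", load_input(config$annotation, read_annotation_any))
  samples <- run_stage("input", load_input(config$samples, read_sample_sheet))
  counts <- run_stage("input", filter_placed(counts, annotation))

  expr <- run_stage("normalize",
                    normalize_rpkm(counts, annotation, config$norm_method))
  readr::write_tsv(expr, out("rpkm.tsv"))
  jsonlite::write_json(list(method = expr_method(expr)), out("rpkm_method.json"),
                       auto_unbox = TRUE)
  files <- c(files, "rpkm.tsv", "rpkm_method.json")

  seeds <- withr::with_seed(config$seed,
                            sample.int(.Machine$integer.max, 4))

  qc <- run_stage("qc", {
    groups <- split(samples$sample_id, paste(samples$sex, samples$stage))
    groups <- groups[vapply(groups, length, integer(1)) >= 3]
    if (length(groups) == 0) {
      tibble::tibble(sample_id = character(), ssd = numeric(),
                     p_value = numeric(), n_perm = integer(),
                     seed = integer(), flagged = logical())
    } else {
      purrr::imap_dfr(groups, function(g, nm) {
        res <- permutation_test(expr, g, n_perm = config$qc_n_perm,
                                alpha = config$qc_alpha, seed = seeds[1])
        res$group <- nm
        res
      })
    }
  })
  readr::write_tsv(qc, out("qc.tsv"))
  files <- c(files, "qc.tsv")

  ratios_for <- function(sample_ids, seed) {
    info <- dplyr::filter(samples, .data$sample_id %in% sample_ids)
    within <- ratio_sweep(expr[, c("gene_id", sample_ids)], annotation, info,
                          thresholds = config$thresholds,
                          ci_range = config$ci_range, n_boot = config$n_boot,
                          level = config$level, seed = seed)
    both_sexes <- all(c("male", "female") %in% info$sex)
    mf <- if (both_sexes) {
      dplyr::bind_rows(
        mf_sweep(expr[, c("gene_id", sample_ids)], annotation, info,
                 thresholds = config$thresholds, method = 1,
                 ci_range = config$ci_range, n_boot = config$n_boot,
                 level = config$level, seed = seed),
        mf_sweep(expr[, c("gene_id", sample_ids)], annotation, info,
                 thresholds = config$thresholds, method = 2,
                 ci_range = config$ci_range, n_boot = config$n_boot,
                 level = config$level, seed = seed))
    } else NULL
    dplyr::bind_rows(within, mf)
  }

  ratios <- run_stage("ratios", ratios_for(samples$sample_id, seeds[2]))
  readr::write_tsv(ratios, out("ratios.tsv"))
  files <- c(files, "ratios.tsv")

  flagged <- qc$sample_id[qc$flagged]
  if (length(flagged) > 0) {
    keep <- setdiff(samples$sample_id, flagged)
    kept_info <- dplyr::filter(samples, .data$sample_id %in% keep)
    if (all(table(kept_info$sex) >= 1)) {
      ratios_excl <- run_stage("ratios", ratios_for(keep, seeds[2]))
      readr::write_tsv(ratios_excl, out("ratios_excluding_flagged.tsv"))
      files <- c(files, "ratios_excluding_flagged.tsv")
    }
  }

  windows <- run_stage("windows", {
    dens <- window_density(expr, annotation, window = config$window,
                           step = config$step)
    xa <- window_xa(expr, annotation, window = config$window,
                    step = config$step, threshold = config$window_threshold,
                    min_genes = config$min_genes)
    readr::write_tsv(dens, out("windows_density.tsv"))
    readr::write_tsv(xa, out("windows_xa.tsv"))
    list(density = dens, xa = xa)
  })
  files <- c(files, "windows_density.tsv", "windows_xa.tsv")

  sexbias <- run_stage("sexbias", {
    by_sex <- split(samples$sample_id, samples$sex)
    if (all(c("male", "female") %in% names(by_sex)) &&
        all(lengths(by_sex[c("male", "female")]) >= 2)) {
      records <- classify_bias(expr, annotation, by_sex$male, by_sex$female,
                               q_cut = config$q_cut, fold_cut = config$fold_cut)
      readr::write_tsv(records, out("sexbias.tsv"))
      enr <- tryCatch(fisher_enrichment(records), error = function(e) NULL)
      if (!is.null(enr)) {
        jsonlite::write_json(
          list(table = enr$table, odds_ratio = enr$odds_ratio,
               p_value = enr$p_value, n_biased = enr$n_biased),
          out("enrichment.json"), auto_unbox = TRUE, digits = NA)
      }
      list(records = records, enrichment = enr)
    } else NULL
  })
  if (!is.null(sexbias)) {
    files <- c(files, "sexbias.tsv",
               if (!is.null(sexbias$enrichment)) "enrichment.json")
  }

  manifest <- list(
    package = "xacomp",
    version = as.character(utils::packageVersion("xacomp")),
    seed = config$seed, stage_seeds = seeds,
    settings = config[setdiff(names(config), c("counts", "annotation", "samples"))],
    outputs = files,
    checksums = as.list(tools::md5sum(file.path(config$out_dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)

  invisible(list(manifest = manifest, qc = qc, ratios = ratios,
                 windows = windows, sexbias = sexbias,
                 out_dir = config$out_dir))
}
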