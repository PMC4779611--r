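#' Default chromosome-arm mapping for *Anopheles gambiae*
#'
#' *A. gambiae* annotations place genes on chromosome arms (2L, 2R, 3L, 3R, X),
#' while chromosome-level expression ratios treat chromosomes 2 and 3 as units.
#' This map collapses arms to chromosomes; any sequence name absent from the
#' map (e.g. the UNKN scaffold bin) is labelled `"unplaced"` and excluded from
#' ratio analyses by [filter_placed()].
#'
#' @return Named character vector mapping sequence names to chromosome labels.
#' @export
#' @examples
#' default_arm_map()
default_arm_map <- function() {
  c("2L" = "chr2", "2R" = "chr2", "3L" = "chr3", "3R" = "chr3",
    "X" = "X", "chr2" = "chr2", "chr3" = "chr3")
}

chrom_labels <- function() c("chr2", "chr3", "X", "unplaced")

#' Exon-union length of a gene
#'
#' Total genomic length covered by at least one exon, i.e. the length of the
#' set union of the exon intervals with overlaps counted once ("total exonic
#' region"). Intervals are 1-based inclusive, as in GFF3.
#'
#' @param starts Integer vector of exon start positions, or a data frame with
#'   columns `start` and `end` (in which case `ends` is ignored).
#' @param ends Integer vector of exon end positions (`end >= start`).
#' @return Integer: base pairs covered by the exon union.
#' @export
#' @examples
#' exon_union_length(c(1, 51), c(100, 150)) # overlap merged -> 150
exon_union_length <- function(starts, ends = NULL) {
  if (is.data.frame(starts)) {
    ends <- starts$end
    starts <- starts$start
  }
  if (length(starts) == 0) {
    rlang::abort("a gene must have at least one exon interval")
  }
  if (length(starts) != length(ends) || any(ends < starts)) {
    rlang::abort("exon intervals must satisfy end >= start")
  }
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start = starts, end = ends))))
}

# Cheap structural scan so malformed GFF3 lines are reported by line number
# (the downstream importer's errors do not carry positions).
scan_gff3_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  bad <- which(body & lengths(strsplit(lines, "\t", fixed = TRUE)) < 9)
  if (length(bad) > 0) {
    rlang::abort(sprintf("malformed GFF3 line %d in '%s' (fewer than 9 tab-separated fields)",
                         bad[1], path))
  }
  sum(body)
}

#' Read gene annotation from GFF3
#'
#' Parses a GFF3 file with `gene` and `exon` features (exons attached to genes
#' directly or through an intermediate mRNA/transcript feature), collapses
#' chromosome arms through `arm_map`, and computes each gene's exon-union
#' length. Genes without exons are rejected, since RPKM divides by exonic
#' length.
#'
#' @param path Path to a GFF3 file.
#' @param arm_map Named character vector mapping GFF3 sequence names to
#'   chromosome labels; unmapped sequences become `"unplaced"`.
#' @return A tibble with columns `gene_id`, `chromosome`, `start`, `end`,
#'   `strand`, `exonic_length` and a list-column `exons` of per-gene exon
#'   interval tibbles. Coordinates are 1-based inclusive.
#' @export
read_annotation_gff3 <- function(path, arm_map = default_arm_map()) {
  if (scan_gff3_lines(path) == 0) {
    return(tibble::tibble(gene_id = character(), chromosome = character(),
                          start = integer(), end = integer(),
                          strand = character(), exonic_length = integer(),
                          exons = list()))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  ids <- as.character(meta$ID)

  is_gene <- type == "gene"
  gene_ids <- ids[is_gene]
  if (anyDuplicated(gene_ids)) {
    rlang::abort("duplicate gene IDs in GFF3")
  }

  # transcript-level features forward their Parent so exons resolve to genes
  parent1 <- vapply(as.list(meta$Parent), function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))
  tx_parent <- parent1[!is_gene & type != "exon"]
  names(tx_parent) <- ids[!is_gene & type != "exon"]

  is_exon <- type == "exon"
  exon_parent <- parent1[is_exon]
  resolved <- ifelse(exon_parent %in% gene_ids, exon_parent,
                     unname(tx_parent[exon_parent]))
  if (anyNA(resolved)) {
    bad <- unique(exon_parent[is.na(resolved)])
    rlang::abort(paste0("exon feature(s) without resolvable gene parent: ",
                        paste(utils::head(bad, 5), collapse = ", ")))
  }

  ex_start <- BiocGenerics::start(gr)[is_exon]
  ex_end <- BiocGenerics::end(gr)[is_exon]
  exon_sets <- split(tibble::tibble(start = ex_start, end = ex_end), resolved)
  no_exons <- setdiff(gene_ids, names(exon_sets))
  if (length(no_exons) > 0) {
    rlang::abort(paste0("gene(s) without exon features: ",
                        paste(utils::head(no_exons, 5), collapse = ", ")))
  }

  seqn <- as.character(GenomeInfoDb::seqnames(gr))[is_gene]
  chrom <- ifelse(seqn %in% names(arm_map), unname(arm_map[seqn]), "unplaced")
  exons <- exon_sets[gene_ids]
  out <- tibble::tibble(
    gene_id = gene_ids,
    chromosome = chrom,
    start = BiocGenerics::start(gr)[is_gene],
    end = BiocGenerics::end(gr)[is_gene],
    strand = as.character(BiocGenerics::strand(gr))[is_gene],
    exonic_length = unname(vapply(exons, exon_union_length, numeric(1))),
    exons = unname(exons)
  )
  bad_span <- vapply(seq_len(nrow(out)), function(i) {
    any(out$exons[[i]]$start < out$start[i] | out$exons[[i]]$end > out$end[i])
  }, logical(1))
  if (any(bad_span)) {
    rlang::abort(paste0("exon interval outside gene span for: ",
                        paste(utils::head(out$gene_id[bad_span], 5), collapse = ", ")))
  }
  out
}

#' Read / write the tab-separated annotation dialect
#'
#' Columns `gene_id`, `chromosome`, `start`, `end`, `strand`, `exonic_length`
#' (header required). This is the flat equivalent of the GFF3 reader's output
#' without exon structure.
#'
#' @param path File path.
#' @return `read_annotation_tsv()`: a tibble of gene annotations.
#' @export
read_annotation_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           gene_id = "c", chromosome = "c", start = "i",
                           end = "i", strand = "c", exonic_length = "i"))
  required <- c("gene_id", "chromosome", "start", "end", "strand", "exonic_length")
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    rlang::abort(paste0("annotation TSV lacks column(s): ",
                        paste(missing, collapse = ", ")))
  }
  if (any(out$exonic_length < 1 | is.na(out$exonic_length))) {
    rlang::abort("annotation contains genes with missing or zero exonic_length")
  }
  out
}

#' @rdname read_annotation_tsv
#' @param annotation Annotation tibble.
#' @export
write_annotation_tsv <- function(annotation, path) {
  readr::write_tsv(
    annotation[, c("gene_id", "chromosome", "start", "end", "strand", "exonic_length")],
    path)
  invisible(path)
}

#' Write annotation (with exon structure) as GFF3
#'
#' @param annotation Annotation tibble carrying an `exons` list-column, e.g.
#'   from [read_annotation_gff3()] or [simulate_dataset()].
#' @param path Output path.
#' @param seqnames Optional named vector renaming chromosome labels back to
#'   sequence names; defaults to the labels themselves.
#' @export
write_annotation_gff3 <- function(annotation, path, seqnames = NULL) {
  if (is.null(annotation$exons)) {
    rlang::abort("annotation has no exons list-column; cannot emit GFF3")
  }
  sq <- annotation$chromosome
  if (!is.null(seqnames)) sq <- unname(seqnames[sq])
  strand <- ifelse(annotation$strand %in% c("+", "-"), annotation$strand, ".")
  gene_lines <- sprintf("%s\txacomp\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                        sq, annotation$start, annotation$end, strand,
                        annotation$gene_id)
  exon_lines <- unlist(lapply(seq_len(nrow(annotation)), function(i) {
    ex <- annotation$exons[[i]]
    sprintf("%s\txacomp\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
            sq[i], ex$start, ex$end, strand[i], annotation$gene_id[i])
  }))
  writeLines(c("##gff-version 3", gene_lines, exon_lines), path)
  invisible(path)
}

#' Read / write count matrices and sample sheets
#'
#' The count TSV has `gene_id` as its first column and one column of
#' non-negative integer read counts per sample. The sample sheet TSV has
#' columns `sample_id`, `sex` (`male`/`female`), `stage`, `time_point`
#' (hours, may be missing) and `replicate`.
#'
#' @param path File path.
#' @return A tibble (counts: genes x samples with `gene_id` first).
#' @export
read_counts_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(out)[1] != "gene_id") {
    rlang::abort("count TSV must have 'gene_id' as its first column")
  }
  if (anyDuplicated(out$gene_id)) rlang::abort("duplicate gene_ids in count matrix")
  m <- as.matrix(out[, -1])
  if (any(is.na(m)) || any(m < 0) || any(m != floor(m))) {
    rlang::abort("counts must be non-negative integers")
  }
  out
}

#' @rdname read_counts_tsv
#' @param counts Counts tibble.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname read_counts_tsv
#' @export
read_sample_sheet <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           sample_id = "c", sex = "c", stage = "c",
                           time_point = "d", replicate = "i"))
  if (anyDuplicated(out$sample_id)) rlang::abort("duplicate sample_ids in sample sheet")
  bad_sex <- setdiff(unique(out$sex), c("male", "female"))
  if (length(bad_sex) > 0) {
    rlang::abort(paste0("sex must be male/female; found: ", paste(bad_sex, collapse = ", ")))
  }
  out
}

#' @rdname read_counts_tsv
#' @param samples Sample-sheet tibble.
#' @export
write_sample_sheet <- function(samples, path) {
  readr::write_tsv(samples, path)
  invisible(path)
}

#' Restrict a count matrix to chromosome-placed genes
#'
#' Drops genes whose chromosome label is `"unplaced"` (scaffolds not assigned
#' to chr2, chr3 or X), mirroring the exclusion of UNKN scaffolds from the
#' analysis. Retained count values are untouched; sample columns are unchanged.
#'
#' @param counts Counts (or expression) tibble, `gene_id` first column.
#' @param annotation Annotation tibble covering every gene in `counts`.
#' @return The filtered counts tibble.
#' @export
filter_placed <- function(counts, annotation) {
  missing <- setdiff(counts$gene_id, annotation$gene_id)
  if (length(missing) > 0) {
    rlang::abort(paste0("gene(s) in counts absent from annotation: ",
                        paste(utils::head(missing, 10), collapse = ", ")))
  }
  chrom <- annotation$chromosome[match(counts$gene_id, annotation$gene_id)]
  out <- counts[chrom != "unplaced", , drop = FALSE]
  if (nrow(out) == 0) rlang::warn("all genes are unplaced; returning an empty matrix")
  out
}

# Chromosome label per count/expression row, validated against the annotation.
gene_chromosomes <- function(x, annotation) {
  missing <- setdiff(x$gene_id, annotation$gene_id)
  if (length(missing) > 0) {
    rlang::abort(paste0("gene(s) absent from annotation: ",
                        paste(utils::head(missing, 10), collapse = ", ")))
  }
  annotation$chromosome[match(x$gene_id, annotation$gene_id)]
}
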