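#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# Convert a genes-by-samples tibble (gene_id first column) to a numeric matrix.
expr_matrix <- function(x) {
  stopifnot(is.data.frame(x), names(x)[1] == "gene_id")
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$gene_id
  m
}

# Inverse of expr_matrix().
matrix_tbl <- function(m) {
  out <- tibble::as_tibble(m)
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)), out)
}

sample_cols <- function(x) setdiff(names(x), "gene_id")

check_samples_present <- function(x, samples) {
  missing <- setdiff(samples, sample_cols(x))
  if (length(missing) > 0) {
    rlang::abort(paste0("sample(s) not found in matrix: ",
                        paste(missing, collapse = ", ")))
  }
  invisible(samples)
}

# Per-gene arithmetic mean over a set of sample columns (replicate averaging).
average_samples <- function(x, samples) {
  check_samples_present(x, samples)
  rowMeans(expr_matrix(x)[, samples, drop = FALSE])
}

# Expression-method bookkeeping: downstream analyses refuse to mix methods.
expr_method <- function(x) attr(x, "rpkm_method") %||% NA_character_
set_expr_method <- function(x, method) {
  attr(x, "rpkm_method") <- method
  x
}

# RNG scoping: when `seed` is given, run `expr` under that seed without
# disturbing the caller's RNG stream; otherwise use the ambient stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

geom_mean <- function(x) exp(mean(log(x)))

round_half_up <- function(x) floor(x + 0.5)
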