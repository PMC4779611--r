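#' Sum-of-squared-differences replicate statistic
#'
#' For each replicate r in a group, `ssd(r)` is the sum over genes of the
#' squared expression differences between r and every other replicate:
#' `ssd(r) = sum_g sum_(r' != r) (x[g,r] - x[g,r'])^2`. A divergent replicate
#' carries a conspicuously large value.
#'
#' @param expr Expression tibble (RPKM).
#' @param replicate_group Character vector of sample columns forming the
#'   replicate group (>= 3 recommended; with exactly 2 both values are equal
#'   and the statistic is uninformative, which is warned about).
#' @return Named numeric vector of per-replicate SSD values.
#' @export
ssd_statistic <- function(expr, replicate_group) {
  if (length(replicate_group) < 2) rlang::abort("need at least 2 replicates")
  if (length(replicate_group) == 2) {
    rlang::warn("only 2 replicates: both SSD values are equal and the test is uninformative")
  }
  check_samples_present(expr, replicate_group)
  x <- expr_matrix(expr)[, replicate_group, drop = FALSE]
  ssd_from_matrix(x)
}

# ssd(r) = R * sum_g x[g,r]^2 - 2 * sum_g x[g,r] S_g + sum_g Q_g with
# S = rowSums(x), Q = rowSums(x^2); row-invariant terms are hoisted out so the
# permutation loop only regathers columns.
ssd_from_matrix <- function(x) {
  R <- ncol(x)
  S <- rowSums(x)
  sumQ <- sum(x^2)
  out <- vapply(seq_len(R), function(r) {
    R * sum(x[, r]^2) - 2 * sum(x[, r] * S) + sumQ
  }, numeric(1))
  names(out) <- colnames(x)
  out
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Permutation test for divergent replicates
#'
#' Tests each replicate's SSD statistic against a null in which every gene's
#' expression values are independently shuffled across the replicates. The
#' p-value uses the add-one rule, `p = (1 + #{ssd* >= ssd_obs}) / (1 +
#' n_perm)`, so it is never exactly zero. Replicates with `p < alpha` are
#' flagged as divergent.
#'
#' @inheritParams ssd_statistic
#' @param n_perm Number of permutations (default 10,000; below 100 a warning
#'   is raised).
#' @param alpha Flagging threshold on the permutation p-value.
#' @param seed Optional integer seed.
#' @return Tibble: `sample_id`, `ssd`, `p_value`, `n_perm`, `seed`, `flagged`.
#' @export
permutation_test <- function(expr, replicate_group, n_perm = 10000,
                             alpha = 0.001, seed = NULL) {
  if (n_perm < 100) rlang::warn("n_perm < 100: permutation p-values will be coarse")
  obs <- ssd_statistic(expr, replicate_group)
  x <- expr_matrix(expr)[, replicate_group, drop = FALSE]
  R <- ncol(x)
  G <- nrow(x)
  S <- rowSums(x)
  sumQ <- sum(x^2)
  gseq <- seq_len(G)

  use_table <- R <= 7
  if (use_table) {
    P <- all_permutations(R)
    nP <- nrow(P)
  }
  exceed <- matrix(0L, n_perm, R)
  with_seed_if(seed, {
    for (b in seq_len(n_perm)) {
      if (use_table) {
        k <- sample.int(nP, G, replace = TRUE)
        for (r in seq_len(R)) {
          xv <- x[cbind(gseq, P[k, r])]
          exceed[b, r] <- (R * sum(xv^2) - 2 * sum(xv * S) + sumQ) >= obs[r]
        }
      } else {
        perm <- t(vapply(gseq, function(g) sample.int(R), integer(R)))
        for (r in seq_len(R)) {
          xv <- x[cbind(gseq, perm[, r])]
          exceed[b, r] <- (R * sum(xv^2) - 2 * sum(xv * S) + sumQ) >= obs[r]
        }
      }
    }
  })
  p <- (1 + colSums(exceed)) / (1 + n_perm)
  tibble::tibble(sample_id = replicate_group, ssd = unname(obs),
                 p_value = p, n_perm = as.integer(n_perm),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 flagged = p < alpha)
}
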