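#' Permute expression samples jointly across all genes
#'
#' One random permutation of the sample columns is applied to every gene
#' simultaneously, so all gene-gene correlations are preserved while any
#' genotype-expression linkage is destroyed — the null the permutation FDR
#' is built on.  Column names keep their original order, so the permuted
#' matrix still aligns with the (untouched) genotypes.
#'
#' @param expr Expression matrix (genes x samples).
#' @param seed Seed for the permutation (recorded by the caller).
#' @param per_gene Permute each gene independently instead (breaks
#'   co-expression as well); off by default since the joint permutation
#'   preserves the co-expression null.
#' @return The permuted matrix.
#' @export
permute_expression <- function(expr, seed, per_gene = FALSE) {
  stopifnot(is.matrix(expr))
  with_seed(seed, {
    out <- if (per_gene) {
      t(apply(expr, 1L, sample))
    } else {
      expr[, sample(ncol(expr)), drop = FALSE]
    }
    dimnames(out) <- dimnames(expr)
    attr(out, "condition") <- attr(expr, "condition")
    out
  })
}

#' Permutation-based FDR for an exhaustive scan
#'
#' Re-runs the full filter cascade (same PA cutoff, same thresholds, same
#' model selection) on \code{config$n_permutations} expression-permuted
#' datasets and counts, per permutation, the number of unique gene pairs
#' (2D-traits) in significant modules.  Modules are counted by gene pair
#' rather than individually because one gene pair is typically mapped by
#' several neighbouring, nearly identical marker pairs.
#' FDR = mean(null counts) / (observed unique significant gene pairs).
#'
#' @param expr Expression matrix (normal quantile transformed).
#' @param geno A \code{\link{genotype_matrix}} on the same samples.
#' @param config A \code{\link{scan_config}}; permutation i uses seed
#'   \code{config$rng_seed + i}.
#' @param observed Optional precomputed result of
#'   \code{\link{exhaustive_scan}} on the unpermuted data (computed here
#'   when omitted).
#' @param per_gene Passed to \code{\link{permute_expression}}.
#' @return A list: \code{fdr} (NA when nothing is observed significant),
#'   \code{observed_unique}, \code{null_counts}, \code{null_mean},
#'   \code{null_sd}, \code{seeds}, and the \code{observed} scan results.
#' @export
estimate_fdr <- function(expr, geno, config = scan_config(),
                         observed = NULL, per_gene = FALSE) {
  stopifnot(config$n_permutations >= 1L)
  if (is.null(observed)) {
    observed <- exhaustive_scan(expr, geno, config, quiet = TRUE)
  }
  unique_pairs <- function(res) {
    sig <- res[res$significant, , drop = FALSE]
    length(unique(paste(sig$gene1, sig$gene2)))
  }
  n_obs <- unique_pairs(observed)
  seeds <- config$rng_seed + seq_len(config$n_permutations)
  null_counts <- integer(config$n_permutations)
  for (i in seq_len(config$n_permutations)) {
    perm <- permute_expression(expr, seeds[i], per_gene = per_gene)
    null_counts[i] <- unique_pairs(
      exhaustive_scan(perm, geno, config, quiet = TRUE))
  }
  fdr <- if (n_obs == 0L) {
    message("no observed significant 2D-traits; FDR not applicable")
    NA_real_
  } else {
    mean(null_counts) / n_obs
  }
  list(fdr = fdr, observed_unique = n_obs, null_counts = null_counts,
       null_mean = mean(null_counts), null_sd = stats::sd(null_counts),
       seeds = seeds, observed = observed)
}

#' Write an FDR report as TSV
#'
#' One row per permutation (index, seed, null unique-2D-trait count) plus
#' a summary row with mean, SD and the FDR estimate.
#'
#' @param fdr_result Result of \code{\link{estimate_fdr}}.
#' @param path Output path.
#' @export
write_fdr_report <- function(fdr_result, path) {
  tab <- data.frame(
    permutation = c(seq_along(fdr_result$null_counts), "summary"),
    seed = c(fdr_result$seeds, NA),
    null_unique_2d_traits = c(fdr_result$null_counts,
                              fdr_result$null_mean),
    sd = c(rep(NA, length(fdr_result$null_counts)), fdr_result$null_sd),
    fdr = c(rep(NA, length(fdr_result$null_counts)), fdr_result$fdr))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
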