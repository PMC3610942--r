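#' Re-merge scan markers and collapse duplicate modules
#'
#' After a scan, neighbouring markers tend to show the same interaction
#' pattern, so markers are merged again with a looser discordance
#' threshold (default 15) and module marker ids re-mapped onto the merged
#' loci.  Modules that become identical (same gene pair, same merged locus
#' pair) are collapsed, keeping the row with the smallest LR p-value.
#'
#' @param results Scan results (data.frame from
#'   \code{\link{exhaustive_scan}}).
#' @param geno The \code{\link{genotype_matrix}} the scan used.
#' @param max_discordant Merge threshold (default 15).
#' @return A list: \code{results} (re-mapped, collapsed), \code{geno}
#'   (merged markers), \code{map} (merge map).
#' @export
merge_module_markers <- function(results, geno, max_discordant = 15L) {
  merged <- merge_markers(geno, max_discordant)
  src <- strsplit(merged$map$source_ids, ",", fixed = TRUE)
  to_merged <- rep(merged$map$merged_id, lengths(src))
  names(to_merged) <- unlist(src)
  res <- results
  res$marker1 <- unname(to_merged[res$marker1])
  res$marker2 <- unname(to_merged[res$marker2])
  # canonical order on the merged loci (position order of the merged map)
  pos <- stats::setNames(seq_len(nrow(merged$map)), merged$map$merged_id)
  swap <- pos[res$marker1] > pos[res$marker2]
  tmp <- res$marker1[swap]
  res$marker1[swap] <- res$marker2[swap]
  res$marker2[swap] <- tmp
  key <- paste(res$gene1, res$gene2, res$marker1, res$marker2)
  ord <- order(ifelse(is.na(res$p_value), Inf, res$p_value))
  res <- res[ord, , drop = FALSE]
  res <- res[!duplicated(key[ord]), , drop = FALSE]
  rownames(res) <- NULL
  list(results = res, geno = merged$geno, map = merged$map)
}

#' Build the epistasis map from significant modules
#'
#' The epistasis map is a symmetric locus x locus matrix whose (a, b)
#' entry counts the significant modules mapped to the locus pair (a, b).
#'
#' @param results Scan results (typically after
#'   \code{\link{merge_module_markers}}).
#' @param locus_ids Optional locus universe (row/column order); defaults
#'   to the loci appearing in significant modules.
#' @return An integer matrix with zero diagonal, symmetric by
#'   construction.
#' @export
build_epistasis_map <- function(results, locus_ids = NULL) {
  sig <- results[results$significant, , drop = FALSE]
  if (is.null(locus_ids)) {
    locus_ids <- sort(unique(c(sig$marker1, sig$marker2)))
  }
  E <- matrix(0L, length(locus_ids), length(locus_ids),
              dimnames = list(locus_ids, locus_ids))
  for (i in seq_len(nrow(sig))) {
    a <- sig$marker1[i]; b <- sig$marker2[i]
    E[a, b] <- E[a, b] + 1L
    E[b, a] <- E[b, a] + 1L
  }
  E
}

#' Hierarchically cluster the epistasis map
#'
#' Loci are clustered by their interaction profiles.  By default profiles
#' are binarized (interacts / does not) and compared with the Jaccard
#' distance, then clustered by average-linkage agglomeration; both are
#' configurable.  Deterministic given distance and linkage.
#'
#' @param map Matrix from \code{\link{build_epistasis_map}} (at least one
#'   locus).
#' @param linkage \code{stats::hclust} method (default
#'   \code{"average"}).
#' @param distance \code{"jaccard"} (binarized profiles) or
#'   \code{"euclidean"} (raw counts).
#' @return A list: \code{hclust} (the tree; \code{NULL} for a single
#'   locus), \code{order} (leaf order).
#' @export
cluster_epistasis_map <- function(map, linkage = "average",
                                  distance = c("jaccard", "euclidean")) {
  distance <- match.arg(distance)
  if (nrow(map) == 0L) stop("empty epistasis map")
  if (nrow(map) == 1L) {
    return(list(hclust = NULL, order = rownames(map)))
  }
  d <- if (distance == "jaccard") {
    stats::dist(map > 0L, method = "binary")
  } else {
    stats::dist(map, method = "euclidean")
  }
  hc <- stats::hclust(d, method = linkage)
  list(hclust = hc, order = rownames(map)[hc$order])
}

#' Export a clustering dendrogram in Newick format
#'
#' @param hc An \code{hclust} tree (e.g. from
#'   \code{\link{cluster_epistasis_map}}).
#' @param path Output path.
#' @export
export_dendrogram_newick <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Hypergeometric upper-tail test
#'
#' P(K >= k) for K hypergeometric with \code{n} draws from a universe of
#' \code{N} objects of which \code{M} are marked.
#'
#' @param N Universe size.
#' @param M Marked objects.
#' @param n Draws.
#' @param k Observed marked draws.
#' @return The upper-tail p-value.
#' @export
hyper_tail_test <- function(N, M, n, k) {
  if (M > N || n > N) stop("M and n must not exceed N")
  if (k > min(n, M) || k < 0) stop("k must lie in [0, min(n, M)]")
  stats::phyper(k - 1, M, N - M, n, lower.tail = FALSE)
}

# Unordered term-pair labels carried by one gene pair: every combination
# of a term of gene1 with a term of gene2, each counted once.
pair_term_labels <- function(t1, t2) {
  unique(as.vector(outer(t1, t2, function(a, b) {
    paste(pmin(a, b), pmax(a, b), sep = "|")
  })))
}

#' Enrichment of function pairs among module gene pairs
#'
#' Tests, for each unordered pair of annotation terms, whether module gene
#' pairs carry that term pair more often than expected from the universe
#' of gene pairs, with a hypergeometric upper-tail test (universe N gene
#' pairs, M carrying the term pair, n module pairs, k module pairs
#' carrying it).  Each gene contributes all its terms; unannotated genes
#' get the term \code{"unknown"}.  Bonferroni correction is over the
#' number of term pairs tested (those observed among module pairs).
#'
#' @param module_pairs data.frame with columns \code{gene1},
#'   \code{gene2}.
#' @param universe_pairs data.frame with columns \code{gene1},
#'   \code{gene2} (should contain the module pairs).
#' @param annotation Named list term -> gene ids (e.g. from
#'   \code{\link{read_gmt}}).
#' @return data.frame with columns \code{term1}, \code{term2}, \code{k},
#'   \code{M}, \code{n}, \code{N}, \code{p_raw}, \code{p_bonferroni},
#'   sorted by \code{p_raw}.
#' @export
pair_function_enrichment <- function(module_pairs, universe_pairs,
                                     annotation) {
  genes <- unique(c(universe_pairs$gene1, universe_pairs$gene2,
                    module_pairs$gene1, module_pairs$gene2))
  terms_of <- stats::setNames(vector("list", length(genes)), genes)
  for (g in genes) terms_of[[g]] <- character(0)
  for (tm in names(annotation)) {
    for (g in intersect(annotation[[tm]], genes)) {
      terms_of[[g]] <- c(terms_of[[g]], tm)
    }
  }
  terms_of <- lapply(terms_of, function(t) if (length(t)) t else "unknown")
  labels_of <- function(pairs) {
    lapply(seq_len(nrow(pairs)), function(i) {
      pair_term_labels(terms_of[[pairs$gene1[i]]],
                       terms_of[[pairs$gene2[i]]])
    })
  }
  uni_labels <- labels_of(universe_pairs)
  mod_labels <- labels_of(module_pairs)
  N <- nrow(universe_pairs)
  n <- nrow(module_pairs)
  tested <- sort(unique(unlist(mod_labels)))
  M_tab <- table(unlist(lapply(uni_labels, unique)))
  k_tab <- table(unlist(lapply(mod_labels, unique)))
  out <- data.frame(
    term1 = sub("\\|.*$", "", tested),
    term2 = sub("^.*\\|", "", tested),
    k = as.integer(k_tab[tested]),
    M = as.integer(ifelse(is.na(M_tab[tested]), 0L, M_tab[tested])),
    n = n, N = N, stringsAsFactors = FALSE)
  if (any(out$k > pmin(out$n, out$M))) {
    stop("module pairs carry a term pair absent from the universe; ",
         "universe_pairs must contain the module pairs")
  }
  out$p_raw <- mapply(hyper_tail_test, N = N, M = out$M, n = n, k = out$k)
  out$p_bonferroni <- pmin(1, out$p_raw * nrow(out))
  out[order(out$p_raw), ]
}

#' Enrichment of a function among genes in a set of chromosomal intervals
#'
#' The module loci are chromosomal intervals, each containing
#' \eqn{m_i} genes of which \eqn{k_i} carry the function of interest.
#' Under the null, the marked genes of interval i follow a hypergeometric
#' distribution (universe N, marked M, draws \eqn{m_i}), independently
#' across intervals; the p-value is the exact upper tail of the total
#' \eqn{\sum_i K_i \ge \sum_i k_i}, computed by convolution of the
#' per-interval distributions.  With a single interval this is the
#' standard hypergeometric test.
#'
#' @param N Total annotated genes.
#' @param M Genes carrying the function.
#' @param m Integer vector: genes per interval.
#' @param k Integer vector: function-carrying genes per interval.
#' @return The upper-tail p-value.
#' @export
interval_function_enrichment <- function(N, M, m, k) {
  if (length(m) != length(k)) stop("m and k must have equal lengths")
  if (sum(m) > N) stop("intervals contain more genes than the universe")
  if (M > N) stop("M must not exceed N")
  if (any(k > pmin(m, M)) || any(k < 0)) {
    stop("each k must lie in [0, min(m, M)]")
  }
  pmf <- 1
  for (i in seq_along(m)) {
    x <- 0:m[i]
    pmf_i <- stats::dhyper(x, M, N - M, m[i])
    new <- numeric(length(pmf) + m[i])
    for (j in seq_along(pmf_i)) {
      if (pmf_i[j] > 0) {
        new[seq_along(pmf) + j - 1L] <- new[seq_along(pmf) + j - 1L] +
          pmf * pmf_i[j]
      }
    }
    pmf <- new
  }
  total <- sum(k)
  sum(pmf[(total + 1L):length(pmf)])
}

#' Write an epistasis map as a TSV matrix
#'
#' @param map Matrix from \code{\link{build_epistasis_map}}.
#' @param path Output path.
#' @export
write_epistasis_map <- function(map, path) {
  utils::write.table(cbind(locus = rownames(map), as.data.frame(map)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
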