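#' Remove genes with too many missing values
#'
#' A gene is removed when its missing-value count exceeds \code{max_missing}
#' in any supplied condition, so the retained gene set is shared across
#' conditions.
#'
#' @param expr An expression matrix, or a list of expression matrices (one
#'   per condition) sharing the same genes.
#' @param max_missing Maximum tolerated missing values per gene (default 10).
#' @return The filtered matrix, or list of matrices filtered to the common
#'   retained gene set.
#' @export
filter_genes_by_missing <- function(expr, max_missing = 10L) {
  stopifnot(max_missing >= 0L)
  mats <- if (is.list(expr)) expr else list(expr)
  genes <- rownames(mats[[1L]])
  for (m in mats) {
    stopifnot(is.matrix(m))
    if (!identical(rownames(m), genes)) {
      stop("all condition matrices must share the same genes in the same order")
    }
  }
  drop <- Reduce(`|`, lapply(mats, function(m) rowSums(is.na(m)) > max_missing))
  if (all(drop)) warning("all genes removed by the missing-value filter")
  keep_one <- function(m) {
    cond <- attr(m, "condition")
    m <- m[!drop, , drop = FALSE]
    attr(m, "condition") <- cond
    m
  }
  if (is.list(expr)) lapply(mats, keep_one) else keep_one(mats[[1L]])
}

#' Normal quantile transformation
#'
#' Per gene, replaces each non-missing value by the normal quantile of its
#' rank: \eqn{\Phi^{-1}(r/(n_g+1))} where \eqn{n_g} is the gene's
#' non-missing count and ranks run 1..\eqn{n_g} (ties get average ranks).
#' Missing values stay missing.  The transformed values of a gene are a
#' fixed quantile set, so their mean is exactly 0 and their SD depends
#' only on \eqn{n_g} (about 0.97 at \eqn{n_g = 109}) — which is why the
#' bivariate model can fix both trait SDs at a constant.
#'
#' @param expr Expression matrix (genes x samples).
#' @return The transformed matrix, same shape and dimnames.
#' @export
normal_quantile_transform <- function(expr) {
  stopifnot(is.matrix(expr))
  out <- expr
  for (i in seq_len(nrow(expr))) {
    x <- expr[i, ]
    ok <- !is.na(x)
    n_g <- sum(ok)
    if (n_g < 3L) {
      stop("gene ", rownames(expr)[i], " has fewer than 3 non-missing values")
    }
    out[i, ok] <- stats::qnorm(rank(x[ok], ties.method = "average") / (n_g + 1))
  }
  attr(out, "condition") <- attr(expr, "condition")
  out
}

# Greedy left-to-right merging of position-sorted markers within each
# chromosome.  A marker joins the open group when its calls differ from the
# group's current representative in fewer than `max_discordant` samples.
# The representative is the per-sample majority vote over group members
# (ties resolved to the left-most member's call).
merge_engine <- function(calls, intervals, max_discordant) {
  groups <- list()
  for (chr in unique(intervals$chrom)) {
    idx <- which(intervals$chrom == chr)
    members <- idx[1L]
    rep_call <- calls[idx[1L], ]
    for (i in idx[-1L]) {
      if (sum(calls[i, ] != rep_call) < max_discordant) {
        members <- c(members, i)
        votes <- colMeans(calls[members, , drop = FALSE])
        rep_call <- ifelse(votes > 0.5, 1L,
                    ifelse(votes < 0.5, 0L, calls[members[1L], ]))
      } else {
        groups[[length(groups) + 1L]] <- members
        members <- i
        rep_call <- calls[i, ]
      }
    }
    groups[[length(groups) + 1L]] <- members
  }
  groups
}

#' Merge neighbouring markers with near-identical genotypes
#'
#' In a segregant panel, tightly linked markers carry almost the same call
#' vector.  Neighbouring markers on a chromosome are combined greedily,
#' left to right, whenever the incoming marker differs from the current
#' group's consensus in fewer than \code{max_discordant} samples.  The
#' merged marker keeps the left-most member's id, takes the per-sample
#' majority-vote call (ties resolved to the left-most member), and spans
#' the union of the member intervals.
#'
#' @param geno A \code{\link{genotype_matrix}} (position-sorted).
#' @param max_discordant Discordance threshold: strictly fewer than this
#'   many differing calls allows a merge (default 5).
#' @return A list: \code{geno}, the merged \code{genotype_matrix}; and
#'   \code{map}, a data.frame with columns \code{merged_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{source_ids} (comma-joined).
#' @export
merge_markers <- function(geno, max_discordant = 5L) {
  stopifnot(inherits(geno, "genotype_matrix"), max_discordant >= 0L)
  calls <- geno$calls
  iv <- geno$intervals
  groups <- merge_engine(calls, iv, max_discordant)
  merged_calls <- matrix(0L, length(groups), ncol(calls),
                         dimnames = list(NULL, colnames(calls)))
  map <- data.frame(merged_id = character(length(groups)),
                    chrom = character(length(groups)),
                    start = integer(length(groups)),
                    end = integer(length(groups)),
                    source_ids = character(length(groups)),
                    stringsAsFactors = FALSE)
  for (g in seq_along(groups)) {
    members <- groups[[g]]
    votes <- colMeans(calls[members, , drop = FALSE])
    merged_calls[g, ] <- ifelse(votes > 0.5, 1L,
                          ifelse(votes < 0.5, 0L, calls[members[1L], ]))
    map$merged_id[g] <- rownames(calls)[members[1L]]
    map$chrom[g] <- iv$chrom[members[1L]]
    map$start[g] <- min(iv$start[members])
    map$end[g] <- max(iv$end[members])
    map$source_ids[g] <- paste(rownames(calls)[members], collapse = ",")
  }
  rownames(merged_calls) <- map$merged_id
  merged <- genotype_matrix(merged_calls,
                            data.frame(marker_id = map$merged_id,
                                       chrom = map$chrom,
                                       start = map$start, end = map$end))
  list(geno = merged, map = map)
}

#' Write a marker merge map as TSV
#'
#' @param map The \code{map} element returned by \code{\link{merge_markers}}.
#' @param path Output path.
#' @export
write_merge_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Enumerate marker pairs with adequately populated joint genotypes
#'
#' A marker pair is eligible when each of the four joint-genotype classes
#' (0,0), (0,1), (1,0), (1,1) contains at least \code{min_class_size}
#' samples.  Counts are computed for all unordered pairs at once by matrix
#' products on the binary call matrix.
#'
#' @param geno A \code{\link{genotype_matrix}}.
#' @param min_class_size Minimum per-class count (default 15).
#' @return data.frame with columns \code{marker1}, \code{marker2} (in
#'   position order), \code{n_00}, \code{n_01}, \code{n_10}, \code{n_11},
#'   one row per eligible pair.
#' @export
eligible_marker_pairs <- function(geno, min_class_size = 15L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  G <- geno$calls
  m <- nrow(G)
  if (m < 2L) {
    return(data.frame(marker1 = character(), marker2 = character(),
                      n_00 = integer(), n_01 = integer(),
                      n_10 = integer(), n_11 = integer()))
  }
  n11 <- tcrossprod(G)
  n10 <- tcrossprod(G, 1L - G)
  n01 <- t(n10)
  n00 <- tcrossprod(1L - G)
  storage.mode(n11) <- "integer"
  storage.mode(n10) <- "integer"
  storage.mode(n01) <- "integer"
  storage.mode(n00) <- "integer"
  ut <- upper.tri(n11)
  ok <- ut & n00 >= min_class_size & n01 >= min_class_size &
    n10 >= min_class_size & n11 >= min_class_size
  idx <- which(ok, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(marker1 = rownames(G)[idx[, 1L]],
             marker2 = rownames(G)[idx[, 2L]],
             n_00 = n00[idx], n_01 = n01[idx],
             n_10 = n10[idx], n_11 = n11[idx],
             stringsAsFactors = FALSE)
}
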