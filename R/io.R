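#' Read an expression table
#'
#' Reads a tab-delimited genes x samples expression table.  The first row
#' holds sample ids, the first column gene ids.  Empty fields and the
#' literal string \code{"NA"} are treated as missing values.
#'
#' @param path Path to a tab-delimited text file.
#' @param condition Optional condition label (e.g. \code{"glucose"}),
#'   stored as the \code{"condition"} attribute of the returned matrix.
#' @return A numeric matrix (genes x samples) with gene ids as rownames,
#'   sample ids as colnames and \code{NA} marking missing values.
#' @export
read_expression_table <- function(path, condition = NA_character_) {
  lines <- readLines(path)
  if (length(lines) < 2L) {
    stop("expression table needs a header row and at least one gene row")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  sample_ids <- header[-1L]
  ncol_expect <- length(header)
  widths <- lengths(fields[-1L])
  bad <- which(widths != ncol_expect)
  if (length(bad) > 0L) {
    stop(sprintf("ragged expression table: line %d has %d fields, expected %d",
                 bad[1L] + 1L, widths[bad[1L]], ncol_expect))
  }
  gene_ids <- vapply(fields[-1L], `[[`, character(1L), 1L)
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids in expression table: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in expression table")
  }
  cells <- do.call(rbind, lapply(fields[-1L], `[`, -1L))
  cells[cells == "" | cells == "NA"] <- NA_character_
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  nonnum <- !is.na(cells) & is.na(values)
  if (any(nonnum)) {
    stop("non-numeric expression value: ", cells[which(nonnum)[1L]])
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  attr(values, "condition") <- condition
  values
}

#' Write an expression table
#'
#' Inverse of \code{\link{read_expression_table}}; missing values are
#' written as \code{"NA"}.
#'
#' @param expr Numeric genes x samples matrix with dimnames.
#' @param path Output path.
#' @export
write_expression_table <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(expr)), collapse = "\t"), con)
  body <- apply(format(expr, trim = TRUE, digits = 15), 1L, paste, collapse = "\t")
  writeLines(paste(rownames(expr), body, sep = "\t"), con)
  invisible(path)
}

#' Genotype matrix with marker intervals
#'
#' Bundles a binary markers x samples call matrix with per-marker genomic
#' intervals.  Calls are coded 0/1 (in a BY x RM yeast cross: BY = 1,
#' RM = 0); missing calls are not supported.  Markers are stored sorted by
#' (chromosome, start); coordinates are 1-based inclusive base pairs.
#'
#' @param calls Integer matrix (markers x samples), entries in {0,1},
#'   rownames marker ids, colnames sample ids.
#' @param intervals data.frame with columns \code{marker_id},
#'   \code{chrom}, \code{start}, \code{end}, one row per marker.
#' @return An object of class \code{"genotype_matrix"}: a list with
#'   elements \code{calls} and \code{intervals}, both in position order.
#' @export
genotype_matrix <- function(calls, intervals) {
  if (!is.matrix(calls) || is.null(rownames(calls)) || is.null(colnames(calls))) {
    stop("calls must be a matrix with marker rownames and sample colnames")
  }
  if (anyNA(calls)) stop("missing genotype calls are not supported")
  if (!all(calls %in% c(0L, 1L))) {
    stop("genotype calls must all be 0 or 1; found: ",
         paste(utils::head(setdiff(unique(as.vector(calls)), c(0, 1))), collapse = ", "))
  }
  storage.mode(calls) <- "integer"
  need <- c("marker_id", "chrom", "start", "end")
  if (!all(need %in% names(intervals))) {
    stop("intervals must have columns: ", paste(need, collapse = ", "))
  }
  intervals <- as.data.frame(intervals)[, need]
  if (anyDuplicated(rownames(calls))) stop("duplicate marker ids")
  missing_iv <- setdiff(rownames(calls), intervals$marker_id)
  if (length(missing_iv) > 0L) {
    stop("markers without intervals: ", paste(utils::head(missing_iv), collapse = ", "))
  }
  intervals <- intervals[match(rownames(calls), intervals$marker_id), ]
  if (any(intervals$start > intervals$end)) {
    bad <- intervals$marker_id[intervals$start > intervals$end][1L]
    stop("degenerate interval (start > end) for marker ", bad)
  }
  ord <- order(intervals$chrom, intervals$start)
  intervals <- intervals[ord, , drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(calls = calls[ord, , drop = FALSE], intervals = intervals),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d markers x %d samples on %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$intervals$chrom))))
  invisible(x)
}

#' Read a genotype table with marker intervals
#'
#' @param path Tab-delimited calls file, markers x samples, first row
#'   sample ids, first column marker ids, entries in {0,1}.
#' @param interval_path Tab-delimited intervals file with header columns
#'   \code{marker_id}, \code{chrom}, \code{start}, \code{end}.
#' @return A \code{\link{genotype_matrix}} sorted by genomic position.
#' @export
read_genotype_table <- function(path, interval_path) {
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  marker_ids <- tab[[1L]]
  calls <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(calls) <- "integer")
  rownames(calls) <- marker_ids
  iv <- utils::read.delim(interval_path, check.names = FALSE)
  genotype_matrix(calls, iv)
}

#' Write a genotype table and its intervals
#'
#' @param geno A \code{\link{genotype_matrix}}.
#' @param path Calls output path.
#' @param interval_path Intervals output path.
#' @export
write_genotype_table <- function(geno, path, interval_path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  con <- file(path, "w")
  writeLines(paste(c("marker", colnames(geno$calls)), collapse = "\t"), con)
  writeLines(paste(rownames(geno$calls),
                   apply(geno$calls, 1L, paste, collapse = "\t"), sep = "\t"), con)
  close(con)
  utils::write.table(geno$intervals, interval_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict expression and genotypes to their shared samples
#'
#' Both inputs are restricted to the intersection of their sample ids, in
#' sorted (hence canonical) order; the operation is idempotent.  Dropped
#' samples are reported with a warning.
#'
#' @param expr Expression matrix (genes x samples).
#' @param geno A \code{\link{genotype_matrix}}.
#' @return A list with elements \code{expr} and \code{geno}.
#' @export
align_samples <- function(expr, geno) {
  stopifnot(is.matrix(expr), inherits(geno, "genotype_matrix"))
  shared <- sort(intersect(colnames(expr), colnames(geno$calls)))
  if (length(shared) == 0L) stop("expression and genotypes share no samples")
  dropped <- setdiff(union(colnames(expr), colnames(geno$calls)), shared)
  if (length(dropped) > 0L) {
    warning("dropping samples absent from one input: ",
            paste(dropped, collapse = ", "))
  }
  cond <- attr(expr, "condition")
  expr <- expr[, shared, drop = FALSE]
  attr(expr, "condition") <- cond
  geno$calls <- geno$calls[, shared, drop = FALSE]
  list(expr = expr, geno = geno)
}

#' Read gene annotations in GMT format
#'
#' Each line is: term, description, then member gene ids, tab-delimited.
#'
#' @param path Path to a GMT file.
#' @return A named list mapping term -> character vector of gene ids; term
#'   descriptions are kept in the \code{"descriptions"} attribute.
#' @export
read_gmt <- function(path) {
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  fields <- fields[lengths(fields) > 0L]
  if (any(lengths(fields) < 3L)) {
    stop("GMT lines need at least term, description and one gene")
  }
  terms <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(terms)) stop("duplicate GMT terms")
  out <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(out) <- terms
  attr(out, "descriptions") <- stats::setNames(
    vapply(fields, `[[`, character(1L), 2L), terms)
  out
}
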