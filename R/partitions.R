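# The four joint genotypes of two biallelic haploid markers, in canonical
# order.  Class assignments and per-class parameters are always keyed by
# these labels.
JOINT_GENOTYPES <- c("00", "01", "10", "11")

#' Enumerate genotype partitions
#'
#' Every way of assigning the four joint genotypes {(0,0),(0,1),(1,0),(1,1)}
#' to correlation classes is a set partition of a 4-element set; there are
#' Bell(4) = 15.  Each partition gets a role:
#' \itemize{
#'   \item \code{null} — one class (correlation independent of genotype);
#'   \item \code{marginal_m1} / \code{marginal_m2} — the two-class
#'     partitions splitting purely by the first / second marker;
#'   \item \code{epistatic} — the remaining 12, in which the class of a
#'     sample cannot be read off either marker alone.
#' }
#' Ordering is canonical (by number of classes, then by the restricted
#' growth string), so partition ids are stable across runs.
#'
#' @return A list of 15 partitions, each a list with elements \code{id}
#'   (e.g. \code{"P07"}), \code{class_of} (named integer vector over the
#'   joint genotypes, classes 1..k), \code{k}, and \code{role}.
#' @export
enumerate_partitions <- function() {
  # restricted growth strings over 4 elements: a1 = 1, a_{i+1} <= max + 1
  rgs <- list(integer(0))
  for (i in 1:4) {
    rgs <- do.call(c, lapply(rgs, function(a) {
      top <- if (length(a) == 0L) 0L else max(a)
      lapply(seq_len(top + 1L), function(v) c(a, v))
    }))
  }
  ks <- vapply(rgs, max, integer(1L))
  ord <- order(ks, vapply(rgs, paste, character(1L), collapse = ""))
  rgs <- rgs[ord]
  out <- vector("list", length(rgs))
  for (i in seq_along(rgs)) {
    a <- rgs[[i]]
    names(a) <- JOINT_GENOTYPES
    k <- max(a)
    role <- if (k == 1L) {
      "null"
    } else if (identical(unname(a), c(1L, 1L, 2L, 2L))) {
      "marginal_m1"                       # split by the first marker
    } else if (identical(unname(a), c(1L, 2L, 1L, 2L))) {
      "marginal_m2"                       # split by the second marker
    } else {
      "epistatic"
    }
    out[[i]] <- list(id = sprintf("P%02d", i), class_of = a, k = k, role = role)
  }
  out
}

#' Partition catalogue as a data.frame
#'
#' @return data.frame with columns \code{id}, \code{assignment} (e.g.
#'   \code{"00:1,01:1,10:1,11:2"}), \code{k}, \code{role}.
#' @export
partition_catalogue <- function() {
  parts <- enumerate_partitions()
  data.frame(
    id = vapply(parts, `[[`, character(1L), "id"),
    assignment = vapply(parts, function(p)
      paste(sprintf("%s:%d", names(p$class_of), p$class_of), collapse = ","),
      character(1L)),
    k = vapply(parts, `[[`, integer(1L), "k"),
    role = vapply(parts, `[[`, character(1L), "role"),
    stringsAsFactors = FALSE)
}

#' Write the partition catalogue as TSV
#'
#' @param path Output path.
#' @export
write_partition_catalogue <- function(path) {
  utils::write.table(partition_catalogue(), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# TRUE when `coarse` is a coarsening of `fine` (every class of `fine`
# lies inside one class of `coarse`), i.e. the two models are nested.
is_coarsening <- function(coarse, fine) {
  tab <- table(fine$class_of, coarse$class_of)
  all(rowSums(tab > 0L) == 1L)
}

# Class label (integer 1..k) of every sample given the partition and the
# two marker call vectors.
class_assignments <- function(partition, g1, g2) {
  stopifnot(length(g1) == length(g2))
  partition$class_of[paste0(g1, g2)]
}
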