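#' PA score (Potential of Association) of one module
#'
#' A closed-form screening statistic for correlation heterogeneity across
#' the four joint-genotype classes, computed directly from Pearson
#' correlations without any likelihood optimization:
#' \deqn{PA = \sum_{(i,j)} n_{ij} [\ln(1 - r^2) - \ln(1 - r_{ij}^2)]}
#' where \eqn{n_{ij}} and \eqn{r_{ij}} are the sample count and Pearson
#' correlation of the two traits within joint-genotype class (i,j), and
#' \eqn{r} is the all-sample correlation.  PA lives on the same scale as
#' the full-model LR statistic and bounds its attainable significance, so
#' modules with small PA can be skipped before the expensive LR fits.
#'
#' @param x,y Trait vectors (no missing values; drop incomplete samples
#'   first).
#' @param g1,g2 Binary genotype vectors at the two markers.
#' @return A list of class \code{"pa_stat"}: \code{pa}, \code{r_overall},
#'   \code{r_class} (named by joint genotype), \code{n_class}.
#' @export
pa_score <- function(x, y, g1, g2) {
  if (length(unique(c(length(x), length(y), length(g1), length(g2)))) != 1L) {
    stop("x, y, g1, g2 must have equal lengths")
  }
  if (anyNA(x) || anyNA(y)) stop("pa_score expects complete trait values")
  cls <- factor(paste0(g1, g2), levels = JOINT_GENOTYPES)
  n_class <- as.integer(table(cls))
  names(n_class) <- JOINT_GENOTYPES
  if (any(n_class < 2L)) stop("every joint-genotype class needs >= 2 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero trait variance across all samples")
  }
  r_overall <- stats::cor(x, y)
  r_class <- vapply(JOINT_GENOTYPES, function(cc) {
    idx <- which(cls == cc)
    if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) {
      stop("zero trait variance within joint-genotype class ", cc)
    }
    stats::cor(x[idx], y[idx])
  }, numeric(1L))
  if (any(abs(r_class) >= 1)) {
    stop("degenerate within-class correlation |r| = 1")
  }
  pa <- sum(n_class * (log1p(-r_overall^2) - log1p(-r_class^2)))
  structure(list(pa = pa, r_overall = r_overall,
                 r_class = r_class, n_class = n_class),
            class = "pa_stat")
}

#' Filter candidate modules by PA score
#'
#' Retains, in order, exactly the candidates whose \code{pa} column is at
#' least \code{cutoff}; rows with \code{NA} PA (degenerate classes that
#' could not be scored) are dropped.
#'
#' @param candidates data.frame with a numeric \code{pa} column.
#' @param cutoff Non-negative PA cutoff (default 45).
#' @return The retained rows of \code{candidates}.
#' @export
pa_filter <- function(candidates, cutoff = 45) {
  stopifnot(is.data.frame(candidates), "pa" %in% names(candidates),
            cutoff >= 0)
  candidates[!is.na(candidates$pa) & candidates$pa >= cutoff, , drop = FALSE]
}

#' Calibrate the PA cutoff from paired PA and LR values
#'
#' Given PA and LR statistics of the same modules (from simulation or a
#' data subsample), the cutoff \code{lr_threshold + q}, with \code{q} the
#' empirical \code{quantile} of \code{pa - lr}, bounds the fraction of
#' LR-significant modules lost to the PA filter at the quantile level
#' (i.e. filter sensitivity about \code{1 - quantile}).
#'
#' @param pa_values,lr_values Paired numeric vectors (at least 100 pairs).
#' @param lr_threshold LR-statistic threshold corresponding to the scan's
#'   p-value cutoff.
#' @param quantile Target false-removal level in (0,1) (default 0.005).
#' @return The calibrated PA cutoff (scalar).
#' @export
calibrate_pa_cutoff <- function(pa_values, lr_values, lr_threshold,
                                quantile = 0.005) {
  if (length(pa_values) != length(lr_values)) {
    stop("pa_values and lr_values must be paired")
  }
  if (length(pa_values) < 100L) {
    stop("need at least 100 pa/lr pairs for a stable quantile")
  }
  if (quantile <= 0 || quantile >= 1) stop("quantile must lie in (0,1)")
  lr_threshold + unname(stats::quantile(pa_values - lr_values, quantile,
                                        type = 7))
}
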