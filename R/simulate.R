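#' Specification of a synthetic segregant-panel dataset
#'
#' Describes a haploid biparental cross (binary markers with chromosomal
#' linkage) plus bivariate expression whose correlation — and optionally
#' mean and variance — depends on the joint genotype at a planted marker
#' pair.
#'
#' @param n_samples Number of segregants.
#' @param chromosomes List of chromosomes, each \code{list(n_markers =,
#'   recomb =)} with \code{recomb} the inter-marker recombination
#'   probability in (0, 0.5].
#' @param modules List of planted modules, each \code{list(marker1 =,
#'   marker2 =, partition_id =, rho =)} with \code{rho} a per-class
#'   correlation vector (length = number of classes of the partition);
#'   optional \code{means} (per-class 2-column matrix or per-class vector
#'   applied to both traits) and \code{sds} (per-class common SD) switch
#'   on genotype-dependent means / variances.
#' @param n_background_genes Genes with no genotype dependence.
#' @param background_cor Exchangeable correlation among background genes
#'   (default 0), generated through a shared latent factor.
#' @param sd Baseline trait SD (default 0.97, matching the fixed-SD model
#'   assumption after normal quantile transformation).
#' @param rng_seed Seed making the dataset fully reproducible.
#' @return A list of class \code{"sim_spec"}.
#' @export
sim_spec <- function(n_samples,
                     chromosomes = list(list(n_markers = 3L, recomb = 0.3)),
                     modules = list(),
                     n_background_genes = 10L,
                     background_cor = 0,
                     sd = 0.97,
                     rng_seed = 1L) {
  stopifnot(n_samples >= 4L, n_background_genes >= 0L,
            sd > 0, background_cor >= 0, background_cor < 1)
  for (ch in chromosomes) {
    if (ch$recomb <= 0 || ch$recomb > 0.5) {
      stop("recombination probabilities must lie in (0, 0.5]")
    }
  }
  parts <- enumerate_partitions()
  ids <- vapply(parts, `[[`, character(1L), "id")
  for (m in modules) {
    hit <- match(m$partition_id, ids)
    if (is.na(hit)) stop("unknown partition id: ", m$partition_id)
    p <- parts[[hit]]
    if (length(m$rho) != p$k) {
      stop("module rho must have one entry per partition class")
    }
    if (any(abs(m$rho) >= 1)) stop("|rho| must be < 1")
  }
  structure(list(n_samples = as.integer(n_samples), chromosomes = chromosomes,
                 modules = modules,
                 n_background_genes = as.integer(n_background_genes),
                 background_cor = background_cor, sd = sd,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_spec")
}

#' Simulate segregant genotypes with chromosomal linkage
#'
#' Per sample and chromosome, the first marker is Bernoulli(0.5) and each
#' subsequent marker flips allele with the chromosome's recombination
#' probability (a two-state Markov chain).  This produces the runs of
#' near-identical neighbouring markers that make marker merging and
#' duplicate-module collapsing meaningful.
#'
#' @param spec A \code{\link{sim_spec}} (only the genotype fields are
#'   used).
#' @return A \code{\link{genotype_matrix}}; markers are named
#'   \code{chr<c>_m<i>} and spaced 20 kb apart (1 kb wide).
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$rng_seed, {
    rows <- list()
    iv <- list()
    for (c_i in seq_along(spec$chromosomes)) {
      ch <- spec$chromosomes[[c_i]]
      m <- ch$n_markers
      calls <- matrix(0L, m, spec$n_samples)
      calls[1L, ] <- stats::rbinom(spec$n_samples, 1L, 0.5)
      if (m > 1L) for (i in 2:m) {
        flip <- stats::rbinom(spec$n_samples, 1L, ch$recomb)
        calls[i, ] <- bitwXor(calls[i - 1L, ], flip)
      }
      rownames(calls) <- sprintf("chr%02d_m%02d", c_i, seq_len(m))
      rows[[c_i]] <- calls
      start <- (seq_len(m) - 1L) * 20000L + 1L
      iv[[c_i]] <- data.frame(marker_id = rownames(calls),
                              chrom = sprintf("chr%02d", c_i),
                              start = start, end = start + 999L)
    }
    calls <- do.call(rbind, rows)
    colnames(calls) <- sprintf("seg%03d", seq_len(spec$n_samples))
    genotype_matrix(calls, do.call(rbind, iv))
  })
}

# Draw one bivariate normal pair per sample with per-sample parameters.
rbvn <- function(mu_x, mu_y, sd_vec, rho_vec) {
  n <- length(rho_vec)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  x <- mu_x + sd_vec * z1
  y <- mu_y + sd_vec * (rho_vec * z1 + sqrt(1 - rho_vec^2) * z2)
  cbind(x = x, y = y)
}

#' Simulate one module's trait pair given genotypes
#'
#' Each sample's (x, y) is drawn from a bivariate normal whose correlation
#' is set by the sample's class under the module's genotype partition;
#' means and SDs are genotype-dependent only when per-class values are
#' supplied.
#'
#' @param genotypes A \code{\link{genotype_matrix}}.
#' @param marker1,marker2 Marker ids of the planted pair.
#' @param partition_id Partition id (see
#'   \code{\link{enumerate_partitions}}).
#' @param rho Per-class correlations (length = partition classes).
#' @param means Optional per-class means: a vector (applied to both
#'   traits) or a 2-column matrix (x, y); default 0.
#' @param sds Optional per-class common SD; default \code{sd}.
#' @param sd Baseline SD used for classes without an explicit entry
#'   (default 0.97).
#' @return A 2-column matrix (x, y) with one row per sample.
#' @export
simulate_module <- function(genotypes, marker1, marker2, partition_id, rho,
                            means = NULL, sds = NULL, sd = 0.97) {
  parts <- enumerate_partitions()
  hit <- match(partition_id, vapply(parts, `[[`, character(1L), "id"))
  if (is.na(hit)) stop("unknown partition id: ", partition_id)
  part <- parts[[hit]]
  if (length(rho) != part$k) stop("rho must have one entry per class")
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1")
  g1 <- genotypes$calls[marker1, ]
  g2 <- genotypes$calls[marker2, ]
  cls <- class_assignments(part, g1, g2)
  mu <- if (is.null(means)) matrix(0, part$k, 2L)
        else if (is.matrix(means)) means else cbind(means, means)
  sdv <- if (is.null(sds)) rep(sd, part$k) else sds
  if (nrow(mu) != part$k || length(sdv) != part$k) {
    stop("means/sds must have one entry per class")
  }
  if (any(sdv <= 0)) stop("class SDs must be > 0")
  rbvn(mu[cls, 1L], mu[cls, 2L], sdv[cls], rho[cls])
}

#' Build a benchmark dataset with planted epistatic modules
#'
#' Background genes have no genotype dependence (optionally an
#' exchangeable correlation through a shared latent factor); each planted
#' module contributes one gene pair drawn by \code{\link{simulate_module}}.
#' The returned truth table records every planted signal.
#'
#' @param spec A \code{\link{sim_spec}}.
#' @return A list: \code{expr} (genes x samples matrix), \code{geno}
#'   (a \code{genotype_matrix}), \code{truth} (data.frame with columns
#'   \code{gene1}, \code{gene2}, \code{marker1}, \code{marker2},
#'   \code{partition_id}, \code{rho}).
#' @export
make_benchmark_dataset <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  geno <- simulate_genotypes(spec)
  with_seed(spec$rng_seed + 1L, {
    n <- spec$n_samples
    rows <- list()
    truth <- list()
    for (m_i in seq_along(spec$modules)) {
      m <- spec$modules[[m_i]]
      xy <- simulate_module(geno, m$marker1, m$marker2, m$partition_id,
                            m$rho, means = m$means, sds = m$sds,
                            sd = spec$sd)
      gx <- sprintf("mod%02d_g1", m_i)
      gy <- sprintf("mod%02d_g2", m_i)
      rows[[gx]] <- xy[, 1L]
      rows[[gy]] <- xy[, 2L]
      g12 <- sort(c(gx, gy))
      truth[[m_i]] <- data.frame(gene1 = g12[1L], gene2 = g12[2L],
                                 marker1 = m$marker1, marker2 = m$marker2,
                                 partition_id = m$partition_id,
                                 rho = paste(m$rho, collapse = ","),
                                 stringsAsFactors = FALSE)
    }
    if (spec$n_background_genes > 0L) {
      f <- stats::rnorm(n)
      a <- sqrt(spec$background_cor)
      b <- sqrt(1 - spec$background_cor)
      for (g_i in seq_len(spec$n_background_genes)) {
        rows[[sprintf("bg%03d", g_i)]] <-
          spec$sd * (a * f + b * stats::rnorm(n))
      }
    }
    expr <- do.call(rbind, rows)
    colnames(expr) <- colnames(geno$calls)
    truth <- if (length(truth) > 0L) do.call(rbind, truth) else
      data.frame(gene1 = character(), gene2 = character(),
                 marker1 = character(), marker2 = character(),
                 partition_id = character(), rho = character())
    list(expr = expr, geno = geno, truth = truth)
  })
}

#' The bundled demo specification
#'
#' A small but complete benchmark: 20 genes (3 planted module pairs + 14
#' background genes) and 12 markers on four chromosomes of a 150-segregant
#' panel.  The three planted modules cover the qualitatively different
#' epistatic patterns: a single divergent joint genotype ((1,1) vs rest),
#' an XOR pattern with no marginal signal, and a three-class gradient.
#'
#' @param rng_seed Seed (default 1).
#' @return A \code{\link{sim_spec}}.
#' @export
demo_sim_spec <- function(rng_seed = 1L) {
  parts <- partition_catalogue()
  id_of <- function(assign) parts$id[parts$assignment == assign]
  sim_spec(
    n_samples = 150L,
    chromosomes = list(list(n_markers = 3L, recomb = 0.3),
                       list(n_markers = 3L, recomb = 0.3),
                       list(n_markers = 3L, recomb = 0.3),
                       list(n_markers = 3L, recomb = 0.3)),
    modules = list(
      # one divergent joint genotype: rho 0.9 in class (1,1), 0 elsewhere
      list(marker1 = "chr01_m01", marker2 = "chr02_m01",
           partition_id = id_of("00:1,01:1,10:1,11:2"), rho = c(0, 0.9)),
      # XOR: correlated when alleles agree, anti-correlated when they differ
      list(marker1 = "chr02_m03", marker2 = "chr03_m02",
           partition_id = id_of("00:1,01:2,10:2,11:1"), rho = c(0.8, -0.4)),
      # three-class gradient keyed to the joint genotype
      list(marker1 = "chr03_m03", marker2 = "chr04_m01",
           partition_id = id_of("00:1,01:2,10:2,11:3"),
           rho = c(-0.6, 0, 0.8))),
    n_background_genes = 14L,
    background_cor = 0,
    sd = 0.97,
    rng_seed = rng_seed)
}
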