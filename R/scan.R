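#' Single-trait (1D) eQTL linkage p-values
#'
#' Two-sided Wilcoxon rank-sum test of each gene's expression split by
#' each marker's genotype.  Used to remove modules whose association is
#' already visible at the single-gene expression level (mean shifts), so
#' the scan keeps only correlation-level signals.
#'
#' @param expr Expression matrix (genes x samples; NA allowed).
#' @param geno A \code{\link{genotype_matrix}} on the same samples.
#' @return A genes x markers matrix of p-values.  A marker with an empty
#'   genotype class yields p = 1 with a warning.
#' @export
one_d_linkage <- function(expr, geno) {
  stopifnot(is.matrix(expr), inherits(geno, "genotype_matrix"),
            identical(colnames(expr), colnames(geno$calls)))
  G <- geno$calls
  p <- matrix(1, nrow(expr), nrow(G),
              dimnames = list(rownames(expr), rownames(G)))
  for (m in seq_len(nrow(G))) {
    in1 <- G[m, ] == 1L
    if (all(in1) || !any(in1)) {
      warning("marker ", rownames(G)[m], " has a single genotype class; p = 1")
      next
    }
    for (g in seq_len(nrow(expr))) {
      x0 <- expr[g, !in1]; x1 <- expr[g, in1]
      x0 <- x0[!is.na(x0)]; x1 <- x1[!is.na(x1)]
      if (length(x0) == 0L || length(x1) == 0L) next
      p[g, m] <- suppressWarnings(
        stats::wilcox.test(x1, x0, alternative = "two.sided")$p.value)
    }
  }
  p
}

#' Remove candidates explainable by single-gene linkage
#'
#' A candidate is removed when either of its genes is linked (Wilcoxon
#' p < \code{threshold}) to either of its markers; survivors carry
#' \code{passed_1d = TRUE}.
#'
#' @param candidates data.frame with columns \code{gene1}, \code{gene2},
#'   \code{marker1}, \code{marker2}.
#' @param pmat p-value matrix from \code{\link{one_d_linkage}} covering
#'   all candidate genes and markers.
#' @param threshold 1D linkage p-value threshold (default 1e-5).
#' @return \code{candidates} with a logical \code{passed_1d} column,
#'   restricted to the passing rows.
#' @export
one_d_filter <- function(candidates, pmat, threshold = 1e-5) {
  stopifnot(all(c("gene1", "gene2", "marker1", "marker2") %in%
                  names(candidates)))
  pass <- pmat[cbind(candidates$gene1, candidates$marker1)] >= threshold &
    pmat[cbind(candidates$gene1, candidates$marker2)] >= threshold &
    pmat[cbind(candidates$gene2, candidates$marker1)] >= threshold &
    pmat[cbind(candidates$gene2, candidates$marker2)] >= threshold
  out <- candidates[pass, , drop = FALSE]
  out$passed_1d <- rep(TRUE, nrow(out))
  out
}

# Format a per-class rho vector as "1:0.812,2:-0.034".
format_rho <- function(rho) {
  paste(sprintf("%d:%.4f", seq_along(rho), rho), collapse = ",")
}

#' Exhaustive two-locus scan for epistatic co-expression modules
#'
#' For every gene pair crossed with every eligible marker pair, runs the
#' filter cascade: PA pre-filter, 1D (single-gene linkage) filter,
#' likelihood-ratio model selection over the 12 epistatic genotype
#' partitions, and the epistasis-vs-marginal test.  Every evaluated
#' candidate is emitted with its stage flags so filter attrition is
#' auditable; \code{significant} marks candidates surviving the whole
#' cascade at \code{config$p_threshold}.
#'
#' The result is deterministic given the inputs and config, and invariant
#' to gene and marker input order (module identities are canonicalized:
#' genes lexicographically, markers by genomic position).
#'
#' @param expr Expression matrix (genes x samples), normal quantile
#'   transformed; NA marks missing values.
#' @param geno A \code{\link{genotype_matrix}} on the same samples
#'   (use \code{\link{align_samples}} first if needed).
#' @param config A \code{\link{scan_config}}.
#' @param quiet Suppress the stage-count messages (default FALSE).
#' @return data.frame with one row per evaluated candidate: ids, class
#'   counts, \code{pa}, stage flags, and for candidates reaching the LR
#'   stage the selected \code{partition_id}, \code{rho_hat},
#'   \code{loglik_alt}, \code{loglik_null}, \code{lr}, \code{df},
#'   \code{p_value}, \code{p_marginal1}, \code{p_marginal2},
#'   \code{epistasis_p}.  Stage counts are attached as the
#'   \code{"stage_counts"} attribute.
#' @export
exhaustive_scan <- function(expr, geno, config = scan_config(),
                            quiet = FALSE) {
  stopifnot(is.matrix(expr), inherits(geno, "genotype_matrix"))
  if (!identical(colnames(expr), colnames(geno$calls))) {
    stop("expression and genotype samples differ; run align_samples() first")
  }
  elig <- eligible_marker_pairs(geno, config$min_class_size)
  if (nrow(elig) == 0L) stop("no eligible marker pairs")
  genes <- sort(rownames(expr))
  if (length(genes) < 2L) stop("need at least two genes")
  E <- t(expr[genes, , drop = FALSE])        # samples x genes
  obs <- !is.na(E)
  gp <- utils::combn(length(genes), 2L)
  gi <- gp[1L, ]; gj <- gp[2L, ]
  gp_idx <- cbind(gi, gj)
  n_gp <- ncol(gp)
  pmat <- one_d_linkage(expr, geno)
  R_all <- suppressWarnings(stats::cor(E, use = "pairwise.complete.obs"))

  blocks <- vector("list", nrow(elig))
  for (mp in seq_len(nrow(elig))) {
    m1 <- elig$marker1[mp]; m2 <- elig$marker2[mp]
    cls <- paste0(geno$calls[m1, ], geno$calls[m2, ])
    pa_sum <- numeric(n_gp)
    degenerate <- rep(FALSE, n_gp)
    counts <- matrix(0L, n_gp, 4L, dimnames = list(NULL, JOINT_GENOTYPES))
    for (cc in JOINT_GENOTYPES) {
      idx <- which(cls == cc)
      n_c <- crossprod(obs[idx, , drop = FALSE])[gp_idx]
      r_c <- suppressWarnings(
        stats::cor(E[idx, , drop = FALSE],
                   use = "pairwise.complete.obs"))[gp_idx]
      counts[, cc] <- n_c
      bad <- is.na(r_c) | abs(r_c) >= 1 - 1e-12 | n_c < 2L
      degenerate <- degenerate | bad
      term <- n_c * (log1p(-R_all[gp_idx]^2) - log1p(-r_c^2))
      pa_sum <- pa_sum + ifelse(bad, 0, term)
    }
    pa_sum[degenerate] <- NA_real_
    blocks[[mp]] <- data.frame(
      gene1 = genes[gi], gene2 = genes[gj],
      marker1 = m1, marker2 = m2,
      n_00 = counts[, "00"], n_01 = counts[, "01"],
      n_10 = counts[, "10"], n_11 = counts[, "11"],
      pa = pa_sum,
      eligible = counts[, "00"] >= config$min_class_size &
        counts[, "01"] >= config$min_class_size &
        counts[, "10"] >= config$min_class_size &
        counts[, "11"] >= config$min_class_size & !degenerate,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, blocks)
  res$passed_pa <- res$eligible & !is.na(res$pa) & res$pa >= config$pa_cutoff
  res$passed_1d <-
    pmat[cbind(res$gene1, res$marker1)] >= config$oned_p_threshold &
    pmat[cbind(res$gene1, res$marker2)] >= config$oned_p_threshold &
    pmat[cbind(res$gene2, res$marker1)] >= config$oned_p_threshold &
    pmat[cbind(res$gene2, res$marker2)] >= config$oned_p_threshold

  res$partition_id <- NA_character_
  res$rho_hat <- NA_character_
  res$loglik_alt <- NA_real_
  res$loglik_null <- NA_real_
  res$lr <- NA_real_
  res$df <- NA_integer_
  res$p_value <- NA_real_
  res$p_marginal1 <- NA_real_
  res$p_marginal2 <- NA_real_
  res$epistasis_p <- NA_real_
  res$passed_epistasis <- FALSE
  res$significant <- FALSE

  todo <- which(res$passed_pa & res$passed_1d)
  for (i in todo) {
    g1 <- geno$calls[res$marker1[i], ]
    g2 <- geno$calls[res$marker2[i], ]
    x <- expr[res$gene1[i], ]
    y <- expr[res$gene2[i], ]
    keep <- !is.na(x) & !is.na(y)
    counts <- table(factor(paste0(g1[keep], g2[keep]),
                           levels = JOINT_GENOTYPES))
    if (any(counts < config$min_class_size)) next
    best <- select_best_model(x[keep], y[keep], g1[keep], g2[keep], config)
    epi <- epistasis_vs_marginal(x[keep], y[keep], g1[keep], g2[keep],
                                 best, config)
    res$partition_id[i] <- best$partition_id
    res$rho_hat[i] <- format_rho(best$rho_hat)
    res$loglik_alt[i] <- best$loglik_alt
    res$loglik_null[i] <- best$loglik_null
    res$lr[i] <- best$lr
    res$df[i] <- best$df
    res$p_value[i] <- best$p_value
    res$p_marginal1[i] <- epi$p_marginal1
    res$p_marginal2[i] <- epi$p_marginal2
    res$epistasis_p[i] <- epi$epistasis_p
    res$passed_epistasis[i] <- epi$passed_epistasis
    res$significant[i] <- best$p_value < config$p_threshold &&
      epi$passed_epistasis
  }
  stage_counts <- c(
    formed = nrow(res),
    scored_pa = sum(!is.na(res$pa) & res$eligible),
    after_pa = sum(res$passed_pa),
    after_1d = sum(res$passed_pa & res$passed_1d),
    after_lr = sum(!is.na(res$p_value) & res$p_value < config$p_threshold),
    significant = sum(res$significant))
  if (!quiet) {
    message(paste(sprintf("%s=%d", names(stage_counts), stage_counts),
                  collapse = " "))
  }
  rownames(res) <- NULL
  attr(res, "stage_counts") <- stage_counts
  res
}

#' Forward (greedy two-stage) search for one gene pair
#'
#' The comparator strategy: stage 1 finds the single marker whose
#' two-class (marker-split) correlation model is most significant against
#' the constant-correlation null; if that marker passes
#' \code{config$p_threshold}, stage 2 scans all second markers with full
#' epistatic model selection conditional on the first.  Modules whose loci
#' have no marginal correlation effect (e.g. XOR patterns) fail stage 1
#' and are missed, while the exhaustive scan finds them.
#'
#' @param x,y Trait vectors of one gene pair (complete values).
#' @param geno A \code{\link{genotype_matrix}}.
#' @param config A \code{\link{scan_config}}.
#' @return A one-row data.frame (first marker, partner marker, selected
#'   partition, p-values), or \code{NULL} when stage 1 passes no marker.
#' @export
forward_search_scan <- function(x, y, geno, config = scan_config()) {
  stopifnot(length(x) == ncol(geno$calls))
  parts <- enumerate_partitions()
  roles <- vapply(parts, `[[`, character(1L), "role")
  null_part <- parts[[which(roles == "null")]]
  split_part <- parts[[which(roles == "marginal_m1")]]
  markers <- rownames(geno$calls)
  best1 <- NULL
  for (m in markers) {
    g <- geno$calls[m, ]
    if (min(table(factor(g, levels = 0:1))) < config$min_class_size) next
    # marker-split two-class model: implemented as the first-marker
    # marginal partition with a constant second coordinate
    fit_alt <- fit_correlations(x, y, split_part, g, rep(0L, length(g)),
                                config$sd_fixed)
    fit_null <- fit_correlations(x, y, null_part, g, rep(0L, length(g)),
                                 config$sd_fixed)
    p <- lr_test(fit_alt, fit_null)$p_value
    if (is.null(best1) || p < best1$p) best1 <- list(marker = m, p = p)
  }
  if (is.null(best1) || best1$p > config$p_threshold) return(NULL)
  m1 <- best1$marker
  best2 <- NULL
  for (m2 in setdiff(markers, m1)) {
    g1 <- geno$calls[m1, ]; g2 <- geno$calls[m2, ]
    counts <- table(factor(paste0(g1, g2), levels = JOINT_GENOTYPES))
    if (any(counts < config$min_class_size)) next
    fit <- select_best_model(x, y, g1, g2, config)
    if (is.null(best2) || fit$p_value < best2$fit$p_value) {
      best2 <- list(marker = m2, fit = fit)
    }
  }
  if (is.null(best2)) return(NULL)
  g1 <- geno$calls[m1, ]; g2 <- geno$calls[best2$marker, ]
  epi <- epistasis_vs_marginal(x, y, g1, g2, best2$fit, config)
  data.frame(first_marker = m1, first_p = best1$p,
             marker1 = m1, marker2 = best2$marker,
             partition_id = best2$fit$partition_id,
             rho_hat = format_rho(best2$fit$rho_hat),
             lr = best2$fit$lr, df = best2$fit$df,
             p_value = best2$fit$p_value,
             epistasis_p = epi$epistasis_p,
             stringsAsFactors = FALSE)
}

#' Write scan results as TSV
#'
#' @param results data.frame from \code{\link{exhaustive_scan}}.
#' @param path Output path.
#' @export
write_scan_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
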