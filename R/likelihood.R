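# Sufficient statistics of the zero-mean fixed-SD bivariate normal
# likelihood within one correlation class: A = sum(x^2 + y^2),
# B = sum(x*y), n.  The class log-likelihood at correlation rho is
#   -n [ log(2 pi) + 2 log(sd) + 0.5 log(1 - rho^2) ]
#   - (A - 2 rho B) / (2 sd^2 (1 - rho^2)).
class_loglik <- function(rho, A, B, n, sd) {
  -n * (log(2 * pi) + 2 * log(sd) + 0.5 * log1p(-rho^2)) -
    (A - 2 * rho * B) / (2 * sd^2 * (1 - rho^2))
}

RHO_EPS <- 1e-6

# Maximize the class log-likelihood over rho in (-1 + eps, 1 - eps) by
# bounded one-dimensional search.  The stationary condition is a cubic in
# rho; numerical maximization to tolerance ~1e-9 is accurate far beyond
# the 1e-3 the downstream tests require (verified against a grid oracle).
fit_rho <- function(A, B, n, sd) {
  opt <- stats::optimize(class_loglik, c(-1 + RHO_EPS, 1 - RHO_EPS),
                         A = A, B = B, n = n, sd = sd,
                         maximum = TRUE, tol = 1e-9)
  list(rho = opt$maximum, loglik = opt$objective)
}

#' Bivariate normal log-likelihood with genotype-class correlations
#'
#' Evaluates the log-likelihood of paired traits under the conditional
#' bivariate normal model: both means 0, both SDs \code{sd}, and a
#' correlation that depends only on the sample's correlation class.
#'
#' @param x,y Numeric vectors of equal length (no missing values).
#' @param class Class label per sample (indexes into \code{rho}).
#' @param rho Named (or integer-indexed) vector of per-class correlations,
#'   each strictly inside (-1, 1).
#' @param sd Common standard deviation (> 0).
#' @return The scalar log-likelihood.
#' @export
bvn_loglik <- function(x, y, class, rho, sd = 0.97) {
  if (length(x) != length(y) || length(x) != length(class)) {
    stop("x, y and class must have equal lengths")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite trait values")
  if (any(abs(rho) >= 1)) stop("all correlations must lie strictly in (-1, 1)")
  if (sd <= 0) stop("sd must be > 0")
  r <- unname(rho[class])
  if (anyNA(r)) stop("sample class without a correlation value")
  sum(-(log(2 * pi) + 2 * log(sd) + 0.5 * log1p(-r^2)) -
        (x^2 - 2 * r * x * y + y^2) / (2 * sd^2 * (1 - r^2)))
}

#' Per-class maximum-likelihood correlations under a genotype partition
#'
#' For each class of the partition, estimates the correlation of the
#' zero-mean, fixed-SD bivariate normal by maximizing the class likelihood
#' over (-1, 1).  Classes are independent, so the partition's maximized
#' log-likelihood is the sum of the class maxima.
#'
#' @param x,y Trait vectors (already normal quantile transformed).
#' @param partition A partition from \code{\link{enumerate_partitions}}.
#' @param g1,g2 Binary genotype vectors at the two markers, aligned with
#'   \code{x} and \code{y}.
#' @param sd Fixed common SD (default 0.97).
#' @return A list of class \code{"cor_fit"}: \code{partition},
#'   \code{rho_hat} (per class), \code{loglik}, \code{sd},
#'   \code{n_per_class}.
#' @export
fit_correlations <- function(x, y, partition, g1, g2, sd = 0.97) {
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite trait values")
  cls <- class_assignments(partition, g1, g2)
  k <- partition$k
  rho_hat <- numeric(k)
  n_per_class <- integer(k)
  loglik <- 0
  for (c in seq_len(k)) {
    idx <- which(cls == c)
    if (length(idx) == 0L) {
      stop("empty correlation class ", c, " in partition ", partition$id)
    }
    n_per_class[c] <- length(idx)
    fit <- fit_rho(sum(x[idx]^2 + y[idx]^2), sum(x[idx] * y[idx]),
                   length(idx), sd)
    rho_hat[c] <- fit$rho
    loglik <- loglik + fit$loglik
  }
  structure(list(partition = partition, rho_hat = rho_hat, loglik = loglik,
                 sd = sd, n_per_class = n_per_class),
            class = "cor_fit")
}

#' Likelihood-ratio test between nested partition fits
#'
#' @param fit_alt,fit_null \code{cor_fit} objects on the same data;
#'   \code{fit_null}'s partition must be a coarsening of
#'   \code{fit_alt}'s.
#' @return A list: \code{lr} (2 x log-likelihood difference, clipped at
#'   0), \code{df} (difference in class counts), \code{p_value}
#'   (chi-square upper tail).
#' @export
lr_test <- function(fit_alt, fit_null) {
  stopifnot(inherits(fit_alt, "cor_fit"), inherits(fit_null, "cor_fit"))
  if (!is_coarsening(fit_null$partition, fit_alt$partition)) {
    stop("partitions are not nested; use epistasis_vs_marginal for ",
         "non-nested comparisons")
  }
  lr <- max(0, 2 * (fit_alt$loglik - fit_null$loglik))
  df <- fit_alt$partition$k - fit_null$partition$k
  p <- if (df == 0L) 1 else stats::pchisq(lr, df, lower.tail = FALSE)
  list(lr = lr, df = df, p_value = p)
}

#' Select the best epistatic correlation model for one module
#'
#' Fits all 12 epistatic genotype partitions against the one-class null
#' and keeps the partition with the smallest LR p-value (ties broken by
#' fewer classes, then canonical partition order).  The selected p-value
#' is not adjusted for the selection over 12 partitions; the permutation
#' FDR of the full pipeline absorbs that multiplicity.
#'
#' @param x,y Trait vectors.
#' @param g1,g2 Binary genotype vectors at the two markers.
#' @param config A \code{\link{scan_config}} (uses \code{sd_fixed} and
#'   \code{min_class_size}).
#' @return A list with \code{partition_id}, \code{partition},
#'   \code{rho_hat}, \code{n_per_class}, \code{loglik_alt},
#'   \code{loglik_null}, \code{rho_null}, \code{lr}, \code{df},
#'   \code{p_value}.
#' @export
select_best_model <- function(x, y, g1, g2, config = scan_config()) {
  parts <- enumerate_partitions()
  null_part <- parts[[1L]]
  cls4 <- paste0(g1, g2)
  counts <- table(factor(cls4, levels = JOINT_GENOTYPES))
  if (any(counts < config$min_class_size)) {
    stop("module ineligible: joint-genotype class below min_class_size")
  }
  fit_null <- fit_correlations(x, y, null_part, g1, g2, config$sd_fixed)
  best <- NULL
  for (p in parts) {
    if (p$role != "epistatic") next
    fit <- fit_correlations(x, y, p, g1, g2, config$sd_fixed)
    test <- lr_test(fit, fit_null)
    if (is.null(best) || test$p_value < best$p_value ||
        (test$p_value == best$p_value && p$k < best$partition$k)) {
      best <- list(partition_id = p$id, partition = p, rho_hat = fit$rho_hat,
                   n_per_class = fit$n_per_class,
                   loglik_alt = fit$loglik, loglik_null = fit_null$loglik,
                   rho_null = fit_null$rho_hat,
                   lr = test$lr, df = test$df, p_value = test$p_value)
    }
  }
  best
}

#' Test the selected model against the two marginal (single-marker) models
#'
#' Modules whose correlation pattern is explained by one marker alone are
#' not epistatic.  The selected epistatic model is compared against the
#' better of the two marginal two-class fits with a generalized LR:
#' \code{epistasis_p} is the chi-square upper tail of
#' 2 (loglik_best - max marginal loglik) at df = max(k_best - 2, 1),
#' which reduces to the standard nested test whenever the selected
#' partition refines a marginal one.
#'
#' @param x,y Trait vectors.
#' @param g1,g2 Binary genotype vectors.
#' @param best Result of \code{\link{select_best_model}}.
#' @param config A \code{\link{scan_config}}.
#' @return A list: \code{p_marginal1}, \code{p_marginal2} (each marginal
#'   model against the null, df = 1), \code{epistasis_p}, and
#'   \code{passed_epistasis}.
#' @export
epistasis_vs_marginal <- function(x, y, g1, g2, best, config = scan_config()) {
  parts <- enumerate_partitions()
  roles <- vapply(parts, `[[`, character(1L), "role")
  fit_null <- fit_correlations(x, y, parts[[which(roles == "null")]],
                               g1, g2, config$sd_fixed)
  fit_m1 <- fit_correlations(x, y, parts[[which(roles == "marginal_m1")]],
                             g1, g2, config$sd_fixed)
  fit_m2 <- fit_correlations(x, y, parts[[which(roles == "marginal_m2")]],
                             g1, g2, config$sd_fixed)
  p_m1 <- lr_test(fit_m1, fit_null)$p_value
  p_m2 <- lr_test(fit_m2, fit_null)$p_value
  lr_epi <- max(0, 2 * (best$loglik_alt - max(fit_m1$loglik, fit_m2$loglik)))
  df_epi <- max(best$partition$k - 2L, 1L)
  epistasis_p <- stats::pchisq(lr_epi, df_epi, lower.tail = FALSE)
  list(p_marginal1 = p_m1, p_marginal2 = p_m2, epistasis_p = epistasis_p,
       passed_epistasis = epistasis_p < config$epistasis_p_threshold)
}

#' Per-class fits with genotype-dependent variances (and optionally means)
#'
#' Variant fits used only for power comparisons, not the main scan:
#' \code{"model6"} estimates a common per-class SD jointly with the
#' correlation (means fixed at 0); \code{"model20"} additionally gives
#' each class its own trait means (estimated by the class sample means).
#'
#' @param x,y Trait vectors.
#' @param partition A genotype partition.
#' @param g1,g2 Binary genotype vectors.
#' @param variant \code{"model6"} or \code{"model20"}.
#' @return A list of class \code{"cor_fit"} with extra elements
#'   \code{sd_hat} (per class) and, for \code{"model20"}, \code{mu_hat}
#'   (per class, columns x and y).
#' @export
fit_variance_dependent <- function(x, y, partition, g1, g2,
                                   variant = c("model6", "model20")) {
  variant <- match.arg(variant)
  cls <- class_assignments(partition, g1, g2)
  k <- partition$k
  rho_hat <- numeric(k)
  sd_hat <- numeric(k)
  mu_hat <- matrix(0, k, 2L, dimnames = list(NULL, c("x", "y")))
  n_per_class <- integer(k)
  loglik <- 0
  for (c in seq_len(k)) {
    idx <- which(cls == c)
    if (length(idx) < 4L) stop("class ", c, " has fewer than 4 samples")
    xc <- x[idx]; yc <- y[idx]
    if (variant == "model20") {
      mu_hat[c, ] <- c(mean(xc), mean(yc))
      xc <- xc - mu_hat[c, 1L]
      yc <- yc - mu_hat[c, 2L]
    }
    A <- sum(xc^2 + yc^2); B <- sum(xc * yc); n <- length(idx)
    # maximize over (log sd, atanh rho); unconstrained parameterization
    neg <- function(par) -class_loglik(tanh(par[2L]), A, B, n, exp(par[1L]))
    start <- c(log(sqrt(A / (2 * n))), atanh(min(0.9, max(-0.9, 2 * B / A))))
    opt <- stats::optim(start, neg, method = "BFGS",
                        control = list(reltol = 1e-12))
    sd_hat[c] <- exp(opt$par[1L])
    rho_hat[c] <- tanh(opt$par[2L])
    loglik <- loglik - opt$value
    n_per_class[c] <- n
  }
  structure(list(partition = partition, rho_hat = rho_hat, loglik = loglik,
                 sd = NA_real_, sd_hat = sd_hat,
                 mu_hat = if (variant == "model20") mu_hat else NULL,
                 n_per_class = n_per_class, variant = variant),
            class = "cor_fit")
}
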