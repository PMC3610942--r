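# Shared fixtures and independent oracles for the suite.

# Balanced joint genotypes: n_per samples in each of (0,0),(0,1),(1,0),(1,1).
balanced_genotypes <- function(n_per) {
  list(g1 = rep(c(0L, 0L, 1L, 1L), each = n_per),
       g2 = rep(c(0L, 1L, 0L, 1L), each = n_per))
}

# Draw one zero-mean bivariate normal sample per entry of rho_vec.
draw_bvn <- function(rho_vec, sd = 0.97) {
  n <- length(rho_vec)
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  cbind(x = sd * z1, y = sd * (rho_vec * z1 + sqrt(1 - rho_vec^2) * z2))
}

# Independent log-likelihood oracle: per-sample density by the conditional
# factorization x ~ N(0, sd^2), y | x ~ N(rho x, sd^2 (1 - rho^2)).
oracle_loglik <- function(x, y, rho, sd) {
  sum(dnorm(x, 0, sd, log = TRUE) +
        dnorm(y, rho * x, sd * sqrt(1 - rho^2), log = TRUE))
}

# Grid-search oracle for the per-class correlation MLE (fixed mean 0, fixed
# sd), built on oracle_loglik, step 1e-4 over (-0.9999, 0.9999).
grid_fit_rho <- function(x, y, sd, step = 1e-4) {
  grid <- seq(-0.9999, 0.9999, by = step)
  resid <- outer(y, rep(1, length(grid))) - outer(x, grid)
  sd_y <- sd * sqrt(1 - grid^2)
  ll <- colSums(dnorm(resid, 0, rep(sd_y, each = length(x)), log = TRUE)) +
    sum(dnorm(x, 0, sd, log = TRUE))
  i <- which.max(ll)
  list(rho = grid[i], loglik = ll[i])
}

# Full-model (4-class) LR statistic against the 1-class null, via the
# package's fitting route; used by simulation-heavy tests.
full_model_lr <- function(x, y, g1, g2, sd = 0.97) {
  parts <- enumerate_partitions()
  full <- parts[[length(parts)]]
  nullp <- parts[[1L]]
  stopifnot(full$k == 4L, nullp$k == 1L)
  fa <- fit_correlations(x, y, full, g1, g2, sd)
  f0 <- fit_correlations(x, y, nullp, g1, g2, sd)
  lr_test(fa, f0)
}

# Tiny deterministic expression/genotype fixture for io tests.
toy_expression <- function() {
  m <- matrix(c(1.5, -0.2, 0.3, NA, 2.25, -1.1), nrow = 2, byrow = TRUE,
              dimnames = list(c("geneA", "geneB"),
                              c("s1", "s2", "s3")))
  m
}

toy_genotype <- function() {
  calls <- matrix(c(0L, 1L, 1L,
                    1L, 1L, 0L,
                    0L, 0L, 1L), nrow = 3, byrow = TRUE,
                  dimnames = list(c("mk2", "mk1", "mk3"),
                                  c("s1", "s2", "s3")))
  iv <- data.frame(marker_id = c("mk1", "mk2", "mk3"),
                   chrom = c("chr01", "chr01", "chr02"),
                   start = c(100L, 5000L, 40L), end = c(200L, 5100L, 90L))
  genotype_matrix(calls, iv)
}
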