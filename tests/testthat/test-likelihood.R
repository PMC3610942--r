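test_that("the bivariate log-likelihood matches closed forms and a density oracle", {
  expect_equal(bvn_loglik(0, 0, 1L, c(`1` = 0), sd = 1), -log(2 * pi))
  expect_equal(bvn_loglik(0, 0, 1L, c(`1` = 0), sd = 0.97),
               -log(2 * pi * 0.97^2))
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    rho <- runif(1, -0.95, 0.95)
    sd <- runif(1, 0.5, 1.5)
    xy <- draw_bvn(rep(rho, n), sd)
    got <- bvn_loglik(xy[, 1], xy[, 2], rep(1L, n), c(`1` = rho), sd)
    expect_equal(got, oracle_loglik(xy[, 1], xy[, 2], rho, sd),
                 tolerance = 1e-10)
  }
  expect_error(bvn_loglik(1:3, 1:2, rep(1L, 3), c(`1` = 0)), "equal lengths")
  expect_error(bvn_loglik(1:3, 1:3, rep(1L, 3), c(`1` = 1)), "strictly")
})

test_that("per-class MLE respects symmetry and is consistent", {
  # a class symmetric under (x,y) -> (x,-y) forces rho_hat = 0
  x <- c(1, -1, 0, 0)
  y <- c(0, 0, 1, -1)
  parts <- enumerate_partitions()
  nullp <- parts[[1]]
  g0 <- rep(0L, 4)
  fit <- fit_correlations(x, y, nullp, g0, g0, sd = 1)
  expect_equal(unname(fit$rho_hat), 0, tolerance = 1e-6)

  set.seed(33)
  xy <- draw_bvn(rep(0.6, 5000), sd = 0.97)
  fit <- fit_correlations(xy[, 1], xy[, 2], nullp,
                          rep(0L, 5000), rep(0L, 5000), sd = 0.97)
  expect_lt(abs(fit$rho_hat - 0.6), 0.03)
})

test_that("fit is equivariant under negating one trait", {
  set.seed(34)
  gg <- balanced_genotypes(10)
  parts <- enumerate_partitions()
  full <- parts[[15]]
  cls <- epi2d:::class_assignments(full, gg$g1, gg$g2)
  xy <- draw_bvn(c(0.7, -0.3, 0, 0.5)[cls], sd = 0.97)
  f1 <- fit_correlations(xy[, 1], xy[, 2], full, gg$g1, gg$g2, 0.97)
  f2 <- fit_correlations(xy[, 1], -xy[, 2], full, gg$g1, gg$g2, 0.97)
  expect_equal(f2$rho_hat, -f1$rho_hat, tolerance = 1e-6)
  expect_equal(f2$loglik, f1$loglik, tolerance = 1e-8)
  expect_true(all(abs(f1$rho_hat) < 1))
})

test_that("maximized likelihood is monotone under partition refinement", {
  set.seed(35)
  gg <- balanced_genotypes(8)
  parts <- enumerate_partitions()
  xy <- draw_bvn(runif(32, -0.5, 0.5), sd = 0.97)
  lls <- vapply(parts, function(p)
    fit_correlations(xy[, 1], xy[, 2], p, gg$g1, gg$g2, 0.97)$loglik,
    numeric(1))
  for (i in seq_along(parts)) for (j in seq_along(parts)) {
    if (i != j && epi2d:::is_coarsening(parts[[i]], parts[[j]])) {
      expect_gte(lls[j] - lls[i], -1e-8)
    }
  }
})

test_that("lr_test handles identity, refinement and non-nested inputs", {
  set.seed(36)
  gg <- balanced_genotypes(10)
  parts <- enumerate_partitions()
  xy <- draw_bvn(rep(0.2, 40), sd = 0.97)
  f_null <- fit_correlations(xy[, 1], xy[, 2], parts[[1]], gg$g1, gg$g2, 0.97)
  f_full <- fit_correlations(xy[, 1], xy[, 2], parts[[15]], gg$g1, gg$g2, 0.97)
  same <- lr_test(f_null, f_null)
  expect_identical(same$lr, 0)
  expect_identical(same$p_value, 1)
  ref <- lr_test(f_full, f_null)
  expect_gte(ref$lr, 0)
  expect_identical(ref$df, 3L)
  roles <- vapply(parts, `[[`, character(1), "role")
  f_m1 <- fit_correlations(xy[, 1], xy[, 2],
                           parts[[which(roles == "marginal_m1")]],
                           gg$g1, gg$g2, 0.97)
  f_m2 <- fit_correlations(xy[, 1], xy[, 2],
                           parts[[which(roles == "marginal_m2")]],
                           gg$g1, gg$g2, 0.97)
  expect_error(lr_test(f_m1, f_m2), "not nested")
})

test_that("select_best_model minimizes over the 12 epistatic partitions", {
  set.seed(37)
  gg <- balanced_genotypes(20)
  parts <- enumerate_partitions()
  full <- parts[[15]]
  cls <- epi2d:::class_assignments(full, gg$g1, gg$g2)
  xy <- draw_bvn(c(0, 0, 0, 0.85)[cls], sd = 0.97)
  cfg <- scan_config(min_class_size = 15)
  best <- select_best_model(xy[, 1], xy[, 2], gg$g1, gg$g2, cfg)
  f_null <- fit_correlations(xy[, 1], xy[, 2], parts[[1]], gg$g1, gg$g2, 0.97)
  pvals <- vapply(parts, function(p) {
    if (p$role != "epistatic") return(NA_real_)
    lr_test(fit_correlations(xy[, 1], xy[, 2], p, gg$g1, gg$g2, 0.97),
            f_null)$p_value
  }, numeric(1))
  expect_equal(best$p_value, min(pvals, na.rm = TRUE))
  expect_error(select_best_model(xy[, 1], xy[, 2], gg$g1,
                                 c(gg$g2[-1], 1L), scan_config()),
               NA)  # still a valid module as long as classes stay populated
})

test_that("the epistasis test separates marginal from genuinely epistatic patterns", {
  set.seed(38)
  gg <- balanced_genotypes(60)
  parts <- enumerate_partitions()
  full <- parts[[15]]
  cls <- epi2d:::class_assignments(full, gg$g1, gg$g2)
  cfg <- scan_config(min_class_size = 15)

  # pattern depends only on marker 1: epistasis test must clear it
  marg_reject <- replicate(30, {
    xy <- draw_bvn(c(0.7, 0.7, -0.2, -0.2)[cls], sd = 0.97)
    best <- select_best_model(xy[, 1], xy[, 2], gg$g1, gg$g2, cfg)
    epistasis_vs_marginal(xy[, 1], xy[, 2], gg$g1, gg$g2,
                          best, cfg)$passed_epistasis
  })
  expect_lt(mean(marg_reject), 0.5)

  # XOR pattern: high correlation when alleles agree — no marginal signal
  xor_keep <- replicate(30, {
    xy <- draw_bvn(c(0.7, -0.2, -0.2, 0.7)[cls], sd = 0.97)
    best <- select_best_model(xy[, 1], xy[, 2], gg$g1, gg$g2, cfg)
    epistasis_vs_marginal(xy[, 1], xy[, 2], gg$g1, gg$g2,
                          best, cfg)$passed_epistasis
  })
  expect_gt(mean(xor_keep), 0.9)
})

test_that("variance/mean-dependent fits recover their parameters", {
  set.seed(39)
  parts <- enumerate_partitions()
  nullp <- parts[[1]]
  g0 <- rep(0L, 400)
  xy <- draw_bvn(rep(0.5, 400), sd = 1.2)
  f6 <- fit_variance_dependent(xy[, 1], xy[, 2], nullp, g0, g0, "model6")
  expect_lt(abs(f6$sd_hat - 1.2), 0.1)
  expect_lt(abs(f6$rho_hat - 0.5), 0.1)

  xy20 <- sweep(xy, 2, c(2, -1), `+`)
  f20 <- fit_variance_dependent(xy20[, 1], xy20[, 2], nullp, g0, g0, "model20")
  expect_lt(max(abs(f20$mu_hat - c(2, -1))), 0.2)
  expect_lt(abs(f20$sd_hat - 1.2), 0.1)

  # small-class estimates agree with a 2-D grid oracle
  set.seed(40)
  xy <- draw_bvn(rep(0.4, 16), sd = 0.9)
  fit <- fit_variance_dependent(xy[, 1], xy[, 2], nullp,
                                rep(0L, 16), rep(0L, 16), "model6")
  grid_sd <- seq(0.3, 2.5, by = 0.005)
  grid_rho <- seq(-0.995, 0.995, by = 0.005)
  ll <- outer(grid_sd, grid_rho, function(s, r)
    mapply(function(si, ri) oracle_loglik(xy[, 1], xy[, 2], ri, si), s, r))
  i <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  expect_lt(abs(fit$sd_hat - grid_sd[i[1]]), 1e-2)
  expect_lt(abs(fit$rho_hat - grid_rho[i[2]]), 1e-2)
})

test_that("fixed-SD correlation model outpowers the variance-dependent fit on IMIVED data", {
  # IMIVED: means and variances genotype-independent, correlation epistatic.
  set.seed(41)
  gg <- balanced_genotypes(25)
  parts <- enumerate_partitions()
  full <- parts[[15]]
  nullp <- parts[[1]]
  cls <- epi2d:::class_assignments(full, gg$g1, gg$g2)
  wins3 <- replicate(40, {
    xy <- draw_bvn(c(0, 0, 0, 0.7)[cls], sd = 0.97)
    t3 <- full_model_lr(xy[, 1], xy[, 2], gg$g1, gg$g2, 0.97)
    a6 <- fit_variance_dependent(xy[, 1], xy[, 2], full, gg$g1, gg$g2, "model6")
    n6 <- fit_variance_dependent(xy[, 1], xy[, 2], nullp, gg$g1, gg$g2, "model6")
    lr6 <- max(0, 2 * (a6$loglik - n6$loglik))
    p6 <- pchisq(lr6, df = 2 * (full$k - 1), lower.tail = FALSE)
    t3$p_value < p6
  })
  expect_gt(mean(wins3), 0.5)
})
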