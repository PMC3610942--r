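# Small helper constructing a results-like data.frame.
fake_results <- function(...) {
  rows <- list(...)
  base <- data.frame(gene1 = character(), gene2 = character(),
                     marker1 = character(), marker2 = character(),
                     p_value = numeric(), significant = logical())
  out <- do.call(rbind, c(list(base), lapply(rows, as.data.frame)))
  rownames(out) <- NULL
  out
}

test_that("post-scan marker merging collapses duplicate modules to the best p", {
  calls <- rbind(mA = rep(c(0L, 1L), each = 20),
                 mB = c(0L, rep(c(0L, 1L), each = 20)[-1]),   # 1 discordant
                 mC = rep(c(1L, 0L), each = 20))
  colnames(calls) <- sprintf("s%02d", 1:40)
  iv <- data.frame(marker_id = c("mA", "mB", "mC"), chrom = "chr01",
                   start = c(1L, 50L, 5000L), end = c(10L, 60L, 5010L))
  geno <- genotype_matrix(calls, iv)
  res <- fake_results(
    list(gene1 = "g1", gene2 = "g2", marker1 = "mA", marker2 = "mC",
         p_value = 1e-8, significant = TRUE),
    list(gene1 = "g1", gene2 = "g2", marker1 = "mB", marker2 = "mC",
         p_value = 1e-6, significant = TRUE))
  merged <- merge_module_markers(res, geno, max_discordant = 15L)
  expect_identical(nrow(merged$results), 1L)
  expect_identical(merged$results$marker1, "mA")   # mB folded into mA
  expect_identical(merged$results$p_value, 1e-8)   # smallest p kept
  # threshold 0 merges nothing here (mA and mB differ in one call)
  m0 <- merge_module_markers(res, geno, max_discordant = 0L)
  expect_identical(nrow(m0$results), 2L)
})

test_that("the epistasis map is symmetric with conserved counts", {
  expect_identical(dim(build_epistasis_map(fake_results())), c(0L, 0L))
  res <- fake_results(
    list(gene1 = "g1", gene2 = "g2", marker1 = "A", marker2 = "B",
         p_value = 1e-8, significant = TRUE),
    list(gene1 = "g3", gene2 = "g4", marker1 = "A", marker2 = "B",
         p_value = 1e-7, significant = TRUE),
    list(gene1 = "g5", gene2 = "g6", marker1 = "A", marker2 = "C",
         p_value = 1e-7, significant = TRUE),
    list(gene1 = "g7", gene2 = "g8", marker1 = "B", marker2 = "C",
         p_value = 0.5, significant = FALSE))
  E <- build_epistasis_map(res)
  expect_identical(E, t(E))
  expect_true(all(diag(E) == 0L))
  expect_identical(E["A", "B"], 2L)
  expect_identical(sum(E[upper.tri(E)]), 3L)   # = number of significant modules
  # hub: locus A interacts with 5 partners
  hub <- fake_results()
  for (i in 1:5) {
    hub <- rbind(hub, data.frame(gene1 = paste0("h", i), gene2 = "hx",
                                 marker1 = "HUB", marker2 = paste0("L", i),
                                 p_value = 1e-9, significant = TRUE))
  }
  expect_identical(sum(build_epistasis_map(hub)["HUB", ]), 5L)
})

test_that("clustering the map recovers planted cliques and exports Newick", {
  loci <- c(paste0("a", 1:3), paste0("b", 1:3))
  E <- matrix(0L, 6, 6, dimnames = list(loci, loci))
  for (i in 1:3) for (j in 1:3) if (i != j) {
    E[paste0("a", i), paste0("a", j)] <- 2L
    E[paste0("b", i), paste0("b", j)] <- 1L
  }
  cl <- cluster_epistasis_map(E)
  groups <- cutree(cl$hclust, k = 2)
  expect_identical(length(unique(groups[paste0("a", 1:3)])), 1L)
  expect_identical(length(unique(groups[paste0("b", 1:3)])), 1L)
  expect_false(groups[["a1"]] == groups[["b1"]])
  # two loci with identical interaction profiles merge at distance zero
  twins <- matrix(0L, 3, 3, dimnames = list(c("p", "q", "r"),
                                            c("p", "q", "r")))
  twins["p", "r"] <- twins["r", "p"] <- 1L
  twins["q", "r"] <- twins["r", "q"] <- 1L
  cl2 <- cluster_epistasis_map(twins)
  expect_equal(min(cl2$hclust$height), 0)
  path <- withr::local_tempfile(fileext = ".nwk")
  export_dendrogram_newick(cl$hclust, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, loci)
  # single-locus map degenerates gracefully
  single <- cluster_epistasis_map(E[1, 1, drop = FALSE])
  expect_null(single$hclust)
})

test_that("the hypergeometric pair test matches direct combinatorial sums", {
  expect_equal(hyper_tail_test(10, 3, 4, 0), 1)
  expect_equal(hyper_tail_test(10, 3, 4, 3),
               choose(3, 3) * choose(7, 1) / choose(10, 4))
  # direct-sum oracle across the whole support
  N <- 12; M <- 5; n <- 6
  for (k in 0:5) {
    want <- sum(sapply(k:min(n, M), function(j)
      choose(M, j) * choose(N - M, n - j))) / choose(N, n)
    expect_equal(hyper_tail_test(N, M, n, k), want, tolerance = 1e-12)
  }
  # monotone non-increasing in k
  ps <- sapply(0:5, function(k) hyper_tail_test(N, M, n, k))
  expect_true(all(diff(ps) <= 0))
  expect_error(hyper_tail_test(10, 3, 4, 4), "min")
  expect_error(hyper_tail_test(10, 11, 4, 1), "exceed")
})

test_that("function-pair enrichment counts unordered term pairs once per gene pair", {
  ann <- list(ribo = c("g1", "g2", "g3"), sig = c("g4", "g3"))
  universe <- expand.grid(gene1 = paste0("g", 1:4), gene2 = paste0("g", 1:5),
                          stringsAsFactors = FALSE)
  universe <- universe[universe$gene1 < universe$gene2, ]
  modules <- data.frame(gene1 = c("g1", "g3"), gene2 = c("g2", "g4"))
  out <- pair_function_enrichment(modules, universe, ann)
  rr <- out[out$term1 == "ribo" & out$term2 == "ribo", ]
  # only g1-g2 carries ribo|ribo; g3-g4 contributes ribo|sig and sig|sig
  expect_identical(rr$k, 1L)
  # oracle for one cell: recompute M by brute force
  terms <- list(g1 = "ribo", g2 = "ribo", g3 = c("ribo", "sig"),
                g4 = "sig", g5 = "unknown")
  M_want <- sum(sapply(seq_len(nrow(universe)), function(i) {
    t1 <- terms[[universe$gene1[i]]]; t2 <- terms[[universe$gene2[i]]]
    any(outer(t1, t2, function(a, b) a == "ribo" & b == "ribo"))
  }))
  expect_identical(rr$M, as.integer(M_want))
  expect_equal(rr$p_raw,
               hyper_tail_test(nrow(universe), M_want, 2, 1))
  expect_true(all(out$p_bonferroni >= out$p_raw))
  expect_true(all(out$p_bonferroni <= 1))
  # unannotated genes fall back to the "unknown" term
  expect_true(any(out$term1 == "unknown" | out$term2 == "unknown") ||
                !"g5" %in% c(modules$gene1, modules$gene2))
})

test_that("interval enrichment reduces to a single hypergeometric and matches enumeration", {
  # one interval: the standard tail
  expect_equal(interval_function_enrichment(20, 4, 5, 2),
               hyper_tail_test(20, 4, 5, 2), tolerance = 1e-12)
  # two intervals, observed zero -> p = 1
  expect_equal(interval_function_enrichment(20, 4, c(3, 2), c(0, 0)), 1)
  # exhaustive enumeration oracle over all (K1, K2) outcomes
  N <- 20; M <- 4; m <- c(3, 2)
  want <- 0
  for (k1 in 0:3) for (k2 in 0:2) {
    if (k1 + k2 >= 3) {
      want <- want + dhyper(k1, M, N - M, m[1]) * dhyper(k2, M, N - M, m[2])
    }
  }
  expect_equal(interval_function_enrichment(N, M, m, c(2, 1)), want,
               tolerance = 1e-12)
  # size-1 intervals approach the single-interval union when intervals are
  # small relative to the universe (the convolution treats intervals as
  # independent, so equality is asymptotic in N)
  expect_equal(interval_function_enrichment(2000, 50, c(1, 1, 1), c(1, 1, 0)),
               interval_function_enrichment(2000, 50, 3, 2),
               tolerance = 0.01)
  # monotone non-increasing in the observed total
  ps <- sapply(0:3, function(t)
    interval_function_enrichment(N, M, m, c(min(t, 3), max(0, t - 3))))
  expect_true(all(diff(ps) <= 1e-12))
  expect_error(interval_function_enrichment(10, 4, c(8, 8), c(0, 0)),
               "universe")
  expect_error(interval_function_enrichment(20, 4, 3, 4), "min")
})
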