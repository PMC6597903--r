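test_that("over-representation p is the hypergeometric upper tail", {
  universe <- paste0("g", 1:20)
  set <- paste0("g", 1:5)
  signature <- paste0("g", c(1, 2, 3, 10))
  expect_equal(ora_test(set, signature, universe), 155 / 4845,
               tolerance = 1e-12)
  # zero overlap: the upper tail including 0 is 1
  expect_equal(ora_test(paste0("g", 6:9), paste0("g", 1:3), universe), 1)
  # set covering the whole universe is uninformative
  expect_equal(ora_test(universe, signature, universe), 1)
})

test_that("rank-sum test flags a top-ranked set and handles degenerate input", {
  stats_vec <- setNames(c(seq(10, 8, length.out = 5), runif(95)),
                        paste0("g", 1:100))
  p <- rank_test(paste0("g", 1:5), stats_vec)
  expect_lt(p, 1e-3)
  # normal approximation agrees with an independent hand computation
  n1 <- 5; n2 <- 95
  w <- sum(rank(stats_vec)[1:5]) - n1 * (n1 + 1) / 2  # in-set Mann-Whitney U
  z <- (w - n1 * n2 / 2 - 0.5) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  expect_equal(p, 2 * pnorm(-abs(z)), tolerance = 1e-10)
  expect_warning(p_tied <- rank_test(paste0("g", 1:5),
                                     setNames(rep(1, 20), paste0("g", 1:20))),
                 "tied")
  expect_equal(p_tied, 1)
  # equal-size groups with identical score multisets are symmetric
  sym <- setNames(rep(c(1, 2, 3, 4, 5), 2), paste0("g", 1:10))
  expect_gt(rank_test(paste0("g", 1:5), sym), 0.9)
})

test_that("rank-sum p-values are uniform under exchangeable scores", {
  set.seed(13)
  ps <- replicate(200, {
    stats_vec <- setNames(rnorm(60), paste0("g", 1:60))
    rank_test(paste0("g", sample(60, 10)), stats_vec)
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("permutation test is seeded, floored and degenerate-safe", {
  stats_vec <- setNames(c(rep(100, 5), rnorm(195)), paste0("g", 1:200))
  p <- perm_test(paste0("g", 1:5), stats_vec, n_perm = 999, seed = 7)
  expect_equal(p, 1 / 1000)  # top set can never be matched
  expect_identical(p, perm_test(paste0("g", 1:5), stats_vec,
                                n_perm = 999, seed = 7))
  const <- setNames(rep(2, 50), paste0("g", 1:50))
  expect_equal(perm_test(paste0("g", 1:5), const, n_perm = 99, seed = 1), 1)
  expect_error(perm_test(paste0("g", 1:5), stats_vec, n_perm = 10),
               ">= 99")
})

test_that("Fisher combination matches a numerical chi-square oracle", {
  expect_equal(ensemble_combine(1, 1, 1)$p_combined, 1)
  x <- -2 * 3 * log(0.05)
  oracle <- integrate(function(t) dchisq(t, df = 6), x, Inf,
                      rel.tol = 1e-12)$value
  expect_equal(ensemble_combine(0.05, 0.05, 0.05)$p_combined, oracle,
               tolerance = 1e-9)
  # monotone: lowering any one p can only lower the combined p
  base <- ensemble_combine(0.2, 0.3, 0.4)$p_combined
  expect_lt(ensemble_combine(0.1, 0.3, 0.4)$p_combined, base)
  expect_lt(ensemble_combine(0.2, 0.3, 0.05)$p_combined, base)
  expect_warning(ensemble_combine(0, 0.5, 0.5), "clamped")
})

test_that("a degenerate flat signature reports no sets", {
  integ <- data.frame(gene_symbol = paste0("G", 1:100),
                      log2fc_integrated = 0,
                      p_adj_integrated = 1,
                      significant_any = FALSE, direction = "up",
                      in_signature = FALSE)
  sets <- geneset_collection(list(A = paste0("G", 1:10),
                                  B = paste0("G", 11:20)))
  res <- suppressWarnings(enrich_all(integ, sets, n_perm = 99, seed = 1))
  expect_true(all(!res$reported))
  expect_true(all(res$p_ora == 1))
})

test_that("enrichment statistics do not depend on set order", {
  cfg <- small_cfg(planted_sets = "PLANTED", seed = 17)
  sim <- simulate_counts(cfg)
  im <- simulate_intensities(cfg, sim$truth)
  integ <- integrate_tables(protein_differential(im, 35),
                            protein_differential(im, 56),
                            nb_differential(sim$counts, 35),
                            nb_differential(sim$counts, 56))
  gs <- build_genesets(cfg, sim$truth, n_sets = 8, set_size_range = c(10, 15))
  r1 <- enrich_all(integ, gs, n_perm = 199, seed = 3)
  perm <- rev(seq_along(gs$sets))
  gs2 <- geneset_collection(gs$sets[perm], gs$description[perm])
  r2 <- enrich_all(integ, gs2, n_perm = 199, seed = 3)
  r2 <- r2[match(r1$set_name, r2$set_name), ]
  rownames(r2) <- NULL
  expect_equal(r1, r2)
})

test_that("a planted set outranks decoys end to end", {
  cfg <- sim_config(n_genes = 1500, n_proteins = 750, frac_de = 0.1,
                    effect_log2fc = 1, planted_sets = "PLANTED", seed = 19)
  sim <- simulate_counts(cfg)
  im <- simulate_intensities(cfg, sim$truth)
  integ <- integrate_tables(protein_differential(im, 35),
                            protein_differential(im, 56),
                            nb_differential(sim$counts, 35),
                            nb_differential(sim$counts, 56))
  gs <- build_genesets(cfg, sim$truth, n_sets = 51,
                       set_size_range = c(20, 20))
  res <- enrich_all(integ, gs, n_perm = 499, seed = 23)
  top <- res[res$set_name == "PLANTED", ]
  expect_equal(top$median_rank, 1)
  expect_lt(top$p_adj, 0.05)
  expect_true(top$reported)
})
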