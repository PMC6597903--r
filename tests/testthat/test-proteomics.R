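test_that("channel-median normalization equalizes medians, preserving scale", {
  m <- matrix(c(10, 30, 20, 40), 2, 2,
              dimnames = list(c("p1", "p2"), c("c1", "c2")))
  out <- channel_median_normalize(m)
  expect_equal(out, matrix(c(12.5, 37.5, 50 / 3, 100 / 3), 2, 2,
                           dimnames = dimnames(m)), tolerance = 1e-12)
  # fixed point when medians already agree
  m2 <- matrix(c(1, 2, 3, 3, 2, 1), 3, 2,
               dimnames = list(paste0("p", 1:3), c("c1", "c2")))
  expect_equal(channel_median_normalize(m2), m2, tolerance = 1e-12)
  # row permutation commutes with normalization
  set.seed(4)
  m3 <- matrix(rlnorm(50 * 4, 10, 1), 50, 4,
               dimnames = list(paste0("p", 1:50), paste0("c", 1:4)))
  perm <- sample(50)
  expect_equal(channel_median_normalize(m3)[perm, ],
               channel_median_normalize(m3[perm, ]), tolerance = 1e-12)
  # post-normalization medians equal within 1e-9 relative
  med <- apply(channel_median_normalize(m3), 2, median)
  expect_lt(diff(range(med)) / med[1], 1e-9)
})

test_that("a channel with no finite values is rejected by name", {
  m <- matrix(c(1, 2, NA, 0), 2, 2,
              dimnames = list(c("p1", "p2"), c("good", "dead")))
  expect_error(channel_median_normalize(m), "dead")
})

test_that("relative ratios scale every row to mean one", {
  m <- matrix(c(2, 4, 6), 1, 3, dimnames = list("p1", c("a", "b", "c")))
  expect_equal(unname(relative_ratio(m)[1, ]), c(0.5, 1.0, 1.5),
               tolerance = 1e-12)
  m2 <- matrix(7, 2, 4, dimnames = list(c("p1", "p2"), letters[1:4]))
  expect_true(all(relative_ratio(m2) == 1))
  # row scaling cancels; re-application is the identity
  set.seed(5)
  m3 <- matrix(rlnorm(40, 5, 1), 10, 4,
               dimnames = list(paste0("p", 1:10), letters[1:4]))
  r1 <- relative_ratio(m3)
  expect_equal(relative_ratio(3.7 * m3), r1, tolerance = 1e-12)
  expect_equal(relative_ratio(r1), r1, tolerance = 1e-12)
  expect_equal(unname(rowMeans(r1)), rep(1, 10), tolerance = 1e-12)
})

test_that("equal group means give a zero moderated t and p of one", {
  y <- matrix(2 ^ c(1, 2, 3, 1, 2, 3), 1, 6,
              dimnames = list("p1", paste0("c", 1:6)))
  y <- rbind(y, matrix(2 ^ rnorm(5 * 6), 5, 6))
  rownames(y) <- paste0("p", 1:6)
  fit <- moderated_t(y, rep(c("control", "mutant"), each = 3))
  expect_equal(fit$log2fc[1], 0, tolerance = 1e-12)
  expect_equal(fit$t_mod[1], 0, tolerance = 1e-12)
  expect_equal(fit$p_raw[1], 1, tolerance = 1e-12)
})

test_that("with the prior weight removed the moderated t is the pooled t", {
  set.seed(6)
  y <- matrix(rlnorm(300 * 10, 0, 0.5), 300, 10,
              dimnames = list(paste0("p", 1:300), paste0("c", 1:10)))
  grp <- rep(c("control", "mutant"), each = 5)
  fit <- moderated_t(y, grp, d0 = 0)
  for (i in c(1, 57, 300)) {
    tt <- t.test(log2(y[i, grp == "mutant"]), log2(y[i, grp == "control"]),
                 var.equal = TRUE)
    expect_equal(fit$t_mod[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(fit$p_raw[i], tt$p.value, tolerance = 1e-10)
  }
  ord_t <- apply(y, 1, function(r)
    unname(t.test(log2(r[grp == "mutant"]), log2(r[grp == "control"]),
                  var.equal = TRUE)$statistic))
  expect_equal(fit$t_mod, unname(ord_t), tolerance = 1e-10)
})

test_that("posterior variance lies between the observed and prior variance", {
  set.seed(7)
  y <- matrix(rlnorm(500 * 10, 0, 0.4), 500, 10,
              dimnames = list(paste0("p", 1:500), paste0("c", 1:10)))
  fit <- moderated_t(y, rep(c("control", "mutant"), each = 5))
  expect_true(is.finite(fit$d0[1]) || is.infinite(fit$d0[1]))
  lo <- pmin(fit$s2, fit$s2_0)
  hi <- pmax(fit$s2, fit$s2_0)
  expect_true(all(fit$s2_post >= lo - 1e-12 & fit$s2_post <= hi + 1e-12))
})

test_that("hyperparameters agree with an independent empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(8)
  n <- 400
  true_s <- sqrt(0.04 * rf(n, 8, 10))  # heterogeneous true variances
  y <- matrix(rnorm(n * 10, 0, rep(true_s, 10)), n, 10,
              dimnames = list(paste0("p", 1:n), paste0("c", 1:10)))
  grp <- rep(c("control", "mutant"), each = 5)
  design <- cbind(1, as.numeric(grp == "mutant"))
  lfit <- limma::eBayes(limma::lmFit(y, design))
  ours <- moderated_t(2 ^ y, grp)
  # free estimates of the prior track the reference implementation
  expect_equal(ours$d0[1], lfit$df.prior, tolerance = 0.1 * lfit$df.prior)
  expect_equal(ours$s2_0[1], lfit$s2.prior, tolerance = 0.05 * lfit$s2.prior)
  # with the prior forced to the reference values, statistics match exactly
  forced <- moderated_t(2 ^ y, grp, d0 = lfit$df.prior, s2_0 = lfit$s2.prior)
  expect_equal(forced$t_mod, unname(lfit$t[, 2]), tolerance = 1e-8)
  expect_equal(forced$p_raw, unname(lfit$p.value[, 2]), tolerance = 1e-8)
})

test_that("proteins quantified in under two channels per group are dropped", {
  y <- matrix(rlnorm(4 * 6), 4, 6,
              dimnames = list(paste0("p", 1:4), paste0("c", 1:6)))
  y[1, 1:2] <- NA  # one control channel left
  expect_warning(fit <- moderated_t(y, rep(c("control", "mutant"), each = 3)),
                 "excluding 1")
  expect_false("p1" %in% fit$feature)
})

test_that("BH adjustment follows the step-up formula and validates input", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.02)), rep(0.04, 4),
               tolerance = 1e-12)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("duplicate gene symbols collapse to the strongest protein", {
  cfg <- small_cfg(seed = 12)
  sim <- simulate_counts(cfg)
  im <- simulate_intensities(cfg, sim$truth)
  im$gene_symbols[2] <- im$gene_symbols[1]  # force a duplicate mapping
  tab <- protein_differential(im, 35)
  expect_equal(anyDuplicated(tab$feature), 0L)
  expect_equal(nrow(tab), cfg$n_proteins - 1L)
})
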