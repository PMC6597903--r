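test_that("size factors follow the median-of-ratios formula", {
  m <- cbind(s1 = c(10, 200, 3000), s2 = c(10, 200, 3000))
  rownames(m) <- paste0("g", 1:3)
  expect_equal(unname(size_factors(m)), c(1, 1), tolerance = 1e-12)

  m2 <- cbind(s1 = c(10, 200, 3000), s2 = 2 * c(10, 200, 3000))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
})

test_that("rescaling one sample rescales only its size factor ratio", {
  set.seed(1)
  m <- matrix(rpois(60, 100) + 1, 20, 3,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
  s0 <- size_factors(m)
  m2 <- m
  m2[, 3] <- m2[, 3] * 4
  s1 <- size_factors(m2)
  expect_equal(s1[2] / s1[1], s0[2] / s0[1], tolerance = 1e-12)
  expect_equal(unname(s1[3] / s1[1]), unname(4 * s0[3] / s0[1]),
               tolerance = 1e-12)
})

test_that("size factors fail loudly when no gene covers all samples", {
  m <- cbind(s1 = c(5, 0), s2 = c(0, 5))
  rownames(m) <- c("g1", "g2")
  expect_error(size_factors(m), "no gene has nonzero counts")
})

test_that("fpkm implements counts * 1e9 / (length * library)", {
  m <- matrix(c(500, 9999500), 2, 1,
              dimnames = list(c("g1", "g2"), "s1"))
  f <- fpkm(m, lengths_bp = c(2000, 1000))
  expect_equal(f["g1", "s1"], 25.0, tolerance = 1e-12)
  m0 <- matrix(c(0, 1e7), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(fpkm(m0, c(2000, 1000))["g1", 1], 0)
  # doubling every count in a sample leaves its FPKM unchanged
  set.seed(2)
  m3 <- matrix(rpois(40, 50) + 1, 20, 2,
               dimnames = list(paste0("g", 1:20), c("a", "b")))
  len <- sample(500:2000, 20)
  f1 <- fpkm(m3, len)
  m3[, 2] <- m3[, 2] * 2
  expect_equal(fpkm(m3, len)[, 2], f1[, 2], tolerance = 1e-12)
  expect_error(fpkm(matrix(0, 2, 1, dimnames = list(c("a", "b"), "s")),
                    c(100, 100)), "zero library")
})

test_that("detection threshold is a strict inequality at 0.5 FPKM", {
  expect_identical(detection_filter(c(0.5, 0.51, 0)), c(FALSE, TRUE, FALSE))
})

test_that("identical groups give zero fold change and p of one", {
  set.seed(3)
  block <- matrix(rpois(33 * 3, 80) + 1, 33, 3)
  counts <- cbind(block, block)  # mutant samples mirror the controls
  rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  colnames(counts) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  cm <- count_matrix(counts, rep(1000, nrow(counts)),
                     data.frame(sample_id = colnames(counts),
                                genotype = rep(c("control", "mutant"), each = 3),
                                timepoint = 35L))
  tab <- nb_differential(cm, 35)
  expect_equal(tab$log2fc, rep(0, nrow(counts)), tolerance = 1e-12)
  expect_equal(tab$p_raw, rep(1, nrow(counts)), tolerance = 1e-12)
})

test_that("size factors absorb sample rescaling up to a common shift", {
  cfg <- small_cfg(seed = 9)
  cm <- simulate_counts(cfg)$counts
  sel <- cm$samples$timepoint == 35
  m1 <- cm$counts[, sel]
  m2 <- m1
  m2[, 1] <- m2[, 1] * 3
  nc1 <- sweep(m1, 2, size_factors(m1), "/")
  nc2 <- sweep(m2, 2, size_factors(m2), "/")
  # normalized matrices identical up to one global geometric-mean factor
  ratio <- nc2[m1 > 0] / nc1[m1 > 0]
  expect_lt(diff(range(ratio)), 1e-10)
  # so inferred fold changes are unaffected (tiny pseudocount shift aside)
  cm2 <- cm
  cm2$counts[, which(sel)[1]] <- cm2$counts[, which(sel)[1]] * 3
  expect_equal(nb_differential(cm2, 35)$log2fc,
               nb_differential(cm, 35)$log2fc, tolerance = 5e-3)
})

test_that("planted RNA effects are recovered with small bias", {
  cfg <- sim_config(n_genes = 2000, n_proteins = 500, frac_de = 0.1,
                    effect_log2fc = 1, seed = 21)
  sim <- simulate_counts(cfg)
  tab <- nb_differential(sim$counts, 56)
  tr <- sim$truth$de_features
  i <- match(tr$feature, tab$feature)
  bias <- mean(tab$log2fc[i] * sign(tr$log2fc)) - 1
  expect_lt(abs(bias), 0.1)
  # planted genes dominate the significant calls
  sig <- tab$feature[!is.na(tab$p_adj) & tab$p_adj < 0.05]
  expect_gt(mean(sig %in% tr$feature), 0.8)
})

test_that("degenerate designs are rejected", {
  counts <- matrix(rpois(30, 50) + 1, 10, 3,
                   dimnames = list(paste0("g", 1:10), c("a", "b", "c")))
  cm <- count_matrix(counts, rep(1000, 10),
                     data.frame(sample_id = c("a", "b", "c"),
                                genotype = c("control", "control", "mutant"),
                                timepoint = 35L))
  expect_error(nb_differential(cm, 35), ">= 2 samples per genotype")
  expect_error(nb_differential(cm, 56), "no samples")
})
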