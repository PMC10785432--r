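test_that("median-of-ratios size factors obey the formula", {
  base <- matrix(c(10L, 5L, 100L, 50L, 8L,
                   20L, 10L, 200L, 100L, 16L), ncol = 2,
                 dimnames = list(paste0("g", 1:5), c("a", "b")))
  sf <- median_of_ratios_size_factors(count_matrix(base))
  expect_equal(unname(sf$factors["b"] / sf$factors["a"]), 2)

  same <- count_matrix(cbind(a = base[, 1], b = base[, 1], c = base[, 1]))
  sf <- median_of_ratios_size_factors(same)
  expect_equal(unname(sf$factors), rep(sf$factors[[1]], 3))

  # hand-worked 3x6 example; expected values frozen from an independent
  # evaluation of the median-ratio formula (DESeq2's estimateSizeFactorsForMatrix)
  cnt <- matrix(c(10, 20, 30, 5, 10, 20, 0, 4, 8,
                  100, 180, 320, 50, 45, 60, 8, 16, 20),
                nrow = 6, byrow = TRUE,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:3)))
  sf <- median_of_ratios_size_factors(count_matrix(cnt))
  expect_equal(unname(sf$factors),
               c(0.557860791735142, 1.004149425123255, 1.650963624447313),
               tolerance = 1e-13)

  # rescaled variant has geometric mean one
  sfr <- median_of_ratios_size_factors(count_matrix(cnt), rescale = TRUE)
  expect_equal(exp(mean(log(sfr$factors))), 1)
})

test_that("size factors agree with the DESeq2 reference implementation", {
  set.seed(12)
  m <- matrix(rnbinom(300, mu = 10^runif(300, 0.5, 3), size = 8), ncol = 3,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:3)))
  ours <- median_of_ratios_size_factors(count_matrix(m))$factors
  theirs <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-12)
})

test_that("size factors are scale-equivariant and fail without usable genes", {
  cnt <- matrix(c(10L, 20L, 30L, 40L, 50L, 60L), 2, 3,
                dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  sf1 <- median_of_ratios_size_factors(count_matrix(cnt))
  cnt2 <- cnt
  cnt2[, "b"] <- cnt2[, "b"] * 5L
  sf2 <- median_of_ratios_size_factors(count_matrix(cnt2))
  # scaling one library by c multiplies its factor by c relative to the
  # others (the per-gene geometric means absorb a c^(1/3) term, so the
  # raw factors are equivariant only as ratios)
  expect_equal(unname((sf2$factors["b"] / sf2$factors["a"]) /
                        (sf1$factors["b"] / sf1$factors["a"])), 5)
  expect_equal(unname(sf2$factors["c"] / sf2$factors["a"]),
               unname(sf1$factors["c"] / sf1$factors["a"]))

  degenerate <- count_matrix(matrix(c(0L, 3L, 5L, 0L), 2, 2,
                                    dimnames = list(c("g1", "g2"), c("a", "b"))))
  expect_error(median_of_ratios_size_factors(degenerate), "no gene")
})

test_that("the NB Wald test is calibrated under the null", {
  set.seed(99)
  ng <- 2000
  lam <- 10^rnorm(ng, 2, 1)
  m <- sapply(1:4, function(i) rnbinom(ng, mu = lam, size = 10))
  rownames(m) <- paste0("g", 1:ng)
  cm <- count_matrix(m, sample_ids = paste0("s", 1:4))
  de <- nb_wald_de(cm, c(s1 = "a", s2 = "a", s3 = "b", s4 = "b"), alpha = 0.01)
  expect_gt(mean(de$pvalue < 0.05, na.rm = TRUE), 0.03)
  expect_lt(mean(de$pvalue < 0.05, na.rm = TRUE), 0.07)
  expect_identical(sum(de$significant), 0L)
})

test_that("a strong true effect at high expression is detected", {
  set.seed(17)
  ng <- 2000
  lam <- 10^rnorm(ng, 2, 1)
  m <- sapply(1:4, function(i) rnbinom(ng, mu = lam, size = 10))
  m[1, ] <- c(rnbinom(2, mu = 1000, size = 10), rnbinom(2, mu = 8000, size = 10))
  rownames(m) <- paste0("g", 1:ng)
  cm <- count_matrix(m, sample_ids = paste0("s", 1:4))
  de <- nb_wald_de(cm, c(s1 = "a", s2 = "a", s3 = "b", s4 = "b"), alpha = 0.01)
  expect_true(de$significant[de$gene_id == "g1"])
  expect_gt(de$log2FC[de$gene_id == "g1"], 2)
})

test_that("all-zero genes are excluded and flagged; BH preserves ordering", {
  set.seed(3)
  m <- matrix(rnbinom(40, mu = 50, size = 10), 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  m["g4", ] <- 0L
  cm <- count_matrix(m)
  de <- nb_wald_de(cm, c("a", "a", "b", "b"), alpha = 0.01)
  expect_false("g4" %in% de$gene_id)
  expect_identical(attr(de, "excluded"), "g4")
  ord <- order(de$pvalue)
  expect_true(all(diff(de$padj[ord]) >= -1e-12))
})

test_that("design errors are rejected", {
  m <- count_matrix(matrix(1:8, 2, 4,
                           dimnames = list(c("g1", "g2"), paste0("s", 1:4))))
  expect_error(nb_wald_de(m, rep("a", 4)), "2 condition levels")
  expect_warning(nb_wald_de(m, c("a", "b", "b", "b")), "single sample")
})

test_that("degenerate resampling reproduces the baseline calls exactly", {
  set.seed(8)
  ng <- 60
  lam <- 10^rnorm(ng, 2.5, 0.5)
  m <- sapply(1:4, function(i) rnbinom(ng, mu = lam, size = 10))
  m <- rbind(m, strong = c(500L, 500L, 4000L, 4000L))
  rownames(m) <- c(paste0("g", 1:ng), "strong")
  cm <- count_matrix(m, sample_ids = paste0("s", 1:4))
  cond <- c(s1 = "a", s2 = "a", s3 = "b", s4 = "b")
  posts <- list(s2 = fake_posterior(0, 0), s3 = fake_posterior(0, 0),
                s4 = fake_posterior(0, 0))
  rr <- reproducibility_resampling(cm, posts, cond, "s1",
                                   n_iterations = 3, alpha = 0.05, seed = 1)
  expect_true(all(rr$call_frequency %in% c(0, 1)))
  expect_identical(rr$call_frequency, as.numeric(rr$baseline_call))
  expect_true(rr$call_frequency[rr$gene_ids == "strong"] == 1)

  one <- reproducibility_resampling(cm, lapply(posts, function(p)
    fake_posterior(0, 0.4)), cond, "s1", n_iterations = 1, alpha = 0.05,
    seed = 2)
  expect_true(all(one$call_frequency %in% c(0, 1)))
})

test_that("always-called genes under tight posteriors are baseline calls", {
  set.seed(9)
  ng <- 60
  lam <- 10^rnorm(ng, 2.5, 0.5)
  m <- sapply(1:4, function(i) rnbinom(ng, mu = lam, size = 10))
  m <- rbind(m, strong = c(500L, 500L, 4000L, 4000L))
  rownames(m) <- c(paste0("g", 1:ng), "strong")
  cm <- count_matrix(m, sample_ids = paste0("s", 1:4))
  cond <- c(s1 = "a", s2 = "a", s3 = "b", s4 = "b")
  posts <- list(s2 = fake_posterior(0, 0.02), s3 = fake_posterior(0, 0.02),
                s4 = fake_posterior(0, 0.02))
  rr <- reproducibility_resampling(cm, posts, cond, "s1",
                                   n_iterations = 25, alpha = 0.05, seed = 5)
  expect_true(all(rr$baseline_call[rr$call_frequency == 1]))

  expect_error(reproducibility_resampling(cm, posts[1:2], cond, "s1",
                                          n_iterations = 2, alpha = 0.05),
               "missing posterior")
})
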