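test_that("identical samples give a factor of zero", {
  tr <- simulate_pair(synthetic_config(n_regions = 500, true_log2_factor = 0,
                                       seed = 41))
  m <- unclass(tr$matrix)
  cm <- count_matrix(cbind(a = m[, "query"], b = m[, "query"]))
  post <- fit_quiet(cm, "a", "b", mcmc = quick_mcmc(1))
  expect_lt(abs(post$mu_mean), 0.05)
  expect_lte(post$ci95[1], 0)
  expect_gte(post$ci95[2], 0)
})

test_that("an exact doubling recovers one log2 unit", {
  tr <- simulate_pair(synthetic_config(n_regions = 500, true_log2_factor = 0,
                                       seed = 42))
  m <- unclass(tr$matrix)
  cm <- count_matrix(cbind(a = m[, "query"], b = 2L * m[, "query"]))
  post <- fit_quiet(cm, "a", "b", mcmc = quick_mcmc(2))
  expect_lt(abs(post$mu_mean - 1), 0.05)
})

test_that("the generating factor is recovered from a synthetic pair", {
  tr <- simulate_pair(synthetic_config(n_regions = 1000,
                                       true_log2_factor = -1.5, seed = 7))
  post <- fit_quiet(tr$matrix, "query", "reference",
                    mcmc = quick_mcmc(1, draws = 2000, burn_in = 500))
  expect_lt(abs(post$mu_mean - (-1.5)), 0.1)
  expect_gt(post$mu_sd, 0)
  expect_equal(post$n_regions, 1000L)
})

test_that("posterior draws have the documented shape and determinism", {
  tr <- simulate_pair(synthetic_config(n_regions = 200, true_log2_factor = 1,
                                       seed = 9))
  mc <- quick_mcmc(5, draws = 400, burn_in = 150, chains = 3)
  post <- fit_quiet(tr$matrix, "query", "reference", mcmc = mc)
  expect_length(post$mu_slope_draws, 400L * 3L)
  expect_identical(nrow(post$draws), 1200L)
  expect_setequal(unique(post$draws$chain), 1:3)
  expect_true(all(c("mu_slope", "intercept", "sigma_fit", "sigma_mean",
                    "phi_x", "phi_y") %in% names(post$draws)))
  expect_true(post$ci95[1] <= post$mu_mean && post$mu_mean <= post$ci95[2])

  again <- fit_quiet(tr$matrix, "query", "reference", mcmc = mc)
  expect_identical(post$draws, again$draws)
})

test_that("fit direction is antisymmetric between query and reference", {
  tr <- simulate_pair(synthetic_config(n_regions = 800, true_log2_factor = 1.2,
                                       seed = 23))
  ab <- fit_quiet(tr$matrix, "query", "reference", mcmc = quick_mcmc(3))
  ba <- fit_quiet(tr$matrix, "reference", "query", mcmc = quick_mcmc(3))
  expect_lt(abs(ab$mu_mean + ba$mu_mean), 2 * max(ab$mu_sd, ba$mu_sd))
})

test_that("estimate error and uncertainty shrink as regions accumulate", {
  sizes <- c(100, 1000, 5000)
  seeds <- 1:10
  stats <- vapply(sizes, function(n) {
    per_seed <- vapply(seeds, function(s) {
      tr <- simulate_pair(synthetic_config(n_regions = n,
                                           true_log2_factor = 0.8,
                                           seed = 100 + s))
      p <- fit_quiet(tr$matrix, "query", "reference",
                     mcmc = quick_mcmc(s, draws = 800, burn_in = 300))
      c(err = abs(p$mu_mean - 0.8), sd = p$mu_sd)
    }, numeric(2))
    apply(per_seed, 1L, median)
  }, numeric(2))
  # the error median drops steeply and then plateaus at the model's small
  # systematic floor (~0.03 log2 at this truth), so allow plateau noise;
  # the posterior width must shrink strictly
  expect_true(all(diff(stats["err", ]) <= 0.01))
  expect_true(all(diff(stats["sd", ]) <= 0))
})

test_that("summarize_posterior reduces draws as documented", {
  post <- structure(list(mu_slope_draws = rep(0.7, 50)),
                    class = "vsi_posterior")
  s <- summarize_posterior(post, 0.95)
  expect_equal(s$estimate, 0.7)
  expect_equal(s$sd, 0)
  expect_equal(unname(s$interval), c(0.7, 0.7))

  post$mu_slope_draws <- rep(c(-1, 0, 1), each = 100)
  s <- summarize_posterior(post, 0.999)
  expect_equal(s$estimate, 0)
  expect_equal(unname(s$interval), c(-1, 1))

  post$mu_slope_draws <- local({set.seed(123); rnorm(10000, 0.5, 0.1)})
  s <- summarize_posterior(post, 0.95)
  expect_lt(abs(s$interval[1] - 0.304), 0.01)
  expect_lt(abs(s$interval[2] - 0.696), 0.01)

  expect_error(summarize_posterior(post, 1), "in \\(0, 1\\)")
  expect_error(summarize_posterior(post, 0), "in \\(0, 1\\)")
})

test_that("normalization factor resampling is parametric and reproducible", {
  p0 <- fake_posterior(1.3, 0)
  expect_identical(sample_normalization_factors(p0, 5, seed = 1),
                   rep(1.3, 5))

  p <- fake_posterior(1, 0.2)
  a <- sample_normalization_factors(p, 1000, seed = 99)
  b <- sample_normalization_factors(p, 1000, seed = 99)
  expect_identical(a, b)

  big <- sample_normalization_factors(p, 100000, seed = 4)
  expect_lt(abs(mean(big) - 1), 0.01)
  expect_lt(abs(sd(big) - 0.2), 0.01)

  expect_error(sample_normalization_factors(p, 0), ">= 1")
})

test_that("fit rejects undersized inputs", {
  cm <- count_matrix(matrix(1:2, 1, 2), "r1", c("a", "b"))
  expect_error(fit_vsi(cm, "a", "b"), "at least 2 regions")
})

test_that("posterior export writes draws TSV plus summary JSON", {
  tr <- simulate_pair(synthetic_config(n_regions = 100, true_log2_factor = 0,
                                       seed = 1))
  post <- fit_quiet(tr$matrix, "query", "reference",
                    mcmc = quick_mcmc(1, draws = 200, burn_in = 100))
  dir <- withr::local_tempdir()
  paths <- write_posterior(post, file.path(dir, "fit"))
  draws <- read.delim(paths[1])
  expect_identical(nrow(draws), 400L)
  summ <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
  expect_equal(summ$mu_mean, post$mu_mean)
  expect_equal(summ$n_regions, 100L)
  expect_named(summ, c("sample_id", "reference_id", "mu_mean", "mu_sd",
                       "ci95", "rhat", "ess", "n_regions"),
               ignore.order = TRUE)
})

test_that("local_seed leaves the ambient RNG stream untouched", {
  set.seed(555)
  before <- .Random.seed
  invisible(sample_normalization_factors(fake_posterior(0, 1), 10, seed = 3))
  expect_identical(.Random.seed, before)
})
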