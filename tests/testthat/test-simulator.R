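test_that("MAF draws cover the configured range", {
  d <- simulation_design("marginal", or = 1.5, n_noise = 4, n = 100,
                         maf_range = c(0.3, 0.3), seed = 1)
  set.seed(1)
  expect_equal(draw_mafs(d), rep(0.3, 10))

  d2 <- simulation_design("marginal", or = 1.5, n_noise = 9994, n = 100, seed = 1)
  set.seed(2)
  m <- draw_mafs(d2)            # 10^4 draws
  expect_true(all(m >= 0.15 & m <= 0.45))
  se <- sqrt((0.45 - 0.15)^2 / 12 / length(m))
  expect_lt(abs(mean(m) - 0.30), 3 * se)
})

test_that("genotypes are Hardy-Weinberg with independent SNPs", {
  set.seed(3)
  g <- simulate_genotypes(c(0.3, 0.2), 1e5)
  freq <- tabulate(unclass(g)[, 1] + 1L, 3L) / nrow(g)
  expected <- dbinom(0:2, 2, 0.3)
  se <- sqrt(expected * (1 - expected) / nrow(g))
  expect_true(all(abs(freq - expected) < 3 * se))
  # chi-square goodness of fit at alpha = 0.001
  gof <- chisq.test(tabulate(unclass(g)[, 1] + 1L, 3L), p = expected)
  expect_gt(gof$p.value, 0.001)
  expect_lt(abs(cor(unclass(g)[, 1], unclass(g)[, 2])), 3 / sqrt(nrow(g)))
  expect_true(all(simulate_genotypes(c(0, 0), 50) == 0L))
})

test_that("environmental exposures are bivariate normal with the set moments", {
  d <- simulation_design("gxe", or_gxe = 1.8, rho = 0.9, seed = 1)
  set.seed(4)
  e <- simulate_environment(d, 1e5)
  expect_lt(abs(cor(e[, 1], e[, 2]) - 0.9), 3 / sqrt(nrow(e)))
  expect_lt(abs(mean(e[, 1]) - 20), 3 * sqrt(10 / nrow(e)))
  expect_lt(abs(var(e[, 2]) - 10), 3 * 10 * sqrt(2 / nrow(e)))
  d0 <- simulation_design("marginal", seed = 1)
  expect_error(simulate_environment(d0, 10), "gxe")
})

test_that("per-IQR odds ratios convert through the theoretical normal IQR", {
  expect_equal(or_per_iqr_to_beta(1, 10), 0)
  iqr <- 2 * qnorm(0.75) * sqrt(10)
  expect_equal(iqr, 4.26585, tolerance = 1e-5)
  expect_equal(or_per_iqr_to_beta(1.2, 10), log(1.2) / iqr)
  expect_equal(or_per_iqr_to_beta(1.2, 10), 0.042737, tolerance = 1e-4)
})

test_that("the linear predictor evaluates each scenario's terms exactly", {
  d1 <- simulation_design("marginal", or = 1.5, n_noise = 4, seed = 1)
  m1 <- structure(list(intercept = -1, terms = grsforge:::design_terms(d1),
                       design = d1), class = "grs_true_model")
  zeros <- snp_matrix(matrix(0L, 2, 10))
  expect_equal(linear_predictor(m1, zeros), c(-1, -1))
  ones <- snp_matrix(matrix(1L, 1, 10))
  expect_equal(linear_predictor(m1, ones), -1 + 6 * log(1.5))

  d2 <- simulation_design("gene_gene", or_interaction = 2, n_noise = 5,
                          interaction_pair = c(4, 5), seed = 1)
  m2 <- structure(list(intercept = 0, terms = grsforge:::design_terms(d2),
                       design = d2), class = "grs_true_model")
  g <- matrix(0L, 1, 10); g[1, 1:3] <- 1L      # SNP4 = SNP5 = 0
  expect_equal(linear_predictor(m2, snp_matrix(g)), 3 * log(1.2))
})

test_that("intercept calibration hits the target case fraction", {
  d0 <- null_design(n_snps = 10, n = 100, seed = 1)
  set.seed(5)
  m0 <- calibrate_true_model(d0, calibration_n = 2e4)
  expect_lt(abs(m0$intercept), 0.01)   # all effects zero -> b0 = 0

  d <- simulation_design("marginal", or = 1.8, n_noise = 4, n = 100, seed = 1)
  set.seed(6)
  m <- calibrate_true_model(d, calibration_n = 1e5)
  expect_lt(m$intercept, 0)            # risk-increasing effects push b0 down
  # the intercept targets the average case fraction across replicates,
  # each of which redraws its MAFs; average over fresh replicate draws
  fracs <- replicate(30, mean(true_model_predict(m,
    simulate_genotypes(draw_mafs(d), 5e3))))
  frac <- mean(fracs)
  expect_gte(frac, 0.48)
  expect_lte(frac, 0.52)
  g <- simulate_genotypes(draw_mafs(d), 1e5)
  # case fraction is strictly increasing in the intercept
  shift <- function(b0) {
    mm <- m; mm$intercept <- b0
    mean(true_model_predict(mm, g))
  }
  expect_lt(shift(m$intercept - 1), shift(m$intercept))
  expect_gt(shift(m$intercept + 1), shift(m$intercept))
})

test_that("outcomes are Bernoulli draws from the model risks", {
  d <- simulation_design("marginal", or = 1.5, n_noise = 4, seed = 1)
  m <- structure(list(intercept = 50, terms = grsforge:::design_terms(d),
                      design = d), class = "grs_true_model")
  g <- snp_matrix(matrix(0L, 100, 10))
  set.seed(7)
  expect_true(all(simulate_outcome(m, g) == 1L))  # saturated intercept

  m$intercept <- -0.5
  set.seed(8)
  gg <- simulate_genotypes(rep(0.3, 10), 2e4)
  y <- simulate_outcome(m, gg)
  # conditional case rate within a genotype stratum matches logistic(eta)
  stratum <- rowSums(unclass(gg)[, 1:6] != 0L) == 2L
  expected <- plogis(-0.5 + 2 * log(1.5))
  n_s <- sum(stratum)
  expect_lt(abs(mean(y[stratum]) - expected),
            3 * sqrt(expected * (1 - expected) / n_s))
})

test_that("replicate generation is deterministic and correctly shaped", {
  d <- simulation_design("marginal", or = 1.2, n_noise = 4, n = 50,
                         n_replicates = 3, seed = 11)
  r1 <- simulate_grs_data(d, calibration_n = 5e3)
  r2 <- simulate_grs_data(d, calibration_n = 5e3)
  expect_identical(r1, r2)
  expect_equal(ncol(r1[[1]]$genotypes), 10L)
  expect_false(identical(unclass(r1[[1]]$genotypes), unclass(r1[[2]]$genotypes)))

  d3 <- simulation_design("gxe", or_gxe = 1.8, n = 40, n_replicates = 2, seed = 3)
  r3 <- simulate_grs_data(d3, calibration_n = 5e3)
  expect_equal(ncol(r3[[1]]$genotypes), 50L)
  expect_equal(ncol(r3[[1]]$environment), 2L)
})

test_that("the marginal-scenario true GRS is discrete and monotone in carrier count", {
  d <- simulation_design("marginal", or = 1.5, n_noise = 0, seed = 1)
  set.seed(9)
  m <- calibrate_true_model(d, calibration_n = 2e4)
  patterns <- as.matrix(expand.grid(rep(list(0:2), 6)))
  risks <- true_model_predict(m, snp_matrix(patterns))
  expect_equal(length(unique(round(risks, 12))), 7L)
  carriers <- rowSums(patterns != 0)
  means <- tapply(risks, carriers, unique)
  expect_true(all(diff(unlist(means)) > 0))
})

test_that("scenario sweeps enumerate the full setting grids", {
  expect_length(scenario_settings("marginal"), 27L)
  expect_length(scenario_settings("gene_gene"), 45L)
  expect_length(scenario_settings("gxe"), 20L)
})
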