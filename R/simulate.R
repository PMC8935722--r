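#' Simulation designs for case-control SNP data
#'
#' Defines the generating model for one simulation setting. Three scenarios
#' are supported, all logistic models on dominant-coded SNPs with the
#' intercept calibrated so that roughly half of the simulated individuals
#' are cases:
#'
#' * `"marginal"` — six influential SNPs with a common per-SNP odds ratio
#'   acting through dominant indicators:
#'   `logit P(Y=1) = b0 + sum_{i=1}^{6} b_i 1(SNP_i != 0)`.
#' * `"gene_gene"` — three SNPs with weak marginal odds ratios of 1.2 plus
#'   one product term `b4 * SNP_jD * SNP_kD` between a pair
#'   `(j, k)` of SNPs that may or may not carry marginal effects.
#' * `"gxe"` — three marginal SNPs (odds ratios 1.2, 1.5, 1.8), a fixed
#'   gene-gene interaction between SNPs 1 and 4 (odds ratio 1.8), a
#'   continuous exposure E1 with odds ratio 1.2 per interquartile range,
#'   and a gene-environment product `E2 * SNP_jD` with a configurable odds
#'   ratio per IQR. (E1, E2) are bivariate normal with means 20, variances
#'   10 and correlation `rho`.
#'
#' Minor allele frequencies are redrawn per replicate, uniformly from
#' `maf_range`; genotypes are Hardy-Weinberg, i.e. Binomial(2, MAF), and
#' SNPs are mutually independent (emulating LD-pruned panels). Setting
#' `or = 1` (and interaction odds ratios 1) yields null data in which the
#' outcome is independent of all predictors.
#'
#' @param scenario `"marginal"`, `"gene_gene"` or `"gxe"`.
#' @param or scenario `"marginal"`: common odds ratio of the six SNPs.
#' @param or_interaction odds ratio of the gene-gene product term
#'   (scenario `"gene_gene"`; fixed at 1.8 in `"gxe"`).
#' @param or_gxe odds ratio per IQR of the `E2 * SNP_jD` term (`"gxe"`).
#' @param n_noise number of non-influential SNPs appended to the panel.
#' @param n samples per replicate.
#' @param interaction_pair `(j, k)` for `"gene_gene"`: one of
#'   `c(1, 2)`, `c(1, 4)`, `c(4, 5)`.
#' @param gxe_index SNP index j of the gene-environment interaction
#'   (`"gxe"`): 2 (also has a marginal effect) or 5 (interaction only).
#' @param rho correlation between E1 and E2 (`"gxe"`).
#' @param env_mean,env_variance mean and variance of E1 and E2.
#' @param maf_range interval the per-SNP MAFs are drawn from.
#' @param target_case_fraction calibration target for the intercept.
#' @param n_replicates independent datasets generated per setting.
#' @param seed integer seed governing all randomness of the setting.
#' @return An object of class `simulation_design`.
#' @examples
#' d <- simulation_design("marginal", or = 1.5, n_noise = 4, n = 500,
#'                        n_replicates = 2, seed = 1)
#' reps <- simulate_grs_data(d)
#' table(reps[[1]]$outcome)
#' @export
simulation_design <- function(scenario = c("marginal", "gene_gene", "gxe"),
                              or = 1.5, or_interaction = 1.8, or_gxe = 1.8,
                              n_noise = NULL, n = 2000,
                              interaction_pair = c(1L, 2L), gxe_index = 2L,
                              rho = 0.5, env_mean = 20, env_variance = 10,
                              maf_range = c(0.15, 0.45),
                              target_case_fraction = 0.5,
                              n_replicates = 100L, seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(
    or > 0, or_interaction > 0, or_gxe > 0, n >= 2,
    length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
    maf_range[1] <= maf_range[2], rho > -1, rho < 1, env_variance > 0,
    target_case_fraction > 0, target_case_fraction < 1, n_replicates >= 1
  )
  if (is.null(n_noise)) {
    n_noise <- switch(scenario, marginal = 44L, gene_gene = 45L, gxe = 45L)
  }
  if (scenario == "gene_gene") {
    pair <- as.integer(interaction_pair)
    if (!paste(pair, collapse = ",") %in% c("1,2", "1,4", "4,5")) {
      stop("interaction_pair must be one of (1,2), (1,4), (4,5)")
    }
  }
  if (scenario == "gxe" && !gxe_index %in% c(2L, 5L)) {
    stop("gxe_index must be 2 or 5")
  }
  n_model_snps <- switch(scenario,
    marginal = 6L,
    gene_gene = max(3L, max(as.integer(interaction_pair))),
    gxe = 5L
  )
  design <- structure(list(
    scenario = scenario, or = or, or_interaction = or_interaction,
    or_gxe = or_gxe, n_noise = as.integer(n_noise), n = as.integer(n),
    interaction_pair = as.integer(interaction_pair),
    gxe_index = as.integer(gxe_index), rho = rho, env_mean = env_mean,
    env_variance = env_variance, maf_range = maf_range,
    target_case_fraction = target_case_fraction,
    n_model_snps = n_model_snps,
    n_snps = switch(scenario, marginal = 6L, gene_gene = 5L, gxe = 5L) +
      as.integer(n_noise),
    n_replicates = as.integer(n_replicates), seed = as.integer(seed)
  ), class = "simulation_design")
  design
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf("simulation_design: scenario '%s', %d SNPs (%d noise), n = %d, %d replicates\n",
              x$scenario, x$n_snps, x$n_noise, x$n, x$n_replicates))
  invisible(x)
}

#' Convenience null design: outcome independent of all SNPs
#'
#' A marginal-scenario shell with every odds ratio equal to 1, so all
#' genetic coefficients are zero and the calibrated intercept is zero.
#' Used for type-I-error estimation.
#'
#' @param n_snps total SNP count (6 model positions plus noise).
#' @param n samples per replicate.
#' @param ... passed to [simulation_design()].
#' @export
null_design <- function(n_snps = 50L, n = 1000L, ...) {
  stopifnot(n_snps >= 6L)
  simulation_design("marginal", or = 1, n_noise = as.integer(n_snps) - 6L,
                    n = n, ...)
}

#' Convert an odds ratio per IQR of a normal exposure to a coefficient
#'
#' Environmental odds ratios are specified per interquartile range of the
#' exposure; the model coefficient is `log(or)` divided by the theoretical
#' IQR of a normal with variance `sigma2`, i.e. `2 * qnorm(0.75) * sqrt(sigma2)`.
#'
#' @param odds_ratio odds ratio per IQR (> 0).
#' @param sigma2 variance of the normal exposure (> 0).
#' @return The per-unit log-odds coefficient.
#' @export
or_per_iqr_to_beta <- function(odds_ratio, sigma2) {
  stopifnot(odds_ratio > 0, sigma2 > 0)
  log(odds_ratio) / (2 * qnorm(0.75) * sqrt(sigma2))
}

#' Draw per-SNP minor allele frequencies
#'
#' @param design a `simulation_design`.
#' @return A vector of `design$n_snps` independent uniforms on `maf_range`.
#' @export
draw_mafs <- function(design) {
  runif(design$n_snps, design$maf_range[1], design$maf_range[2])
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Each genotype is the sum of two independent allele draws with success
#' probability equal to the SNP's MAF, i.e. Binomial(2, MAF); SNPs are
#' mutually independent.
#'
#' @param mafs vector of minor allele frequencies in (0, 0.5].
#' @param n number of samples.
#' @return An n x length(mafs) `snp_matrix`.
#' @export
simulate_genotypes <- function(mafs, n) {
  stopifnot(all(mafs >= 0), all(mafs <= 0.5))
  p <- length(mafs)
  g <- matrix(rbinom(n * p, 2L, rep(mafs, each = n)), nrow = n, ncol = p)
  snp_matrix(g)
}

#' Simulate correlated environmental exposures
#'
#' Rows are i.i.d. bivariate normal with means `env_mean`, variances
#' `env_variance` and correlation `rho`.
#'
#' @param design a `simulation_design` with `scenario == "gxe"`.
#' @param n number of samples.
#' @return An n x 2 matrix with columns `E1`, `E2`.
#' @export
simulate_environment <- function(design, n) {
  if (design$scenario != "gxe") {
    stop("environmental variables are only defined for the 'gxe' scenario")
  }
  z <- matrix(rnorm(2L * n), n, 2L)
  e2 <- design$rho * z[, 1L] + sqrt(1 - design$rho^2) * z[, 2L]
  e <- cbind(E1 = z[, 1L], E2 = e2) * sqrt(design$env_variance) + design$env_mean
  e
}

# Build the effect terms (everything except the intercept) of a design.
# Each term is a list(label, type, snps, env, beta).
design_terms <- function(design) {
  terms <- list()
  add <- function(label, type, beta, snps = integer(), env = NA_integer_) {
    terms[[length(terms) + 1L]] <<- list(label = label, type = type,
                                         beta = beta, snps = snps, env = env)
    invisible(NULL)
  }
  if (design$scenario == "marginal") {
    for (i in 1:6) add(sprintf("snp%d_D", i), "snp_d", log(design$or), snps = i)
  } else if (design$scenario == "gene_gene") {
    for (i in 1:3) add(sprintf("snp%d_D", i), "snp_d", log(1.2), snps = i)
    jk <- design$interaction_pair
    add(sprintf("snp%d_D:snp%d_D", jk[1], jk[2]), "snp_d_product",
        log(design$or_interaction), snps = jk)
  } else {
    ors <- c(1.2, 1.5, 1.8)
    for (i in 1:3) add(sprintf("snp%d_D", i), "snp_d", log(ors[i]), snps = i)
    add("snp1_D:snp4_D", "snp_d_product", log(design$or_interaction),
        snps = c(1L, 4L))
    add("E1", "env", or_per_iqr_to_beta(1.2, design$env_variance), env = 1L)
    add(sprintf("E2:snp%d_D", design$gxe_index), "env_x_snp_d",
        or_per_iqr_to_beta(design$or_gxe, design$env_variance),
        snps = design$gxe_index, env = 2L)
  }
  terms
}

#' Evaluate the linear predictor of a true generating model
#'
#' @param model a `grs_true_model` (see [calibrate_true_model()]).
#' @param genotypes a `snp_matrix` covering the model's SNP indices.
#' @param environment N x 2 exposure matrix, required when the model has
#'   environmental terms.
#' @return Length-N numeric vector `b0 + sum_k beta_k * term_k`.
#' @export
linear_predictor <- function(model, genotypes, environment = NULL) {
  g <- unclass(as_snp_matrix(genotypes))
  eta <- rep(model$intercept, nrow(g))
  for (term in model$terms) {
    if (term$beta == 0) next
    x <- switch(term$type,
      snp_d = as.numeric(g[, term$snps] != 0L),
      snp_d_product = as.numeric(g[, term$snps[1]] != 0L) *
        as.numeric(g[, term$snps[2]] != 0L),
      env = {
        if (is.null(environment)) stop("model has environmental terms but no environment was supplied")
        environment[, term$env]
      },
      env_x_snp_d = {
        if (is.null(environment)) stop("model has environmental terms but no environment was supplied")
        environment[, term$env] * as.numeric(g[, term$snps] != 0L)
      },
      stop("unknown term type: ", term$type)
    )
    eta <- eta + term$beta * x
  }
  eta
}

#' Calibrate the intercept of a generating model to a target case fraction
#'
#' Draws a large calibration sample and bisects on the intercept so that
#' the Monte-Carlo mean of `plogis(linear predictor)` matches
#' `target_case_fraction` within `tol`. Because the intercept is calibrated
#' once per setting but reused across replicates that each redraw their
#' MAFs, the calibration sample marginalizes over the MAF distribution:
#' every calibration individual receives freshly drawn per-SNP MAFs, so
#' the achieved fraction targets the average case fraction across
#' replicates (individual replicates scatter around it).
#'
#' @param design a `simulation_design`.
#' @param calibration_n calibration sample size.
#' @param tol tolerance on the achieved case fraction.
#' @return A `grs_true_model`: list with `intercept`, `terms`, `design`.
#' @export
calibrate_true_model <- function(design, calibration_n = 2e5, tol = 0.005) {
  terms <- design_terms(design)
  n <- as.integer(calibration_n)
  p <- design$n_snps
  maf_draws <- runif(as.double(n) * p, design$maf_range[1], design$maf_range[2])
  g <- snp_matrix(matrix(rbinom(n * p, 2L, maf_draws), nrow = n, ncol = p))
  env <- if (design$scenario == "gxe") simulate_environment(design, n) else NULL
  base <- structure(list(intercept = 0, terms = terms, design = design),
                    class = "grs_true_model")
  s <- linear_predictor(base, g, env)   # fixed part; intercept shifts it
  target <- design$target_case_fraction
  frac <- function(b0) mean(plogis(b0 + s))
  lo <- -20; hi <- 20
  if (frac(lo) > target || frac(hi) < target) {
    stop("failed to bracket the intercept in [-20, 20]")
  }
  while (hi - lo > 1e-9) {
    mid <- (lo + hi) / 2
    f <- frac(mid)
    if (abs(f - target) <= tol) { lo <- mid; hi <- mid; break }
    if (f < target) lo <- mid else hi <- mid
  }
  b0 <- (lo + hi) / 2
  structure(list(intercept = b0, terms = terms, design = design),
            class = "grs_true_model")
}

#' Risk predictions of the true generating model
#'
#' The oracle genetic risk score: `plogis(linear predictor)`.
#'
#' @param model a `grs_true_model`.
#' @param genotypes a `snp_matrix`.
#' @param environment exposure matrix for models with environmental terms.
#' @return Risk probabilities in (0, 1).
#' @export
true_model_predict <- function(model, genotypes, environment = NULL) {
  plogis(linear_predictor(model, genotypes, environment))
}

#' @export
predict.grs_true_model <- function(object, newdata, environment = NULL, ...) {
  true_model_predict(object, newdata, environment)
}

#' @export
print.grs_true_model <- function(x, ...) {
  cat(sprintf("true generating model (%s scenario), intercept %.4f\n",
              x$design$scenario, x$intercept))
  for (term in x$terms) {
    cat(sprintf("  %-18s beta = %8.4f (OR %.3f)\n", term$label, term$beta,
                exp(term$beta)))
  }
  invisible(x)
}

#' Simulate Bernoulli outcomes from a generating model
#'
#' @param model a calibrated `grs_true_model`.
#' @param genotypes a `snp_matrix`.
#' @param environment exposure matrix when the model requires one.
#' @return 0/1 integer vector with `Y_i ~ Bernoulli(plogis(eta_i))`.
#' @export
simulate_outcome <- function(model, genotypes, environment = NULL) {
  pr <- true_model_predict(model, genotypes, environment)
  rbinom(length(pr), 1L, pr)
}

#' Generate independent replicate datasets for a simulation setting
#'
#' Calibrates the intercept once, then generates `design$n_replicates`
#' datasets, each with freshly drawn MAFs, genotypes, exposures and
#' outcomes. Per-replicate seeds are derived deterministically from
#' `design$seed`, so equal seeds reproduce identical data.
#'
#' @param design a `simulation_design`.
#' @param true_model optional pre-calibrated model (skips calibration).
#' @param calibration_n sample size used by [calibrate_true_model()].
#' @return A list of datasets, each a list with elements `genotypes`,
#'   `environment` (NULL outside the gxe scenario), `outcome`,
#'   `true_model`, `mafs`, `replicate`.
#' @export
simulate_grs_data <- function(design, true_model = NULL, calibration_n = 2e5) {
  seeds <- derive_seeds(design$seed, design$n_replicates + 1L)
  if (is.null(true_model)) {
    set.seed(seeds[1L])
    true_model <- calibrate_true_model(design, calibration_n = calibration_n)
  }
  lapply(seq_len(design$n_replicates), function(r) {
    set.seed(seeds[r + 1L])
    mafs <- draw_mafs(design)
    g <- simulate_genotypes(mafs, design$n)
    env <- if (design$scenario == "gxe") simulate_environment(design, design$n) else NULL
    y <- simulate_outcome(true_model, g, env)
    structure(list(genotypes = g, environment = env, outcome = y,
                   true_model = true_model, mafs = mafs, replicate = r),
              class = "grs_dataset")
  })
}

# Deterministic sub-seed derivation: a fixed-seed draw of distinct 31-bit
# integers, so replicate streams are reproducible and do not overlap by
# construction of R's RNG reseeding.
derive_seeds <- function(seed, k) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

#' Enumerate the full grid of study settings for a scenario
#'
#' Materializes every combination of the varied parameters: 27 settings for
#' the marginal scenario (3 odds ratios x 3 noise levels x 3 sample sizes),
#' 45 for the gene-gene scenario (5 interaction odds ratios x 3 noise
#' levels x 3 interacting pairs) and 20 for the gene-environment scenario
#' (5 interaction odds ratios x 2 interacting SNPs x 2 correlations).
#'
#' @param scenario `"marginal"`, `"gene_gene"` or `"gxe"`.
#' @param seed base seed; setting i receives `seed + i`.
#' @param n_replicates replicates per setting.
#' @return A list of `simulation_design` objects.
#' @export
scenario_settings <- function(scenario = c("marginal", "gene_gene", "gxe"),
                              seed = 1L, n_replicates = 100L) {
  scenario <- match.arg(scenario)
  grid <- switch(scenario,
    marginal = expand.grid(or = c(1.2, 1.5, 1.8), n_noise = c(4L, 14L, 44L),
                           n = c(500L, 1000L, 2000L)),
    gene_gene = expand.grid(or_interaction = c(1.2, 1.5, 1.8, 2.1, 2.4),
                            n_noise = c(5L, 15L, 45L), pair = 1:3),
    gxe = expand.grid(or_gxe = c(1.2, 1.5, 1.8, 2.1, 2.4),
                      gxe_index = c(2L, 5L), rho = c(0.5, 0.9))
  )
  pairs <- list(c(1L, 2L), c(1L, 4L), c(4L, 5L))
  lapply(seq_len(nrow(grid)), function(i) {
    row <- grid[i, , drop = FALSE]
    switch(scenario,
      marginal = simulation_design("marginal", or = row$or,
        n_noise = row$n_noise, n = row$n, n_replicates = n_replicates,
        seed = seed + i),
      gene_gene = simulation_design("gene_gene",
        or_interaction = row$or_interaction, n_noise = row$n_noise, n = 2000L,
        interaction_pair = pairs[[row$pair]], n_replicates = n_replicates,
        seed = seed + i),
      gxe = simulation_design("gxe", or_gxe = row$or_gxe,
        gxe_index = row$gxe_index, rho = row$rho, n_noise = 45L, n = 2000L,
        n_replicates = n_replicates, seed = seed + i)
    )
  })
}
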