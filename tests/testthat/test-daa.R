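test_that("log_linear_fit recovers a known slope exactly", {
  # noiseless construction: log abundance linear in the covariate up to the
  # common normalization, which shifts all slopes equally
  x <- c(0, 0, 1, 1)
  raw <- cbind(exp(0.7 * x), exp(-0.2 * x), rep(1, 4))
  comp <- row_normalize(raw)
  res <- log_linear_fit(comp, x)
  expect_equal(nrow(res), 3)
  expect_equal(res$df, rep(2L, 3))
  # slope differences are invariant to the normalization shift
  expect_equal(res$slope[1] - res$slope[3], 0.7, tolerance = 1e-10)
  expect_equal(res$slope[2] - res$slope[3], -0.2, tolerance = 1e-10)
  # perfectly linear log abundances: residual se is guarded, tiny
  expect_true(all(res$se <= 1e-6))
})

test_that("log_linear_fit matches lm() on noisy data", {
  set.seed(101)
  n <- 30
  x <- rnorm(n)
  comp <- row_normalize(matrix(rgamma(n * 4, 2) + 0.01, n, 4))
  res <- log_linear_fit(comp, x)
  for (j in 1:4) {
    ref <- summary(lm(log(comp[, j]) ~ x))$coefficients["x", ]
    expect_equal(res$slope[j], unname(ref["Estimate"]), tolerance = 1e-10)
    expect_equal(res$se[j], unname(ref["Std. Error"]), tolerance = 1e-10)
  }
})

test_that("log_linear_fit validates input and handles factors and winsorization", {
  comp <- row_normalize(matrix(rgamma(12, 2) + 0.1, 4, 3))
  expect_error(log_linear_fit(comp, c(1, 1, 1, 1)), "constant")
  expect_error(log_linear_fit(comp, 1:3), "length")
  zeroed <- comp; zeroed[1, 1] <- 0
  expect_error(log_linear_fit(zeroed, 1:4), "strictly positive")
  fac <- log_linear_fit(comp, factor(c("a", "a", "b", "b")))
  num <- log_linear_fit(comp, c(0, 0, 1, 1))
  expect_equal(fac$slope, num$slope)
  wins <- log_linear_fit(comp, 1:4, winsor_quantile = 0.75)
  expect_true(is.finite(sum(wins$slope)))
})

test_that("bias_correct is shift-invariant and recovers a planted mode", {
  set.seed(102)
  slopes <- c(rnorm(80, 0, 0.02), rnorm(8, 1.4, 0.05))
  centered <- bias_correct(slopes + 5)
  expect_equal(centered, bias_correct(slopes), tolerance = 1e-9)
  # the dense null cluster sits at 0 after centering
  expect_lt(abs(median(centered[1:80])), 0.05)
  expect_equal(bias_correct(rep(2, 6)), rep(0, 6))
  expect_error(bias_correct(c(1, 2)), "at least 5")
})

test_that("rubin_pool reproduces a hand-worked two-imputation example", {
  est <- matrix(c(1, 3), 2, 1)          # qbar = 2, B = 2
  vars <- matrix(c(1, 1), 2, 1)         # ubar = 1
  out <- rubin_pool(est, vars, df_com = 10)
  expect_equal(out$estimate, 2)
  expect_equal(out$variance, 1 + (1 + 1 / 2) * 2)  # T = ubar + (1+1/M) B = 4
  lambda <- (1 + 1 / 2) * 2 / 4
  nu_old <- (2 - 1) / lambda^2
  nu_obs <- (10 + 1) / (10 + 3) * 10 * (1 - lambda)
  expect_equal(out$df, 1 / (1 / nu_old + 1 / nu_obs))
  expect_lt(out$df, 10)  # pooled df never exceed the complete-data df
})

test_that("rubin_pool with no between-imputation variance keeps ubar", {
  est <- matrix(2, 5, 3)
  vars <- matrix(0.5, 5, 3)
  out <- rubin_pool(est, vars, df_com = 20)
  expect_equal(out$variance, rep(0.5, 3))
  expect_equal(out$estimate, rep(2, 3))
  expect_true(all(is.finite(out$df)))
  expect_error(rubin_pool(est[1, , drop = FALSE], vars[1, , drop = FALSE], 20),
               "at least 2")
  expect_error(rubin_pool(est, vars[, 1:2], 20), "identical shape")
})

test_that("pooled variance is at least the mean within-imputation variance", {
  set.seed(103)
  est <- matrix(rnorm(40), 8, 5)
  vars <- matrix(rgamma(40, 2, 10), 8, 5)
  out <- rubin_pool(est, vars, df_com = 15)
  expect_true(all(out$variance >= colMeans(vars) - 1e-12))
})

test_that("mi_daa returns a complete, BH-adjusted result table", {
  cfg <- sim_config(n_samples = 40, n_taxa = 12, setting = "gamma",
                    diff_fraction = 0.25, effect_range = c(log(4), log(8)),
                    depth_range = c(2000, 5000), seed = 104)
  truth <- spike_signal(simulate_parametric(cfg), cfg)
  res <- mi_daa(truth$table, truth$group, n_imputations = 5, seed = 1)
  expect_s3_class(res, "daa_result")
  expect_equal(nrow(res), 12)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_equal(res$q_value, p.adjust(res$p_value, "BH"))
  expect_identical(res$rejected, res$q_value <= 0.1)
  expect_error(mi_daa(truth$table, truth$group, n_imputations = 1),
               "at least 2")
})

test_that("mi_daa keeps the type-I error under a global null", {
  cfg <- sim_config(n_samples = 50, n_taxa = 15, setting = "gamma",
                    diff_fraction = 0, depth_range = c(2000, 5000),
                    seed = 105)
  truth <- spike_signal(simulate_parametric(cfg), cfg)
  res <- mi_daa(truth$table, truth$group, n_imputations = 10,
                target_fdr = 0.05, seed = 2)
  expect_lte(sum(res$rejected), 1)
})

test_that("benchmark_fdr_power aggregates replicate-level quantities", {
  cfg <- sim_config(n_samples = 30, n_taxa = 12, setting = "gamma",
                    diff_fraction = 0.25, effect_range = c(log(4), log(8)),
                    depth_range = c(2000, 5000), seed = 106)
  rep <- benchmark_fdr_power(cfg, n_imputations = 4, replicates = 2, seed = 3)
  expect_s3_class(rep, "bench_report")
  expect_equal(length(rep$fdp), 2)
  expect_equal(rep$fdr, mean(rep$fdp))
  expect_equal(rep$power, mean(rep$tpr))
  expect_true(all(rep$fdp >= 0 & rep$fdp <= 1))
  expect_true(all(rep$tpr >= 0 & rep$tpr <= 1))
})
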