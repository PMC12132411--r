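test_that("preset_hyperparams produces the documented archetype mix", {
  h <- preset_hyperparams(100, seed = 71)
  arch <- attr(h, "archetype")
  expect_equal(sum(arch == "spike"), 40)
  expect_equal(sum(arch == "bimodal"), 30)
  expect_equal(sum(arch == "unimodal"), 30)
  expect_true(all(h$alpha0 <= h$alpha1))
  expect_true(all(h$pi > 0.2 & h$pi < 0.8))
  expect_true(any(h$alpha0 < 0.01))  # the extreme zero-spike archetype
  expect_true(all(h$alpha0[arch == "spike"] <= 0.05))
  expect_error(preset_hyperparams(10, preset = "nope"), "unknown preset")
})

test_that("simulate_bmdd honors depths, dimensions and determinism", {
  cfg <- sim_config(n_samples = 12, n_taxa = 7, depth_range = c(100, 400),
                    seed = 72)
  t1 <- simulate_bmdd(cfg)
  t2 <- simulate_bmdd(cfg)
  expect_identical(t1$table$counts, t2$table$counts)
  expect_equal(dim(t1$table), c(12L, 7L))
  expect_identical(unname(t1$table$depths), as.numeric(t1$requested_depths))
  expect_true(all(t1$requested_depths >= 100 & t1$requested_depths <= 400))
  expect_true(all(t1$delta %in% c(0, 1)))
  expect_equal(unname(rowSums(t1$composition)), rep(1, 12))
  # fixed depth
  cfg2 <- sim_config(n_samples = 4, n_taxa = 5, depth_range = 250, seed = 73)
  expect_true(all(simulate_bmdd(cfg2)$table$depths == 250))
})

test_that("degenerate mode probabilities pin the mode indicators", {
  hyper <- hyperparams(pi = c(1e-9, 1 - 1e-9), alpha0 = c(0.1, 0.1),
                       alpha1 = c(5, 5))
  cfg <- sim_config(n_samples = 50, n_taxa = 2, hyper = hyper,
                    depth_range = 100, seed = 74)
  truth <- simulate_bmdd(cfg)
  expect_true(all(truth$delta[, 1] == 0))
  expect_true(all(truth$delta[, 2] == 1))
})

test_that("bmdd compositions have the conditional Dirichlet mean", {
  hyper <- hyperparams(pi = c(0.5, 0.5), alpha0 = c(0.5, 0.5),
                       alpha1 = c(6, 6))
  cfg <- sim_config(n_samples = 4000, n_taxa = 2, hyper = hyper,
                    depth_range = 50, seed = 75)
  truth <- simulate_bmdd(cfg)
  # conditionally on delta, E[X_1] = shape_1 / (shape_1 + shape_2)
  sh1 <- ifelse(truth$delta[, 1] == 1, 6, 0.5)
  sh2 <- ifelse(truth$delta[, 2] == 1, 6, 0.5)
  grp <- interaction(truth$delta[, 1], truth$delta[, 2])
  emp <- tapply(truth$composition[, 1], grp, mean)
  thy <- tapply(sh1 / (sh1 + sh2), grp, mean)
  expect_true(all(abs(emp - thy) < 0.05))
})

test_that("misspecified settings produce valid tables; copula strength works", {
  for (s in c("gamma", "lognormal", "poisson", "negbin")) {
    cfg <- sim_config(n_samples = 10, n_taxa = 8, setting = s,
                      depth_range = c(200, 500), block_size = 4, seed = 76)
    truth <- simulate_parametric(cfg)
    expect_s3_class(truth$table, "count_table")
    expect_null(truth$delta)
    expect_equal(unname(rowSums(truth$composition)), rep(1, 10))
  }
  # strength 0 leaves taxa uncorrelated; 0.9 induces strong within-block
  # correlation of the latent normals, visible in log abundance
  n <- 2000
  c0 <- sim_config(n_samples = n, n_taxa = 4, setting = "lognormal",
                   correlation = 0, block_size = 2, depth_range = 100,
                   seed = 77)
  c9 <- sim_config(n_samples = n, n_taxa = 4, setting = "lognormal",
                   correlation = 0.9, block_size = 2, depth_range = 100,
                   seed = 77)
  a0 <- log(simulate_parametric(c0)$abs_abundance)
  a9 <- log(simulate_parametric(c9)$abs_abundance)
  expect_lt(abs(cor(a0[, 1], a0[, 2])), 0.08)
  expect_gt(cor(a9[, 1], a9[, 2]), 0.7)
  expect_lt(abs(cor(a9[, 2], a9[, 3])), 0.08)  # across blocks: independent
})

test_that("negbin counts are overdispersed relative to poisson", {
  base <- function(s, size) {
    sim_config(n_samples = 800, n_taxa = 4, setting = s, depth_range = 300,
               correlation = 0, nb_size = size, seed = 78)
  }
  wp <- simulate_parametric(base("poisson", 5))$table$counts
  wn <- simulate_parametric(base("negbin", 0.5))$table$counts
  # identical latent means (same seed, same draws), different count noise
  expect_gt(mean(apply(wn, 2, var) / pmax(apply(wp, 2, var), 1e-9)), 1.5)
})

test_that("spike_signal flags the requested taxa and shifts their abundance", {
  cfg <- sim_config(n_samples = 100, n_taxa = 20, setting = "gamma",
                    diff_fraction = 0.2, depth_range = c(2000, 4000),
                    seed = 79)
  truth <- simulate_parametric(cfg)
  spiked <- spike_signal(truth, cfg)
  expect_equal(sum(spiked$differential), 4)
  expect_equal(sort(unique(spiked$group)), c(0L, 1L))
  expect_equal(sum(spiked$group == 1), 50)
  expect_true(all(abs(spiked$effect_sizes[spiked$differential]) >= log(2) - 1e-9))
  expect_true(all(abs(spiked$effect_sizes[spiked$differential]) <= log(4) + 1e-9))
  expect_true(all(spiked$effect_sizes[!spiked$differential] == 0))
  # the absolute abundance of spiked taxa in group 1 moved by exactly exp(eff)
  j <- which(spiked$differential)[1]
  eff <- spiked$effect_sizes[j]
  g1 <- spiked$group == 1
  expect_equal(spiked$abs_abundance[g1, j],
               truth$abs_abundance[g1, j] * exp(eff), tolerance = 1e-12)
  expect_equal(spiked$abs_abundance[!g1, j], truth$abs_abundance[!g1, j])
  # determinism: the derived spike seed makes the operation reproducible
  expect_identical(spike_signal(truth, cfg)$table$counts,
                   spiked$table$counts)
})

test_that("a zero diff_fraction spike is a flagged no-op", {
  cfg <- sim_config(n_samples = 10, n_taxa = 6, seed = 80)
  truth <- simulate_bmdd(cfg)
  out <- spike_signal(truth, cfg)
  expect_identical(out$table$counts, truth$table$counts)
  expect_false(any(out$differential))
  expect_true(all(out$effect_sizes == 0))
  expect_equal(length(out$group), 10)
})
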