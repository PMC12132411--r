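test_that("all fifteen metrics vanish when the estimate equals the truth", {
  set.seed(91)
  X <- row_normalize(matrix(rgamma(8 * 6, 1), 8, 6))
  rep <- evaluate_all(X, X)
  expect_equal(nrow(rep), 15)
  expect_equal(rep$value, rep(0, 15))
  expect_setequal(unique(rep$category),
                  c("overall", "sample-wise", "taxon-wise"))
  expect_equal(as.vector(table(rep$category)[c("overall", "sample-wise",
                                               "taxon-wise")]),
               c(3L, 6L, 6L))
})

test_that("metrics respect their analytic bounds on random pairs", {
  set.seed(92)
  for (k in 1:20) {
    n <- sample(3:10, 1); m <- sample(3:8, 1)
    E <- row_normalize(matrix(rgamma(n * m, 0.5) + 1e-9, n, m))
    X <- row_normalize(matrix(rgamma(n * m, 0.5) + 1e-9, n, m))
    r <- evaluate_all(E, X)
    v <- setNames(r$value, r$metric)
    expect_true(all(v >= 0))
    expect_lte(v["mse"], 1)
    expect_lte(v["bray_curtis"], 1)
    expect_lte(v["js"], 1)
    expect_lte(v["hellinger"], 1)
    expect_lte(v["ks"], 1)
    expect_lte(v["gini"], 1)
    expect_lte(v["simpson"], 1)
    expect_lte(v["correlation"], 2)
    expect_true(all(is.finite(v)))
  }
})

test_that("hand-computable cases give the expected metric values", {
  E <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  X <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
  r <- evaluate_all(E, X)
  v <- setNames(r$value, r$metric)
  expect_equal(unname(v["bray_curtis"]), 1)      # disjoint support
  expect_equal(unname(v["hellinger"]), 1)
  expect_equal(unname(v["mse"]), 1)
  expect_equal(unname(v["sample_distance"]), sqrt(2))
  expect_equal(unname(v["js"]), 1, tolerance = 1e-6)

  # Shannon entropy difference: uniform on 4 vs point mass
  U <- matrix(rep(0.25, 4), 1, 4)
  P <- matrix(c(1, 0, 0, 0), 1, 4)
  r2 <- evaluate_all(rbind(U, U), rbind(P, P))
  v2 <- setNames(r2$value, r2$metric)
  expect_equal(unname(v2["shannon"]), log(4), tolerance = 1e-9)
  expect_equal(unname(v2["simpson"]), 0.75)
})

test_that("sample-symmetric metrics are symmetric and kl uses truth as reference", {
  set.seed(93)
  E <- row_normalize(matrix(rgamma(6 * 5, 1) + 0.01, 6, 5))
  X <- row_normalize(matrix(rgamma(6 * 5, 1) + 0.01, 6, 5))
  a <- setNames(evaluate_all(E, X)$value, evaluate_all(E, X)$metric)
  b <- setNames(evaluate_all(X, E)$value, evaluate_all(X, E)$metric)
  for (mname in c("mse", "sample_distance", "taxon_distance", "bray_curtis",
                  "js", "hellinger", "ks", "wasserstein", "correlation")) {
    expect_equal(unname(a[mname]), unname(b[mname]), tolerance = 1e-12)
  }
  # kl is directed, so swapping the arguments changes it in general
  expect_false(isTRUE(all.equal(unname(a["kl"]), unname(b["kl"]))))
})

test_that("metrics grow monotonically with perturbation size", {
  set.seed(94)
  X <- row_normalize(matrix(rgamma(10 * 6, 2) + 0.05, 10, 6))
  perturb <- function(eps) {
    row_normalize(X * exp(matrix(eps * seq(-1, 1, length.out = 60), 10, 6)))
  }
  small <- setNames(evaluate_all(perturb(0.1), X)$value,
                    evaluate_all(perturb(0.1), X)$metric)
  large <- setNames(evaluate_all(perturb(0.8), X)$value,
                    evaluate_all(perturb(0.8), X)$metric)
  for (mname in c("mse", "sample_distance", "bray_curtis", "kl", "js",
                  "hellinger", "wasserstein")) {
    expect_gt(unname(large[mname]), unname(small[mname]))
  }
})

test_that("naive_impute variants implement the documented formulas", {
  ct <- count_table(matrix(c(0L, 1L,
                             3L, 1L), 2, 2, byrow = TRUE),
                    sample_ids = c("a", "b"))
  # variant 1: raw proportions
  expect_equal(unname(unclass(naive_impute(ct, 1))),
               matrix(c(0, 1, 0.75, 0.25), 2, 2, byrow = TRUE))
  # variant 2: +1 pseudocount; row a becomes (1, 2) / 3
  expect_equal(unname(unclass(naive_impute(ct, 2))),
               matrix(c(1 / 3, 2 / 3, 4 / 6, 2 / 6), 2, 2, byrow = TRUE))
  # variant 3: zeros -> 0.5 then renormalize; row a becomes (0.5, 1) / 1.5
  expect_equal(unname(unclass(naive_impute(ct, 3))),
               matrix(c(1 / 3, 2 / 3, 0.75, 0.25), 2, 2, byrow = TRUE))
  expect_error(naive_impute(ct, 5), "variant")
})

test_that("naive variant 4 scales zero cells by relative depth", {
  W <- matrix(c(0L, 10L,
                0L, 40L,
                5L, 5L), 3, 2, byrow = TRUE)
  ct <- count_table(W)
  v4 <- naive_impute(ct, 4)
  # taxon 1 is zero in samples 1 (depth 10) and 2 (depth 40): the imputed
  # raw values are 10/40 and 40/40 before renormalization
  expect_equal(unname(unclass(v4)[1, ]), c(0.25, 10) / 10.25)
  expect_equal(unname(unclass(v4)[2, ]), c(1, 40) / 41)
  expect_equal(unname(unclass(v4)[3, ]), c(0.5, 0.5))
})
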