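# Shared helpers for the test suite: small random problem instances and
# slow, independent re-implementations of the core quantities used as
# oracles. The oracles deliberately use naive loops and textbook formulas so
# that agreement with the fast vectorized package code is meaningful.

random_hyper <- function(m) {
  hyperparams(
    pi = runif(m, 0.2, 0.8),
    alpha0 = exp(runif(m, log(0.05), log(0.5))),
    alpha1 = exp(runif(m, log(1), log(8)))
  )
}

random_instance <- function(n = 5, m = 4, depth = c(50, 300), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hyper <- random_hyper(m)
  cfg <- sim_config(n_samples = n, n_taxa = m, hyper = hyper,
                    depth_range = depth, seed = sample.int(1e6, 1))
  truth <- simulate_bmdd(cfg)
  list(truth = truth, table = truth$table, hyper = hyper)
}

random_state <- function(n, m, hyper) {
  gamma <- matrix(runif(n * m), n, m)
  beta <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      beta[i, j] <- gamma[i, j] * hyper$alpha1[j] +
        (1 - gamma[i, j]) * hyper$alpha0[j]
    }
  }
  list(beta = beta, gamma = gamma)
}

# loop-based reference for the per-entry mode log-weights: recomputes
# h(delta) from the written-out formula, independent of compute_h()'s code
reference_h <- function(beta_row, gamma_row, hyper, j) {
  m <- length(beta_row)
  s <- 0
  for (k in seq_len(m)) {
    if (k == j) next
    s <- s + gamma_row[k] * hyper$alpha1[k] +
      (1 - gamma_row[k]) * hyper$alpha0[k]
  }
  tj <- digamma(beta_row[j]) - digamma(sum(beta_row))
  hd <- function(a) lgamma(a + s) + (a - 1) * tj - lgamma(a)
  c(h0 = hd(hyper$alpha0[j]), h1 = hd(hyper$alpha1[j]))
}

# slow fixed-point iteration for the variational factors, entry by entry,
# used as an oracle for e_step() on tiny problems
reference_e_step <- function(table, state, hyper, iters = 2000, tol = 1e-13) {
  W <- table$counts
  n <- nrow(W)
  m <- ncol(W)
  gamma <- state$gamma
  for (t in seq_len(iters)) {
    beta <- matrix(0, n, m)
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        beta[i, j] <- W[i, j] + gamma[i, j] * hyper$alpha1[j] +
          (1 - gamma[i, j]) * hyper$alpha0[j]
      }
    }
    delta <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        h <- reference_h(beta[i, ], gamma[i, ], hyper, j)
        lo <- log(hyper$pi[j]) - log1p(-hyper$pi[j]) + h["h1"] - h["h0"]
        g <- plogis(unname(lo))
        delta <- max(delta, abs(g - gamma[i, j]))
        gamma[i, j] <- g
      }
    }
    if (delta < tol) break
  }
  beta <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      beta[i, j] <- W[i, j] + gamma[i, j] * hyper$alpha1[j] +
        (1 - gamma[i, j]) * hyper$alpha0[j]
    }
  }
  list(beta = beta, gamma = gamma)
}

# central finite-difference gradient of a scalar function
fd_gradient <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(k) {
    xp <- x; xp[k] <- xp[k] + eps
    xm <- x; xm[k] <- xm[k] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

small_count_table <- function() {
  count_table(matrix(c(5L, 0L, 2L,
                       1L, 3L, 0L,
                       0L, 2L, 4L,
                       2L, 2L, 2L), 4, 3, byrow = TRUE))
}
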