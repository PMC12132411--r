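# Core model: bimodal-Dirichlet-multinomial hierarchy fitted by
# coordinate-ascent mean-field variational EM.
#
# Model, per sample i and taxon j:
#   delta_ij ~ Bernoulli(pi_j)
#   theta_ij = alpha1_j if delta_ij = 1 else alpha0_j
#   X_i      ~ Dirichlet(theta_i1, ..., theta_im)
#   W_i      ~ Multinomial(N_i, X_i)
# Variational family: X_i ~ Dirichlet(beta_i) x delta_ij ~ Bernoulli(gamma_ij),
# fully factorized over samples and taxa.

# mixture-averaged shape: abar_ij = gamma_ij * alpha1_j + (1 - gamma_ij) * alpha0_j
abar_matrix <- function(gamma, alpha0, alpha1) {
  n <- nrow(gamma)
  gamma * rep(alpha1 - alpha0, each = n) + rep(alpha0, each = n)
}

# x * v[col] and x + v[col] with column-vector recycling (avoids sweep())
col_scale <- function(x, v) x * rep(v, each = nrow(x))

# E[log X_ij] under Dirichlet(beta_i)
elog_x <- function(beta) {
  digamma(beta) - digamma(rowSums(beta))
}

#' Initialize hyperparameters and variational state
#'
#' Deterministic, data-driven starting values for [bmdd_fit()]. The
#' responsibilities `gamma` come from a per-taxon two-group split of
#' log relative abundance (pseudocount 0.5): entries above the taxon's median
#' nonzero value start at 0.8, the rest at 0.2. The Dirichlet shapes come from
#' a method-of-moments fit to the pseudocount compositions, scaled down
#' (x 0.1) for the low mode and up (x 2) for the high mode; `pi` starts at
#' the column means of the initial `gamma`.
#'
#' @param table A [count_table()].
#' @param control A [bmdd_control()] list (supplies the clamps).
#' @return A list with elements `hyperparams` ([hyperparams()]) and `state`
#'   (list with matrices `beta`, `gamma`).
#' @export
init_params <- function(table, control = bmdd_control()) {
  assert_count_table(table)
  W <- table$counts
  n <- nrow(W)
  m <- ncol(W)
  if (m < 2) stop("a composition needs at least 2 taxa", call. = FALSE)

  P <- row_normalize(W + 0.5)
  L <- log(P)

  gamma <- matrix(0.2, n, m)
  for (j in seq_len(m)) {
    nz <- W[, j] > 0
    if (any(nz)) {
      med <- stats::median(L[nz, j])
      gamma[L[, j] > med, j] <- 0.8
    }
  }

  # method-of-moments Dirichlet precision from the pseudocount compositions
  mj <- colMeans(P)
  vj <- apply(P, 2, stats::var)
  ok <- vj > 0 & mj > 0 & mj < 1
  s_j <- (mj[ok] * (1 - mj[ok]) / vj[ok]) - 1
  s_j <- s_j[is.finite(s_j) & s_j > 0]
  s <- if (length(s_j)) stats::median(s_j) else 1
  ahat <- pmax(mj * s, 1e-3)

  clamp_a <- function(a) pmin(pmax(a, control$alpha_min), control$alpha_max)
  alpha0 <- clamp_a(0.1 * ahat)
  alpha1 <- clamp_a(2 * ahat)
  pi <- pmin(pmax(colMeans(gamma), control$pi_clamp), 1 - control$pi_clamp)

  hyper <- hyperparams(pi, alpha0, alpha1, taxon_ids = table$taxon_ids)
  beta <- update_beta(table, gamma, hyper)
  list(hyperparams = hyper, state = list(beta = beta, gamma = gamma))
}

#' Closed-form update of the Dirichlet variational parameters
#'
#' The optimal Dirichlet factor for sample `i` has shape
#' `beta_ij = W_ij + gamma_ij * alpha1_j + (1 - gamma_ij) * alpha0_j`.
#'
#' @param table A [count_table()].
#' @param gamma An `n x m` matrix of responsibilities in `[0, 1]`.
#' @param hyper A [hyperparams()] object.
#' @return The `n x m` matrix `beta` (strictly positive).
#' @export
update_beta <- function(table, gamma, hyper) {
  assert_count_table(table)
  W <- table$counts
  assert_hyperparams(hyper, ncol(W))
  if (!is.matrix(gamma) || any(dim(gamma) != dim(W))) {
    stop("gamma must be a matrix with the same shape as the counts", call. = FALSE)
  }
  if (anyNA(gamma) || any(gamma < 0) || any(gamma > 1)) {
    stop("gamma entries must lie in [0, 1]", call. = FALSE)
  }
  W + abar_matrix(gamma, hyper$alpha0, hyper$alpha1)
}

#' Per-entry variational log-weights of the two prior modes
#'
#' For a single sample row and taxon `j`, evaluates the (Jensen-surrogate)
#' log-weight `h(delta)` of assigning taxon `j` to the low (`delta = 0`) or
#' high (`delta = 1`) mode:
#' `h(delta) = lgamma(alpha_{j,delta} + s) +
#'   (alpha_{j,delta} - 1) * (digamma(beta_j) - digamma(sum(beta))) -
#'   lgamma(alpha_{j,delta})`,
#' where `s` is the sum over the other taxa of their mixture-averaged shapes.
#' The expectation of the log-gamma of the summed shape, which has no closed
#' form, is replaced by its Jensen lower bound (log-gamma is convex).
#'
#' @param beta_row Positive numeric vector: the sample's Dirichlet parameters.
#' @param gamma_row Responsibilities of the same sample, in `[0, 1]`.
#' @param hyper A [hyperparams()] object.
#' @param j Taxon index.
#' @return Named numeric vector `c(h0 = ..., h1 = ...)`.
#' @export
compute_h <- function(beta_row, gamma_row, hyper, j) {
  m <- length(beta_row)
  assert_hyperparams(hyper, m)
  if (any(beta_row <= 0) || anyNA(beta_row)) {
    stop("beta entries must be strictly positive", call. = FALSE)
  }
  if (length(gamma_row) != m || any(gamma_row < 0) || any(gamma_row > 1)) {
    stop("gamma_row must lie in [0, 1] and match beta_row in length", call. = FALSE)
  }
  if (j < 1 || j > m) stop("taxon index out of range", call. = FALSE)
  abar <- gamma_row * hyper$alpha1 + (1 - gamma_row) * hyper$alpha0
  s <- sum(abar[-j])
  tj <- digamma(beta_row[j]) - digamma(sum(beta_row))
  h <- function(a) lgamma(a + s) + (a - 1) * tj - lgamma(a)
  c(h0 = h(hyper$alpha0[j]), h1 = h(hyper$alpha1[j]))
}

# Vectorized coordinate-ascent sweeps of gamma over taxa, beta held fixed.
# Rows (samples) are mutually independent; each sweep visits taxa in order
# and updates all samples at once.
gamma_sweeps <- function(W, beta, gamma, hyper, inner_tol, max_sweeps) {
  m <- ncol(W)
  a0 <- hyper$alpha0
  a1 <- hyper$alpha1
  pi <- hyper$pi
  d_a <- a1 - a0
  lg1 <- lgamma(a1)
  lg0 <- lgamma(a0)
  lpi <- log(pi) - log1p(-pi)          # logit in log-space
  Tm <- elog_x(beta)
  abar <- abar_matrix(gamma, a0, a1)
  S <- rowSums(abar)
  converged <- FALSE
  for (sweep_i in seq_len(max_sweeps)) {
    gmax <- 0
    for (j in seq_len(m)) {
      s <- S - abar[, j]
      dh <- lgamma(a1[j] + s) - lgamma(a0[j] + s) + d_a[j] * Tm[, j] -
        lg1[j] + lg0[j]
      gnew <- stats::plogis(lpi[j] + dh)
      # tie-break: identical mode weights leave gamma at the prior exactly
      ties <- dh == 0
      if (any(ties)) gnew[ties] <- pi[j]
      ch <- gnew - gamma[, j]
      mx <- max(abs(ch))
      if (mx > gmax) gmax <- mx
      S <- S + ch * d_a[j]
      abar[, j] <- abar[, j] + ch * d_a[j]
      gamma[, j] <- gnew
    }
    if (gmax < inner_tol) {
      converged <- TRUE
      break
    }
  }
  attr(gamma, "converged") <- converged
  gamma
}

#' Coordinate-ascent update of the mode responsibilities
#'
#' Sweeps over taxa, updating `gamma_ij` for all samples at once via the
#' numerically stable logistic of `logit(pi_j) + h1 - h0` (see [compute_h()]),
#' with `beta` held fixed, until the largest elementwise change falls below
#' `inner_tol` or `max_sweeps` is reached.
#'
#' @param table A [count_table()].
#' @param state List with matrices `beta` (positive) and `gamma` (in `[0,1]`).
#' @param hyper A [hyperparams()] object.
#' @param inner_tol,max_sweeps Inner convergence controls.
#' @return The updated `gamma` matrix.
#' @export
update_gamma <- function(table, state, hyper, inner_tol = 1e-6,
                         max_sweeps = 50L) {
  assert_count_table(table)
  W <- table$counts
  assert_hyperparams(hyper, ncol(W))
  if (any(state$beta <= 0)) stop("beta entries must be strictly positive", call. = FALSE)
  g <- gamma_sweeps(W, state$beta, state$gamma, hyper, inner_tol, max_sweeps)
  attr(g, "converged") <- NULL
  g
}

#' One E-step: jointly converge the variational factors
#'
#' Alternates the closed-form `beta` update with single `gamma` sweeps until
#' the responsibilities stabilize, then refreshes `beta` once more so the
#' coupling `beta = W + gamma * alpha1 + (1 - gamma) * alpha0` holds exactly
#' on return.
#'
#' The `gamma` update maximizes a per-coordinate Jensen bound rather than the
#' global surrogate objective, so an individual sweep can, rarely, lower the
#' surrogate ELBO slightly. With `guard = TRUE` (the default) each sweep is
#' accepted only if it does not decrease the surrogate ELBO; a rejected sweep
#' ends the E-step at the previous state, making the E-step monotone in the
#' surrogate objective. `guard = FALSE` skips the per-sweep evaluations (the
#' fitting loop in [bmdd_fit()] uses the fast path and falls back to a
#' guarded E-step only when its recorded trace would decrease).
#'
#' @inheritParams update_gamma
#' @param guard Logical; reject surrogate-ELBO-decreasing sweeps (see
#'   Details).
#' @return A list with the converged `beta` and `gamma`.
#' @export
e_step <- function(table, state, hyper, inner_tol = 1e-6, max_sweeps = 50L,
                   guard = TRUE) {
  assert_count_table(table)
  W <- table$counts
  assert_hyperparams(hyper, ncol(W))
  gamma <- state$gamma
  mult_const <- if (guard) {
    sum(lgamma(table$depths + 1)) - sum(lgamma(W + 1))
  } else {
    NA_real_
  }
  el_cur <- if (guard) {
    elbo_core(W, update_beta(table, gamma, hyper), gamma, hyper, mult_const)
  } else {
    NA_real_
  }
  converged <- FALSE
  for (it in seq_len(max_sweeps)) {
    beta <- update_beta(table, gamma, hyper)
    gnew <- gamma_sweeps(W, beta, gamma, hyper, inner_tol, max_sweeps = 1L)
    attr(gnew, "converged") <- NULL
    if (guard) {
      el_new <- elbo_core(W, update_beta(table, gnew, hyper), gnew, hyper,
                          mult_const)
      if (el_new < el_cur) {
        converged <- TRUE  # stop at the previous (non-inferior) state
        break
      }
      el_cur <- el_new
    }
    delta <- max(abs(gnew - gamma))
    gamma <- gnew
    if (delta < inner_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("E-step did not reach inner tolerance within max_sweeps; ",
            "returning the last state", call. = FALSE)
  }
  beta <- update_beta(table, gamma, hyper)
  list(beta = beta, gamma = gamma)
}

#' Closed-form update of the mixture probabilities
#'
#' `pi_j` is the column mean of the responsibilities, clamped away from the
#' boundary.
#'
#' @param gamma Responsibility matrix in `[0, 1]`.
#' @param pi_clamp Clamp width; result lies in `[pi_clamp, 1 - pi_clamp]`.
#' @return Numeric vector `pi`.
#' @export
update_pi <- function(gamma, pi_clamp = 1e-4) {
  if (anyNA(gamma) || any(gamma < 0) || any(gamma > 1)) {
    stop("gamma entries must lie in [0, 1]", call. = FALSE)
  }
  pmin(pmax(colMeans(gamma), pi_clamp), 1 - pi_clamp)
}

#' M-step objective for the Dirichlet shapes, with analytic gradient
#'
#' The expected complete-data log prior of the compositions under the
#' variational posterior (Jensen surrogate for the log-gamma of the summed
#' shape), as a function of the 2m shape parameters:
#' `F = sum_i lgamma(sum_j abar_ij) + sum_ij (abar_ij - 1) Elog X_ij -
#'  sum_ij [gamma_ij lgamma(alpha1_j) + (1 - gamma_ij) lgamma(alpha0_j)]`
#' with `abar_ij = gamma_ij alpha1_j + (1 - gamma_ij) alpha0_j`.
#'
#' @param alpha0,alpha1 Positive shape vectors of length `m`.
#' @param beta Positive `n x m` matrix of Dirichlet variational parameters.
#' @param gamma Responsibility matrix in `[0, 1]`.
#' @return List with `value` (scalar) and `gradient` (length-`2m` vector,
#'   alpha0 derivatives first, then alpha1).
#' @export
alpha_objective <- function(alpha0, alpha1, beta, gamma) {
  if (any(alpha0 <= 0) || any(alpha1 <= 0)) {
    stop("shape parameters must be strictly positive", call. = FALSE)
  }
  alpha_objective_cached(alpha0, alpha1, elog_x(beta), gamma)
}

# beta enters only through E[log X]; the optimizer loop precomputes it once
alpha_objective_cached <- function(alpha0, alpha1, Tm, gamma) {
  abar <- abar_matrix(gamma, alpha0, alpha1)
  Srow <- rowSums(abar)
  lg_term <- col_scale(gamma, lgamma(alpha1)) +
    col_scale(1 - gamma, lgamma(alpha0))
  value <- sum(lgamma(Srow)) + sum((abar - 1) * Tm) - sum(lg_term)
  psi_S <- digamma(Srow)
  inner <- psi_S + Tm                       # recycles psi_S down columns
  g1 <- colSums(gamma * inner) - colSums(gamma) * digamma(alpha1)
  g0 <- colSums((1 - gamma) * inner) - colSums(1 - gamma) * digamma(alpha0)
  list(value = value, gradient = c(g0, g1))
}

#' One M-step: update the hyperparameters
#'
#' `pi` is updated in closed form ([update_pi()]); the shapes are updated by
#' box-constrained quasi-Newton maximization of [alpha_objective()]
#' (`nlminb` with the analytic gradient), warm-started at the current values.
#' If the optimizer fails or worsens the objective, the previous shapes are
#' kept. The labeling convention `alpha0 <= alpha1` is then restored by
#' swapping offending taxa, with the likelihood-invariant relabeling
#' `gamma -> 1 - gamma`, `pi -> 1 - pi`.
#'
#' @param state List with matrices `beta` and `gamma`.
#' @param hyper Current [hyperparams()].
#' @param control A [bmdd_control()] list.
#' @return List with the new `hyperparams` and the (possibly relabeled)
#'   `gamma` matrix.
#' @export
m_step <- function(state, hyper, control = bmdd_control()) {
  gamma <- state$gamma
  beta <- state$beta
  m <- ncol(gamma)
  pi_new <- update_pi(gamma, control$pi_clamp)

  clamp_a <- function(a) pmin(pmax(a, control$alpha_min), control$alpha_max)
  start <- clamp_a(c(hyper$alpha0, hyper$alpha1))

  # The objective only touches the data through a handful of contractions of
  # gamma and E[log X]; precomputing them reduces every optimizer evaluation
  # to O(n + m) plus one BLAS matrix-vector product (for lgamma(Srow)).
  Tm <- elog_x(beta)
  n <- nrow(gamma)
  cg <- colSums(gamma)                 # sum_i gamma_ij
  GT <- colSums(gamma * Tm)            # sum_i gamma_ij Tm_ij
  CT <- colSums(Tm)                    # sum_i Tm_ij
  sTm <- sum(CT)
  cache_par <- NULL
  cache_val <- NULL
  eval_at <- function(par) {
    if (!is.null(cache_par) && identical(par, cache_par)) return(cache_val)
    a0 <- par[seq_len(m)]
    a1 <- par[m + seq_len(m)]
    d_a <- a1 - a0
    Srow <- as.vector(gamma %*% d_a) + sum(a0)
    value <- sum(lgamma(Srow)) +
      sum(d_a * GT) + sum(a0 * CT) - sTm -
      sum(cg * lgamma(a1) + (n - cg) * lgamma(a0))
    psi_S <- digamma(Srow)
    gpsi <- as.vector(crossprod(gamma, psi_S))
    g1 <- gpsi + GT - cg * digamma(a1)
    g0 <- (sum(psi_S) - gpsi) + (CT - GT) - (n - cg) * digamma(a0)
    cache_par <<- par
    cache_val <<- list(value = value, gradient = c(g0, g1))
    cache_val
  }
  negobj <- function(par) -eval_at(par)$value
  neggrad <- function(par) -eval_at(par)$gradient
  f_start <- negobj(start)
  opt <- tryCatch(
    stats::nlminb(start, negobj, gradient = neggrad,
                  lower = control$alpha_min, upper = control$alpha_max,
                  control = list(iter.max = 300L, eval.max = 400L)),
    error = function(e) NULL
  )
  if (is.null(opt) || !is.finite(opt$objective) || opt$objective > f_start + 1e-8) {
    if (is.null(opt)) {
      warning("shape optimizer failed; keeping previous alpha values",
              call. = FALSE)
    }
    a0 <- hyper$alpha0
    a1 <- hyper$alpha1
  } else {
    a0 <- opt$par[seq_len(m)]
    a1 <- opt$par[m + seq_len(m)]
  }

  swap <- a0 > a1
  if (any(swap)) {
    tmp <- a0[swap]
    a0[swap] <- a1[swap]
    a1[swap] <- tmp
    pi_new[swap] <- 1 - pi_new[swap]
    gamma[, swap] <- 1 - gamma[, swap]
  }
  list(hyperparams = hyperparams(pi_new, a0, a1, taxon_ids = hyper$taxon_ids),
       gamma = gamma)
}

#' Surrogate evidence lower bound
#'
#' The mean-field ELBO with the intractable expectation of the log-gamma of
#' the summed shape replaced by its Jensen lower bound
#' `lgamma(sum_j abar_ij)`. The returned value therefore lower-bounds the
#' exact log marginal likelihood `log p(W | pi, alpha)`.
#'
#' @param table A [count_table()].
#' @param state List with matrices `beta` and `gamma`.
#' @param hyper A [hyperparams()] object.
#' @return A finite scalar.
#' @export
elbo_surrogate <- function(table, state, hyper) {
  assert_count_table(table)
  W <- table$counts
  assert_hyperparams(hyper, ncol(W))
  mult_const <- sum(lgamma(table$depths + 1)) - sum(lgamma(W + 1))
  elbo_core(W, state$beta, state$gamma, hyper, mult_const)
}

# elbo with the count-only multinomial constant precomputed (it is reused
# across the guarded E-step sweeps)
elbo_core <- function(W, beta, gamma, hyper, mult_const) {
  Tm <- elog_x(beta)
  abar <- abar_matrix(gamma, hyper$alpha0, hyper$alpha1)
  Srow <- rowSums(abar)
  cg <- colSums(gamma)
  n <- nrow(gamma)

  ll_mult <- mult_const + sum(W * Tm)
  e_prior_x <- sum(lgamma(Srow)) + sum((abar - 1) * Tm) -
    sum(cg * lgamma(hyper$alpha1) + (n - cg) * lgamma(hyper$alpha0))
  e_prior_d <- sum(cg * log(hyper$pi) + (n - cg) * log1p(-hyper$pi))
  e_log_g <- sum(lgamma(rowSums(beta))) - sum(lgamma(beta)) +
    sum((beta - 1) * Tm)
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  e_log_q <- sum(xlx(gamma) + xlx(1 - gamma))

  ll_mult + e_prior_x + e_prior_d - e_log_g - e_log_q
}

#' Fit the bimodal Dirichlet model by variational EM
#'
#' Alternates E-steps ([e_step()]: coordinate ascent on the variational
#' factors) and M-steps ([m_step()]: closed-form `pi`, quasi-Newton shapes)
#' until the relative change of the surrogate ELBO falls below
#' `control$tol` or `control$max_iter` iterations. The whole procedure is
#' deterministic: initialization is data-driven and no randomness is used.
#'
#' @param table A [count_table()] with at least 2 samples and 2 taxa.
#' @param control A [bmdd_control()] list.
#' @return An object of class `bmdd_fit`: list with `hyperparams`, `state`
#'   (`beta`, `gamma`), `elbo_trace` (one surrogate-ELBO value per EM
#'   iteration, recorded after the E-step), `n_iter`, `converged`,
#'   `sample_ids`, `taxon_ids` and, when `control$keep_trace`, `trace_hyper`
#'   (the hyperparameters in force at each recorded value).
#' @examples
#' truth <- simulate_bmdd(sim_config(n_samples = 30, n_taxa = 8, seed = 1))
#' fit <- bmdd_fit(truth$table, bmdd_control(max_iter = 20))
#' fit
#' @export
bmdd_fit <- function(table, control = bmdd_control()) {
  assert_count_table(table)
  W <- table$counts
  if (nrow(W) < 2) {
    stop("at least 2 samples are required to fit the model", call. = FALSE)
  }
  if (ncol(W) < 2) stop("a composition needs at least 2 taxa", call. = FALSE)
  zero_taxa <- colSums(W) == 0
  if (any(zero_taxa)) {
    message("note: ", sum(zero_taxa),
            " taxa have no reads in any sample; their imputed abundance is ",
            "prior-driven")
  }

  ini <- init_params(table, control)
  hyper <- ini$hyperparams
  state <- ini$state

  elbo_trace <- numeric(0)
  trace_hyper <- if (control$keep_trace) list() else NULL
  elbo_prev <- NA_real_
  converged <- FALSE
  it <- 0L

  for (it in seq_len(control$max_iter)) {
    state_in <- state
    state <- suppressWarnings(
      e_step(table, state, hyper, control$inner_tol, control$max_sweeps,
             guard = FALSE)
    )
    el <- elbo_surrogate(table, state, hyper)
    if (!is.na(elbo_prev) && el < elbo_prev) {
      # rare: the fast gamma sweeps overshot the surrogate objective;
      # redo this E-step with per-sweep guarding, which cannot decrease it
      state <- suppressWarnings(
        e_step(table, state_in, hyper, control$inner_tol,
               control$max_sweeps, guard = TRUE)
      )
      el <- elbo_surrogate(table, state, hyper)
    }
    elbo_trace <- c(elbo_trace, el)
    if (control$keep_trace) trace_hyper[[it]] <- hyper
    if (control$verbose) {
      message(sprintf("iter %3d: surrogate ELBO = %.8g", it, el))
    }
    if (!is.na(elbo_prev) &&
        abs(el - elbo_prev) < control$tol * max(1, abs(elbo_prev))) {
      converged <- TRUE
      break
    }
    elbo_prev <- el
    if (it == control$max_iter) break
    ms <- m_step(state, hyper, control)
    hyper <- ms$hyperparams
    state$gamma <- ms$gamma
    state$beta <- update_beta(table, state$gamma, hyper)
  }

  structure(
    list(hyperparams = hyper, state = state, elbo_trace = elbo_trace,
         n_iter = it, converged = converged,
         sample_ids = table$sample_ids, taxon_ids = table$taxon_ids,
         control = control, trace_hyper = trace_hyper),
    class = "bmdd_fit"
  )
}

#' @export
print.bmdd_fit <- function(x, ...) {
  cat(sprintf("bmdd_fit: %d samples x %d taxa\n",
              nrow(x$state$beta), ncol(x$state$beta)))
  cat(sprintf("  %d EM iterations (%s); final surrogate ELBO %.6g\n",
              x$n_iter, if (x$converged) "converged" else "not converged",
              x$elbo_trace[length(x$elbo_trace)]))
  invisible(x)
}
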