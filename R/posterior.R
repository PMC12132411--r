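# Posterior-based imputation: the fitted variational posterior over each
# sample's composition is Dirichlet(beta_i); its mean is the single
# imputation, and independent draws provide multiple imputations.

get_beta <- function(x) {
  if (inherits(x, "bmdd_fit")) return(x$state$beta)
  if (is.list(x) && is.matrix(x$beta)) return(x$beta)
  stop("expected a 'bmdd_fit' object or a state list with a 'beta' matrix",
       call. = FALSE)
}

get_axis_ids <- function(x) {
  if (inherits(x, "bmdd_fit")) return(list(x$sample_ids, x$taxon_ids))
  b <- get_beta(x)
  list(rownames(b), colnames(b))
}

#' Posterior-mean composition (single imputation)
#'
#' The mean of the variational Dirichlet posterior:
#' `Xhat_ij = beta_ij / sum_k beta_ik`. Entries are strictly positive, so the
#' result can be log-transformed directly.
#'
#' @param x A `bmdd_fit` object, or a state list with a `beta` matrix.
#' @return A [composition()] matrix.
#' @examples
#' posterior_mean(list(beta = matrix(c(2, 1, 3, 1, 5, 8), 2, 3)))
#' @export
posterior_mean <- function(x) {
  beta <- get_beta(x)
  if (any(beta <= 0)) stop("beta entries must be strictly positive", call. = FALSE)
  ids <- get_axis_ids(x)
  composition(row_normalize(beta), sample_ids = ids[[1]], taxon_ids = ids[[2]])
}

#' Posterior samples of the composition (multiple imputation)
#'
#' Draws `n_draws` independent composition matrices, each row sampled from
#' the fitted Dirichlet posterior `Dirichlet(beta_i)` (via normalized gamma
#' variates). The empirical mean over draws converges to [posterior_mean()].
#'
#' @param x A `bmdd_fit` object, or a state list with a `beta` matrix.
#' @param n_draws Number of posterior draws (>= 1).
#' @param seed Optional integer seed; the caller's RNG state is restored on
#'   exit, and identical seeds give identical draws.
#' @return A list of `n_draws` [composition()] matrices.
#' @export
posterior_sample <- function(x, n_draws, seed = NULL) {
  beta <- get_beta(x)
  if (any(beta <= 0)) stop("beta entries must be strictly positive", call. = FALSE)
  n_draws <- as.integer(n_draws)
  if (is.na(n_draws) || n_draws < 1) {
    stop("n_draws must be a positive integer", call. = FALSE)
  }
  ids <- get_axis_ids(x)
  n <- nrow(beta)
  m <- ncol(beta)
  with_seed(seed, lapply(seq_len(n_draws), function(d) {
    g <- matrix(stats::rgamma(n * m, shape = beta, rate = 1), n, m)
    rs <- rowSums(g)
    if (any(rs <= 0)) {
      # can only happen when every shape in a row underflows; resample those
      bad <- which(rs <= 0)
      for (i in bad) {
        while (sum(g[i, ]) <= 0) {
          g[i, ] <- stats::rgamma(m, shape = beta[i, ], rate = 1)
        }
      }
    }
    composition(row_normalize(g), sample_ids = ids[[1]], taxon_ids = ids[[2]])
  }))
}

# evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards; `seed = NULL` evaluates unchanged
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Exact posterior mean by mode enumeration (validation oracle)
#'
#' For a single sample, the posterior over the composition is an explicit
#' mixture over the `2^m` mode configurations `delta`, each contributing a
#' conjugate Dirichlet posterior. This routine enumerates all configurations
#' (log-space weight accumulation) and returns the exact posterior mean.
#' Intended for validating the variational approximation on small problems.
#'
#' @param counts_row Nonnegative integer vector of length `m <= 15`.
#' @param hyper A [hyperparams()] object for the same `m` taxa.
#' @return Numeric vector: the exact posterior mean composition.
#' @export
exact_posterior_mean <- function(counts_row, hyper) {
  ew <- enumerate_modes(counts_row, hyper)
  w <- exp(ew$logw - max(ew$logw))
  w <- w / sum(w)
  N <- sum(counts_row)
  Wm <- matrix(counts_row, nrow(ew$A), length(counts_row), byrow = TRUE)
  colSums(w * (ew$A + Wm) / (N + ew$rowsA))
}

#' Exact log marginal likelihood by mode enumeration
#'
#' Enumerates the `2^m` mode configurations to evaluate
#' `log p(W | pi, alpha)` exactly; rows (samples) are independent so a whole
#' table's log marginal is the sum over rows. Used to verify that the
#' surrogate ELBO is a true lower bound.
#'
#' @param x A [count_table()] or a single nonnegative integer count vector.
#' @param hyper A [hyperparams()] object (`m <= 15` taxa).
#' @return Scalar log marginal likelihood.
#' @export
exact_log_marginal <- function(x, hyper) {
  if (is_count_table(x)) {
    return(sum(apply(x$counts, 1, exact_log_marginal, hyper = hyper)))
  }
  counts_row <- x
  ew <- enumerate_modes(counts_row, hyper)
  mx <- max(ew$logw)
  N <- sum(counts_row)
  mx + log(sum(exp(ew$logw - mx))) +
    lgamma(N + 1) - sum(lgamma(counts_row + 1))
}

# shared enumeration: per configuration, the shape vector A and the
# log posterior weight (prior mass x Dirichlet-multinomial likelihood,
# multinomial coefficient omitted as it is configuration-independent)
enumerate_modes <- function(counts_row, hyper) {
  m <- length(counts_row)
  assert_hyperparams(hyper, m)
  if (m > 15) {
    stop("exact enumeration is limited to m <= 15 taxa (2^m configurations)",
         call. = FALSE)
  }
  if (any(counts_row < 0) || anyNA(counts_row)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  N <- sum(counts_row)
  D <- as.matrix(expand.grid(rep(list(c(0, 1)), m), KEEP.OUT.ATTRS = FALSE))
  dimnames(D) <- NULL
  A <- sweep(D, 2, hyper$alpha1, "*") + sweep(1 - D, 2, hyper$alpha0, "*")
  rowsA <- rowSums(A)
  Wm <- matrix(counts_row, nrow(D), m, byrow = TRUE)
  logw <- as.vector(D %*% log(hyper$pi) + (1 - D) %*% log1p(-hyper$pi)) +
    lgamma(rowsA) - lgamma(N + rowsA) +
    rowSums(lgamma(A + Wm) - lgamma(A))
  list(A = A, rowsA = rowsA, logw = logw)
}
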