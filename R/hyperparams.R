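#' Construct the per-taxon prior hyperparameters
#'
#' The prior on each sample's composition is a bimodal Dirichlet: taxon `j`
#' contributes shape `alpha1[j]` (high mode) with probability `pi[j]` and
#' shape `alpha0[j]` (low mode) otherwise, the mode being selected
#' independently per sample and taxon.
#'
#' @param pi Numeric vector of mixture probabilities, strictly inside (0, 1).
#' @param alpha0 Numeric vector of low-mode Dirichlet shapes, positive.
#' @param alpha1 Numeric vector of high-mode Dirichlet shapes, positive.
#'   The ordering convention `alpha0 <= alpha1` is enforced elementwise by
#'   swapping (with the matching `pi -> 1 - pi` relabeling), which leaves the
#'   model invariant.
#' @param taxon_ids Optional taxon labels.
#'
#' @return An object of class `bmdd_hyperparams`: a list with elements `pi`,
#'   `alpha0`, `alpha1` and `taxon_ids`.
#' @examples
#' hyperparams(pi = c(0.3, 0.7), alpha0 = c(0.01, 0.5), alpha1 = c(2, 1))
#' @export
hyperparams <- function(pi, alpha0, alpha1, taxon_ids = NULL) {
  m <- length(pi)
  if (length(alpha0) != m || length(alpha1) != m) {
    stop("pi, alpha0 and alpha1 must have equal length", call. = FALSE)
  }
  if (m < 2) stop("a composition prior needs at least 2 taxa", call. = FALSE)
  if (anyNA(pi) || any(pi <= 0) || any(pi >= 1)) {
    stop("pi must lie strictly in (0, 1)", call. = FALSE)
  }
  if (anyNA(alpha0) || anyNA(alpha1) || any(alpha0 <= 0) || any(alpha1 <= 0)) {
    stop("alpha0 and alpha1 must be strictly positive", call. = FALSE)
  }
  # relabel so that alpha0 is always the low mode
  swap <- alpha0 > alpha1
  if (any(swap)) {
    tmp <- alpha0[swap]
    alpha0[swap] <- alpha1[swap]
    alpha1[swap] <- tmp
    pi[swap] <- 1 - pi[swap]
  }
  if (is.null(taxon_ids)) taxon_ids <- paste0("T", seq_len(m))
  structure(
    list(pi = as.numeric(pi), alpha0 = as.numeric(alpha0),
         alpha1 = as.numeric(alpha1), taxon_ids = as.character(taxon_ids)),
    class = "bmdd_hyperparams"
  )
}

#' @export
print.bmdd_hyperparams <- function(x, ...) {
  m <- length(x$pi)
  cat(sprintf("bmdd_hyperparams for %d taxa\n", m))
  cat(sprintf("  pi:     %s\n", summary_line(x$pi)))
  cat(sprintf("  alpha0: %s\n", summary_line(x$alpha0)))
  cat(sprintf("  alpha1: %s\n", summary_line(x$alpha1)))
  invisible(x)
}

summary_line <- function(v) {
  sprintf("min %.4g / median %.4g / max %.4g", min(v), stats::median(v), max(v))
}

assert_hyperparams <- function(hyper, m = NULL) {
  if (!inherits(hyper, "bmdd_hyperparams")) {
    stop("expected a 'bmdd_hyperparams' object; see hyperparams()", call. = FALSE)
  }
  if (!is.null(m) && length(hyper$pi) != m) {
    stop(sprintf("hyperparameters describe %d taxa but the data has %d",
                 length(hyper$pi), m), call. = FALSE)
  }
  invisible(hyper)
}

#' Fitting configuration for the variational EM algorithm
#'
#' @param tol Relative change in the surrogate evidence lower bound below
#'   which the outer EM loop stops.
#' @param max_iter Maximum number of outer EM iterations.
#' @param inner_tol Convergence threshold on `max |delta gamma|` for the
#'   inner coordinate-ascent sweeps of the E-step.
#' @param max_sweeps Maximum number of inner sweeps per E-step call.
#' @param pi_clamp Mixture probabilities are clamped to
#'   `[pi_clamp, 1 - pi_clamp]` to avoid degenerate priors.
#' @param alpha_min,alpha_max Box constraints for the shape optimizer.
#' @param keep_trace If `TRUE`, the fit records the hyperparameters in force
#'   at every recorded ELBO value (used for diagnostics and exact-bound
#'   checks on small problems).
#' @param verbose If `TRUE`, log the surrogate ELBO each EM iteration.
#' @return A list of class `bmdd_control`.
#' @examples
#' bmdd_control(max_iter = 50)
#' @export
bmdd_control <- function(tol = 1e-6, max_iter = 100L,
                         inner_tol = 1e-6, max_sweeps = 50L,
                         pi_clamp = 1e-4,
                         alpha_min = 1e-6, alpha_max = 1e6,
                         keep_trace = FALSE, verbose = FALSE) {
  stopifnot(tol > 0, inner_tol > 0, max_iter >= 1, max_sweeps >= 1,
            pi_clamp > 0, pi_clamp < 0.5, alpha_min > 0, alpha_max > alpha_min)
  structure(
    list(tol = tol, max_iter = as.integer(max_iter),
         inner_tol = inner_tol, max_sweeps = as.integer(max_sweeps),
         pi_clamp = pi_clamp, alpha_min = alpha_min, alpha_max = alpha_max,
         keep_trace = isTRUE(keep_trace), verbose = isTRUE(verbose)),
    class = "bmdd_control"
  )
}
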