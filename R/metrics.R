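# Composition-recovery evaluation: fifteen metrics in three categories
# (overall similarity, sample-wise property preservation, taxon-wise
# property preservation), plus the four naive zero-handling baselines they
# are compared against. All metrics are nonnegative and equal zero when the
# estimate equals the truth; exact aggregation choices (means of per-row /
# per-column discrepancies) are this package's definitions.

#' Naive zero-handling baselines
#'
#' The four standard ad hoc strategies: (1) do nothing, i.e. row-normalize
#' the raw counts; (2) add a pseudocount of 1 to every cell; (3) replace
#' zero cells by 0.5; (4) replace the zero cell `(i, j)` by
#' `N_i / max(N_k : W_kj = 0)`, the sample's depth scaled by the largest
#' depth among samples where the taxon is unobserved. Variants 3 and 4 leave
#' nonzero cells untouched; all variants renormalize rows to compositions.
#'
#' @param table A [count_table()].
#' @param variant Integer 1-4.
#' @return A [composition()] matrix.
#' @examples
#' ct <- count_table(matrix(c(0L, 3L, 5L, 2L), 2, 2))
#' naive_impute(ct, 2)
#' @export
naive_impute <- function(table, variant) {
  assert_count_table(table)
  W <- table$counts
  variant <- as.integer(variant)
  if (!variant %in% 1:4) stop("variant must be 1, 2, 3 or 4", call. = FALSE)
  V <- switch(variant,
    W,
    W + 1,
    {
      V <- W
      V[V == 0] <- 0.5
      V
    },
    {
      V <- W
      N <- table$depths
      for (j in seq_len(ncol(W))) {
        z <- W[, j] == 0
        if (any(z)) V[z, j] <- N[z] / max(N[z])
      }
      V
    }
  )
  composition(row_normalize(V), table$sample_ids, table$taxon_ids)
}

#' Evaluate all fifteen composition-recovery metrics
#'
#' Compares an estimated composition matrix against the true one:
#'
#' * Overall similarity: `mse` (mean squared entry error), `sample_distance`
#'   (mean Euclidean row distance), `taxon_distance` (mean Euclidean column
#'   distance).
#' * Sample-wise properties, averaged over samples: absolute difference of
#'   `shannon` entropy and `simpson` index (1 - sum p^2), and the per-row
#'   `bray_curtis`, `kl` (truth as reference), `js` (base-2, normalized to
#'   `[0,1]`) and `hellinger` divergences.
#' * Taxon-wise properties: `gini` (mean over samples of the absolute Gini
#'   coefficient difference of the abundance profile), `mean_sd` (Euclidean
#'   distance between the concatenated per-taxon mean and standard-deviation
#'   vectors), `cv` (mean over taxa of the absolute coefficient-of-variation
#'   difference), `ks` and `wasserstein` (mean over taxa of the distance
#'   between the across-sample empirical distributions), and `correlation`
#'   (mean absolute difference of the upper-triangular taxon-taxon Pearson
#'   correlations).
#'
#' Zeros in either argument are guarded in `kl` by adding `1e-12` to both
#' rows before renormalizing; undefined coefficients of variation and
#' correlations (constant taxa) are treated as 0.
#'
#' @param estimated,truth [composition()] matrices (or plain row-stochastic
#'   matrices) of identical shape.
#' @return A data frame with columns `metric`, `category` and `value`
#'   (15 rows).
#' @export
evaluate_all <- function(estimated, truth) {
  E <- unclass_matrix(estimated)
  X <- unclass_matrix(truth)
  if (!all(dim(E) == dim(X))) {
    stop("estimated and true compositions must have identical shape",
         call. = FALSE)
  }
  n <- nrow(E)
  m <- ncol(E)

  # --- overall similarity ---
  mse <- mean((E - X)^2)
  sample_distance <- mean(sqrt(rowSums((E - X)^2)))
  taxon_distance <- mean(sqrt(colSums((E - X)^2)))

  # --- sample-wise properties ---
  shannon <- mean(abs(apply(E, 1, entropy_nat) - apply(X, 1, entropy_nat)))
  simpson <- mean(abs((1 - rowSums(E^2)) - (1 - rowSums(X^2))))
  bray_curtis <- mean(rowSums(abs(E - X)) / rowSums(E + X))
  kl <- mean(vapply(seq_len(n), function(i) kl_div(X[i, ], E[i, ]),
                    numeric(1)))
  js <- mean(vapply(seq_len(n), function(i) js_div(E[i, ], X[i, ]),
                    numeric(1)))
  hellinger <- mean(sqrt(0.5 * rowSums((sqrt(E) - sqrt(X))^2)))

  # --- taxon-wise properties ---
  gini <- mean(abs(apply(E, 1, gini_coef) - apply(X, 1, gini_coef)))
  me <- colMeans(E); mx <- colMeans(X)
  se <- apply(E, 2, stats::sd); sx <- apply(X, 2, stats::sd)
  mean_sd <- sqrt(sum((me - mx)^2) + sum((se - sx)^2))
  cv <- mean(abs(safe_cv(se, me) - safe_cv(sx, mx)))
  ks <- mean(vapply(seq_len(m), function(j) ks_stat(E[, j], X[, j]),
                    numeric(1)))
  wasserstein <- mean(vapply(seq_len(m),
                             function(j) mean(abs(sort(E[, j]) - sort(X[, j]))),
                             numeric(1)))
  ce <- safe_cor(E); cx <- safe_cor(X)
  ut <- upper.tri(ce)
  correlation <- if (any(ut)) mean(abs(ce[ut] - cx[ut])) else 0

  data.frame(
    metric = c("mse", "sample_distance", "taxon_distance",
               "shannon", "simpson", "bray_curtis", "kl", "js", "hellinger",
               "gini", "mean_sd", "cv", "ks", "wasserstein", "correlation"),
    category = rep(c("overall", "sample-wise", "taxon-wise"), c(3, 6, 6)),
    value = c(mse, sample_distance, taxon_distance,
              shannon, simpson, bray_curtis, kl, js, hellinger,
              gini, mean_sd, cv, ks, wasserstein, correlation),
    stringsAsFactors = FALSE
  )
}

unclass_matrix <- function(x) {
  attr(x, "class") <- NULL
  as.matrix(x)
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# KL(p || q) in nats, zero-guarded: both arguments get +1e-12 and are
# renormalized before the divergence is taken
kl_div <- function(p, q) {
  p <- (p + 1e-12) / sum(p + 1e-12)
  q <- (q + 1e-12) / sum(q + 1e-12)
  sum(p * (log(p) - log(q)))
}

# Jensen-Shannon divergence, base 2, in [0, 1]
js_div <- function(p, q) {
  p <- (p + 1e-12) / sum(p + 1e-12)
  q <- (q + 1e-12) / sum(q + 1e-12)
  mid <- (p + q) / 2
  0.5 * sum(p * (log2(p) - log2(mid))) + 0.5 * sum(q * (log2(q) - log2(mid)))
}

# Gini coefficient of a nonnegative abundance vector
gini_coef <- function(p) {
  m <- length(p)
  s <- sum(p)
  if (s <= 0) return(0)
  p <- sort(p)
  (2 * sum(seq_len(m) * p) / (m * s)) - (m + 1) / m
}

safe_cv <- function(s, mu) ifelse(mu > 0 & s > 0, s / mu, 0)

safe_cor <- function(x) {
  suppressWarnings(r <- stats::cor(x))
  r[!is.finite(r)] <- 0
  r
}

# two-sample Kolmogorov-Smirnov statistic (ties handled exactly)
ks_stat <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  w <- c(x, y)
  o <- order(w)
  z <- cumsum(ifelse(o <= nx, 1 / nx, -1 / ny))
  # at tied values only the last cumulative step counts
  ties <- c(diff(w[o]) == 0, FALSE)
  max(abs(z[!ties]))
}
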