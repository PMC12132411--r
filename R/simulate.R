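# Ground-truth simulators: the model's own generative process (setting
# "bmdd") and four misspecified parametric generators with inter-taxon
# correlation ("gamma", "lognormal", "poisson", "negbin"), plus
# differential-abundance signal spiking for the benchmark harness.

#' Simulation configuration
#'
#' @param n_samples,n_taxa Dimensions of the simulated table. Defaults
#'   emulate a typical genus-level study (80 samples, 100 taxa).
#' @param setting Generative model: `"bmdd"` (the model's own process) or one
#'   of the misspecified settings `"gamma"`, `"lognormal"`, `"poisson"`,
#'   `"negbin"`.
#' @param depth_range Sequencing depths: a single value for fixed depth, or a
#'   `c(lo, hi)` range sampled log-uniformly per sample. For the `"poisson"`
#'   and `"negbin"` settings counts are drawn directly and the depth is the
#'   expected (not exact) row total.
#' @param hyper Optional explicit [hyperparams()] for the `"bmdd"` setting;
#'   when `NULL`, [preset_hyperparams()] is used with `preset`.
#' @param preset Hyperparameter preset name (see [preset_hyperparams()]).
#' @param correlation Within-block copula/factor correlation for the
#'   misspecified settings (0 disables correlation).
#' @param block_size Taxa are grouped into exchangeable correlation blocks of
#'   this size.
#' @param diff_fraction Fraction of taxa carrying a differential-abundance
#'   signal when [spike_signal()] is applied.
#' @param effect_range Range `c(lo, hi)` of absolute log-fold changes;
#'   each spiked taxon gets a log-fold change drawn uniformly from this range
#'   with a random sign.
#' @param nb_size Negative-binomial size (inverse-dispersion) for the
#'   `"negbin"` setting; the Poisson limit is `nb_size -> Inf`.
#' @param seed Optional integer seed controlling all randomness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 80L, n_taxa = 100L,
                       setting = c("bmdd", "gamma", "lognormal", "poisson",
                                   "negbin"),
                       depth_range = c(5000, 50000),
                       hyper = NULL, preset = "combo-like",
                       correlation = 0.4, block_size = 10L,
                       diff_fraction = 0, effect_range = c(log(2), log(4)),
                       nb_size = 5, seed = NULL) {
  setting <- match.arg(setting)
  stopifnot(n_samples >= 2, n_taxa >= 2,
            diff_fraction >= 0, diff_fraction <= 1,
            correlation >= 0, correlation < 1, block_size >= 1,
            length(depth_range) %in% c(1L, 2L), all(depth_range > 0),
            nb_size > 0)
  if (!is.null(hyper)) assert_hyperparams(hyper, n_taxa)
  structure(
    list(n_samples = as.integer(n_samples), n_taxa = as.integer(n_taxa),
         setting = setting, depth_range = depth_range, hyper = hyper,
         preset = preset, correlation = correlation,
         block_size = as.integer(block_size),
         diff_fraction = diff_fraction, effect_range = effect_range,
         nb_size = nb_size, seed = seed),
    class = "sim_config"
  )
}

draw_depths <- function(n, depth_range) {
  if (length(depth_range) == 1L) return(rep(round(depth_range), n))
  round(exp(stats::runif(n, log(depth_range[1]), log(depth_range[2]))))
}

#' Preset prior hyperparameters for simulation
#'
#' The `"combo-like"` preset emulates the qualitative mix of taxon archetypes
#' seen in fitted stool-microbiome data: 40% zero-spike taxa (very small low
#' mode, so most samples yield near-zero abundance), 30% clearly bimodal taxa
#' (modes separated by a factor 5-50), and 30% near-unimodal taxa. Mixture
#' probabilities are uniform on (0.2, 0.8). The first zero-spike taxon is
#' always given `alpha0 < 0.01` so every draw contains the archetype.
#'
#' @param m Number of taxa (>= 2).
#' @param preset Preset name; currently only `"combo-like"`.
#' @param seed Optional integer seed (RNG state restored on exit).
#' @return A [hyperparams()] object with an `archetype` attribute labeling
#'   each taxon as `"spike"`, `"bimodal"` or `"unimodal"`.
#' @export
preset_hyperparams <- function(m, preset = "combo-like", seed = NULL) {
  if (m < 2) stop("need at least 2 taxa", call. = FALSE)
  if (!identical(preset, "combo-like")) {
    stop("unknown preset '", preset, "'; available presets: combo-like",
         call. = FALSE)
  }
  with_seed(seed, {
    n_spike <- round(0.4 * m)
    n_bim <- round(0.3 * m)
    n_uni <- m - n_spike - n_bim
    arch <- sample(rep(c("spike", "bimodal", "unimodal"),
                       c(n_spike, n_bim, n_uni)))
    alpha0 <- numeric(m)
    alpha1 <- numeric(m)
    logu <- function(k, lo, hi) exp(stats::runif(k, log(lo), log(hi)))
    is_sp <- arch == "spike"
    is_bi <- arch == "bimodal"
    is_un <- arch == "unimodal"
    alpha0[is_sp] <- stats::runif(sum(is_sp), 0.001, 0.05)
    alpha1[is_sp] <- logu(sum(is_sp), 0.5, 20)
    alpha0[is_bi] <- logu(sum(is_bi), 0.1, 1)
    alpha1[is_bi] <- alpha0[is_bi] * logu(sum(is_bi), 5, 50)
    alpha0[is_un] <- logu(sum(is_un), 0.5, 5)
    alpha1[is_un] <- alpha0[is_un] * stats::runif(sum(is_un), 1, 2)
    if (any(is_sp)) {
      first <- which(is_sp)[1]
      alpha0[first] <- stats::runif(1, 0.001, 0.01)
    }
    pi <- stats::runif(m, 0.2, 0.8)
    h <- hyperparams(pi, alpha0, alpha1)
    attr(h, "archetype") <- arch
    h
  })
}

#' Simulate from the model's own generative process
#'
#' Per sample and taxon: a Bernoulli mode indicator selects the low or high
#' gamma shape; absolute abundances are independent gamma variates (scale 1,
#' which the composition does not depend on); the composition is the
#' normalized row; observed counts are multinomial at the sample's depth.
#'
#' @param config A [sim_config()] with `setting = "bmdd"`.
#' @return A list of class `sim_truth` with fields `delta` (mode indicators),
#'   `abs_abundance`, `composition`, `table`, `hyperparams`,
#'   `requested_depths`, and placeholders `group`, `differential`,
#'   `effect_sizes` (filled by [spike_signal()]).
#' @examples
#' truth <- simulate_bmdd(sim_config(n_samples = 10, n_taxa = 5, seed = 42))
#' truth$table
#' @export
simulate_bmdd <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$setting != "bmdd") {
    stop("simulate_bmdd requires setting = 'bmdd'; see simulate_parametric()",
         call. = FALSE)
  }
  n <- config$n_samples
  m <- config$n_taxa
  with_seed(config$seed, {
    hyper <- config$hyper
    if (is.null(hyper)) hyper <- preset_hyperparams(m, config$preset)
    delta <- matrix(stats::rbinom(n * m, 1L, rep(hyper$pi, each = n)), n, m)
    shapes <- delta * rep(hyper$alpha1, each = n) +
      (1 - delta) * rep(hyper$alpha0, each = n)
    Y <- matrix(stats::rgamma(n * m, shape = shapes, rate = 1), n, m)
    bad <- rowSums(Y) <= 0
    while (any(bad)) {  # all entries underflowed; essentially unreachable
      k <- sum(bad)
      Y[bad, ] <- matrix(stats::rgamma(k * m, shape = shapes[bad, ], rate = 1),
                         k, m)
      bad <- rowSums(Y) <= 0
    }
    X <- row_normalize(Y)
    depths <- draw_depths(n, config$depth_range)
    W <- t(vapply(seq_len(n),
                  function(i) stats::rmultinom(1, depths[i], X[i, ])[, 1],
                  integer(m)))
    new_sim_truth(delta = delta, abs_abundance = Y, X = X, W = W,
                  hyper = hyper, depths = depths, config = config)
  })
}

#' Simulate from misspecified parametric models with correlation
#'
#' Settings `"gamma"` and `"lognormal"`: absolute abundances with the given
#' marginal family, coupled across taxa by a Gaussian copula with
#' exchangeable correlation blocks, then normalized and counted
#' multinomially. Settings `"poisson"` and `"negbin"`: a per-sample,
#' per-taxon mean matrix from correlated log-normal factors; counts drawn
#' directly with expected row total equal to the sample's depth; the true
#' composition is the normalized mean matrix. Marginal parameters are drawn
#' per taxon (gamma: shape log-uniform on (0.3, 3), scale log-uniform on
#' (0.5, 20); log-normal factors: meanlog normal(0, 1.5), sdlog uniform on
#' (0.5, 1.5)).
#'
#' @param config A [sim_config()] with a misspecified `setting`.
#' @return A `sim_truth` list; the `delta` field is `NULL` (these settings
#'   have no mode indicators).
#' @export
simulate_parametric <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!config$setting %in% c("gamma", "lognormal", "poisson", "negbin")) {
    stop("unknown parametric setting '", config$setting,
         "'; use gamma, lognormal, poisson or negbin", call. = FALSE)
  }
  n <- config$n_samples
  m <- config$n_taxa
  with_seed(config$seed, {
    Z <- correlated_normals(n, m, config$correlation, config$block_size)
    logu <- function(k, lo, hi) exp(stats::runif(k, log(lo), log(hi)))
    depths <- draw_depths(n, config$depth_range)
    if (config$setting %in% c("gamma", "lognormal")) {
      if (config$setting == "gamma") {
        shape <- logu(m, 0.3, 3)
        scale <- logu(m, 0.5, 20)
        U <- stats::pnorm(Z)
        Y <- matrix(stats::qgamma(U, shape = rep(shape, each = n),
                                  scale = rep(scale, each = n)), n, m)
      } else {
        meanlog <- stats::rnorm(m, 0, 1.5)
        sdlog <- stats::runif(m, 0.5, 1.5)
        Y <- exp(sweep(sweep(Z, 2, sdlog, "*"), 2, meanlog, "+"))
      }
      bad <- rowSums(Y) <= 0
      if (any(bad)) Y[bad, ] <- Y[bad, , drop = FALSE] + 1e-300
      X <- row_normalize(Y)
      W <- t(vapply(seq_len(n),
                    function(i) stats::rmultinom(1, depths[i], X[i, ])[, 1],
                    integer(m)))
      new_sim_truth(delta = NULL, abs_abundance = Y, X = X, W = W,
                    hyper = NULL, depths = depths, config = config)
    } else {
      meanlog <- stats::rnorm(m, 0, 1.5)
      sdlog <- stats::runif(m, 0.5, 1.5)
      M <- exp(sweep(sweep(Z, 2, sdlog, "*"), 2, meanlog, "+"))
      X <- row_normalize(M)
      mu <- X * depths
      W <- draw_direct_counts(mu, config)
      new_sim_truth(delta = NULL, abs_abundance = M, X = X, W = W,
                    hyper = NULL, depths = depths, config = config)
    }
  })
}

# counts drawn directly from per-cell means (poisson / negbin settings);
# the rare all-zero sample is redrawn so depths stay positive
draw_direct_counts <- function(mu, config) {
  n <- nrow(mu)
  m <- ncol(mu)
  draw_rows <- function(rows) {
    k <- length(rows) * m
    if (config$setting == "poisson") {
      matrix(stats::rpois(k, mu[rows, ]), length(rows), m)
    } else {
      matrix(stats::rnbinom(k, mu = mu[rows, ], size = config$nb_size),
             length(rows), m)
    }
  }
  W <- draw_rows(seq_len(n))
  bad <- rowSums(W) == 0
  while (any(bad)) {
    W[bad, ] <- draw_rows(which(bad))
    bad <- rowSums(W) == 0
  }
  W
}

# n x m standard normals with exchangeable correlation within consecutive
# taxon blocks (shared per-sample factor construction)
correlated_normals <- function(n, m, rho, block_size) {
  E <- matrix(stats::rnorm(n * m), n, m)
  if (rho <= 0) return(E)
  Z <- sqrt(1 - rho) * E
  blocks <- split(seq_len(m), ceiling(seq_len(m) / block_size))
  for (idx in blocks) {
    f <- stats::rnorm(n)
    Z[, idx] <- Z[, idx] + sqrt(rho) * f
  }
  Z
}

new_sim_truth <- function(delta, abs_abundance, X, W, hyper, depths, config,
                          group = NULL, differential = NULL,
                          effect_sizes = NULL) {
  n <- nrow(W)
  m <- ncol(W)
  sample_ids <- paste0("S", seq_len(n))
  taxon_ids <- paste0("T", seq_len(m))
  structure(
    list(delta = delta, abs_abundance = abs_abundance,
         composition = composition(X, sample_ids, taxon_ids),
         table = count_table(W, sample_ids, taxon_ids),
         hyperparams = hyper, requested_depths = depths,
         group = group, differential = differential,
         effect_sizes = effect_sizes, config = config),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth (%s): %d samples x %d taxa\n",
              x$config$setting, nrow(x$table$counts), ncol(x$table$counts)))
  if (!is.null(x$differential)) {
    cat(sprintf("  differential taxa: %d of %d\n",
                sum(x$differential), length(x$differential)))
  }
  invisible(x)
}

#' Spike a differential-abundance signal into a simulated truth
#'
#' Assigns (or reuses) balanced binary group labels, selects
#' `round(diff_fraction * m)` taxa at random, draws each a log-fold change
#' uniformly from `effect_range` with random sign, multiplies the absolute
#' abundance (or mean matrix) of the selected taxa in group 1 accordingly,
#' and regenerates the composition and the counts under the same depths and
#' count mechanism as the original setting.
#'
#' @param truth A `sim_truth` from [simulate_bmdd()] or
#'   [simulate_parametric()].
#' @param config A [sim_config()] supplying `diff_fraction` and
#'   `effect_range`; defaults to the one stored in `truth`.
#' @param seed Optional integer seed for taxon selection, effects and count
#'   regeneration; defaults to `config$seed + 1` when `config$seed` is set.
#' @return The modified `sim_truth` with `group`, `differential` and
#'   `effect_sizes` filled in.
#' @export
spike_signal <- function(truth, config = truth$config, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  n <- nrow(truth$table$counts)
  m <- ncol(truth$table$counts)
  group <- truth$group
  if (is.null(group)) group <- rep(c(0L, 1L), length.out = n)
  fraction <- config$diff_fraction
  if (fraction == 0) {
    truth$group <- group
    truth$differential <- rep(FALSE, m)
    truth$effect_sizes <- rep(0, m)
    return(truth)
  }
  n_diff <- round(fraction * m)
  if (n_diff < 1) {
    stop("diff_fraction * n_taxa rounds to zero differential taxa; ",
         "increase the fraction or the number of taxa", call. = FALSE)
  }
  if (is.null(seed) && !is.null(config$seed)) seed <- config$seed + 1L
  with_seed(seed, {
    sel <- sample.int(m, n_diff)
    eff <- stats::runif(n_diff, config$effect_range[1], config$effect_range[2]) *
      sample(c(-1, 1), n_diff, replace = TRUE)
    A <- truth$abs_abundance
    g1 <- group == 1L
    A[g1, sel] <- sweep(A[g1, sel, drop = FALSE], 2, exp(eff), "*")
    X <- row_normalize(A)
    depths <- truth$requested_depths
    if (truth$config$setting %in% c("poisson", "negbin")) {
      W <- draw_direct_counts(X * depths, truth$config)
    } else {
      W <- t(vapply(seq_len(n),
                    function(i) stats::rmultinom(1, depths[i], X[i, ])[, 1],
                    integer(m)))
    }
    differential <- rep(FALSE, m)
    differential[sel] <- TRUE
    effect_sizes <- rep(0, m)
    effect_sizes[sel] <- eff
    new_sim_truth(delta = truth$delta, abs_abundance = A, X = X, W = W,
                  hyper = truth$hyperparams, depths = depths,
                  config = config, group = group,
                  differential = differential, effect_sizes = effect_sizes)
  })
}

# dispatch a config to the matching simulator
simulate_setting <- function(config) {
  if (config$setting == "bmdd") simulate_bmdd(config) else
    simulate_parametric(config)
}
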