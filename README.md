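# bmdd — bimodal Dirichlet imputation for zero-inflated microbiome counts

Microbiome sequencing yields count tables in which most entries are zero,
mixing genuine near-absence with undersampling at finite depth. Analyses
that need a log transform cannot use those zeros, and ad hoc fixes
(pseudocounts, half-minimum replacement) distort the composition in
depth-dependent ways. **bmdd** models the unobserved relative abundances
explicitly and imputes them by their posterior.

## The model

For samples $i = 1,\dots,n$ and taxa $j = 1,\dots,m$:

$$
\delta_{ij} \sim \mathrm{Bernoulli}(\pi_j),\qquad
\theta_{ij} = \alpha_{j,\delta_{ij}},\qquad
X_i \sim \mathrm{Dirichlet}(\theta_i),\qquad
W_i \sim \mathrm{Multinomial}(N_i, X_i).
$$

Each taxon has a low Dirichlet shape $\alpha_{j,0}$ (near-absence) and a
high shape $\alpha_{j,1}$, selected per sample with probability $\pi_j$, so
zero inflation lives in the prior on the composition rather than in the
count layer. Fitting is by mean-field variational EM on a provable lower
bound of the log marginal likelihood (a Jensen surrogate for one
intractable expectation), with closed-form updates for the variational
Dirichlet parameters and the mixture probabilities and a quasi-Newton
update for the shapes. An exact $2^m$-enumeration oracle
(`exact_posterior_mean()`, `exact_log_marginal()`, $m \le 15$) validates
the variational answers. The fit is fully deterministic; only posterior
*sampling* uses (seeded) randomness. See the methods vignette
(`vignettes/bmdd-methods.Rmd`) for the full derivation and design
decisions.

## Worked example

```r
library(bmdd)

cfg <- sim_config(n_samples = 40, n_taxa = 12,
                  depth_range = c(1000, 5000), seed = 1)
truth <- simulate_bmdd(cfg)
truth$table
#> count_table: 40 samples x 12 taxa
#>   depths: 1017 .. 4971 (median 2308)
#>   zero fraction: 0.219

fit <- bmdd_fit(truth$table)
fit
#> bmdd_fit: 40 samples x 12 taxa
#>   100 EM iterations (not converged); final surrogate ELBO -2100.87

imputed <- posterior_mean(fit)      # strictly positive composition
round(imputed[1:3, 1:5], 4)
#>        T1     T2     T3     T4     T5
#> S1 0.0788 0.1943 0.0820 0.0000 0.0306
#> S2 0.0001 0.3685 0.0392 0.0000 0.0001
#> S3 0.0001 0.0000 0.0423 0.4755 0.0816
round(truth$composition[1:3, 1:5], 4)
#>        T1     T2     T3     T4     T5
#> S1 0.0752 0.1897 0.0785 0.0000 0.0284
#> S2 0.0000 0.3636 0.0419 0.0000 0.0000
#> S3 0.0003 0.0000 0.0278 0.4887 0.0784
```

("not converged" means the 100-iteration budget was reached while the ELBO
was still creeping below the relative tolerance; the imputed compositions
are stable at that point.) Comparing against the +1-pseudocount baseline on
the same data:

```r
r  <- evaluate_all(imputed, truth$composition)
r2 <- evaluate_all(naive_impute(truth$table, 2), truth$composition)
#>           metric     bmdd pseudocount
#>              mse 2.47e-05    2.61e-05
#>  sample_distance 1.61e-02    1.64e-02
#>      bray_curtis 1.94e-02    2.02e-02
#>               kl 2.09e-03    3.19e-03
#>        hellinger 2.23e-02    3.18e-02
```

Multiple-imputation differential abundance on a misspecified (gamma-model)
simulation with 20% spiked taxa:

```r
cfg <- sim_config(n_samples = 60, n_taxa = 30, setting = "gamma",
                  diff_fraction = 0.2, effect_range = c(log(4), log(8)),
                  depth_range = c(5000, 20000), seed = 2)
truth <- spike_signal(simulate_parametric(cfg), cfg)
res <- mi_daa(truth$table, truth$group, n_imputations = 20,
              target_fdr = 0.1, seed = 3)
res[res$rejected, c("taxon", "estimate", "p_value", "q_value")]
#>  taxon estimate  p_value  q_value
#>     T4    -1.54 2.99e-09 8.96e-08
#>     T8     2.20 9.53e-05 9.53e-04
#>    T12     2.14 2.67e-06 4.01e-05
truth$table$taxon_ids[truth$differential]
#> "T4" "T5" "T7" "T8" "T12" "T26"
```

All three discoveries are true positives (no false discoveries at target
FDR 0.1; power 3/6 at this sample size).

## Command line

The installed package ships an `exec/bmdd` wrapper around `bmdd_cli()`:

```sh
bmdd simulate --setting s1 --n 80 --m 100 --seed 1 --out-dir sim/
bmdd fit      --counts sim/counts.tsv --out-dir fit/
bmdd impute   --counts sim/counts.tsv --out imputed.tsv
bmdd sample   --counts sim/counts.tsv --draws 100 --seed 2 --out-dir draws/
bmdd evaluate --est imputed.tsv --truth sim/truth_composition.tsv --out metrics.tsv
bmdd daa      --counts sim/counts.tsv --meta meta.tsv --covariate group \
              --draws 100 --fdr 0.1 --seed 3 --out results.tsv
bmdd bench-daa --config bench.yaml --out bench.tsv
```

`--seed` governs all randomness of a command; `--config` YAML overrides
fitting options; diagnostics go to stderr, results to files only.

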