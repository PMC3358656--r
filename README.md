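# mgmr — population-coupled estimation of RNA-seq expression from multireads

Reads from paralogous genes or shared exons align to several reference
regions at once (*multireads*), making per-gene expression estimates
ambiguous. The standard fix treats each sample alone: expression
proportions are mixture weights, and EM reallocates each ambiguous read in
proportion to the current estimates. But RNA-seq experiments are usually
run on *populations* of samples that share expression structure. `mgmr`
exploits that: per-sample expression vectors are modeled as draws
$p_i \sim \mathrm{Dirichlet}(\alpha)$ from a shared prior with unknown
hyperparameters, and reads from sample $i$ as draws from $p_i$, with

$$P(r \mid G_k) = \frac{(1-\varepsilon)^{\ell - e}\,\varepsilon^{e}}{\ell_k}$$

for a read with $e$ mismatches in its best alignment to region $k$
(read length $\ell$, effective length $\ell_k = L_k - \ell + 1$, constant
per-base error rate $\varepsilon$). The fit alternates, per iteration, one
EM update of every sample's proportions (M-step
$P_{ik} \propto \alpha_k + \sum_j a_{ijk}$, combining responsibilities
with prior pseudo-counts) and one digamma fixed-point update
$\alpha_k \leftarrow \Psi^{-1}[\Psi(\sum_k \alpha_k) + \overline{\log P}_k]$
of the hyperparameters, so every sample borrows strength from the rest of
the population. The uncoupled per-sample EM baseline, a read simulator for
paralog families, and estimate-versus-truth error measures (relative
error, $\chi^2$, KL divergence) are included, so the population benefit
can be demonstrated end-to-end on synthetic data.

Intended users: methods developers and bioinformaticians studying
multiread resolution and hierarchical models of expression, at gene or
transcript level.

## Worked example

Simulate a 10-sample population over 6 regions (two paralog families at 2%
divergence), fit both arms, and compare against the simulated truth:

```r
library(mgmr)
regions <- make_region_set(6, 300, 35L, paralog_groups = c(3, 2),
                           divergence = 0.02, seed = 7)
sim <- simulate_experiment(regions, n_samples = 10, true_alpha = rep(3, 6),
                           coverage = 20, epsilon = 0.01, seed = 8)
fit <- mgmr_fit(sim$tables[[1]], regions)
fit
#> <mgmr_fit> population-coupled (MGMR)
#>   samples: 10   regions: 6   iterations: 100
#>   converged: FALSE   sum(alpha): 18.015

round(fit$alpha, 2)
#> region01 region02 region03 region04 region05 region06
#>     2.95     2.20     3.55     2.98     3.33     3.02
```

The learned hyperparameters recover the generating prior
($\alpha_{\mathrm{true}} = (3,\ldots,3)$, concentration 18 vs. 18.0
fitted). `tidy(fit)` gives one row per (sample, region) with the estimated
proportion; `glance(fit)` one row of fit diagnostics; `autoplot(fit)` the
convergence history. Comparing both arms against the truth:

```r
base <- em_fit(sim$tables[[1]], regions)
aggregate_errors(evaluate_errors(fit$expression, sim$truth))
#> <mgmr_error_report> aggregate over 10 sample(s):
#>   measure           mean      sd
#> 1 relative_error 0.0678  0.0388
#> 2 chi_squared    0.00545 0.00543
#> 3 kl             0.00273 0.00263
aggregate_errors(evaluate_errors(base$expression, sim$truth))
#>   measure           mean      sd
#> 1 relative_error 0.0729  0.0471
#> 2 chi_squared    0.00603 0.00612
#> 3 kl             0.00314 0.00317
```

The population-coupled estimates beat the independent per-sample EM on all
three measures (6.8% vs. 7.3% mean relative error here), and
`improved_region_count()` reports a strictly smaller mean absolute
deviation from truth for 3 of the 6 regions.

A command-line interface wraps the same functions
(`inst/exec/mgmr simulate|fit|evaluate|pipeline`, each honoring `--seed`,
`--iterations`, `--epsilon`, `--tolerance`, `--log-level`); map files use
a plain `read_id<TAB>region:mismatches[,region:mismatches]*` dialect, and
expression matrices are TSV with a `sample_id` column.

See `vignettes/population-multiread-estimation.Rmd` for the model, the
numerical choices (the $+1$ pseudo-count shift, the $10^{-20}$ floor,
digamma inversion), what the simulator does and does not emulate, and
known limitations.

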