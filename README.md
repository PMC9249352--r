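# birfit

Quantitative analysis of **ectopic break-induced replication (BIR)
efficiency** as a function of the length of DNA to synthesize, for
geneticists working with chromosome-fragmentation (telomere-seeding) assays
in budding yeast.

BIR repairs a one-ended double-strand break by invading a homologous
template and copying DNA to the chromosome end. In the fragmentation assay,
efficiency is the ratio of transformants obtained with a linearized vector
(which must complete BIR to be maintained) to transformants with a circular
control. `birfit` models this efficiency as a biphasic per-kilobase survival
process:

    E(d) = k * p1^d                    for d <= T
    E(d) = k * p1^T * p2^(d - T)       for d >  T

where `k` is the initiation probability, `p1` and `p2` are the per-kb
continuation probabilities of a low- and a high-processivity synthesis
phase, and the threshold `T` is the distance at which the two fitted
exponential curves intersect. `1 - p1` and `1 - p2` are per-kb disruption
probabilities. The package provides:

* `bir_fit()` — replicate-level nonlinear least-squares fits of the single
  and two-segment exponential laws, a breakpoint scan, and Gaussian-AIC
  model selection, returning a fitted-model object with `print`, `summary`,
  `coef`, `predict`, `plot`, `simulate`, `residuals` and `AIC` methods;
* `simulate_experiment()` / `parameter_recovery_study()` — a mechanistic
  per-kb chain simulator of transformation experiments and estimator
  calibration studies built on it;
* `terminal_exchange()` / `remap_distance()` — distance-to-telomere
  arithmetic for reciprocal translocations that exchange terminal
  chromosome segments;
* `fisher_exact()`, `compare_aberrant_fractions()`, `efficiency_t_test()` —
  the exact and two-sample tests applied to BIR product classes;
* `run_full_analysis()` — the whole pipeline (load, optional remap, fit,
  tests) writing a JSON + CSV report bundle.

## Worked example

```r
library(birfit)

cfg <- bir_sim_config(seed = 42)     # defaults: k=0.71 p1=0.935 p2=0.995 T=36
dat <- simulate_experiment(cfg)      # 11 loci x 8 replicate experiments
fit <- bir_fit(efficiency ~ distance_kb, dat)
fit
#> Biphasic exponential model of BIR efficiency
#>   replicate observations: 88  distinct distances: 11 
#>   selected: two segments (first 2 distances)
#>     k  = 0.6164
#>     p1 = 0.9439
#>     p2 = 0.9949
#>     T  = 38.97 kb
#>   AIC (independent variance): -461.5
```

The fit recovers the generating parameters: an initiation probability
around 0.6–0.8 (`k` is the noisiest parameter, estimated from the few
telomere-proximal loci), per-kb continuation probabilities near 0.94 and
0.995, and a phase-switch threshold near 36–39 kb — i.e. BIR is ~13 times
less likely to abort per kilobase once synthesis has passed ~35–40 kb. The
AIC table in `summary(fit)` shows the two-segment model beating the single
exponential by ~90 units here, with neighbouring splits flagged when they
are within 1 AIC unit.

Translocation arithmetic and product-class tests:

```r
remap_distance(c(10, 57, 117), terminal_exchange(10, 291))$new_kb
#> [1] 291 338 398
fisher_exact(15, 55, 2, 87)$p.value   # aberrant products, 15/70 vs 2/89
#> [1] 0.0001240184
```

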