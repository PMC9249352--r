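---
title: "Modelling break-induced replication efficiency versus DNA length to synthesize"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling break-induced replication efficiency versus DNA length to synthesize}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The assay and the quantity being modelled

Break-induced replication (BIR) repairs a one-ended DNA double-strand break
by invading a homologous template and copying it, potentially all the way to
the chromosome end. The chromosome fragmentation assay measures how often
this succeeds: a linearized vector carrying a telomere seed, a centromere, a
selection marker and a homology region is transformed into yeast, and is
maintained only if BIR copies the genome from the homology region out to the
telomere. **BIR efficiency** is the number of transformants obtained with the
linearized vector divided by the number obtained with a circular control
vector in the same experiment. The covariate is `dist`, the distance in kb
from the initiating locus to the telomere of its arm — the length of DNA the
BIR fork must synthesize.

Efficiencies are per-experiment ratios, averaged across independent
experiments (`summarize_by_locus()`). The ratio of pooled counts is a
different estimator — it weights experiments by plate yield — and is exposed
only under its own name, `pooled_efficiency()`. Ratios above 1 can occur in
noisy replicates and are kept unclamped.

## The biphasic survival model

The mechanistic picture is a chain of per-kilobase survival events. BIR
initiates with probability $k$; each kilobase of synthesis then completes
without irreversible disruption with probability $p_1$ over the first $T$ kb
(a low-processivity phase) and $p_2$ thereafter (a high-processivity phase):

$$E(d) = k\,p_1^{\,d} \quad (d \le T), \qquad
  E(d) = k\,p_1^{\,T} p_2^{\,d-T} \quad (d > T),$$

continuous at $T$ by construction. `predict_efficiency()` evaluates this
law; $1-p_1$ and $1-p_2$ are the per-kb disruption probabilities returned by
`disruption_probabilities()`.

## Fitting: independent segments, post-hoc threshold

`bir_fit()` fits replicate-level efficiencies (not per-locus means: each
experiment is an independent draw around the curve, and collapsing to means
would discard the replication the model comparison relies on). The distinct
distances, in increasing order, are split into a first segment of $x$
distances and a second segment of the rest; each segment is fitted
independently by nonlinear least squares (`stats::nls`) as
$a\,p^{\,d}$, with **no continuity constraint**. That the two fitted curves
meet near the segment boundary is treated as an emergent property of the
data, and the threshold is derived afterwards as the intersection
$T = \log(a_2/a_1)/\log(p_1/p_2)$ (`intersection_threshold()`). The
assembled model takes $k$ and $p_1$ from segment 1 and $p_2$ from segment 2.

Numerical choices:

* Starting values: amplitude = maximum observed efficiency; base =
  `exp(slope)` of a log-linear regression on the positive efficiencies. Up
  to 20 deterministically jittered restarts precede a non-convergence error.
* Zero efficiencies stay in the least squares; the data are never
  log-transformed for fitting.
* Exact-model (zero-residual) data short-circuit to the analytic log-linear
  solution, since `nls` cannot iterate on a zero-residual problem.
* Constant data are the boundary fit $p = 1$ with zero residual.
* AIC ties are broken toward the smaller split; every candidate within 1
  AIC unit of the minimum is flagged as statistically indistinguishable.

## Model comparison by AIC, and a caveat

Candidates (the single exponential and every split in the scan range) are
compared by Gaussian AIC with maximum-likelihood residual variance,
$n(\log 2\pi + 1 + \log(\mathrm{rss}/n)) + 2(p+1)$ — identical to
`stats::AIC()` on the underlying `nls` fit. For a two-segment combination
the default is the **sum of the two segments' AICs, each with its own
variance**, since the segments are independent fits.

This convention has a consequence worth knowing. Replicate noise in the
assay is heteroscedastic — the binomial scatter of a transformant ratio
shrinks as the efficiency falls — so the second variance parameter bought by
any split improves the Gaussian likelihood even when the mean curve has no
breakpoint. Under the independent-variance convention a two-segment model
can therefore beat a single exponential by 10–35 AIC units on single-phase
data. The pooled-variance variant (`bir_fit(..., aic = "pooled")`, one
common residual variance, $2(4+1)$ penalty) does not show this behaviour
(median gap ≈ 0 on single-phase simulations) and is the right sensitivity
check when the question is whether the *mean* structure is biphasic. With a
genuinely biphasic truth both conventions select the two-segment model
decisively.

## The simulator

`simulate_experiment()` is a mechanistic generator, not a curve-plus-noise
one: each plate draws a Poisson number of transformation-competent events
(independent draws for the linear and control platings, emulating day-to-day
competence variation; a shared-attempts variant sits behind a flag), and
every linear-plating event walks the per-kb survival chain — Bernoulli($k$)
initiation, then one Bernoulli survival per kilobase at $p_1$ up to $T$ and
$p_2$ beyond, with a fractional-exponent final step so the marginal success
probability equals $E(d)$ at any real distance. Control plates that draw
zero events are redrawn, as a plate with no control transformants yields no
ratio and would be repeated at the bench.

Defaults are the assay's study conditions: $k=0.71$, $p_1=0.935$,
$p_2=0.995$, $T=36$ kb, the eleven distinct locus distances of the assay
(10–398 kb; the three largest obtained by reciprocal translocation), 8
replicates per locus. The expected 200 competent events per plate is a
tuning default chosen so replicate scatter resembles the assay's error bars,
not a measured value. A single global RNG seeded from the config gives
byte-identical datasets per seed.

What the generator does **not** emulate: template switching and
multi-invasion (product classes are inputs, never simulated), locus-specific
chromatin or transcription effects, overdispersion beyond Poisson–binomial
sampling, and day or batch effects beyond independent Poisson attempts.
Passing recovery tests therefore shows the estimator works when the model
and noise family are true, not that real data satisfy them.

`parameter_recovery_study()` simulates many datasets, refits each at the
true split, and tabulates bias, median absolute error and RMSE per
parameter; with `scan = TRUE` it also records which split the AIC scan
selects. The packaged studies use 200 datasets of 8 replicates at the 11
distances, and simulator–formula agreement is checked with $10^5$ chain
attempts per distance — sizes chosen to make the Monte Carlo error small
against the assay's printed standard errors.

## Translocation distance arithmetic

A reciprocal translocation exchanging terminal segments is described by the
length removed from the focal arm and the length added from the donor arm
(`terminal_exchange()`). A locus at distance $d$ is retained on the focal
arm when $d \ge$ removed length — the boundary case, a locus abutting the
breakpoint, is treated as retained, matching the assay's most
telomere-proximal locus — and its distance becomes $d - \text{removed} +
\text{added}$. A locus inside the removed segment travels with it and its
telomere, keeping its distance unchanged. Distances are kb reals; no
base-pair coordinate convention is needed.

## Product-class statistics

`fisher_exact()` wraps `stats::fisher.test()`: with margins fixed, the
two-sided p sums all hypergeometric point probabilities not exceeding the
observed one. An empty outcome column is a single possible outcome class
(p = 1); an empty condition row is an error. `compare_aberrant_fractions()`
builds the 2×2 tables for every pair of conditions; no multiplicity
adjustment is applied by default (each contrast stands alone),
Benjamini–Hochberg and friends behind the `adjust` flag.
`efficiency_t_test()` is two-sided and Welch by default — the default
behaviour of the underlying test — with pooled-variance Student behind
`welch = FALSE`, since published summaries rarely say which variance
assumption was used; the zero-variance-unequal-means corner returns the
p → 0 limit with a warning.

## Known limitations

* Least squares on ratios assumes homoscedastic Gaussian errors the assay
  does not have; weighted or binomial-likelihood fitting would be the next
  refinement, and the AIC caveat above is one symptom.
* Standard errors come from the `nls` linearization; no bootstrap or
  profile intervals.
* The threshold $T$ is a derived intersection, not a fitted parameter, so
  it carries no standard error of its own.
* With few distances below the threshold, $k$ is estimated from a short
  lever arm and is the noisiest parameter by far.
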