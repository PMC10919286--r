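---
title: "Methods: posterior inference of Hi-C interaction frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: posterior inference of Hi-C interaction frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A Hi-C contact map records, for every pair of fixed-size genomic bins on a
chromosome, how many sequenced read pairs joined them.  At useful
resolutions (a few kb) the map is a sparse, noisy, biased observation of
the latent quantity of interest -- the true relative interaction frequency
`t[i,j]` of each locus pair -- and every downstream annotation (TADs,
loops, compartments) silently inherits that noise as if the map were
exact.  `hicposterior` treats the map as data in a generative model and
returns *samples* from the posterior distribution of the full frequency
matrix, so that any downstream tool can be run once per sample and the
spread of its answers read as uncertainty.

## Observation model

Counts are modelled as independent Poisson draws given the latent matrix:

    o[i,j] ~ Poisson(b[i] * b[j] * t[i,j])

where `b` is a per-bin multiplicative visibility bias (fragment length,
GC, mappability).  `b` is estimated *first*, by iterative correction
(`ice_balance()`), and then held fixed during sampling: a two-phase
scheme keeps bias estimation flexible (any externally produced bias
vector can be supplied via `read_bias()`) and the sampler simple.
`ice_balance()` works on the banded map as loaded and masks bins with
zero or bottom-2% raw marginals; the fixed point is computed with a
square-root-damped symmetric update, which converges monotonically and
satisfies the same equal-visibility fixed point as the classic
undamped iteration.

Analysis is intra-chromosomal, one chromosome at a time, and restricted
to a distance band (default: the full matrix; for long chromosomes a cap
such as 5 Mb keeps cost linear in the genome length).

## Distance decay

The local anchor of the prior is the expected normalized frequency at
bin distance `d`,

    log g(d) = w0 + B(d),

a Poisson log-linear model with a cubic B-spline `B` in `d`, knots at
0/25/50/75/100% of the maximum analysis distance, and `log(b[i]*b[j])`
as offset (`fit_decay()`).  The fit uses a seeded uniform 10% subsample
of in-band pixels; zero-count pixels are included because zeros carry
information under a Poisson likelihood.  The IRLS solver runs to a
deviance change of 1e-8 or 100 iterations.  `predict_g()` refuses to
extrapolate beyond the fitted band.

## The Markov random field prior

The prior couples each pixel to its second-order (8-pixel) neighbourhood
and anchors it to the decay curve through two Gaussian-kernel potentials
on the log scale:

    local     phi(t[ij])         = exp(-(log t[ij] - log g(d))^2 / (2 * omega2(d)))
    pairwise  phi(t[ij], t[kl])  = exp(-(log t[ij] - log t[kl])^2 / (2 * sigma2_edge))

Both variance fields are estimated empirically from the ICE-normalized
map, *on the log scale*: the potentials penalise log differences, so the
matching moment is the variance of log values.  `omega2(d)` is the
variance of log normalized frequencies in the distance-`d` stratum
(strata with under 3 positive pixels borrow the nearest populated
stratum).  `sigma2[i,j]` is the variance of first-order-adjacent
log-value differences inside a 17x17 window centred on the pixel; 17 was
retained as the default because held-out likelihood is flat across 3-21
with a shallow optimum there, and on a new resolution the window can be
re-selected the same way.  Because `sigma2` differs between the two ends
of an edge, the edge variance is `max(sigma2_p, sigma2_q)`, which makes
the pairwise potential symmetric in its arguments.

Note the potentials are kernels over `t`, not normalised densities: the
local potential is equivalent to a LogNormal(log g + omega2, omega2)
prior on `t`.  The calibration tests generate from exactly this law.

### Boundary-aware pruning

Smoothing across a TAD boundary would blur it.  For every transition
between adjacent rows (and columns) the strip of 17 log values on one
side is compared with the matching strip on the other side by an exact
two-sample Kolmogorov-Smirnov test; transitions significant at
`alpha = 0.01` are removed from both Markov blankets.  Diagonal
neighbour edges inherit pruning from the row/column transitions they
cross.  Strips with fewer than 5 usable values keep the edge -- when in
doubt, smooth.  Every adjacent row/column pair inside the band is a
candidate; `alpha = 0` switches pruning off.  The defaults
(`alpha = 0.01`, `flank = 8`, i.e. strips as long as the 17-window) are
this package's choices; the type-I behaviour of the exact test is
verified on homogeneous fields in the test suite.

### Prior variants

For sensitivity analysis the sampler also runs with: a **uniform** prior
(likelihood only), a **gaussian** prior (local decay term only, no
smoothing), and a **fixed-sigma** MRF (pairwise variance one scalar
everywhere; default: the median of the estimated `sigma2` field, a
neutral fixed choice).  On held-out data the full model should and does
score best, followed by fixed-sigma, gaussian, then uniform.

## Sampling

The posterior is explored by Metropolis-Hastings-within-Gibbs.  Each
pixel's full conditional is its Poisson term times its local potential
times the pairwise potentials over its (pruned) blanket.  Because `t`
is positive, the chain moves in `u = log t`: proposals are
`u* ~ Normal(u, sd^2)` per pixel, and the acceptance ratio carries the
`+u` change-of-variable term so the chain targets the posterior of `t`,
not of `u`.  Chains start from i.i.d. Uniform(0,1) frequencies.

**Adaptation.**  Proposal scales start at 1 and are updated every 10
sweeps by `sd <- sd * exp((gain0 / r) * (rate - 0.234))`, with `r` the
adaptation round: a diminishing-gain controller targeting the classic
0.234 acceptance rate, tuned per pixel (rates are reported band-wide).
After burn-in the scales freeze, so the collected chain is a genuine
time-homogeneous Markov chain.

**Mixing.**  Two independently initialised chains run in lockstep;
every `k = 50` sweeps a thinned draw is recorded.  Once 10 draws exist
(no earlier than `10k` sweeps), mixing is declared when the mean
inter-chain RMSE (same-index draws) exceeds the mean intra-chain RMSE
(consecutive draws, both chains) by at most 10%.  The rule is one-sided:
chains that have not met show inter far above intra, while inter at or
below intra carries no evidence of trouble (two literally identical
chains must count as mixed).  If the cap (`max_sweeps`, default 10,000)
is hit first, sampling proceeds with `mixed = FALSE` and a warning.

**Output.**  After freezing, `n_samples` (default 500) draws are taken
every `k` sweeps from chain A; chain B is kept for diagnostics.
Single-chain output avoids interleaving artefacts; pooling both chains
is available behind `pool_chains`.  Summaries are the element-wise mean,
variance and dispersion index (variance/mean) of the draws.

**Schedule.**  A sweep visits every unmasked in-band pixel once, in
row-block tiles (default 200 rows) executed in two phases (even blocks,
then odd).  Tiles within a phase are separated by a full block, hence
never share a Markov blanket, and each (chain, sweep, tile) triple has
its own counter-based RNG stream -- results are therefore invariant to
the order (or concurrency) of tiles within a phase, and the whole chain
is reproducible from the master seed.  `validate_tile_schedule()`
rejects schedules that would let concurrent tiles touch.

## Diagnostics

* `ppc_pvalues()`: posterior predictive check.  The predictive CDF at a
  pixel is the draw-average of Poisson CDFs; the p-value is drawn
  uniformly between `CDF(o-1)` and `CDF(o)` (randomized PIT), which is
  exactly Uniform(0,1) under a matched model, so the KS statistic
  against uniform is interpretable without simulation.
* `test_loglik()`: held-out score, the mean over the first 100 draws of
  the Poisson log-likelihood of an independent test map (a mean of
  log-likelihoods, deliberately not a log-mean).  Train/test pairs are
  built by independent binomial thinning (`downsample_map()`).
* `kl_vs_sample_size()`: per-pixel marginal KL divergence between the
  posterior approximated from the first `n` draws and a large gold
  standard, histogrammed on 30 shared log-scale bins with add-one
  smoothing -- a practical answer to "how many samples do I need"
  (typically: improvements become negligible by a few hundred).

## The synthetic generator

`make_truth()` builds the minimal structure the model exploits: a
power-law decay `(1+d)^-a` (default exponent 1, the classic intra-arm
slope), multiplicative domain blocks (boundaries split the chromosome
into segments; within-segment pairs are enriched, default 3-fold),
Gaussian loop bumps (default peak 4-fold, sd 1.5 bins), and i.i.d.
lognormal per-bin biases (log-sd 0.3, about the spread of real ICE bias
vectors).  `simulate_counts()` rescales the truth to an expected total
depth and draws independent Poisson counts.  The default fixture is a
200-bin map with 3 domains, 2 loops and 5e5 expected pairs -- roughly 25
pairs per pixel, a realistic mid-coverage regime that keeps a full
two-chain run in the tens of seconds.

What the generator does *not* emulate: overdispersion beyond Poisson,
correlated (fragment-level) biases, unmappable stretches, translocations
or copy-number structure, and inter-chromosomal contacts.  Passing
calibration on this generator therefore demonstrates correctness of the
inference machinery under the stated model, not robustness to every
artefact of real libraries.

## Numerical choices

* Variance floor 1e-4 on both `omega2` and `sigma2`: degenerate strata
  (e.g. locally constant regions) would otherwise produce zero
  variances and infinitely stiff potentials.
* Proposal scales clamped to `[1e-6, 1e3]`; candidate log rates above
  700 are rejected outright (they would overflow `exp`).
* Adaptation gain `gain0 = 2` with `1/r` decay; intervals of 10 sweeps;
  `thin` must be a multiple of the interval so chunk boundaries align.
* Masked bins (zero/low coverage) contribute no likelihood or potential
  terms anywhere; in-band zero-count pixels on usable bins are sampled
  normally.
* Ties in the KS test are not expected (continuous values); strips
  shorter than 5 usable values keep the edge.
* Posterior sample sets are stored as a plain-text container (JSON
  manifest plus one TSV per draw) so every draw is directly consumable
  by external contact-map tools.

## Problem sizes used in the test suite

The statistical tests run at sizes chosen to give each check real
power while keeping the whole suite in minutes: the two-chain
acceptance/mixing checks use the default 200-bin fixture; calibration
uses a 150-bin matched-generator run (11,325 pixels, 400 draws);
the variant-ranking experiment a 100-bin map with 100 draws per
variant; the sample-size curve a 60-bin map with a 5,000-draw gold
standard.

## Limitations

Inference is per-chromosome and conditional on a point estimate of the
bias vector and decay curve (an empirical-Bayes simplification: their
uncertainty is not propagated).  The Poisson observation model has no
overdispersion parameter.  MCMC cost grows with band area; very high
resolutions call for narrower bands or more hardware.  The acceptance
rate is tuned per pixel toward 0.234, which is a convention, not an
optimum, for one-dimensional conditional updates.
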