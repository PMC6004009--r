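---
title: "Modelling foveal crowding curves: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling foveal crowding curves: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdfit)
```

## The compound psychometric model

Identification accuracy for a small, high-contrast optotype flanked at
edge-to-edge gap $x$ (arcminutes) is modelled as the pointwise maximum of
two branches:

$$\Psi(x) = \max\{\,m x + b,\;\gamma + (A - \gamma)\,\Phi((x-\mu)/\sigma)\,\}.$$

The sigmoid is the classical crowding limb: performance rises from the
chance floor $\gamma$ toward the unflanked asymptote $A$ as flankers move
away, with location $\mu$ and width $\sigma$ in arcminutes. The straight
line is the *recovery* limb: with flankers nearly abutting the target,
the nearest flanker strokes fuse perceptually with the target's own
strokes and provide a usable width cue, so accuracy at the very smallest
gaps is *higher* than at the point of maximal crowding and declines with
separation ($m \le 0$) until the sigmoid overtakes it. The maximum
structure encodes the assumption that the two mechanisms operate in
parallel and the observer benefits from whichever is more informative.

Parameters, units, and defaults:

| parameter | meaning | units | constraint |
|---|---|---|---|
| `A` | asymptotic (unflanked) proportion correct | — | $\gamma \le A \le 1$ |
| `mu` | sigmoid location | arcmin | — |
| `sigma` | sigmoid width | arcmin | $> 0$ |
| `m` | recovery slope | proportion / arcmin | $\le 0$ |
| `b` | recovery intercept at abutting flankers | — | $[0, 1]$ |
| `gamma` | guess rate | — | fixed, 0.25 for 4AFC Tumbling E |

The guess rate is fixed by the task (four response alternatives), not
fitted. No lapse-rate parameter is included: the asymptote $A$ itself is
free, so attentional lapses are absorbed into it, and the data this
design produces (tens of trials per spacing) cannot separate the two.
The recovery line is clipped to $[0,1]$ to preserve probability
semantics; with $b \le 1$ and $m \le 0$ the clip never bites at tested
gaps. The unflanked condition is treated as the $x \to \infty$ limit of
the sigmoid and represented internally as `Inf`, which keeps the
"compares greater than any finite gap" ordering and makes
$\Psi(\mathrm{unflanked}) = A$ exact. In trial files it is the literal
token `UNFLANKED`, so no arithmetic can be done on it by accident.

## Probit-unit normalisation

Equal drops in proportion correct are not equal changes in sensitivity:
a fall from 0.95 to 0.90 is a larger perceptual effect than 0.65 to
0.60. `z_reduction()` therefore expresses performance as the change in
Z-score (probit) units from the fitted asymptote,
$z(p) - z(A)$ with $z = \Phi^{-1}$. On this scale the crowding limbs of
curves measured at different letter sizes align, which is what motivates
sharing $\sigma$ and $\mu$ across sizes in the model family below.

Two conventions are possible: transform the raw proportions, or correct
both $p$ and $A$ for guessing first. The function takes an explicit
`mode` argument. The default is `raw`, which reproduces the conventional
worked arithmetic for asymptote-referenced drops
($\Phi^{-1}(0.95)-\Phi^{-1}(0.90) = 0.363$); `guess_corrected` applies
$(p-\gamma)/(1-\gamma)$ to both arguments first and is the right choice
when curves with different guess rates must be compared. Proportions are
clamped to $[\varepsilon, 1-\varepsilon]$, $\varepsilon = 10^{-6}$,
before the probit (with a warning), so empirical cells at exactly 0 or 1
map to finite values.

## Bayesian estimation

Each curve's likelihood is the product of per-trial Bernoulli terms with
success probability $\Psi(x_i)$; unflanked trials enter at probability
$A$ directly, so the asymptote is estimated jointly with the curve
rather than pinned to the unflanked proportion (jointness subsumes the
pinned variant and propagates the unflanked sampling error). Priors are
weak uniforms: `A` (0, 1), `sigma` (0, 5), `mu` (−1, 1), `m` (−1, 0),
`b` (0, 1). The `mu` upper bound can pinch conditions whose true
location approaches 1 arcmin; bounds are configurable via
`prior_spec()`, and posteriors with more than 5% of their mass within 1%
of a prior bound are flagged (`diagnostics$boundary_flag`).

The sampler is an adaptive Metropolis-within-Gibbs scheme written for
this likelihood: componentwise Gaussian proposals tuned toward 44%
acceptance during warmup, interleaved (from mid-warmup on) with a joint
proposal whose covariance is learned from the warmup history and scaled
$2.38/\sqrt{P}$, tuned toward 23% acceptance. The joint move matters:
the posterior correlates $\sigma$ with $\mu$ and $m$ with $b$ strongly,
and purely componentwise walks mix slowly along those ridges. `sigma` is
proposed multiplicatively (a random walk on $\log\sigma$ with the
change-of-variables correction), while its uniform prior applies on the
natural scale. Adaptation uses diminishing step-size updates and stops
at the end of warmup, so the post-warmup chain is a fixed Markov kernel.
Defaults are 4 chains × 1000 post-warmup draws after 1000 warmup
iterations; a run is reproducible from its single integer seed.

Convergence is summarised by split-$\widehat R$ computed per parameter
(each chain split in half; between/within variance ratio). Fits with any
split-$\widehat R$ above 1.01 are flagged `converged = FALSE` rather
than rejected — with random-walk kernels values slightly above the
threshold usually indicate high autocorrelation, not failure, and the
flag lets the caller decide whether to run longer chains. Degenerate
data (all responses identical) proceed but are flagged
`prior_dominated`.

Because the Bernoulli likelihood only depends on the per-(cell, gap)
counts, trials are aggregated to binomial counts before sampling, and
per-trial pointwise log-likelihoods for WAIC are stored per unique
(cell, gap, outcome) point with integer multiplicities — identical
values are never stored twice.

## The hierarchical model family

Only $A$ and $b$ must change with stimulus size; $\sigma$, $\mu$ and $m$
may plausibly be shared. Each of the three receives a constraint code —
`F` (one value for everyone), `O` (one per observer), `C` (one per
observer × optical condition), `N` (free per cell) — giving the
twelve-member lattice of `enumerate_models()`, from the fully yoked
`#0 FFF` to the saturated `#11 NNN`. Sharing is implemented as hard
equality of parameter slots (the "yoked" reading), not partial pooling
with hyperpriors: the family is a set of discrete hypotheses about which
quantities are condition-invariant, and hard sharing keeps each
hypothesis crisp and the comparison interpretable. Shared slots get the
same uniform priors as single-condition fits.

Models are ranked by WAIC computed from per-trial Bernoulli pointwise
log-likelihoods:
$\mathrm{lppd} = \sum_i \log(\tfrac1S\sum_s e^{\ell_{is}})$ (evaluated
with log-sum-exp stabilisation),
$p_{\mathrm{WAIC}} = \sum_i \mathrm{Var}_s(\ell_{is})$ (the variance
form, the standard stabilised estimator), and
$\mathrm{WAIC} = -2(\mathrm{lppd} - p_{\mathrm{WAIC}})$. The per-trial
unit makes the criterion invariant to how sessions or blocks are sliced
into files. Ties in the ranking break by lower $p_{\mathrm{WAIC}}$, then
lower model id. Alongside lppd the comparison table reports the maximum
total log-likelihood over draws (`loglik_max`), an explicitly defined
fit summary; a posterior-mean "log-likelihood" column is avoided because
its definition is ambiguous.

## Critical spacing

The critical spacing is the largest gap at which accuracy is a criterion
amount $c$ below the asymptote. The criterion acts on the proportion
scale (default $c = 0.025$, a deliberately conservative 2.5% drop), not
the Z scale. On the sigmoid branch the crossing is closed-form:

$$x^* = \mu + \sigma\,\Phi^{-1}\!\left(\frac{A - c - \gamma}{A - \gamma}\right).$$

Two degeneracies are flagged `undefined` rather than silently resolved:
the asymptote may sit within $c$ of the chance floor (no level to
cross), or the recovery line may lie above $A - c$ at $x^*$, in which
case the compound curve never dips below the criterion level there and
reporting the sigmoid-only value would overstate the interference zone.

Confidence intervals come from the posterior: `cs_interval()` resamples
`n_mc = 1000` parameter draws, computes $x^*$ for each, and reports the
2.5/97.5 percentiles of the defined values (the median is the point
estimate, so the point always lies inside its own interval). The
fraction of undefined draws is reported, and intervals with more than
half the draws undefined are flagged unreliable. A parametric bootstrap
(resimulate and refit) would measure nearly the same uncertainty at
orders of magnitude more compute; the posterior already quantifies
parameter uncertainty, so it is the natural Monte-Carlo source here.

For synthesis across studies, `center_to_center()` converts edge-to-edge
values: bar flankers add $0.6\times$ the target size, letter flankers
add the full letter size (a Tumbling-E letter is five stroke widths).
`size_limited_line()` gives the foveal size-limited reference
$CS = 1.4 \times \mathrm{size}$ in center-to-center terms.

## The synthetic-trial generator

No trial-level data ship with the package, so `default_design()` and
`simulate_trials()` emulate the experiment the analysis targets: three
observers, each with and without adaptive-optics correction, at
realistic per-observer stroke sizes (2–5 per condition, 0.37–0.97
arcmin), gaps from abutting to 1.6 arcmin plus an unflanked condition,
binomial responses drawn from $\Psi$. Choices the design leaves open
were fixed once:

* **Gap grid** — 0.2-arcmin steps (nine finite gaps). Published curves
  of this kind have ~8–10 spacing points; the grid is an emulation of
  such a design, not a reconstruction of any particular observer's
  grid.
* **Trials per cell** — 20 (10 per block, every condition run in at
  least two sessions).
* **Ground truth** (`default_truth()`) — asymptotes rising 0.80 → 0.97
  with stroke size within each condition, recovery intercept 0.2 below
  the asymptote (abutting flankers cost roughly 20 percentage points),
  observer-specific $\mu$ of 0.45/0.50/0.55 arcmin, $\sigma = 0.2$
  arcmin, $m = -0.4$ per arcmin. This places critical spacings around
  0.75–1.3 arcmin for cells with 80–95% asymptotes — the regime the
  analysis is designed for.
* **RNG contract** — the top-level seed derives one substream per
  (subject, optical, stroke, gap) cell via a string hash, so identical
  seeds give byte-identical data and adding a cell never perturbs the
  draws of existing cells.

The generator reproduces the *statistical* structure (independent
Bernoulli trials from a smooth curve). It deliberately omits sequential
dependencies, learning and fatigue, lapses, eye-movement and fixation
jitter, and any optics: passing recovery tests on synthetic data shows
the estimator is correct for the assumed model, not that the model is
true of any observer.

## Problem sizes in the test suite

The simulation studies in the tests are sized for a desk machine, as the
package's own verification protocol: parameter recovery uses 200
trials/cell on the default grid across 50 seeded replicates (checking
~95% credible-interval coverage of all five generating values);
model-structure recovery uses two observers × three sizes at 100
trials/cell, ten replicates, checking that WAIC prefers the generating
shared-$\sigma,\mu$ structure (`OOF`) over the saturated `NNN`; the CLI
pipeline is checked for byte-level determinism end to end. Larger runs
sharpen the same checks but do not change their logic.

## Known limitations

* Hard parameter sharing cannot express "similar but not equal"
  parameters; if partial pooling is the scientific question, this family
  is the wrong tool.
* The random-walk sampler needs thousands of iterations where a
  gradient-based sampler would need hundreds; for the data sizes this
  design produces (seconds per fit) that trade is acceptable.
* Critical spacings are extrapolations of a parametric form; with weak
  data (20 trials/cell) the posterior admits wide sigmoids and the
  spacing interval grows accordingly — the interval, not the point
  estimate, is the honest summary.
* `fit_condition` requires at least two distinct finite gaps plus
  unflanked trials to constrain all five parameters (it warns
  otherwise); single-gap data leave the posterior prior-dominated.
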