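# crowdfit

Bayesian modelling of foveal crowding psychometric functions.

Crowding — the interference of nearby flankers with target identification —
is tiny at the center of gaze: with well-corrected optics, letter
identification is degraded only when flankers come within roughly an
arcminute of the target, and performance partially *recovers* again when
flankers nearly abut it. Characterising this requires fitting
identification accuracy as a function of edge-to-edge flanker spacing on a
sub-arcminute scale, deciding which curve parameters are shared across
observers, optical conditions and letter sizes, and extracting the
*critical spacing* — the largest gap at which accuracy still falls below
the unflanked asymptote. `crowdfit` implements that full analysis for
trial-level forced-choice data (and ships a synthetic-trial generator
emulating a three-observer adaptive-optics experiment, so the whole
pipeline can be exercised without observer data).

## The model

Proportion correct at edge-to-edge gap *x* (arcmin) is the pointwise
maximum of a crowding sigmoid and a linear recovery branch:

```
Psi(x)          = max( Psi_recovery(x), Psi_crowding(x) )
Psi_recovery(x) = m x + b
Psi_crowding(x) = gamma + (A - gamma) * Phi((x - mu) / sigma)
```

with `Phi` the standard normal CDF and `gamma = 0.25` the guess rate of
the four-alternative Tumbling-E task. The five free parameters are the
asymptote `A`, sigmoid location `mu` and width `sigma` (arcmin), and the
recovery slope `m` (≤ 0) and intercept `b`. Parameters are estimated by
seeded MCMC under weak uniform priors — `A (0,1)`, `sigma (0,5)`,
`mu (−1,1)`, `m (−1,0)`, `b (0,1)`.

On top of the single-condition fit the package provides:

* **probit-unit normalisation** (`z_reduction`) — performance drops
  expressed as changes in Z-score from the asymptote, the scale on which
  crowding curves align across letter sizes;
* a **twelve-member hierarchical model family** (`enumerate_models`,
  `fit_family`) — `sigma`, `mu`, `m` each shared across observers (`F`),
  per observer (`O`), per observer × optical condition (`C`), or free
  (`N`), ranked by WAIC (`waic`, `compare_models`);
* **critical spacing** (`critical_spacing`, `cs_interval`) — the closed
  form `x* = mu + sigma * qnorm((A - c - gamma)/(A - gamma))` for an
  accuracy drop `c` (default 0.025), with Monte-Carlo confidence
  intervals from posterior draws, plus edge-to-edge ↔ center-to-center
  conversions (`center_to_center`) and the foveal size-limited reference
  line `CS = 1.4 × size` (`size_limited_line`).

## Worked example

Simulate one condition (observer S2, adaptive-optics correction,
0.47-arcmin strokes, 100 trials per spacing), fit it, and extract the
critical spacing:

```r
library(crowdfit)

design <- crowding_design(
  tibble::tibble(subject = "S2", optical = "AO", stroke = 0.47),
  n_trials = 100)
truth <- flat_truth(design, crowding_params(A = 0.9, mu = 0.5, sigma = 0.2,
                                            m = -0.4, b = 0.7))
trials <- simulate_trials(design, truth, seed = 1)

fit <- fit_condition(trials, seed = 2)
summary(fit)
#> # A tibble: 5 × 6
#>   param   mean median    q2.5  q97.5  rhat
#>   <chr>  <dbl>  <dbl>   <dbl>  <dbl> <dbl>
#> 1 A      0.880  0.880  0.850   0.913  1.00
#> 2 b      0.729  0.731  0.644   0.805  1.00
#> 3 sigma  0.241  0.225  0.0404  0.539  1.02
#> 4 mu     0.432  0.435  0.243   0.569  1.02
#> 5 m     -0.563 -0.563 -0.954  -0.166  1.00

cs <- cs_interval(fit, criterion = 0.025, n_mc = 1000, seed = 3)
#> critical spacing: 0.82 arcmin (95% CI 0.63-1.22)
center_to_center(cs$value, 5 * 0.47)   # letter flankers: + letter size
#> 3.17
size_limited_line(5 * 0.47)
#> 3.29
```

Every posterior 95% interval covers its generating value; the estimated
edge-to-edge critical spacing (0.82 arcmin, CI 0.63–1.22) sits in the
sub-arcminute-to-arcminute range characteristic of foveal crowding at
80–95% unflanked performance, and its center-to-center conversion lies
close to the size-limited reference line for a 2.35-arcmin letter.

## Command-line pipeline

A thin wrapper (`inst/cli/crowdfit`, or `crowd_cli()` in R) chains the
stages; all stochastic steps take `--seed` and outputs carry provenance
headers:

```sh
crowdfit simulate --seed 1 --out trials.csv
crowdfit fit      --data trials.csv --out-dir fits --seed 2
crowdfit compare  --data trials.csv --out compare.csv --seed 3 --models 5,6,11
crowdfit spacing  --fits fits --out spacing.csv --seed 4
crowdfit report   --spacing spacing.csv --data trials.csv --out-dir report
```

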