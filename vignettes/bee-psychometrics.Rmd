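---
title: "Methods: Bayesian psychometrics for free-choice foraging data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian psychometrics for free-choice foraging data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(beepsych)
```

This vignette documents the statistical model, the sampler and its validation
oracle, and the data-reduction conventions used throughout `beepsych`. The
setting is a two-alternative free-choice (2-AFC) experiment: foragers choose
repeatedly between two options (here, feeder colors carrying sucrose solutions
of different concentrations), and the quantity of interest is the probability
of visiting the sweeter option as a function of how discriminable the two
concentrations are.

## Stimulus scale

Discriminability is expressed as the *relative intensity* of a concentration
pair: the absolute difference divided by the mean,

$$x = \frac{|c_1 - c_2|}{(c_1 + c_2)/2}.$$

This Weber-fraction-like scale captures both the distance effect
(discrimination improves with the difference) and the magnitude effect
(discrimination worsens as both concentrations grow at a fixed difference):

```{r}
relative_intensity(30, 15)   # easy pair
relative_intensity(30, 32)   # hard pair: small difference
relative_intensity(45, 50)   # same difference, higher magnitude -> harder
```

## The psychometric function

`psy_fun()` implements a three-parameter Weibull psychometric function in the
threshold/slope/lapse parameterization of Kuss, Jäkel and Wichmann's Bayesian
psychometric framework:

$$
\Psi(x; m, s, \pi_l) = \tfrac12\Big[\pi_l + (1-\pi_l)\Big(2 -
\exp\!\big(-e^{\,\frac{2sm}{\ln 2}(\ln x - \ln m) + \ln\ln 2}\big)\Big)\Big].
$$

* the lower asymptote is fixed at 0.5 (2-AFC chance performance);
* the upper asymptote is $1 - \pi_l/2$, where $\pi_l$ is the *lapse rate*,
  the probability of responding independently of the stimulus;
* the *threshold* $m$ is the intensity at which performance is halfway
  between the asymptotes: $\Psi(m) = 0.75 - 0.25\,\pi_l$, exactly 0.75 with
  zero lapse;
* the *slope* $s$ is the derivative **of the underlying unscaled sigmoid**
  $F = 2\Psi - 1$ at the threshold. Because the 2-AFC rescaling
  $\Psi = (1+F)/2$ halves every derivative, the visible slope of $\Psi$ at
  $m$ is exactly $s/2$. This convention matters when comparing slopes across
  packages; the test suite pins it down by central differences.

```{r}
p <- psy_params(threshold = 0.25, slope = 5, lapse = 0)
psy_fun(0.25, p)                                     # exactly 0.75
h <- 1e-6
2 * (psy_fun(0.25 + h, p) - psy_fun(0.25 - h, p)) / (2 * h)  # recovers s = 5
```

`psy_inverse()` inverts the curve by bisection on $\log x$, and
`lapse_from_upper_asymptote()` converts a fitted upper asymptote back to a
lapse rate.

## Likelihood, priors and posterior

Data enter as *response records*: one row per condition with the relative
`intensity`, the count `n_sweeter` of visits to the sweeter option, and the
total `n_total`. The likelihood is binomial with success probability
$\Psi(x_i)$. Priors (chosen for concentration-discrimination data on the
relative-intensity scale, where thresholds near 0.2–0.3 and moderate slopes
are plausible while leaving the prior weakly informative) are:

* threshold: Normal(1, 0.5) truncated to $m > 0$;
* slope: Normal(2, 1) truncated to $s > 0$, or optionally flat on
  $(0, s_{\max}]$ via `flat_slope_priors()` when the slope itself is the
  quantity under study;
* lapse: Beta(2, 20).

`fit_psychometric()` samples the posterior with an adaptive random-walk
Metropolis chain on $(\log m, \log s, \operatorname{logit}\pi_l)$ (with the
appropriate Jacobian terms), initialised at the posterior mode found by BFGS
and using the Laplace-approximation covariance, scaled by $2.38^2/3$, as the
proposal. The proposal scale adapts toward a 0.3 acceptance rate during
burn-in (one quarter of the chain) and is frozen afterwards, so the retained
draws come from a valid fixed-kernel chain. Summaries are posterior means
with central 95% credible intervals; effective sample sizes come from
`coda::effectiveSize()`.

```{r}
recs <- simulate_binomial_responses(psy_params(0.25, 5, 0.15),
                                    c(0.05, 0.15, 0.25, 0.4, 0.6),
                                    n_per = 500, seed = 1)
fit <- fit_psychometric(recs, n_draws = 2000, seed = 1)
tidy(fit)
```

Two edge conventions are deliberate:

* **Zero-row data are valid** and return the prior itself; this is how the
  test suite verifies prior recovery without any special hook.
* **Uninformative data** (e.g. responses pinned at 0.5 everywhere) do not
  error; the fit is flagged `prior_dominated` in its diagnostics when the
  threshold posterior is nearly as wide as its prior.

### The grid oracle

Because MCMC output is hard to test directly, `grid_posterior()` computes the
same posterior by brute-force midpoint-rule integration over a dense 3-D
grid (log-sum-exp normalized, default bounds covering at least 99.9% of the
prior mass). It is deterministic and sampler-free, so the test suite demands
that Metropolis posterior means agree with the grid means to within three
Monte-Carlo standard errors across many seeds. `verify_resolution = TRUE`
guards the oracle itself: the grid is recomputed at half resolution and an
error is raised if the integrated mass or any posterior mean shifts by more
than 1%.

```{r}
grd <- grid_posterior(recs, resolution = 61)
tidy(grd)
```

## Reducing visitation event logs

Automated feeder arrays produce time-stamped visit events rather than tidy
binomial counts. The reduction pipeline makes the following choices, each a
function argument rather than a constant:

* **Plateau filtering** (`plateau_filter()`): the first 800 visits of each
  bee on each day are discarded as the learning/exploration phase, and only
  bees that exceed the cutoff contribute. The cutoff is applied *per day*,
  not cumulatively, because daily reversals reset the task. Unmarked bees
  are recorded under one pooled label; their cutoff scales with the
  estimated number of unmarked foragers (`estimate_unmarked_count()`, the
  ratio of unmarked visits to the mean marked bee's daily visits).
* **Daily responses** (`daily_response()`): the proportion of plateau visits
  to the day's sweeter color. Days without qualifying visits yield explicit
  missing values, never 0 or 0.5.
* **Reversal pooling** (`combine_reversal_pairs()`): the two presentations
  of a concentration pair (colors exchanged on consecutive days) are pooled
  by summing counts — a visit-weighted average of the two daily responses —
  which cancels color and position biases.
* **Concordance** (`marked_unmarked_concordance()`): Spearman rank
  correlation between marked and unmarked daily responses, with midranks for
  ties and the S statistic computed as $(1-\rho)\,n(n^2-1)/6$ so that tied
  data produce the fractional S values that rank-based formulas imply.
* **Sequential analyses**: `nonreward_analysis()` compares the proportion of
  non-rewarded visits at the two feeder classes by paired t test across days
  (zero-variance difference series are flagged, not raised);
  `shift_probability_analysis()` estimates, within each qualifying bee's
  early visit stream, the probability of switching away from the
  higher-concentration color after reward histories RR, RN and NN, and runs
  the two paired contrasts (NN vs RN; NN vs RR) that a lose-shift account
  predicts to be positive. `learning_curve()` tracks acquisition in
  100-visit bins.

## The pooling slope-bias experiment

Averaging choice data across individuals that share a slope but differ in
threshold produces a pooled curve that is *shallower* than any individual
curve, so refitting the averaged data underestimates the common slope while
leaving threshold and lapse essentially unbiased. `run_pooling_experiment()`
demonstrates this with 7 individuals (thresholds of mean 0.25 and SD 0.057,
slope 5, lapse 0.15), probed at intensities 0.05–0.6 with 200 visits each
and refit under a flat slope prior (so the shrinkage cannot be blamed on the
prior).

Two determinism choices: the default thresholds are an evenly spaced
symmetric set rescaled to the exact target mean and SD, and the pooled
counts are noise-free expected counts — so the experiment is exactly
reproducible and the bias is attributable to heterogeneity alone. Pass
`thresholds =` (e.g. a normal draw) or `sample_counts = TRUE` to add back
either source of randomness.

```{r}
pool <- run_pooling_experiment(n_draws = 1500, seed = 2)
glance(pool)   # fitted slope well below the true common slope of 5
```

## The synthetic colony generator

`simulate_colony()` generates event streams for end-to-end validation with
the following assumptions, which are deliberately simple and stated here as
limitations:

* per-bee daily visit counts are log-normal, moment-matched to a target mean
  and SD (defaults 1076 and 642, typical of committed foragers on automated
  arrays);
* visit times are uniform over a 12-h session — a Poisson visit process
  conditioned on its count — with no within-day tempo structure;
* each visit's color is an independent Bernoulli draw from the bee's
  psychometric curve at the day's intensity (optionally approached from
  chance through an exponential learning ramp, `learning_tau`);
* rewards are replayed feeder by feeder: a visit is non-rewarded exactly
  when the feeder delivered within the preceding refill delay (10 s
  default), so non-reward rates emerge from forager density rather than
  being sampled;
* no spatial structure beyond the two color classes, and no interaction
  between bees other than competition for refills.

These are sufficient for validating the pipeline and fits (choice
frequencies, reward bookkeeping, learning curves, recovery of generating
parameters) but are not a behavioral model of foraging.

```{r}
cfg <- sim_colony_config(reversal_schedule(list(c(30, 15), c(45, 30))),
                         n_marked = 2, n_unmarked = 5,
                         visits_mean = 300, visits_sd = 80)
ev <- simulate_colony(cfg, seed = 3)
combine_reversal_pairs(daily_response(ev, cfg$schedule))
```

## Problem sizes

The defaults are sized so that every analysis runs on a laptop in seconds to
a few minutes: chains of 5000 draws (one quarter burn-in) for production
fits, grid oracles of about $100^3$ cells, event streams of $10^4$–$10^5$
visits per colony-day. All stochastic entry points accept a `seed` and are
bit-reproducible under it.
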