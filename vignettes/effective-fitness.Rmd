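---
title: "Effective fitness under fluctuating selection with drift: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effective fitness under fluctuating selection with drift: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(effsel)
```

## The problem

The fitness of a mutant allele usually varies through time as the
environment changes. The standard one-number summary of such fluctuating
selection is the geometric mean fitness over $n$ generations,
$f_G = (\prod_{i=1}^n f_i)^{1/n}$. Without genetic drift this summary is
exact: the odds of the mutant frequency multiply by $f_i$ each generation,
so any fitness sequence with the same $f_G$ produces the same final
frequency (the multiplicability of relative fitness). With drift, however,
$f_G$ becomes a biased guide to what selection actually did to the allele,
because the *effect* of a generation's fitness on the allele frequency
depends on the frequency the allele happens to have that generation — and
drift randomises that frequency.

This package implements the machinery to study this effect in a haploid
Wright–Fisher population: an exact per-generation decomposition of
frequency change into selection and drift components, the effective
fitness $f_E$ built from that decomposition, the relative selection effect
$C$, exact binomial-expectation calculations for the two-generation case,
and batch experiment drivers.

## Model and decomposition

One generation at frequency $q$ with mutant relative fitness $f$ proceeds
as deterministic selection followed by binomial sampling of $N_e$
offspring:

$$p = \frac{qf}{1 + q(f-1)}, \qquad m' \sim \mathrm{Binomial}(N_e, p),
\qquad q' = m'/N_e.$$

The package records, for every generation,

* $\Delta_s = p - q$ — the expected frequency change caused by selection
  given $(q, f)$, equal to $q(1-q)(f-1)/(1+q(f-1))$;
* $\Delta_d = q' - p$ — the binomial sampling residual, i.e. drift.

By construction $q' - q = \Delta_s + \Delta_d$ holds exactly (it is
asserted to machine precision in the test suite). At the absorbing states
$q \in \{0, 1\}$ both components are defined to be 0 and simulation stops:
an absorbed allele experiences neither selection nor drift. The model is
haploid with non-overlapping generations and census size equal to $N_e$;
diploidy, mutation, migration, linkage and varying $N_e$ are out of scope.

## The statistics

Over any observed stretch of a trajectory (from emergence to absorption,
or any period in between):

* **Geometric mean fitness** $f_G = \exp(\tfrac1n \sum \log f_i)$,
  computed in log space.
* **Effective fitness** $f_E = (0.5 + \bar\Delta_s)/(0.5 - \bar\Delta_s)$,
  where $\bar\Delta_s$ is the mean per-generation selection component: the
  constant fitness that would move an allele at frequency $0.5$ (where
  selection has maximal leverage) by $\bar\Delta_s$ per generation.
* **Relative selection effect**
  $C = \sum\Delta_{s,i} \,/\, (|\sum\Delta_{s,i}| + |\sum\Delta_{d,i}|)
  \in [-1, 1]$, the signed share of selection in the total change; $C$ is
  undefined (`NA`) when both totals are zero, and $|C| < 0.05$ (strict
  inequality, matching the notation $|C|<0.05$) is the default call of
  *effective neutrality*.

Two predictors reconstruct a final frequency from a summary alone:
$q_G = q_0 f_G^n / (1 + q_0(f_G^n - 1))$ and
$q_E = q_0 + n(f_E-1)/(2(f_E+1))$. $q_E$ is deliberately **not clamped**
to $[0,1]$: the linear predictor has no clamp in its derivation, and
clamping would silently shrink its error in exactly the situations the
bias/variance comparison is about. A warning flags out-of-range values.

A boundary-generation convention: the generation in which the allele fixes
or is lost contributes its $\Delta_s$ (computed from the last interior
frequency). Whether that generation should count is not determined by the
definitions; including it keeps the identity
$\sum\Delta_d = (q_{\text{final}} - q_0) - \sum\Delta_s$ exact over the
whole trajectory.

## Why f_G is biased under drift: the exact two-generation computation

For two generations with fitness $f_1$, $f_2$, the expected frequency with
drift is
$E(q_2) = \sum_{i=0}^{N_e} \Pr(m_1 = i)\, F(i/N_e)$ with
$F(x) = x f_2/(1+x(f_2-1))$. Because $F$ is strictly concave for $f_2>1$
and strictly convex for $f_2<1$, Jensen's inequality forces
$E(q_2) < q_2'$ if $f_2 > 1$ and $E(q_2) > q_2'$ if $f_2 < 1$, where
$q_2'$ is the drift-free value; the direction depends only on $f_2$.
Rather than relying on the analytic argument, `exact_expected_q2()`
evaluates the sum exactly (an $O(N_e)$ enumeration, no normal
approximation, enforced cap $N_e \le 10^5$), and the test suite verifies
the sign pattern exhaustively over a grid of $(N_e, q_0, f_1, f_2)$. The
companion linear-rule enumeration (replacing $F$ by $x f_2$) reproduces
the drift-free value exactly, locating the bias entirely in the
nonlinearity of $F$.

`g_function()` reparameterises $f_1 = e^x f_G$, $f_2 = e^{-x} f_G$ and
evaluates $E(q_2)$ as a function of the spread $x$;
`monotonicity_scan()` checks strict monotonicity of the sampled curve
($x$ from $-1$ to $1$ in steps of $0.02$) over three one-parameter sweeps
($q_0$ from 0.1 to 0.9; $\log_2 f_G$ from $-1$ to $1$; $N_e$ from 1,000 to
10,000). Monotonicity implies $G(x) \ne G(0)$ for $x \ne 0$: no genuinely
fluctuating scenario reproduces the constant-$f_G$ expectation.
Monotonicity is judged on the sampled grid — the same numerical procedure
the question admits short of a symbolic proof, which is known to be hard;
a 10× finer grid cross-check at small $N_e$ is part of the tests. The
three sweeps contain 30 rows, of which 29 are unique parameter
combinations (the $q_0$ and $N_e$ sweeps share their centre point); the
scan reports all 30. The direction of monotonicity is reported, not
asserted, since no particular sign is claimed.

## Fitness regimes

Regimes map (generation, current frequency, internal state, randomness) to
that generation's fitness. Besides constant, block and alternating
regimes, three deserve notes:

* `regime_markov_switch(f1, f2, switch_prob)` — initial state equiprobable,
  then a Bernoulli(`switch_prob`) switch applied *before* selection from
  generation 2 onward (the randomly assigned initial fitness *is*
  generation 1's fitness). With `switch_prob = 0.05` the waiting time
  between switches is geometric with mean 20 generations. A description of
  this regime as "switching after $t \sim$ Poisson(20) generations" also
  circulates; the Bernoulli/geometric mechanism is the implemented
  default, and `regime_poisson_block()` provides the Poisson-waiting-time
  variant for comparison.
* `regime_frequency_dependent(1.01, 0.9, 0.99)` — beneficial at
  intermediate frequencies, deleterious only above frequency 0.99. This is
  the showcase regime in which an allele can fix while $f_G < 1$: negative
  selection acts only where drift dominates ($q > 1 - 1/(N_e|s|)$), so it
  barely affects the outcome, yet it drags the unweighted product of
  fitness down.
* `regime_target_delta(schedule)` — each generation the fitness is
  recomputed from the *current* frequency via
  `fitness_for_delta(q, delta)` $= 1 + \delta/(q(1-q-\delta))$, so the
  realised $\Delta_s$ equals the schedule regardless of drift. This is how
  $f_E = 1$ is engineered exactly (e.g. $\Delta_s = -0.045$ for $n$
  generations then $+0.045$ for $n$). When drift pushes $q$ to where
  $q + \delta$ leaves $(0,1)$ no fitness can achieve the target:
  single-run simulation raises an error naming the generation; the batch
  drivers count such replicates as discards, alongside replicates absorbed
  before the horizon.

## The experiments and their parameter choices

All defaults are the canonical conditions of the study the package
reproduces; they were chosen once and are not tuning knobs.

1. **Controlled $f_G = 1$ / $f_E = 1$** (`run_fg1_fe1_experiment()`):
   $N_e = 1000$, $q_0 = 0.5$, horizons $2n$ for $n = 1..7$, 500,000
   replicates per $n$, fitness $5/6$ then $6/5$ (block), alternating, the
   linear-rule control, or the $\pm 0.045$ target-delta schedule. The
   $\Delta_s = 0.045$ magnitude corresponds to fitness
   $(0.5+0.045)/(0.5-0.045) \approx 5/6$ at $q = 0.5$, making the two
   arms comparable. Early-absorbed runs are discarded but counted; at
   these parameters absorption from 0.5 within 14 generations essentially
   never happens. A two-sided one-sample t-test against 0.5 is reported
   per $n$; the significance level is 0.05 (the conventional level;
   asterisks in the original figures do not state one).
2. **Conditional final-frequency prediction**
   (`run_conditional_frequency_experiment()`): Markov-switching fitness
   $11/10 \leftrightarrow 10/11$, 200 generations, $q_0 = 0.01$ or 0.5;
   the first 500 runs whose final copy number is exactly $0.1 N_e, \dots,
   0.9 N_e$ ("exactly 0.100" is well defined because frequencies live on
   the $1/N_e$ lattice). Bias, bias², variance and MSE of $q_G$ and $q_E$
   are reported per bin; MSE $=$ bias² $+$ variance holds to $10^{-12}$ by
   construction (population variance over runs). "First 500" is well
   defined given the seed because replicates are generated in batches with
   a global run counter.
3. **Outcome prediction** (`run_outcome_prediction_experiment()`): runs to
   absorption, ROC AUC of $f_E$ and $f_G$ with fixation as the positive
   class, computed by the rank-sum (Mann–Whitney) statistic with midrank
   tie handling; the test suite checks it against an explicit
   threshold-sweep trapezoid oracle. The contradiction subsets
   ($f_E>1\ \&\ f_G<1$, and the reverse) are collected from the same run
   stream. At $q_0 = 0.01$ fixations are rare and essentially all carry
   $f_G > 1$, so the contradiction analysis is run at $q_0 = 0.5$ — the
   setting in which the original analysis presents it, immediately after
   noting that the AUCs themselves are nearly tied there.
4. **New mutations** (`run_new_mutation_experiment()`): a single copy,
   run to absorption; among losses the fractions with $|C| < 0.5$ and
   $|C| < 0.05$, among fixations the fractions with $C > 0.5$ and
   $f_E > 1$. Collecting fixations is $\sim N_e$ times more expensive than
   losses, so the fixation quota is configurable (and 0 where only losses
   are analysed).

```{r, fig.width = 6, fig.height = 3.5}
traj <- wf_sim(ne = 1000, init_freq = 0.5,
               regime = regime_markov_switch(11/10, 10/11, 0.05),
               max_generations = 200, seed = 42)
plot(traj, main = "Markov-switching fluctuating selection")
summary(traj)
```

## Randomness, seeds and reproducibility

Every simulating function takes a `seed`; identical (configuration, seed)
pairs give identical results on a platform (R's binomial sampler is
deterministic given the stream). Batch drivers use one seeded stream per
experiment rather than one stream per replicate: per-replicate seeding
would force scalar loops and give no additional guarantee, since
replicate order within the vectorised stream is fixed and recorded.
Cross-platform agreement is distributional, not bitwise.

## Numerical choices and degenerate inputs

* Frequencies are kept on the $1/N_e$ lattice (copy counts divided by
  $N_e$); serialisation writes frequencies at full precision plus the
  lattice size, so files round-trip exactly.
* `effective_fitness()` rejects $|\bar\Delta_s| \ge 0.5$ (unreachable for
  per-generation components, which are bounded below 0.5 in magnitude at
  the fitness values used).
* The linear rule clamps $p = qf$ into $[0,1]$. The clamp cannot trigger
  in the canonical experiment (starting at 0.5 for at most 14
  generations, reaching $q > 5/6$ is a $\sim 10\sigma$ drift excursion);
  it exists, and is tested, so the rule is total.
* An empty fitness sequence, a trajectory with zero generations, or both
  change-totals zero (undefined $C$) are surfaced as errors or `NA`, never
  silently defaulted.

## What the generator emulates, and what a green test does not establish

The synthetic worlds here are exactly the stated simulation conditions:
Wright–Fisher binomial resampling, the named fitness regimes, the stated
$N_e$, initial frequencies and replicate counts. They do not emulate
features of real populations — overlapping generations, diploidy and
dominance, linked selection, demographic change — so green tests establish
correctness of the implementation and reproduction of the simulated
phenomena, not empirical claims about natural populations. Statistical
assertions on stochastic outputs use fixed seeds with margins chosen from
the measured sampling noise (3 Monte-Carlo standard errors, binomial
confidence intervals, or a joint chi-square consistency check where a
single fixed-seed t-test would raise false alarms at its nominal rate).

Two scale choices are worth recording. The alternating-regime bias at
$n = 7$ is about $-2.8\times10^{-4}$ (measured at 2 million replicates),
with standard error $2.7\times10^{-4}$ at 50,000 replicates: a tenfold
scaled-down run has only ~15% power to detect it, so the significance
assertions for the block and alternating scenarios are run at the full
500,000 replicates (seconds of compute) rather than at a reduced scale.
And among fixations under the frequency-dependent showcase regime, runs
with $f_G < 1$ are a minority (roughly one in ten): the classic
"fixes despite $f_G<1$" trajectory is an illustrative, not typical,
outcome, so the tests assert its existence and the behaviour of $f_E$ and
$C$ on it, not its prevalence.

## Known limitations

* Haploid, constant $N_e$, non-overlapping generations only.
* `exact_expected_q2()` covers two generations; longer horizons are
  handled by simulation, not enumeration (the state space grows as
  $N_e^n$).
* Monotonicity of $G(x)$ is established numerically on the stated grids,
  not proved.
* The small residual bias of $f_E$-based prediction for conditioned final
  frequencies (an ascertainment effect of conditioning on survival) is
  reported as measured; no correction is attempted.
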