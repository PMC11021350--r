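---
title: "State-trace analysis by conjoint monotonic regression: methods"
author: "statrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-trace analysis by conjoint monotonic regression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statrace)
```

This vignette documents the statistical model, the numerical algorithms, and
the design decisions behind the package, including the known limitations of
the bootstrap test.

# The model

Let $c = 1, \dots, n$ index experimental conditions and let $x_c$, $y_c$ be
the condition means of two dependent variables. The *one-latent-dimension*
hypothesis states that there is a latent variable $\theta$ and monotone
functions $f$, $g$ such that $E[x_c] = f(\theta_c)$ and $E[y_c] =
g(\theta_c)$. A direct consequence is *joint monotonicity*: some total order
of the conditions makes both mean vectors simultaneously weakly monotone. In
the state-trace plot of $y$ against $x$, the $n$ points then lie on a single
monotone curve. (Jointly *decreasing* relations are covered automatically:
reversing the order flips both directions.)

## The conjoint monotonic regression statistic

Given precision weights $w^x_c$, $w^y_c$, the misfit of an order $\pi$ is

$$ S(\pi) \;=\; \min_{u \in M(\pi)} \sum_c w^x_c (x_c - u_c)^2
            \;+\; \min_{v \in M(\pi)} \sum_c w^y_c (y_c - v_c)^2, $$

where $M(\pi)$ is the cone of vectors weakly non-decreasing along $\pi$. Each
inner minimisation is a weighted isotonic regression, solved exactly by the
pool-adjacent-violators algorithm (PAVA). The test statistic is

$$ T \;=\; \min_\pi S(\pi), $$

which is zero exactly when the data are jointly monotone. Weights default to
$w_c = n_c / s_c^2$ (participants over variance), so $1/\sqrt{w_c}$ is the
standard error of the condition mean and $T$ is a sum of squared
standard-error-scaled deviations — comparable across analyses.

# Numerical core

All inner loops are compiled (C++ via Rcpp).

## Weighted PAVA

The pool-adjacent-violators algorithm maintains a stack of blocks with
weighted means; a violating adjacent pair is merged and the merge cascades
backwards. It returns the exact minimiser of the weighted least-squares
problem over the monotone cone in $O(n)$ after the ordering. The
implementation is allocation-free in the bootstrap path (scratch buffers are
reused across replicates).

Correctness is verified in the test suite against two independent oracles: a
pure-R reference implementation and the order-constrained quadratic program
solved by `pracma::quadprog` (minimise $\|v - u\|^2_w$ subject to the chain
constraints $u_1 \le u_2 \le \dots \le u_n$).

## Search over orders

$T$ minimises over $n!$ orders. Three strategies are provided, selected
automatically by problem size:

- **Exhaustive** ($n \le 8$): all permutations via Heap's algorithm. Exact.
- **Branch and bound** ($n \le 14$ by default): depth-first search over order
  prefixes. The bound is the *prefix isotonic misfit*: the combined PAVA SSE
  of the conditions placed so far, ignoring the unplaced conditions. This is
  a valid lower bound because the optimal full-order solution, restricted to
  the prefix, is a feasible (monotone) fit for the prefix-only problem, so
  the prefix optimum cannot exceed the restriction's cost — and PAVA misfit
  only grows as conditions are appended. An incumbent from the heuristic
  search primes the pruning. Exact.
- **Multistart local search** (larger $n$, e.g. the package's own
  20-condition design): first-improvement hill climbing over the *insertion*
  neighbourhood (remove one condition, reinsert it at every other position),
  started from deterministic rank-based orders (by $x$, by $y$, by their
  average, and reverses) plus random restarts. Heuristic; results are flagged
  `exact = FALSE`. On jointly monotone data it always attains the true zero
  (any sorting start is already optimal), and on 10-condition random
  instances it matches branch-and-bound in the test suite.

Exactly monotone data can leave $O(\epsilon)$ floating-point residue in the
block-sum arithmetic, so a fit below $10^{-10} \times
(\sum w^x x^2 + \sum w^y y^2)$ is snapped to exactly zero; the null-behaviour
guarantee (`fit_stat == 0`, `p == 1`) is exact, not approximate.

# The bootstrap test

`fit_stat` has no pivotal reference distribution (it depends on the unknown
true means through the geometry of the monotone cone), so the package tests
the null by resampling recentred on the fitted model:

1. Fit CMR to the observed means; keep the fitted monotone values
   $\hat\mu^x, \hat\mu^y$ and the observed weights.
2. Generate $B$ replicate datasets whose *expected* condition means are the
   fitted values:
   - `participant_resample`: resample participants with replacement,
     recompute condition means, and recentre,
     $x^*_c = \bar{x}^{(b)}_c + (\hat\mu^x_c - \bar{x}_c)$;
   - `parametric_normal`: draw $x^*_c \sim N(\hat\mu^x_c, 1/\sqrt{w^x_c})$
     (used by `cmr_from_summary()` when only published means/SDs/ns exist).
3. Recompute $T^*$ for each replicate with the **same weights** as the
   observed statistic, and report the add-one p-value
   $p = (1 + \#\{T^* \ge T\}) / (B + 1)$, which is never exactly zero.

**Why the weights stay fixed.** The statistic is a weighted least-squares
criterion; the weights are constants of that criterion, not parameters being
tested. Re-estimating them from each resample adds sampling noise of the
variance estimates into $T^*$ and measurably inflates its upper tail (in our
diagnostics at $n = 50$ participants, the 95th percentile of $T^*$ dropped
from 18.6 to 16.1 when weights were held fixed, against 14.2 for the true
sampling distribution of $T$).

## Known conservativeness

The recentred bootstrap is *conservative* when the true means are strictly
monotone. The reason is geometric: the constrained fit $\hat\mu$ is a
projection onto the monotone cone and generically contains ties (flat blocks)
created by noise. Resampling around a tied configuration produces more
order violations — hence larger $T^*$ — than sampling around the true,
strictly ordered means does. The test is exact at the least-favourable null
configuration (all means equal; verified by simulation with a flat latent
profile) and increasingly conservative the deeper the truth lies inside the
cone. In calibration runs under the package's one-latent generator
($n = 50$, $B = 199$, 200 datasets), the empirical type-I error at
$\alpha = .05$ was 0–0.005 rather than the nominal .05, and the smallest
null p-value was about 0.10.

Two standard remedies were evaluated and rejected: a fast double bootstrap
does not help, because the tie-inflation mechanism reproduces itself at the
second resampling level; and recentring on a strictly-monotonised fit would
make the test anti-conservative for truths near the cone boundary. We accept
the conservative behaviour as the inferentially safe direction — size is
controlled everywhere, so rejections can be trusted — and flag that the test
is under-powered for departures close to the null. The power study shows this
costs little at realistic effect sizes: at the generator's `"large"`
departure preset and 114 participants, all three Bonferroni-adjusted
p-values fall below .05 in every simulated dataset.

## Multiplicity

With three probe types there are three pairwise analyses
(`think`–`feel`, `do`–`feel`, `think`–`do`); `run_three_analyses()` applies
Bonferroni correction with $m = 3$ (`adjust_pvalues()`).

# The item-response pipeline

The pipeline reduces long-format yes/no/don't-know item responses to the
20-condition state-trace design: 5 exchange types (sincere, simple sarcasm,
paradoxical sarcasm, enriched sarcasm, lying) × 2 item types (target, lure)
× 2 emotion-perception groups (between subjects).

- *Screening*: "don't know" responses are removed before scoring; the
  reported percentage uses all input rows as its base, and the scored-probe
  count (93 per participant under the 31-scene layout) is reported
  separately.
- *Endorsement*: the proportion of "yes" among yes/no responses per
  participant × exchange × question × item cell.
- *Grouping*: median split of the emotion-perception scores, **ties to the
  low group**; the generator uses the identical rule, so simulated group
  membership is recovered exactly.
- *Design build*: per-participant condition vectors back each condition mean
  (participants contribute only to their own group's 10 conditions);
  participants missing more than 20% of their cells are excluded wholesale;
  every condition requires at least two contributors. Cell variances are
  floored at $10^{-4}$ so precisions stay finite for degenerate cells.

# The synthetic generator

The generator exists to validate the whole pipeline against a known ground
truth, so its realism targets the *structure*, not psychological fidelity:

- A latent value $\theta_c$ per condition (default: an exchange-type effect
  spanning $[-0.5, 0.5]$, $\pm 1.6$ for target vs lure, $\pm 0.25$ for
  group), mapped through per-probe logistic links
  (`think`: slope 1, intercept 0; `do`: 0.9, −0.1; `feel`: 1.1, 0.1) to
  endorsement probabilities; binomial responses per item; participant random
  intercepts (SD 0.3) induce realistic within-condition variance; a small
  don't-know rate (0.4%) exercises the screening step.
- Under `one_latent`, all three probe types are monotone in the same
  $\theta$, so the population `fit_stat` is exactly zero for every DV pair
  (verified in the tests by exhaustive search on subdesigns).
- Under `two_latent`, a second dimension perturbs the latent values by
  $\pm\delta$ with signs alternating along the rank order of $\theta$ and
  loadings $(0, -1, +1)$ for (think, do, feel) — this guarantees crossing
  (non-monotone) population curves for *all three* DV pairs whenever
  $\delta > 0$. The presets `small`/`medium`/`large` = 0.25/0.5/1.0 on the
  latent scale were tuned once during development and frozen.
- Emotion-perception scores are drawn from two normals
  (high: M 24.92, SD 0.96; low: M 20.90, SD 2.50, rounded and clipped to
  0–28), and the *generating* groups are defined by the generator's own
  median split of the drawn scores. This makes the pipeline's split recover
  the generating groups exactly, keeping the one-latent null exact at
  population level; a misclassification mixture would otherwise bias the
  calibration study.

Limitations: items within a cell are conditionally independent given the
participant intercept (no scene-level effects), the links are logistic by
construction, and the two-latent perturbation is a stylised crossing pattern
rather than a cognitive model of dissociation.

# Reproducibility

Every stochastic entry point takes a `seed`; `run_three_analyses()` derives
one seed per analysis from its master seed. Reports (`write_report()`)
contain the seed, mode, replicate count and package version, carry no
timestamps, and are byte-identical under identical inputs —
`scripts/acceptance.R` checks this end to end.
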