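---
title: "Stochastic models of shadow enhancer noise and fidelity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic models of shadow enhancer noise and fidelity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancerNoise)
```

## The model

Shadow enhancers are sets of two or more enhancers that regulate the same
gene with overlapping activity. `enhancerNoise` asks what such architectures
buy a developing organism in terms of two performance measures of
transcription:

* **noise** — the coefficient of variation of stationary mRNA copy number,
  $\mathrm{CV} = \sigma_R / E[R]$, and
* **fidelity** — the stationary Pearson correlation between a transcription
  factor's free copy number and the mRNA,
  $\mathrm{Corr}(T_1, R) = \mathrm{cov}(T_1, R)/(\sigma_{T_1}\sigma_R)$.

A system is declared by the number of enhancers and, per enhancer, the
number of binding sites for each TF type. The declarative configuration is
compiled into an explicit mass-action chemical reaction network:

* Each enhancer with $k$ binding sites is represented by $2^k$ *occupancy
  state* species $A_I$, where $I$ is the bound/unbound bit pattern over its
  sites. Exactly one occupancy species per enhancer carries a copy at any
  time (a conservation group). This state-species formulation keeps every
  reaction at most bimolecular, which is what the moment machinery requires.
  The builder refuses more than 12 sites per conservation group, since the
  state count grows as $2^k$.
* A free TF $T_m$ binds an empty site ($T_m + A_I \to A_{I+e_j}$ at rate
  $k_{\mathrm{on},m}$, per molecule) and unbinds at $k_{\mathrm{off},m}$.
* TFs are produced in bursts of fixed size $n_m$ at a constant rate and
  degrade linearly — bursty synthesis is required to reproduce the reference
  expression data the default rates were fitted to.
* Each occupancy state with a positive transcription rate fires a catalytic
  mRNA production reaction; mRNA degrades at rate $\alpha$.

The default rate constants are the set fitted to *Kruppel* expression data
(`default_parameters()`): TF 1 binds at 0.36 and unbinds at 1.8, arrives in
bursts of 4 at rate 0.33 and decays at 2.7; TF 2 binds at 0.19, unbinds at
1.5, bursts of 12 at rate 0.29, decay 3.9; transcription contributes 120
(TF 1) or 140 (TF 2) mRNA per time unit per bound site and mRNA decays at
1.96. All rates share one consistent arbitrary time unit; no unit conversion
happens anywhere.

## Interaction regimes

The transcription rule and the binding kinetics encode five regimes:

* **additive** — an enhancer with $n$ bound TF 1 and $m$ bound TF 2
  transcribes at $n r_1 + m r_2$, and enhancers sum. A single enhancer with
  four bound TF 1 sites therefore produces exactly as much mRNA as four
  single-site enhancers.
* **subadditive / superadditive** — the same additive transcription rule,
  but the binding kinetics shift linearly with the total enhancer count
  $n$: subadditive systems use $k_{\mathrm{on}} - n d_1$ and
  $k_{\mathrm{off}} + n d_2$, superadditive systems flip the signs. The
  default coefficients are $d_1 = (0.04, 0.02)$, $d_2 = (0.75, 0.75)$
  (subadditive) and $d_1 = (0.01, 0.01)$, $d_2 = (0.4, 0.3)$
  (superadditive), per TF type. Modulation is applied exactly once per
  network build — a guard flag makes double application an error — and a
  shift that drives any rate negative is a hard error, never clamped; the
  linear scheme is known to break down at large enhancer counts, and
  flagging is the honest behavior.
* **saturation** — transcription proceeds at a fixed rate $r$ whenever at
  least one enhancer has a bound TF.
* **synergy** — transcription requires every enhancer to have a bound TF.

Saturation and synergy couple all enhancers through an indicator over the
*joint* occupancy, which cannot be written as a mass-action propensity of
order two over per-enhancer species. For those two regimes the builder
therefore enumerates the joint product state space as a single conservation
group. The master equation is identical either way; only the species
bookkeeping differs. Because the underlying description says only "a single
type of transcription factor", these regimes default to one TF type with the
TF 1 kinetics and $r = r_1$; both are exposed (`sat_rate`, and the
parameter set) rather than hard-coded.

## Moment closure

Stationary moments are computed by integrating coupled ODEs for all raw
moments up to order 2 (optionally 3) under **zero-cumulant (Gaussian)
closure**. For mass-action propensities $a_r(x) = c_r \prod x$ with
stoichiometry $s_r$,
$$\frac{d E[x^\mu]}{dt} = \sum_r E\!\left[a_r(x)\left(\prod_{i\in\mu}(x_i +
s_{ri}) - x^\mu\right)\right],$$
which closes except that bimolecular binding propensities push moments one
order above the truncation. Those are eliminated by setting the
corresponding cumulant to zero; at order 2 this is the identity
$E[xyz] = E[x]E[yz] + E[y]E[xz] + E[z]E[xy] - 2E[x]E[y]E[z]$
(`close_third_moment()`), and at order 3 the fourth raw moment is rebuilt
from the 14 proper set partitions of its indices with the fourth cumulant
zeroed. Networks with only constant and first-order propensities close
exactly, which provides the package's sharpest correctness oracle: on the
birth–death, bursty and telegraph fixtures the solver must reproduce the
closed-form stationary laws to the integration tolerance.

Implementation choices that were genuinely open:

* **Raw moments, not central moments.** The fluctuation term
  $\sum_r s_r s_r^{\mathsf T} E[a_r]$ stays trivially simple and burst
  stoichiometry ($s = n_m$) enters as $n_m^2$ without extra bookkeeping.
* **Numeric assembly, not symbolic math.** The right-hand side is a single
  sparse matrix product over a vector of dynamic and closed moments, built
  index-wise from the stoichiometry. This scales to the largest grid models
  (19 species, 209 moment ODEs at order 2) at a few seconds per solve.
* **Stationarity by long-time integration** (lsoda, in geometrically
  growing chunks) rather than algebraic root finding — closed moment
  systems can have spurious roots, while integration from the physical
  initial condition (all enhancers empty, zero copies) tracks the physical
  branch. Convergence is declared when the relative right-hand-side norm
  $\max_i |\dot y_i| / \max(|y_i|, 1)$ falls below `tol` ($10^{-8}$ by
  default); failure to converge by `t_max` ($10^4$) is an error that
  carries the last state.
* **Pathology flagging.** Gaussian closure can produce negative variances
  at very low copy numbers. Such states are flagged, never truncated, and
  the metric functions refuse them.

The closure is an approximation: on the one-site single-TF enhancer its CV
and fidelity sit within 15% of the exact truncated-master-equation values
(the test suite certifies this), and the bias is systematic — it does not
shrink with more Monte Carlo effort. Sampling-based cross-checks therefore
compare at that certified accuracy level rather than at Monte Carlo
standard-error resolution.

## Stochastic simulation

`gillespie_simulate()` is a direct-method SSA — exact sampling of the
network's master equation, no tau-leaping; the networks are small and
exactness is the point. Trajectories are recorded on a regular grid
(default 0.5 time units). `ensemble_stats()` combines ensemble and time
averaging: each trajectory is averaged over `[burn_in, t_end]` (defaults
100 and 500; the slowest fixture relaxation time is about 0.5, so the
burn-in is conservative) and per-trajectory batch estimates give Monte
Carlo standard errors. Per-trajectory seeds derive deterministically from
`base_seed`, so a full ensemble is reproducible from its arguments. Both
time-averaged and ensemble-at-fixed-time readings of "average" are
available — time averaging is the default, fixed-time sampling is a
one-line `gillespie_simulate()` loop as used in the test suite's
goodness-of-fit check.

## Oracles and what passing tests show

The package generates its own benchmarks (`make_fixture()`): birth–death
(Poisson law), bursty birth–death (mean $n\beta/\delta$, Fano $(n+1)/2$),
the two-state telegraph promoter, the one-site enhancer, and the reference
two-enhancer system. Three independent routes — closed forms, the exact
stationary solve of the truncated master equation
(`solve_cme_truncated()`, reflecting truncation, sparse direct solve,
boundary mass reported as a truncation diagnostic, default bounds from a
pilot SSA run at mean + 10 SD), and SSA ensembles — must agree on every
fixture that supports them. These fixtures emulate the copy-number scales
and burstiness of the fitted system; they do not emulate extrinsic noise,
cell-to-cell variability, or spatial context, so passing tests certify the
solvers and the model construction, not the biology of any particular
locus.

## The comparative experiments

`enumerate_configurations(4, 4, 2)` generates the deduplicated grid of all
systems with up to four enhancers and up to four total binding sites (55
configurations; enhancer order is never meaningful and configurations are
canonicalized by sorting site-count vectors). `run_sweep()` evaluates a
configuration list under one method, recording flagged failures rather than
dropping them. `duplication_series()` contrasts the two origin scenarios
for shadow enhancers: duplication multiplies a single enhancer (sites and
enhancer count grow together) while splitting deals a fixed site pool —
the duplication end point's pool — across a growing number of enhancers,
as evenly as possible, so the two series coincide at the final step.
`randomize_parameters()` redraws all rates log-uniformly (binding rates
from 0.1–10, transcription rates from 10–1000, everything else from
0.1–100, burst sizes rounded to integers of at least 1) for robustness
checks. `trend_report()` turns group means into direction verdicts — the
sign of a Spearman correlation, with relative spreads below $10^{-3}$
declared flat, a tolerance suited to deterministic closure output where
true invariances hold to $10^{-11}$ — and marks claims with fewer than two
usable groups untestable rather than failed. `standard_trend_suite()`
bundles the canonical claims: subadditive noise rises with enhancer count,
superadditive noise and fidelity fall, additive systems are flat,
saturation trades the opposite way from synergy, and duplication of a
subadditive enhancer raises fidelity and output while noise falls.

Two caveats discovered while building the suite are worth recording. First,
equality of noise across additive systems with the same per-TF site totals
is a statement about stationary moments, not about network isomorphism —
one enhancer with two sites and two one-site enhancers have genuinely
different species sets — so the invariance is verified numerically (it
holds to about $10^{-11}$ relative) rather than by canonical-form equality,
which is reserved for enhancer reordering. Second, under randomized
parameters individual trend claims can genuinely reverse or flatten,
especially fidelity claims when the fixed modulation coefficients are small
relative to a large random binding rate; the robustness check therefore
asserts a majority of verdicts, logging exceptions, rather than demanding
unanimity.

## Problem sizes and defaults used by the shipped checks

The shipped tests and the acceptance script use: the full 55-model additive
grid at closure order 2; truncated-master-equation boxes of 30 TF × 400
mRNA copies (about 25,000 states) for closure-error certification; SSA
ensembles of 200 trajectories of 500 time units; trend series up to four
enhancers with the fitted parameters, and up to three under parameter
randomization (four seeded draws). These sizes were chosen so each check
resolves its question — e.g. Monte Carlo standard errors well below the
effects being tested — while a full run stays comfortably interactive.

## Known limitations

* The linear sub/superadditivity scheme goes negative at large enhancer
  counts; series are truncated with flags at that point. An exponential
  scheme would avoid this but is deliberately out of scope.
* Gaussian closure degrades at very low copy numbers (the synergistic
  regime drives mean mRNA well below one); the pathology flag and the
  SSA/CME oracles are the guard rails.
* Repression between enhancers, hub/condensate mechanisms, refitting rates
  to imaging data, and burst size/duration statistics are not modeled.
* Fidelity uses the *free* TF copy number, matching the model's species;
  a total-TF variant would require adding bound-TF bookkeeping to the
  metric, and the choice is documented rather than hidden.
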