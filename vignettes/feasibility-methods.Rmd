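---
title: "Methods: feasibility of Lotka-Volterra equilibria in large networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feasibility of Lotka-Volterra equilibria in large networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvfeas)
```

## The question

Classical complexity–stability results evaluate the eigenvalues of a
random community matrix and ask whether a large ecosystem, *assumed to be
at equilibrium*, returns there after a small perturbation. That analysis
silently presumes the equilibrium is feasible — every abundance strictly
positive. `lvfeas` makes that presumption testable: it estimates the
probability `P_S` that a randomly assembled Lotka–Volterra community of
`S` species has a fully positive equilibrium, and compares the estimate
with closed-form asymptotics where they exist.

## Model and parameters

The dynamics are `dx/dt = x ∘ (r + (θI + (CS)^(−δ)A)x)` and the
equilibrium is the solution of `(θI + (CS)^(−δ)A) x = −r`. The tunable
parameters, their defaults and meaning:

| parameter | default | meaning |
|---|---|---|
| `S` | — | species richness (dimensionless count) |
| `C` | 0.25 | connectance parameter; link probability of the generators |
| `sigma` | 0.4 | standard deviation of interaction magnitudes (per-capita rate) |
| `theta` | −1 | common intraspecific competition coefficient (< 0) |
| `delta` | 0.5 | interaction-strength scaling exponent in [0, 1] |
| `M` | 200 | Monte-Carlo trials for the mean interaction matrix |
| `n_reps` | 1000 | Monte-Carlo replicates per feasibility estimate |

The defaults are the baseline simulation conditions used throughout the
package's tests (`C = 0.25`, `σ = 0.4`, `θ = −1`); they keep the moderate
regime inside the structurally stable region `σ < |θ|`.

Interaction strengths are divided by the linkage density `CS` raised to
`δ`. The exponent partitions into strong (`δ < 1/2`), moderate
(`δ = 1/2`) and weak (`δ > 1/2`) regimes; `classify_regime()` compares
`δ` with 1/2 exactly, on the value as entered, which is why configuration
files are encouraged to carry `delta` as a decimal string ("0.5" parses to
the exact binary 0.5; no tolerance is applied).

## Network generators

**Unstructured webs.** The directed variant (May's mixture model) sets
each off-diagonal adjacency entry to 1 independently with probability
`C`; the paired variant links each unordered pair in both directions with
probability `C` and supports mutualism, competition and unstructured
predation. Signs: mutualism `+/+`, competition `−/−`, predation `+/−`
with a fair coin deciding the predator of each pair.

**Cascade.** Species are strictly ordered; each ordered pair `i > j` is
linked (`i` preys on `j`) with probability `C`, so the predation
adjacency is strictly lower triangular and the realized connectance
`L/(S(S−1))` targets `C/2` (each trophic link stored once).

**Niche.** Species receive niche values `n_i ~ U(0,1)` (stored sorted,
index 1 = lowest niche), a diet fraction `x ~ Beta(1, 1/C − 1)` and a
range `r_i = x n_i`. The diet is the set of species in an interval of
width `r_i` centred at `c_i ~ U(r_i/2, n_i − r_i/2)`. Two design choices
matter here:

* *Interval placement.* The centre is drawn so the interval lies wholly
  below the consumer's own niche value. Diets are therefore contiguous
  (interval webs), the predation graph is acyclic by construction, and —
  because the interval never protrudes beyond `[0, 1]` — the expected
  number of prey is exactly `r_i (S − 1)`, making the realized
  connectance an unbiased estimator of `C/2` with no edge effects.
  The variant in which the centre ranges up to `n_i` allows diets to
  reach above the consumer and produces occasional cycles; we chose the
  acyclic variant so that trophic ordering, and the variance-by-trophic-
  role analyses that depend on it, are well defined on every draw.
* *Isolated species.* The smallest-niche species always has an empty
  diet, guaranteeing a basal species. Other species may end up with no
  links at all. We keep them (they are classified as basal and flagged by
  `trophic_roles()`): redrawing them until connected conditions the web
  on connectedness, which measurably inflates realized connectance (at
  `S = 30`, `C = 0.25` from an unbiased 0.1246 to ≈ 0.131–0.136, many
  standard errors above the `C/2 = 0.125` target). The conditioning
  behaviour is available as `generate_niche(..., redraw_isolated = TRUE)`
  for comparison with implementations that reject such webs.

**Nested hierarchy.** Niche values as above; the prey count of species
`i` is `round(x n_i (S−1))`, capped at `i − 1` so only lower-ranked prey
are possible (keeping the web acyclic). Prey are picked sequentially: a
random lower-ranked species; if it already has consumers, the new
consumer joins that group and draws subsequent prey from the group's
pooled diet (restricted to lower-ranked species); leftovers are filled
uniformly from the unchosen lower-ranked species. This reproduces the
"inherited diet" constraint that relaxes strict intervality. The cap
costs a small downward connectance bias (≈ −0.001 at `S = 30`), well
inside the Monte-Carlo 3-standard-error band of the generator tests.

**Connectance convention.** `connectance()` counts stored directed links
over `S(S−1)`. Unstructured webs (both variants) therefore target `C`,
matching the Erdős–Rényi definition; structured predation webs store one
direction per trophic link and target `C/2`. For symmetric webs a
pairs-once count is available via `ordered = FALSE`.

## Growth rates and the mean structural vector

Feasibility depends strongly on `r`. The package's default is the *mean
structural vector* `r = −(θI + (CS)^(−δ) Ā)·1`, the deterministic rate
vector that places the mean-field equilibrium exactly at the all-ones
vector — on average as far from the feasibility boundary as possible, so
the resulting `P_S` is an upper envelope over growth-rate choices. `Ā`
is the unconditional mean of the interaction matrix (averaged over both
topology and strengths): zero for the May mixture and paired predation,
`±Cσ√(2/π)` off-diagonal for mutualism/competition (folded-normal mean),
and a Monte-Carlo average over `M = 200` draws for structured webs, whose
rank-dependent link probabilities have no convenient closed form. The
alternative of conditioning `Ā` on each realized topology is deliberately
not the default: the structural vector is meant to be a fixed,
deterministic parameter of the experiment, not a per-draw quantity.
In the moderate regime the structural vector of structured webs contains
negative entries for high-ranked consumers — predators starve without
prey — which is the ecologically expected signature of trophic structure.
I.i.d. Gaussian or uniform rates and explicit vectors are available
through `growth_rate_spec()`.

## Numerical choices

* **Linear solve and degeneracy.** Equilibria come from a dense LU solve.
  The reciprocal condition number (LAPACK `dgecon` via `Matrix::rcond`)
  is estimated for every draw; draws with condition number above `1e12`,
  failed solves, or residual `‖Mx* + r‖∞ > 1e−9 · max(1, ‖r‖∞)` are
  flagged *degenerate*. Degenerate draws are excluded from both the
  numerator and denominator of `P_S` and reported in their own column —
  near `σ ≈ |θ|` the system matrix approaches singularity and counting
  such draws either way would bias the estimate. A warning is raised when
  more than 5% of draws degenerate.
* **Feasibility boundary.** Strict positivity; an exact numerical zero
  counts as infeasible.
* **Stability verdict.** General nonsymmetric `eigen()`; stable iff the
  largest real part is `< 0`, with no tolerance band (a leading real part
  of exactly 0 is reported unstable).
* **Confidence intervals.** Wilson score by default — it behaves sensibly
  at estimates of 0 or 1, where the Wald interval collapses; the Wald
  interval (the one a normal-approximation plot would show) is available
  via `ci_method = "wald"`.
* **ODE verification.** `deSolve::lsoda` with `rtol = atol = 1e−10` and
  non-negativity clipping, used only to verify that trajectories relax
  back to the linear-solve equilibrium; verification integrates in
  chunks of `t = 500` until the sup-norm distance falls below the target,
  because stable systems can carry modes with decay rates near zero.
* **Seeding.** Every experiment accepts a base seed; replicate `k` at
  richness `S` runs under a child seed derived deterministically from
  `(seed, S, k)` (kept below 2³¹). Curves over an `S` grid are therefore
  reproducible point-by-point and extensible without re-running earlier
  points. Setup randomness (the Monte-Carlo `Ā`) uses the reserved
  child index 0.

## What the simulations do and do not show

The generators emulate the *topological* fingerprints of food webs —
hierarchy, contiguous diets, inherited consumer groups — and interaction
magnitudes as i.i.d. (folded-)Gaussians with a single scale `σ`. Real
communities violate several of these idealisations: interaction strengths
correlate within predator–prey pairs and with body size, connectance
decreases with richness rather than being an independent dial, growth
rates are unknown rather than structural, and saturating (Holling
type II) functional responses weaken interactions regardless of `δ`.
Passing tests therefore validate the mathematical claims about this model
class, not quantitative predictions for any empirical web. User-supplied
topologies can be analysed through `read_topology()`, but no empirical
webs ship with the package.

A second caveat is quantitative: the closed-form
`P_S ≈ Φ(√((θ²−σ²)/σ²))^S` is an asymptotic statement. At small richness
(`S` of order tens) the Monte-Carlo feasibility probability sits a few
hundredths *below* the formula (at `S = 25`: ≈ 0.722 from 20 000
replicates against 0.759 analytic), a finite-size deficit that exceeds
the binomial noise of a 1000-replicate experiment. Tests that compare
simulation with the closed form at those sizes document this bias; the
formula becomes accurate in relative terms only as `S` grows.

## Problem sizes used in the test-suite

The packaged experiments are scaled-down versions of full study runs
(which used up to `S = 800` and 1000 replicates everywhere): generator
calibration checks use 1000 draws at `S = 30`; the Gaussian-marginal and
stability checks use 1000 replicates at `S = 100`; weak-regime
convergence uses 200 replicates at `S ∈ {10, 50, 500}`; the structured
variance-ordering experiment uses 500 replicates at `S = 200` and 400.
These sizes are the package's choice of a good precision/runtime
trade-off; all of them rerun in minutes on a single core.

## Known limitations

* Only the linear-solve equilibrium is analysed — no multiple-equilibria
  enumeration, permanence or global-stability analysis.
* Interaction magnitudes are (folded-)Gaussian only; correlated pair
  strengths are out of scope.
* The i.i.d.-rates analogue of the closed-form `P_S` is covered by Monte
  Carlo rather than by a formula; only the structural-vector closed form
  and the Gaussian abundance moments are implemented analytically.
* The trophic rank reported for unstructured paired webs is positional
  only; roles there are meaningful only insofar as the symmetric
  adjacency admits them.
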