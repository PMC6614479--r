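---
title: "Methods: fitness effects of regulatory mutations in the lac operon model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fitness effects of regulatory mutations in the lac operon model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(lacdfe)
library(dplyr)
```

## The model

`lacdfe` simulates how random mutations in the transcriptional regulation of
the *E. coli* lactose-utilization network shift organismal fitness. The
network is described by a deterministic ODE model with three dynamic
species — the enzyme LacZ, the permease LacY and intracellular lactose
$lac_{in}$ — plus the repressor LacI, whose total pool is decoupled and
linear:

$$\frac{d[LacZ]}{dt} = Bas_1 + \frac{K^y}{K^y_m + [lacI]} - k_{d1}[LacZ]$$
$$\frac{d[LacY]}{dt} = \left(Bas_1 + \frac{K^y}{K^y_m + [lacI]}\right) K_t - k_{d2}[LacY]$$
$$\frac{d[lacI_{tot}]}{dt} = Bas_2 - k_{d3}[lacI_{tot}]
  \;\Rightarrow\; [lacI_{tot}] = Bas_2 / k_{d3}$$
$$[lacI] = \frac{[lacI_{tot}]}{1 + [lac_{in}]/K}$$
$$\frac{d[lac_{in}]}{dt} = \frac{k_1 [LacY]\, lac_{out}}{k_2 + lac_{out}}
  - \frac{k_3 [LacZ] [lac_{in}]}{k_4 + [lac_{in}]}$$

Free repressor $[lacI]$ falls as intracellular lactose accumulates
(repressor sequestration), which activates the lac promoter — the familiar
positive feedback of the system. The environment is a constant, high
extracellular lactose concentration $lac_{out}$ (a chemostat-like setting);
under that assumption the system has a unique, globally attracting steady
state, and no bistability enters (see *Well-posedness* below).

Fitness is a cost–benefit balance evaluated at steady state:

$$\text{Benefit} = \frac{k_3 [LacZ][lac_{in}]}{k_4 + [lac_{in}]}, \qquad
  \text{Cost} = \alpha\,(\alpha_z [LacZ] + \alpha_y [LacY] + \alpha_I [lacI_{tot}]),$$
$$f = \text{Benefit} - \text{Cost}.$$

Benefit is the lactose metabolized per unit time; cost is proportional to
the protein that must be produced per unit time to maintain that benefit.
The cost term uses the *total* LacI pool: every repressor molecule, free or
lactose-bound, has to be synthesized. The per-protein factors
$\alpha_z, \alpha_y, \alpha_I$ default to each protein's length relative to
LacZ (1023, 417 and 360 amino acids) times its degradation constant.
Fitness can be negative (expression without return, or repressor cost with
no benefit) and is bounded above by the benefit.

Five parameters describing transcriptional regulation are mutable —
$Bas_1$, $Bas_2$, $K^y$, $K^y_m$, $K_t$ — each confined to a configured
range; all kinetic constants of the proteins themselves are fixed. This
captures short-timescale regulatory evolution: promoter and translation
mutations, not protein-function mutations.

## Steady-state computation

The model has a useful exact structure: at steady state the ratio
$[LacY]/[LacZ] = K_t k_{d1}/k_{d2}$ is the same for every parameter set, so
the lactose balance closes in the single unknown $[lac_{in}]$:

$$\frac{[lac_{in}]}{k_4 + [lac_{in}]} = r, \qquad
  r = \frac{k_1\, lac_{out}}{k_2 + lac_{out}} \cdot \frac{K_t\, k_{d1}}{k_{d2}\, k_3},$$

giving $[lac_{in}] = k_4\, r/(1-r)$ when $r < 1$, after which free LacI,
promoter activity, and both protein concentrations follow in closed form.
`steady_state()` exposes three routes:

* `"analytic"` (default): the exact reduction above — used for all
  large-scale simulation because it is exact and vectorizes;
* `"root"`: bracketing 1-D root finding on the full nonlinear lactose
  balance, independent of the reduction;
* `"integrate"`: stiff time integration (`deSolve::lsoda`) from the empty
  state $(0,0,0)$, with the horizon doubled until the relative residual of
  the right-hand side falls below the solver tolerance (default $10^{-9}$).

The three routes are cross-checked in the test suite (100 random in-range
parameter sets agree to better than $10^{-6}$ relative in every species).

**Well-posedness.** When $r \ge 1$, influx exceeds the maximal metabolic
capacity and intracellular lactose has no finite steady state; such
parameter sets are returned as non-converged (`NA` fitness) rather than
silently truncated. The packaged default ranges keep $r \le 0.91$ over the
whole box, so every in-range parameter set converges. Degenerate inputs:
zero production ($Bas_1 = K^y = 0$) or zero external lactose give the exact
boundary steady states; $k_4 + [lac_{in}] = 0$ is rejected as a degenerate
half-saturation.

## Default parameterization

The published table of parameter values and ranges for this system is not
available to the package, so the defaults in
`inst/extdata/default_config.yaml` are package choices, made once and
documented here; they are *not* canonical. All units are consistent
arbitrary units (concentration, time); fitness is in benefit units. The
guiding constraints were:

* degradation constants $k_{d1} = k_{d2} = k_{d3} = 0.02$: protein removal
  dominated by dilution at a realistic bacterial doubling time relative to
  the fast lactose kinetics ($k_1 = k_3 = 1$);
* a saturating environment, $lac_{out} = 100 \gg k_2 = 10$: the constant
  high-lactose assumption of the study design;
* mutable ranges spanning the regimes of interest (repressed to fully
  induced), with $K_t \in [0.01, 1]$ keeping $r < 1$ (well-posedness) and
  reflecting that LacY is translated less efficiently than LacZ;
* a cost scale $\alpha = 20$ placing the zero-fitness surface well inside
  the box, so that low-fitness parameter sets are plentiful, the fitness
  maximum is nontrivial ($f_{max} \approx 2.4 \times 10^4$ at the
  high-expression, low-repressor corner), and the model sits in the regime
  the study describes (a large majority of random parameter sets are far
  below $f_{max}$, and beneficial-mutation DFEs at low fitness are
  exponential-like).

With these defaults the fitness optimum lies at a *corner* of the mutable
box. That is structural, not accidental: fitness is exactly linear in the
promoter activity $A = Bas_1 + K^y/(K^y_m + [lacI])$ and in $[lacI_{tot}]$,
so no interior stationary point exists in those directions (see
*Epistasis*, below, for the consequences).

## The landscape sampler (the synthetic-input generator)

The pipeline's inputs are parameter sets at prescribed fitness levels —
0.001, 0.1 and 0.5 of $f_{max}$, with 100 replicate sets per level at study
scale. `estimate_fmax()` runs bounded L-BFGS-B from 32 Latin-hypercube
starts (the landscape is smooth and five-dimensional; no global-optimality
certificate is claimed). `sample_at_fitness()` then draws uniform points in
the box and moves each onto the target-fitness surface by 1-D root finding
along a randomly chosen coordinate. When no single coordinate can bracket
the target from a uniform draw — the typical case at 0.1 and 0.5 $f_{max}$,
where uniform draws top out near 0.06 $f_{max}$ — the sampler makes greedy
1-D uphill moves along randomly ordered coordinates, crossing onto the
target the moment it becomes reachable, so coordinates are pushed to their
1-D optima only when the climb requires it. Accepted sets must match the
target within 1% relative (configurable), be pairwise distinct (> $10^{-6}$
relative in some coordinate), and are re-verified by recomputing their
fitness. The per-proposal acceptance rate falls steeply with the target
level, mirroring the increasing sparsity of high-fitness parameter sets;
a shortfall against the requested count is reported explicitly rather than
padded.

What the generator emulates — and what it does not: it reproduces the
*design* of the study (replicated, distinct, same-fitness starting points in
a fixed environment). It does not emulate measurement noise, population
dynamics, or any property of real sequence mutations; passing tests
demonstrate properties of the model and pipeline, not of *E. coli*.

## Mutational framework and DFE

A mutation picks one of the five regulatory parameters uniformly at random
and redraws its value from $\mathcal{N}(v, (0.1\,v)^2)$ — a multiplicative
kernel whose width (`cv`, default 0.1) is a package choice, since the
original study does not state its proposal width. A multiplicative kernel
respects the parameters' different scales; a zero current value falls back
to an absolute std of `cv` × range width. Out-of-range proposals are
redrawn (up to 100 times, then clipped); a `"clip"` policy is available,
and a uniform-kernel variant can be emulated by widening `cv`. DFE
summaries — especially the beneficial fraction and the fitted exponential
rate — depend quantitatively on `cv`; halving or doubling it changes
per-set $\lambda$ roughly proportionally, which is why published per-set
numbers can only be matched approximately.

`build_dfe()` scores `n_mutations` (study scale: 10,000) independent single
mutations against the background's fitness, excluding and counting any
non-converged mutants (none occur in-range under the defaults).
Classification uses a neutral threshold `neutral_epsilon` (default 0, so
beneficial/deleterious fractions sum to one, matching the study's
dichotomy; truly zero deltas are rare in a continuous model).

**Exponential fits.** Effect magnitudes are binned from zero with a
Freedman–Diaconis bin count bounded to $[10, 60]$, density-normalized, and
the rate $\lambda$ minimizes the Euclidean distance between the binned
density and $|\lambda| e^{-\lambda x}$ at the bin centers — a binned
least-squares criterion, not maximum likelihood, matching a
distance-to-histogram notion of fit. The objective is multimodal in
$\lambda$ (a very large rate can fit the first bin alone), so the fitter
scans a log-spaced grid over both signs before local refinement; negative
fitted rates (a rising histogram, seen for some deleterious DFEs at high
fitness) are flagged `sign_ok = FALSE`. $R^2$ is computed on the same
binned representation and may be negative for badly misspecified samples.
On $10^5$ true exponential draws the fitter recovers $\lambda \in \{0.5, 3,
20\}$ within 5%.

**Two-peaked deleterious DFEs.** `detect_bimodality()` counts local maxima
of a Gaussian-kernel density of the effect magnitudes whose topographic
prominence exceeds 5% of the tallest peak (both thresholds configurable).
A single exponential yields one peak; a well-separated two-scale mixture
yields two.

## Epistasis protocol

`epistasis_scan()` implements the two-background comparison: a focal
beneficial mutation $\mu$ applied to the starting set $P_0$ gives
$\Delta f = f_0^* - f_0$; re-applied, bit-identically, to backgrounds
$P_M$ that carry one other beneficial mutation (spread evenly over the four
non-focal parameters; study scale 4,000 backgrounds, exploratory default
200) it gives $\Delta f^* = f_M^* - f_M$. Records store both effects, the
ratio $\Delta f/\Delta f^*$ (undefined when $\Delta f^* = 0$; such records
are excluded from trend statistics), a sign-epistasis flag (opposite signs
of the two effects), and the focal mutation's benefit and cost components
on both backgrounds. Beneficial mutations are found by rejection sampling
from the mutation kernel with an explicit budget; near a 1-D optimum the
search fails with a distinct error condition, which the scan reports as a
per-background shortfall.

Two oracle properties pin the implementation down: with any additive
fitness function substituted for the model, every ratio equals 1 to machine
precision; and with a negligible kernel width for the background mutations,
ratios approach 1 in the no-epistasis limit.

**What the model actually shows.** Under the equations above, the epistasis
between beneficial mutations is *synergistic*, not diminishing-returns: the
ratio $\Delta f/\Delta f^*$ sits at or below 1 and *decreases* with
background fitness (Spearman $\rho$ between $-0.1$ and $-0.96$ per focal
parameter under the defaults). This is structural. At steady state the
benefit equals the influx, $\frac{k_1 lac_{out}}{k_2+lac_{out}}[LacY]$, so
fitness factorizes as (per-activity net rate, set by $K_t$) × (promoter
activity, set by $Bas_1, Bas_2, K^y, K^y_m$) minus the repressor cost.
Beneficial mutations in different factors of a product amplify each other
in absolute terms; mutations sharing the additive activity channel (e.g. a
$Bas_1$ background under an activity-channel focal) give ratios of exactly
1. A diminishing-returns trend with ratios far above 1 would require a
concave (saturating) benefit, which these equations cannot produce for any
parameter values — the saturation constant $k_4$ cancels from the
steady-state benefit. For the same reason, sign epistasis between
beneficial mutations cannot occur at positive-fitness backgrounds here:
positive fitness forces a positive net rate, and every beneficial move
keeps it positive. The ratio clustering by background parameter *is*
reproduced (distinct, tight clusters per background parameter, with the
additive $Bas_1$ cluster pinned at 1). The narrative description of the
lactose balance that accompanies the model (a separate efflux term and a
dedicated metabolism saturation) would break this factorization and could
restore diminishing returns; the equations as written are what this
package implements.

A related consequence for the DFE trends: because the kernel is
multiplicative and fitness is linear in activity, absolute beneficial
effect sizes scale with the fitness magnitude, so the mean *absolute*
beneficial effect increases monotonically across the three levels under
the defaults. Expressed as selection coefficients
($\Delta f / f_{background}$, the `mean_beneficial_s` column), the mean
beneficial effect *does* peak at the intermediate level. Both readings are
reported; the experiment table keeps the absolute definition primary.

## Scales, determinism and numerical choices

* Every seeded entry point restores the caller's RNG state and derives
  named per-stage sub-seeds from its root seed, so collections, DFEs,
  scans and the full study are bit-reproducible (`run_full_study()` writes
  a manifest with the seed and a configuration hash, and identical inputs
  reproduce identical TSVs).
* Steady-state tolerance $10^{-9}$ relative residual; root finding at
  $10^{-12}$–$10^{-13}$ absolute on bracketed intervals; optimizer budget
  500 L-BFGS-B iterations per start.
* The test suite runs the analyses at reduced but statistically meaningful
  scales (e.g. 10 sets per level × 2,000 mutations for the level trends;
  20 sets × 10,000 mutations for fit-quality shares; 200 epistasis
  backgrounds per focal parameter), chosen so the full suite completes in
  well under a minute of compute for the simulation-heavy parts while the
  assertions remain stable across seeds. `scripts/acceptance.R` re-runs
  the pipeline at 20 sets × 10,000 mutations per level.

## Known limitations

* The defaults are surrogates for an unavailable published table; absolute
  numbers ($f_{max}$, per-set $\lambda$, exact beneficial percentages)
  carry no biological meaning and should be read only through the
  qualitative claims.
* The kernel width is a free choice that every quantitative DFE summary
  depends on; sensitivity should be explored via `kernel$cv`.
* LacA, catabolite repression, inducer exclusion, stochastic gene
  expression and bistable regimes are outside the model by construction;
  time-varying environments are not implemented.
* Fitness-level labels follow the study design (0.001/0.1/0.5 of
  $f_{max}$); the level is an ordinary config value, so other fractions
  can be requested directly.
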