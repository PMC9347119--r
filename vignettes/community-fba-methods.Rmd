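---
title: "Modelling syntrophic CO2 methanation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling syntrophic CO2 methanation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntroflux)
```

## The scientific problem

Ex-situ biogas upgrading reactors feed H2 and CO2 to a biofilm whose
dominant members divide the work of methanation: a hydrogenotrophic
methanogen reduces CO2 (and formate) to CH4, a versatile acetogen fixes
CO2 through the reductive acetyl-CoA route into acetate and formate,
and satellite guilds ferment or oxidize the resulting volatile fatty
acids (VFA) while trading amino acids. None of these interactions is
directly measurable at the flux level, which is where constraint-based
community modelling earns its keep: given each organism's stoichiometric
network, the community composition, and the measured boundary conditions,
flux balance analysis (FBA) predicts a consistent set of intracellular
and exchange fluxes.

This vignette documents the model this package implements, the defaults
it ships, the numerical choices underneath, and — explicitly — what the
synthetic test systems do and do not demonstrate.

## Community model

Each species model is a stoichiometric network with flux bounds and a
biomass reaction; fluxes are mmol/gDW/h, biomass flux in 1/h. Metabolites
live in the species or in a shared environment compartment, and exchange
reactions (export-positive) move environment metabolites across the
species boundary.

`build_community()` namespaces each species' network, gives it a private
copy of every environment metabolite it touches, and couples it to a
shared pool: the exchange of species $i$ for metabolite $m$ enters the
pool mass balance with weight $a_i$, its relative abundance. One
community exchange per pool metabolite connects the pool to the medium,
so at steady state

$$ v^{c,m} \;=\; \sum_i a_i\, v^{i,m}. $$

Species fluxes therefore stay in per-gDW-of-that-species units while
community exchanges are per gDW of community; internal fluxes are never
rescaled by abundance. The community growth rate is
$\mu_c = \sum_i a_i \mu_i$.

## Cooperative tradeoff

Maximizing $\mu_c$ alone is degenerate: the linear program (LP) is free
to concentrate all growth in whichever species is cheapest. The
cooperative tradeoff resolves this in two stages, with a third added here
for reporting:

1. **Stage 1 (LP).** Maximize $\mu_c$ over
   $\{v : Sv = 0,\; lb \le v \le ub\}$, giving $\mu_c^{\max}$.
2. **Stage 2 (QP).** Minimize $\sum_i \mu_i^2$ subject to the same
   constraints plus $\mu_c \ge f\,\mu_c^{\max}$. The quadratic is
   *unweighted*: with that choice, in the regime where no species is
   individually constrained the Lagrangian gives
   $\mu_i = f\,\mu_c^{\max} a_i / \lVert a\rVert^2$ — growth proportional
   to abundance, which is the observed community behaviour and a pillar
   of the test suite. (An abundance-weighted quadratic would equalize
   growth rates instead.) The enforced fraction defaults to $f = 0.5$,
   the value used for all community simulations.
3. **Stage 3 (QP).** Growth rates from stage 2 are pinned and the squared
   norm of all exchange fluxes is minimized. The literature is silent on
   how to report fluxes from a degenerate optimum; the minimum-norm
   representative is unique, stable across solver runs and species
   orderings, and keeps reported cross-feeding networks reproducible.

## Reactor boundary conditions

`gas_to_flux()` converts a gas stream of $q$ L per L reactor per day and
molar fraction $x$ into a specific flux

$$ \frac{q \cdot x \cdot 1000}{V_m \cdot \rho_X \cdot 24}
   \;\; \text{mmol/gDW/h}, $$

with the ideal-gas molar volume $V_m = RT/P$ (24.46 L/mol at 298 K — the
conventional figure corresponds to 298.15 K truncated to two decimals,
and `molar_volume()` exposes the exact law) and a community biomass
density $\rho_X$ of 1.17 gDW/L. The default operating point fixes CO2
and H2 uptake at 1.20 and 5.11 mmol/gDW/h (both bounds, i.e. forced
uptake), requires CH4 export of at least 1.15 mmol/gDW/h, and pins the
*community* exchange of acetate, propionate and butyrate to zero:
measured VFA concentrations in such reactors are stable, so the medium
must accumulate none, yet species-level VFA exchanges stay free and
cross-feeding through the pool is still possible. The stated 1:4
CO2:H2 ratio of the feed is treated as descriptive; the numeric rates
(ratio 4.26) are the operational constraint.

Media are built from recipes in mmol/L. Water is capped at 1000
mmol/gDW/h; every other component is mapped linearly by relative
concentration, $b_i = \mathrm{clamp}(100\,c_i/c_{\max}, 1, 100)$. The
linear-with-clamping map is the simplest rule consistent with the two
stated anchors (a [1, 100] band, scaling by relative concentration); the
recipe concentrations are deliberately treated as dimensionless weights
rather than put through a volumetric-to-specific conversion, so the LP
lives in a single unit system. Metabolites absent from the medium may
still be *exported* — a defined medium constrains what the community can
eat, not what it can excrete.

## The synthetic community

`make_toy_community()` builds lumped caricatures of the five dominant
guilds, with abundances (0.33, 0.26, 0.20, 0.11, 0.10) following the
dominance ordering observed in upgrading biofilms:

* **methanogen** — the only CH4 exporter and the only formate importer;
  direct hydrogenotrophic methanogenesis (4 H2 + CO2 → CH4) is capped at
  3 mmol/gDW/h to reflect finite catalytic capacity, with formate-driven
  methanogenesis (4 HCOOH → CH4 + 3 CO2) as the overflow route;
* **acetogen** — fixes CO2 into acetate and formate, synthesizes and
  exports alanine, glycine and serine, imports threonine and glutamate;
* **VFA degrader** — oxidizes acetate and propionate, supplies the
  glutamate-family amino acids (it is the methanogen's only glutamate
  source);
* **two fermenters** — convert acetate to propionate (one also to
  butyrate), export threonine, and depend on serine or alanine/glutamine.

Energy is tracked through a lumped ATP proxy plus a reduced carrier made
from H2, so every guild must import H2 to grow; every reaction conserves
carbon, so CH4 export can never exceed carbon uptake. Biomass costs
(20 ATP, 0.5 reduced carrier, 1 ammonium, 0.1 phosphate and 0.05 of each
required amino acid per unit growth) and the pathway capacity caps were
chosen once so that, at the reactor operating point, the H2 forced into
the community exceeds what methanogenesis alone can absorb: the surplus
must leave through the acetogen's overflow metabolism, which is exactly
the regime in which the formate shuttle and the acetate cross-feeding
become obligatory rather than optional. A small log-normal jitter
(sd 0.01) on the pathway ATP yields, driven by the blueprint seed,
emulates reconstruction-to-reconstruction variability without moving any
qualitative behaviour.

What the toys deliberately do **not** model: genome-scale pathway detail,
gene–protein–reaction rules, thermodynamic feasibility, elemental
balancing beyond carbon, or biofilm spatial structure. A passing test
suite therefore shows that the *pipeline machinery* — coupling,
optimization, network extraction, elasticity — behaves correctly on
networks with the right exchange topology; it does not validate any
genome-scale reconstruction.

`make_toy_medium()` is a fixed mineral medium: water, dissolved CO2 and
~15 inorganic components spanning more than three orders of magnitude in
concentration, with no organic carbon and an inert tracer that no pathway
can use (the anchor for zero-elasticity controls).

## Gas sweep and elasticity

`growth_sweep()` re-solves the tradeoff over a grid of H2/CO2 uptake
bounds (default nine points, 0–160 mmol/gDW/h, the same threshold applied
to both gases; a per-gas scaling argument covers fixed-ratio sweeps). A
plateau is flagged when the relative change of $\mu_c$ between
consecutive thresholds drops below $10^{-3}$. On the synthetic community
the catalytic caps saturate early, so the curve rises from zero and is
flat from the second grid point on — the plateau equals the fully
unconstrained optimum to machine precision.

`elasticity()` quantifies interventions as a one-sided multiplicative
finite difference on the log scale,

$$ \epsilon \;=\; \frac{\ln(|v'| + 10^{-8}) - \ln(|v| + 10^{-8})}
                       {\ln(\theta'/\theta)}, $$

with a doubling step by default (the reference implementation of the
coefficient is not described in enough detail to copy; a multiplicative
step respects the univariate-intervention framing and is trivially
reproducible; steps below 1 probe the downward direction, and on smooth
regions the two directions agree). Medium interventions scale the uptake
bound (and a forced-uptake upper bound, if present); abundance
interventions scale one species and renormalize, because abundances are
compositional — the effective post-normalization ratio enters the
denominator. Responses below $10^{-6}$ in both states are reported as
exactly zero. On the default community, doubling the methanogen's
abundance increases CH4 export (the bacterial H2 sinks shrink after
renormalization, forcing more H2 through methanogenesis) while doubling
the acetogen's decreases it — the same signs the elasticity analysis
reports for the corresponding biofilm species.

## Exchange networks

FBA defines species-to-pool fluxes only. Pairwise arrows are attributed
by proportional allocation: for metabolite $m$ with producer exports
$E_p$ and consumer imports $I_c$ (community units), the edge $p \to c$
carries $E_p I_c / \max(E, I)$ and the residual $|E - I|$ flows to or
from a distinguished medium node. The rule conserves flow exactly, is
deterministic, and needs no extra assumptions. Edges are kept when they
exceed 0.3 mmol/gDW/h, the same cut used to draw the biofilm exchange
figures; metabolites classify into the methanogenesis set (CO2, H2, CH4,
acetate, pyruvate, formate), the twenty proteinogenic amino acids, and
everything else.

## Co-occurrence screen

Coverage profiles of metagenome-assembled genomes across samples are
averaged over replicates per experiment, experiments are retained when
the dominant species jointly reach 1% (inclusive) of the column total,
and pairwise Pearson correlations are computed with two-sided p-values
from the t transform. Pairs with $p \ge 0.05$ are masked — the
conventional reading, kept even though the source figure legend's
wording could be read the other way. Plain Pearson on relative
abundances is used deliberately, compositionality caveats
notwithstanding, to match the published screen.

The synthetic coverage generator uses a Gaussian copula with log-normal
margins: correlated normal scores pushed through an exponential give
non-negative, right-skewed coverages. For equal log-scale dispersions
$s$ the coverage-scale Pearson correlation of a pair with normal-scale
correlation $r_z$ is $(e^{r_z s^2}-1)/(e^{s^2}-1)$, and the generator
inverts this so the *planted* value is on the observable scale; targets
that would need $r_z$ outside $[-1, 1]$ are rejected. The default
dispersion of 0.5 keeps tails heavy enough to be realistic while leaving
the sample correlation estimator stable at a few hundred experiments
(at dispersion 1 the estimator's sampling noise for mid-range
correlations would dominate).

## Numerical choices

* **LP.** A bounded-variable two-phase primal simplex with Bland's
  smallest-index rule throughout (entering and leaving); stoichiometric
  systems are heavily degenerate and redundant, and Bland's rule rules
  out cycling at a cost that is irrelevant at these sizes (~100
  variables). All bounds are finite (default magnitude 1000, matching
  the water cap convention), so unboundedness cannot occur.
* **QP.** The dual active-set method (quadprog), with redundant equality
  rows removed by QR factorization and variables with equal bounds
  converted to equality constraints. A ridge of $10^{-8}$ on the fluxes
  outside each stage's quadratic keeps the Hessian positive definite;
  its effect on the growth rates is orders of magnitude below every
  tolerance asserted in the tests.
* **Tolerances.** Feasibility $10^{-6}$ (mass-balance residuals are
  checked on every returned solution), stage-2 floor slack $10^{-9}$
  (so $f = 1$ and numerically-zero optima remain feasible), exchange
  zero-cut $10^{-9}$.
* **Determinism.** Generators restore the RNG state; identical seeds
  give bit-identical models, media and coverage matrices, and repeated
  solves of the same community agree to $10^{-12}$.

Problem sizes throughout the tests are deliberately modest — the
five-guild community has ~80 metabolites and ~106 reactions, oracle
comparisons run on communities of up to seven reactions (exhaustive
vertex enumeration) and on $2.4\times10^3$-point-per-axis growth grids,
and the co-occurrence screen uses up to 500 synthetic experiments. These
sizes exercise every code path while keeping the full suite near ten
seconds.

## Known limitations

* The toy stoichiometries are carbon-consistent but not elementally
  balanced in H/O/N; hydrogen bookkeeping is folded into lumped ATP and
  carrier yields.
* Proportional allocation cannot distinguish which consumer a given
  producer "really" feeds when several overlap; only the pool fluxes are
  model outputs.
* Elasticities are one-sided finite differences of an optimization
  problem and can sit on kinks of the solution map; signs are robust,
  magnitudes are step-dependent.
* The cooperative tradeoff assumes a common growth objective and steady
  state; dynamic phenomena (start-up, washout, biofilm succession) are
  out of scope.
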