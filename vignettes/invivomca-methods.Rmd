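---
title: "In vivo metabolic control analysis: models, estimators, and design choices"
author: "invivomca"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In vivo metabolic control analysis: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invivomca)
```

## Scope

`invivomca` implements the computational side of *in vivo* metabolic control
analysis (MCA) for an L-cysteine-producing *E. coli* fed-batch process: a
reduced stoichiometric model of central carbon metabolism and cysteine
biosynthesis, constraint-based flux estimation (FBA, loopless FVA, TFA),
thermodynamic classification of reactions, elasticity estimation from
short-term perturbation experiments, control-coefficient algebra with Monte
Carlo uncertainty propagation, and the bioprocess bookkeeping (specific
rates, exporter selectivity, gas exchange, carbon balances) that surrounds
such a campaign. Because the original fermentation data are not deposited,
the package ships a synthetic-data generator with known ground truth; it is
first-class, tested code, and every inferential stage is validated against
it.

## The reduced network

`build_reduced_model()` returns the 37-reaction network spanning glycolysis,
the pentose phosphate pathway, the citrate cycle, serine/cysteine
biosynthesis, the S-sulfocysteine route from thiosulfate, the coupled
YdeD export of O-acetylserine (OAS) and L-cysteine, and two lumped
energy-metabolism steps (NADH dehydrogenase, ATP synthase). Identifiers
follow BiGG conventions. Three species are extracellular; water and the
currency/cofactor pool (ATP/ADP/AMP, NAD(H), NADP(H), quinones, Pi, PPi,
CO2, the sulphur species, glutamate) are clamped by default: their
concentrations are treated as fixed boundary parameters, which is standard
in reduced-model MCA and avoids spurious conserved moieties dominating the
Jacobian. The clamp list is an argument, not a constant. Free CoA,
acetyl-CoA and succinyl-CoA remain balanced, so the model retains one true
conserved moiety (the CoA pool) and the link-matrix machinery is exercised
rather than bypassed.

Two structural facts of this network are worth knowing. First, the printed
reaction set has no pyruvate kinase, so phosphoenolpyruvate can leave
glycolysis only through the phosphotransferase system, PPC, or the biomass
drain; this couples the admissible fluxes of G6PDH, glucose/succinate
uptake and the biomass drain through a rigid row-space invariant. Second,
acetate closes a small internal loop (cysteine-forming reactions release
acetate, ACS re-activates it), forcing `ACS = CYSS + SLCYSS` at any steady
state. Both facts are respected by the reference flux distribution
(`reference_fluxes()`), which pins eight valid free coordinates (glucose,
pyruvate and succinate uptake, oxidative PPP flux, the CYSS/SLCYSS split,
and the two lumped respiration fluxes) and derives the rest from the mass
balances, yielding a strictly positive flux vector.

The default carbon map tracks skeleton carbons (acetyl-CoA counts its
2 acetyl carbons; adenine nucleotides count 10 so ATP-consuming reactions
balance; nicotinamide/quinone backbones are untracked because they always
appear as redox pairs). Under this convention every reaction except the
flagged pseudo-reactions (NADH5, ATPS, the YdeD transport step) is checked
to be carbon balanced.

## Thermodynamics and classification

Gibbs reaction energies are evaluated as `dG_r = dG0' + RT * sum(s_j ln c_j)`
with concentrations in mol/L, water at unit activity, and `R = 8.314e-3`
kJ/mol/K at 305.15 K (32 °C, the cultivation temperature). Reactions with a
representative `dG_r` in `[-10, 0]` kJ/mol are *near* equilibrium and those
below −10 kJ/mol *far* from it; the −10 boundary is assigned to "near"
(inclusive convention, noted in the output). In the full TFA
(`tfa()`), flux direction is coupled to the sign of `dG_r` through binary
indicators with a big-M of 1000 kJ/mol and a strictness margin of
1e-3 kJ/mol; a presolve substitutes out every indicator whose sign is
already decided by the concentration bounds (with a measured metabolome
nearly all of them), so the branch-and-bound usually degenerates to plain
LPs. Default concentration bounds are 1e-5 to 0.05 mol/L; measured values
narrow them to ±20%. In `run_pipeline()` the classification is obtained by
direct evaluation of `dG_r` at the measured reference metabolome, which on
the reduced model is equivalent to the MILP route and much cheaper; the
MILP is available per state via `run_tfa = TRUE`.

## Linear programming

No LP solver package is assumed. All constraint-based analyses run on an
internal dense two-phase simplex (Dantzig pricing with a Bland anti-cycling
fallback), which is deliberately boring: flux-balance systems are heavily
degenerate (all-zero right-hand sides), and general-purpose simplex codes
without anti-cycling protection misreport feasibility on exactly these
instances. The FVA fractional-optimum cut is implemented as a bound on the
objective reaction (exactly equivalent for single-flux objectives).
Loopless FVA post-processes each extreme flux distribution by a
cycle-removal LP — minimum total flux with exchange fluxes held fixed and
per-reaction sign boxes — so internal cycles cannot inflate the reported
ranges.

## Elasticities

Near-equilibrium reactions get the thermokinetic affinity elasticity
`eps = -s * Gamma / (1 - Gamma)` with `Gamma = exp(dG_r / RT)`: the
thermodynamic component dominates near equilibrium, diverges as
`dG_r -> 0-` and vanishes in the saturated forward limit. A kinetic
saturation offset can be layered on top by supplying explicit effector
overrides; the shipped estimator implements the pure thermodynamic
component.

Far-from-equilibrium reactions are estimated by lin-log regression across
the perturbation states:
`v_k / J_ref - 1 = sum_j eps_j ln(c_jk / c_j,ref)`,
with enzyme levels held at the reference — the identifying assumption of a
short-term (≤ 21 min) experiment, during which expression cannot change.
The default effector set is the reaction's internal reactants and products
*plus* any measured boundary substrate in its stoichiometry (extracellular
glucose for the PTS, the sulphur donors for the cysteine-forming
reactions). The extension matters: an uptake reaction's flux is driven by
the fed substrate, and a regression that omits it is structurally
unidentifiable. Ordinary least squares is used when the design is full
rank; if the condition number exceeds 1e6 a small ridge penalty (1e-6) is
applied with a warning. Diagnostics (residual variance, condition number,
number of states) are kept per reaction.

## Control coefficients

With scaled elasticities `E`, reference fluxes `J` and concentrations `c`,
the unscaled rate sensitivities are `dv/dc = dg(J) E dg(c)^-1`. The
internal stoichiometric matrix is decomposed as `N = L N_R`
(`link_decomposition()`), the Jacobian is `M = N_R (dv/dc) L`, and

* `C_S^u = -L M^-1 N_R`,
* `C_J^u = I + (dv/dc) C_S^u`,
* `C_J = dg(J)^-1 C_J^u dg(J)`, `C_S = dg(c)^-1 C_S^u dg(J)`.

Rows of `C_J` sum to one and rows of `C_S` to zero (summation theorems)
whether or not conserved moieties are present; on conservation-free
networks the connectivity theorems `C_J E = 0` and `C_S E = -I` hold as
well, and both are asserted in the test suite. Every reaction is an
"enzyme" column, including the fixed boundary fluxes (uptakes, biomass
drain) and lumped pseudo-reactions, which enter with zero elasticities —
without them the summation theorem cannot hold on the augmented network;
they are flagged in the output. Reference fluxes below 1e-9 would make the
scaling undefined and are rejected with an informative error.

Measured rates carry noise and need not satisfy the mass balances, but the
summation theorems require a steady-state-consistent reference flux. The
reference rates are therefore reconciled before the control analysis — an
orthogonal least-squares projection onto the null space of the internal
stoichiometric matrix (`reconcile_fluxes()`), the classic data
reconciliation step that the constraint-based flux estimation performs
implicitly. It is a no-op for balanced fluxes, and with it the theorems
hold to 1e-12 on every Monte Carlo iterate.

Monte Carlo propagation (`monte_carlo_mca()`) resamples every measured
concentration and rate — normal truncated at zero by default, log-normal as
an alternative — re-runs elasticity assembly (classification held fixed,
`dG_r` refreshed) and the control-coefficient algebra, and reports
per-coefficient medians, 2.5/97.5 percentiles and sign-stability
(the fraction of iterations agreeing with the median's sign). Iterations
with singular Jacobians are dropped and counted; more than 50% drops is an
error. The reference analysis uses 10,000 iterations; the test suite runs
a scaled-down 1,000.

## The synthetic perturbation generator

`make_default_kinetic_model()` equips the network with rate laws: the 17
near-equilibrium reactions get thermokinetic laws
`v = J_ref (1 - Gamma)/(1 - Gamma_ref)`, the 20 far-from-equilibrium
reactions get lin-log laws with elasticities drawn once per seed from a
uniform prior (magnitude 0.1–2, sign from stoichiometry), and the three
boundary reactions (pyruvate/succinate uptake, biomass drain) are imposed
fluxes. Standard Gibbs energies are reverse-engineered so that
reference-state `dG_r` lands in (−6, −1.5) kJ/mol for near-equilibrium and
(−35, −12) kJ/mol for far-from-equilibrium reactions. The near window is
narrower than the (−10, 0) classification band on purpose: the
thermokinetic law saturates at `J_ref/(1 - Gamma_ref)`, and a reaction
parameterized at `dG_r = -8` kJ/mol has only ~4% flux headroom — too little
for any perturbation to pass through the TCA or serine chains. The
(−6, −1.5) window gives every near-equilibrium step at least ~16% headroom
while keeping the classification unchanged. Draws whose steady-state
Jacobian is ill-conditioned or unstable are rejected and redrawn
deterministically.

Steady states are found by a damped Newton iteration on the internal
log-concentrations (conserved-moiety totals pinned to reference), with a
warm-started boundary continuation as fallback; convergence requires the
independent internal mass balances to vanish to 1e-10 relative.

The default design (`perturbation_design()`) emulates four parallel
reactors fed with glucose, pyruvate, glucose+pyruvate and
glucose+succinate, three feed levels each, 7-minute stages: 12 states plus
the production-process reference. Feed levels map to boundary settings —
the extracellular glucose level for the PTS-fed regimes, uptake-flux scale
factors for pyruvate/succinate. Two further axes vary across states: the
sulphur donors (thiosulfate, H2S, ±10–20%) and a mild (±5%) modulation of
the biomass-precursor demand. Both are physiologically grounded (the
parallel reactors carry their own thiosulfate supply; precursor demand
responds to carbon availability within a stage) and they are what makes the
estimation problem well posed: with carbon-feed knobs alone, the
cysteine-branch metabolites respond along a one-dimensional manifold —
their log-concentrations are exactly collinear across all states, no matter
how many states are collected — and the elasticities of reactions with
three or more effectors in that branch are unidentifiable. The level mixes
are deliberately non-collinear so the 12 states span all boundary
directions; the worst regression design condition number on the default
draw is ~1300.

Measurement noise is multiplicative log-normal per observation with a
default CV of 10% (a plausible LC–MS technical error; positive quantities
stay positive). A consequence worth stating plainly: although the design
is exactly identified, its conditioning (up to ~1e3 for the most
collinear effector sets) amplifies measurement noise into the regressed
elasticities roughly proportionally — the median relative elasticity
error is ~0.4% at CV 0.01%, ~4% at CV 0.1%, and exceeds 50% at realistic
CVs of 1–10%. Point estimates of individual elasticities (and hence
individual control coefficients) at realistic noise are therefore not
trustworthy on their own; only patterns that survive the Monte Carlo
resampling (sign-stable coefficients, rank orders) should be interpreted.
This is exactly why the analysis wraps the MCA in a resampling loop
rather than reporting single numbers. What the generator does **not** emulate: quenching losses,
13C internal-standard correction, LC–MS matrix effects, transients within
a stage, enzyme-level drift, or regulation of the clamped cofactor pools.
A pass on synthetic data therefore demonstrates correctness of the
estimators under the stated assumptions, not robustness to every artefact
of real metabolomics.

`true_control_coefficients()` is the generator's independent oracle:
central finite differences of the steady state with respect to each enzyme
activity (step 1e-3). The MCA algebra agrees with it to better than 1e-3
absolute on the shipped fixture, and both obey the summation theorems.

## Fed-batch generator and rate estimation

`generate_fedbatch_series()` integrates carbon-amount balances for a
10-L-initial dual-feed process (10 g/L batch glucose; 670 g/L glucose feed
started automatically at batch-glucose depletion; 320 g/L thiosulfate feed
from 2 h): consumed glucose carbon is partitioned into biomass, cysteine
(after a 7-h lag), NAS, acetate, and CO2 as the remainder, so total carbon
is conserved by construction at every sample. Default partition fractions
(biomass 18.4%, NAS 19.4%, cysteine 9%, acetate 1% of consumed carbon
during feeding; 50/50 biomass/CO2 in batch) reproduce the typical share
structure of such a process. Off-gas fractions are generated from the
carbon evolution rate through a nitrogen balance at a respiratory quotient
of 1, and `gas_exchange_rates()` inverts exactly that balance.

Cell-specific rates use total-amount differences with explicit feed
correction, `q = [V2 C2 - V1 C1 - fed] / ∫ X V dt` (trapezoidal), because
fed-batch volume changes make concentration derivatives biased. The biomass
carbon content defaults to 0.474 g C/g CDW (CH1.77O0.49N0.24), overridable.
Exported OAS is quantified via medium NAS — OAS isomerizes spontaneously in
the medium and the two have identical molar mass, so mg-based rates are
interchangeable. Exporter selectivity is the plain ratio of product to
by-product specific export rate; the package always reports the computed
ratio.

## Problem sizes and determinism

The shipped checks run the full 40-reaction network: 13 steady states, a
results-complete pipeline, 1,000-iteration Monte Carlo, and an
80-solve FVA, all in a few minutes on one CPU; the reference Monte Carlo
setting is 10,000 iterations. Every stochastic component (parameter draw,
noise, resampling) is governed by explicit integer seeds; reruns of the
same configuration agree to floating-point reproducibility (a threaded
BLAS may differ in the last bits between runs, so numeric agreement is
asserted at 1e-9 rather than bytewise).

## Known limitations

* Elasticities are identifiable only along directions the perturbations
  actually excite; the sulphur/demand axes fix this for the default
  network, but a user-supplied network with additional isolated branches
  may need additional designed inputs.
* Clamped currency metabolites mean regulatory effects through the
  energy/redox state are invisible to the analysis by construction.
* The thermokinetic elasticity is the pure thermodynamic component; strong
  substrate saturation near equilibrium would require an explicit kinetic
  term.
* The TFA branch-and-bound is intended for reduced-model scale (tens of
  binaries after presolve), not genome scale.
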