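# invivomca

In vivo metabolic control analysis (MCA) for microbial production
processes, built around an L-cysteine-producing *Escherichia coli*
fed-batch process.

Strain engineering for metabolite overproduction needs to know *which*
enzyme actually controls the pathway flux. MCA answers that with flux
control coefficients `C^J_ij = d ln J_i / d ln e_j` — the fractional change
of a steady-state flux per fractional change of an enzyme activity — whose
rows sum to 1 (summation theorem). The *in vivo* variant estimates the
required elasticities (`eps = d ln v / d ln c`) directly from cells pulled
out of a running production process: short-term (≤ 21 min) parallel
perturbation experiments with different carbon feeds generate a set of
metabolic steady states; intracellular metabolite concentrations and
extracellular rates per state feed a constraint-based flux estimation
(FBA / loopless FVA / thermodynamics-based flux analysis), reactions are
classified by their Gibbs reaction energy
(`dG_r = dG0' + RT * sum_j s_j ln c_j`; near equilibrium within
[-10, 0] kJ/mol), elasticities come from the thermokinetic affinity model
(`eps = -s * Gamma / (1 - Gamma)`, `Gamma = exp(dG_r/RT)`) near
equilibrium and from lin-log regression
(`v/J_ref - 1 = sum_j eps_j ln(c_j/c_j,ref)`) far from it, and control
coefficients follow from the stoichiometric matrix `N = L N_R` via
`C_S^u = -L (N_R dv/dc L)^-1 N_R`, `C_J^u = I + (dv/dc) C_S^u`. A Monte
Carlo loop (10,000 iterations by default) propagates measurement
uncertainty through the whole chain.

The package provides:

* the 37-reaction reduced model of central carbon metabolism and
  L-cysteine biosynthesis (`build_reduced_model()`), with JSON and SBML
  serialization;
* FBA, loopless FVA and TFA on an internal anti-cycling simplex
  (`fba()`, `fva()`, `tfa()`), plus `delta_g_reaction()`,
  `classify_equilibrium()`, and measured-rate reconciliation
  (`reconcile_fluxes()`);
* elasticity estimation (`thermokinetic_elasticity()`,
  `linlog_elasticities()`, `assemble_elasticity_matrix()`);
* control-coefficient algebra and Monte Carlo
  (`control_coefficients()`, `monte_carlo_mca()`,
  `control_pattern_report()`);
* bioprocess calculations (`specific_rate()`, `volumetric_productivity()`,
  `selectivity()`, `gas_exchange_rates()`, `carbon_balance()`);
* a synthetic generator with known ground truth
  (`make_default_kinetic_model()`, `generate_perturbation_dataset()`,
  `generate_fedbatch_series()`, `true_control_coefficients()`) standing in
  for the undeposited fermentation data;
* one-call orchestration (`run_pipeline()`, `run_demo()`).

See the methods vignette (`vignettes/invivomca-methods.Rmd`) for the
models, estimators and design choices.

## Worked example

```r
library(invivomca)

m <- build_reduced_model()
m
#> <metabolic_model> ecoli_cys_reduced: 37 reactions, 53 species (33 internal)

## exporter selectivity from measured specific export rates (mg/g/h):
## 24.6 mg/g/h L-cysteine vs 30.1 mg/g/h OAS (via its medium isomer NAS)
selectivity(24.6, 30.1)
#> [1] 0.8172757   # i.e. ~0.82: the exporter loses more carbon as OAS

## a mass-balanced synthetic fed-batch run and its carbon balance
fb <- generate_fedbatch_series(noise_cv = 0)
carbon_balance(fb)
#> Carbon molar balance (% of glucose carbon fed):
#>               sink    carbon_mol share_pct
#> 1          biomass  1.559355e+01     19.73
#> 2              co2  4.144782e+01     52.45
#> 3         cysteine  6.544218e+00      8.28
#> 4              nas  1.468530e+01     18.58
#> 5          acetate  7.569741e-01      0.96
#> 6 residual_glucose -3.078124e-19      0.00
#> accounted: 100%, unaccounted: 0%

specific_rate(fb, "cysteine", 20, 30)   # mg per g CDW per h, 20-30 h window
#> [1] 27.9

## full analysis on a synthetic 13-state perturbation campaign
res <- run_pipeline(pipeline_config(outdir = "mca_run", seed = 1,
                                    noise_cv = 0, mc_iterations = 200))
res$mca
#> <control_analysis> C_J: 40x40, C_S: 33x40
#>   max |row sum C_J - 1|: 4.42e-14;  max |row sum C_S|: 1.95e-13

head(control_pattern_report(res$mca, target = "YdeD"), 5)
#>   enzyme       C_J rank
#> 1    PGK 0.4907050    1
#> 2   PYRt 0.4161475    2
#> 3   PGCD 0.2080838    3
#> 4  SERAT 0.1897016    4
#> 5    FBA 0.1441566    5
```

The carbon balance closes exactly on noise-free generated data (the
generator conserves carbon by construction), so the calculator is
validated end to end; the summation-theorem residuals of the control
coefficients are at machine precision; and the ranked report reads as
"a 1% increase in phosphoglycerate kinase activity raises the
L-cysteine/OAS export flux by ~0.49%" for the leading entry. On noisy
data, interpret only coefficients that are sign-stable across the Monte
Carlo summary (`res$montecarlo$summary`).

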