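---
title: "Models and methods: formate assimilation yield, thermodynamics and chemostat statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: formate assimilation yield, thermodynamics and chemostat statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formayield)
```

`formayield` compares two ways a *Cupriavidus necator* cell can turn
formate into biomass: the native Calvin–Benson–Bassham (CBB) cycle, in
which all formate is oxidised to CO₂ and NADH and carbon re-enters through
RuBisCO, and the synthetic reductive glycine pathway (rGlyP), in which
formate is condensed onto tetrahydrofolate (THF), reduced to
methylene-THF, and fixed into glycine by the glycine cleavage system
running in reverse. This vignette documents the models behind each module,
the parameters that matter, the numerical choices, and what the bundled
synthetic data can and cannot establish.

## Flux balance analysis and the yield protocol

A stoichiometric model is a pair (S, bounds): S has one row per metabolite
and one column per reaction, and flux balance analysis (FBA) solves

$$\max_v \; c^\top v \quad \text{s.t.}\quad S v = 0,\; lb \le v \le ub .$$

The yield protocol mirrors chemostat practice. The biomass flux is fixed
to the growth rate $\mu = \ln 2 / T_d$ (we use the exact
$\ln 2/14 = 0.0495\,h^{-1}$, not the rounded dilution rate), maintenance
is imposed as

* **GAM** (growth-associated maintenance, default 135 mmol ATP gCDW⁻¹),
  the ATP-hydrolysis block of the biomass reaction. `predict_yield()`
  treats GAM as a parameter by rewriting the biomass ATP/H₂O/ADP/Pi/H⁺
  coefficients, which is what makes maintenance sweeps possible; and
* **NGAM** (non-growth-associated maintenance, default
  3 mmol ATP gCDW⁻¹ h⁻¹), a fixed flux through the ATP-maintenance
  reaction;

and the formate exchange flux is then optimised. Exchange fluxes are
negative for uptake throughout the package, so *maximising*
`EX_formate_e` minimises the uptake magnitude $q$; this is the only
direction that has a finite, biologically meaningful optimum at fixed
growth, which resolves the ambiguity in "used as the objective function".
The yield is $Y = 1000\,\mu/q$ in g CDW per mol formate. Only the
objective value (and hence $Y$) is contractually reproducible: flux
vectors at alternative optima are one of possibly many, and the solver
reports them as such.

When the requested $\mu$ is infeasible the error message reports the
largest feasible growth rate found by an 8-step bisection, which is the
quantity a user actually needs next.

CO₂/bicarbonate exchange is left unbounded by default, consistent with a
10 % CO₂ headspace; users modelling carbon-limited regimes should bound it
themselves.

### The linear-programming core

No linear-programming package ships with the R stack this package targets,
and the LP is the computational heart of both FBA and the thermodynamic
module, so `lp_solve()` implements a dense two-phase primal simplex with
explicit variable bounds. Pivoting is deterministic (Dantzig pricing,
smallest-index tie-breaks, Bland's rule after prolonged degeneracy), the
basis inverse is eta-updated and refactorised every 60 pivots, and the
pricing/feasibility tolerance is 1e−9 with reported solutions checked at
1e−6 (`S v` residual). The suite validates the solver against an
exhaustive vertex-enumeration oracle on random steady-state networks and
against closed-form chains; problems in this package's scale (tens to a
few thousand columns) are well within its comfort zone, though the dense
factorisation makes no claims for genome-scale models beyond the published
one.

### Pathway-variant edits

`variant_spec("CBB")` sets the glycine cleavage reaction `GLYAMT` — written
in the glycine-*cleaving* direction — irreversible (lower bound 0), which
blocks the glycine-synthesising reverse flux and with it the rGlyP.
`variant_spec("RGLYP")` adds formate–THF ligase (`Ftl`, formate + THF +
ATP → 10-formyl-THF + ADP + Pi) and methenyl-THF cyclohydrolase (`Fch`,
10-formyl-THF + H⁺ → 5,10-methenyl-THF + H₂O), frees `GLYAMT`, and pins
the RuBisCO flux `RBPC` to (0, 0). Added reactions are written against
canonical compound names and mapped to the target model's id dialect
through a user-editable two-column table (`read_id_map()`), because THF
species naming varies between reconstructions; the default map targets the
bundled core model.

## Max–min driving force

For a route of reactions with transformed standard Gibbs energies
$\Delta G'^\circ_j$, the MDF is

$$B^\* = \max_{B, \ln c} B \quad \text{s.t.}\quad
-\bigl(\Delta G'^\circ_j + RT \textstyle\sum_i s_{ij} \ln c_i\bigr) \ge B,$$

with each free log-concentration boxed by the constraint set. Defaults
follow the comparison conditions: 1 µM–10 mM for metabolites and
cofactors, pH 7.5, ionic strength 0.25 M, 1 mM Mg²⁺, CO₂ fixed at the
Henry's-law value for a 10 % headspace (3.4 mM), NADH/NAD⁺ fixed at 0.1
as an exact equality on logs, and the Calvin-route GAPDH step
NAD⁺-dependent. Water and protons carry no concentration variable (their
activity is inside $\Delta G'^\circ$), fixed compounds are exempt from the
box, and $RT$ uses the constraint set's temperature (default 298.15 K,
the reference temperature of the tabulated energies).

The bundled ΔG′° tables are *reconstructed* component-contribution-style
estimates (so labelled in their provenance column): the study's exact
per-reaction values live in supplementary material that is not
redistributed here, and no thermodynamic estimator is bundled. All
MDF claims in the test suite are therefore property-based — closed forms
(a single ΔG′° = 0 step attains $RT\ln 10^4 = 22.83$ kJ mol⁻¹ under the
default box), exhaustive grid search at 0.01 ln-unit resolution (kept
two-dimensional by fixing route end-points; finer-than-memory grids in
higher dimension are not attainable), and relaxation monotonicity —
never comparisons against published MDF numbers.

One property often quoted for such programs — that reversing every
reaction and negating every ΔG′° leaves B unchanged — is *not* true in
general (a single A→B step with ΔG′° = −4 has B = 26.83 forward but 18.83
reversed); the suite instead asserts the symmetric special case and the
exact pairing $B_{fwd} + B_{rev} = 2RT\ln(c_{hi}/c_{lo})$ for single
steps.

`dissolved_co2()` uses $K_H(298.15\,K) = 0.0340$ M atm⁻¹ with a van 't
Hoff coefficient of 2400 K. The familiar "10 % CO₂ = 3.4 mM" figure is
this 25 °C value (0.1 atm / 29.41 atm M⁻¹); at a 30 °C cultivation
temperature the same law gives ≈3.0 mM, and the package reports whatever
the stated temperature implies rather than forcing the rounded figure.

## Exact net route stoichiometry

`net_conversion()` finds non-negative flux multipliers, one per route
reaction, that cancel every internal intermediate and produce exactly one
pyruvate. The elimination is done in exact rational arithmetic
(integer numerator/denominator Gauss–Jordan), because the contract is that
internal compounds net to *rational zero*, not to 1e−15; when the system
is underdetermined, free multipliers are set to zero in reaction order,
which is the deterministic minimal-support tie-break. Both bundled routes
have full-rank systems with unique solutions:

* **rGlyP** (6 reactions): 2 formate + 1 CO₂ + 2 ATP + 2 NADPH + 1 NADH →
  pyruvate, THF species and ammonia fully internal. The glycine cleavage
  system is encoded in its reductive, glycine-synthesising direction, and
  serine deaminase is an ATP-neutral deamination to pyruvate.
* **CBB** (16 reactions): 3 CO₂ + 7 ATP + 5 NADH → pyruvate through
  RuBisCO (×3), reduction (×5), the full regeneration scaffold and lower
  glycolysis. The GAPDH cofactor is NAD⁺ by default; switching it to NADP⁺
  moves cost between the NADH and NADPH tallies without changing totals.

Carbon (3 per pyruvate) and degree-of-reduction balances close exactly for
both routes, using the compound formula/charge registry in
`compound_db()`.

`total_formate_per_pyruvate()` converts cofactor tallies into formate:
1 formate per NADH (formate dehydrogenase), `atp_per_nadh` (a P/O-like
lumped parameter, default 2) ATP per NADH for respiration, and a
transhydrogenase overhead per NADPH (default 1 formate-equivalent —
PntAB's proton stoichiometry is deliberately a parameter, not a membrane
model). Under any `atp_per_nadh` in (0, 10] the rGlyP's total formate
bill stays below the CBB's for the bundled routes.

## Chemostat statistics

Steady-state chemostat arithmetic is deliberately small and explicit:
doubling time $\ln 2/D$ (with a separate rounding helper for display),
turnover time $n/D$, yield = CDW / formate consumed, percent increase to
one decimal, and the plate-to-cuvette OD600 factor 4.35.
`two_sample_t()` computes per-sample yields and delegates the test itself
to `stats::t.test` (pooled or Welch, two-tailed, optionally paired),
reporting the difference of means (rGlyP − CBB), its standard error, the
95 % CI, and *both* df conventions: published figure legends sometimes
print a df that matches neither the pooled (16 for 9 + 9 samples) nor the
Welch value, and surfacing both is more useful than silently picking one.
Display rounding (yields 2 dp, percents 1 dp, hours integer) never
truncates the values carried internally.

## Synthetic data: what it does and does not establish

`build_core_model()` generates a ~30-reaction, fully element- and
charge-balanced core network: formate exchange/transport, formate
dehydrogenase, the rGlyP reactions (with the C1-entry `Ftl`/`Fch`
deliberately absent so the RGLYP recipe adds them, exactly as on the
genome-scale model), a lumped Calvin module, PntAB, lumped respiration
(η ATP per NADH), maintenance, and a single biomass pseudo-reaction whose
species formula is derived from its own stoichiometry so the balance audit
closes by construction. Defaults, chosen once as round figures for this
organism: 13 mmol pyruvate gCDW⁻¹ precursor demand (≈39 mmol C gCDW⁻¹,
kept integer so the derived biomass formula is integral), 10 mmol NADPH
and 10 mmol NH₄⁺ gCDW⁻¹, η = 2, GAM 135, NGAM 3. At the 14 h operating
point these give 5.38 (rGlyP) vs 4.58 (CBB) g CDW mol⁻¹ — the correct
*ordering* and a ~17 % relative gap, but deliberately not the genome-scale
point predictions: a single-precursor biomass is far coarser than a real
reconstruction, so the core model's contract is ordering, balances and
closed-form checkability, nothing more. The genome-scale yield figures
bind only to the published model, which users must obtain themselves.

`simulate_chemostat()` draws per-sample yields from a normal truncated at
zero (plain normals can cross zero at extreme seeds) and derives CDW as
yield × formate fed (default 0.08 mol l⁻¹; consumed = fed, since residual
formate at steady state sits below detection). It emulates sampling
variation only — no autocorrelation between sampling days, no wash-out
dynamics, no formate toxicity — so passing tests show the statistical
machinery recovers known generator parameters, not that real reactors
behave this way.

Problem sizes throughout the suite (random 8×12 networks for the LP
oracle, two free compounds for the MDF grid, n = 9 and 200 replicate
seeds for the statistics) were chosen as the smallest sizes at which the
oracles are exhaustive and the comparisons exact.

## Known limitations

* The SBML layer covers the constraint-based subset (species, formulas,
  charges, reactions, fbc-v2 and kinetic-law bounds) — it is not a general
  SBML library; models using other packages round-trip only that subset.
* The simplex is dense; fine through genome scale of the published model,
  not engineered for much larger reconstructions.
* MDF fixtures are reconstructed estimates, suitable for method validation
  and qualitative route comparison, not for quoting absolute driving
  forces.
* No proton/charge bookkeeping across the membrane: PntAB and respiration
  are lumped stoichiometric parameters.
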