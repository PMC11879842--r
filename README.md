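# formayield

Constraint-based and thermodynamic comparison of formate-assimilation
pathways in *Cupriavidus necator*: does the synthetic reductive glycine
pathway (rGlyP) support a higher biomass yield on formate than the native
Calvin–Benson–Bassham (CBB) cycle?

Formate is a promising electro-microbial feedstock, and the pathway used to
assimilate it sets the ceiling on how much cell mass a mole of formate can
buy. `formayield` packages the computational half of that question for
metabolic modellers and bioprocess engineers:

* **Flux balance analysis** as an explicit linear program
  (max c·v s.t. S·v = 0, lb ≤ v ≤ ub) over SBML Level 3 Version 1 models,
  with the pathway-variant model edits that switch a *C. necator* network
  between CBB-only and rGlyP-only formatotrophy (make the glycine cleavage
  reaction `GLYAMT` irreversible for CBB; add `Ftl`/`Fch`, free `GLYAMT`,
  and pin `RBPC` to zero for the rGlyP), growth fixed at μ = ln 2 / T_d,
  maintenance split into GAM (biomass ATP hydrolysis, mmol gCDW⁻¹) and
  NGAM (fixed ATP-maintenance flux, mmol gCDW⁻¹ h⁻¹), and the yield
  Y = 1000·μ/q in g CDW per mol formate, q being the minimised uptake
  magnitude.
* **Max–min driving force (MDF)** analysis: the largest B such that every
  route reaction can sustain a driving force −ΔG′ ≥ B with metabolite
  concentrations in 1 µM–10 mM at pH 7.5, I = 0.25 M, 1 mM Mg²⁺, CO₂ fixed
  at its 10 %-headspace Henry value (3.4 mM) and NADH/NAD⁺ = 0.1 — solved
  as a linear program over log-concentrations.
* **Exact net pathway stoichiometry**: rational-arithmetic elimination of
  route intermediates yielding per-pyruvate ATP/NAD(P)H/formate/CO₂
  tallies, plus the total formate bill once formate dehydrogenase and the
  PntAB transhydrogenase regenerate the cofactors.
* **Chemostat yield statistics**: dilution-rate arithmetic, yield =
  CDW / formate consumed, percent increase, and the two-sample t machinery
  (pooled and Welch) for strain comparisons.
* **Synthetic data generators** for all of the above: a fully
  element/charge-balanced ~30-reaction *C. necator* core network that
  supports both pathway variants, toy models with closed-form yields, and
  seeded chemostat sample tables — so the entire pipeline runs and is
  tested without downloading anything.

## Worked example

```r
library(formayield)

core <- build_core_model()           # balanced core network, 27 reactions
predict_yield(core, "CBB",   doubling_time = 14, gam = 135, ngam = 3)
#> yield_prediction [CBB]: Td=14 h, mu=0.0495 h^-1, q=10.8080 mmol/gCDW/h, Y=4.581 g CDW/mol
predict_yield(core, "RGLYP", doubling_time = 14, gam = 135, ngam = 3)
#> yield_prediction [RGLYP]: Td=14 h, mu=0.0495 h^-1, q=9.1989 mmol/gCDW/h, Y=5.382 g CDW/mol
```

At the chemostat operating point (14 h doubling time, GAM = 135,
NGAM = 3) the rGlyP variant of the core network needs ~15 % less formate
per unit biomass than the CBB variant — a ~17 % higher yield, the ordering
the pathway energetics predict:

```r
compare_routes(atp_per_nadh = 2)
#>   route reaction_count atp_cost nadph_cost nadh_cost formate_assimilated co2_fixed formate_total
#> 1 RGLYP              6        2          2         1                   2         1           6.0
#> 2   CBB             16        7          0         5                   0         3           8.5
```

Per pyruvate, the rGlyP assimilates 2 formate + 1 CO₂ at a cost of 2 ATP,
2 NADPH and 1 NADH (6 formate total once cofactors are regenerated); the
Calvin route fixes 3 CO₂ for 7 ATP and 5 NADH (8.5 formate total at
2 ATP/NADH respiration). A simulated chemostat at the study conditions
(means 3.88/4.52 g CDW mol⁻¹, SDs 0.19/0.17, n = 9):

```r
two_sample_t(simulate_chemostat(seed = 1), "welch")
#> yield_comparison (welch):
#>   CBB   3.91 +/- 0.15 (n=9)
#>   RGLYP 4.53 +/- 0.19 (n=9)
#>   diff 0.6201 +/- 0.08138; t=7.621 df=15.37 p=1.33e-06
#>   95% CI [0.4471, 0.7932]; +15.8%
```

A command-line entry point wraps the same functions:

```sh
Rscript inst/exec/formayield predict-yield --model core --variant both \
    --doubling-time 14 --gam 135 --ngam 3
Rscript inst/exec/formayield mdf --route both
Rscript inst/exec/formayield simulate chemostat --seed 1 -o samples.tsv
```

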