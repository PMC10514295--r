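# enzchar

Characterization of small-molecule enzyme inhibitors from plate-reader data,
as applied to α-glucosidase inhibitors assayed with p-nitrophenyl
glucopyranoside: dose-response potency, inhibition kinetics, fluorescence
binding analysis, thermodynamics, and secondary-structure comparison — with
seeded synthetic-data generators so every estimator is validated by
parameter recovery.

The pipeline covers five stages:

1. **IC50 by the logit method** — percent inhibition
   `%I = 100·(A_ctrl − A_sample)/A_ctrl`, then OLS of `ln(p/(1−p))` on
   `log10 c` and inversion `IC50 = 10^(−intercept/slope)`; fold potency and
   Welch t-tests against a reference inhibitor.
2. **Ki and inhibition mode** — per-inhibitor Lineweaver–Burk fits
   (`1/v` on `1/S`), the secondary replot
   `Km_app = Km + (Km/Ki)·[I]` giving `Ki = intercept/slope`, and
   classification of competitive / noncompetitive / uncompetitive / mixed
   patterns from the Km_app and Vmax trends.
3. **Binding constants from static quenching** — the linearized plot
   `F0/F = KA·x − n·KA·Pt` with `x = Dt·F0/(F0 − F)`, an exact consequence
   of the ground-state complexation mass balance; a forward-model refit
   (`refine_binding`) for noisy data; static-vs-dynamic classification from
   KA's temperature dependence.
4. **Thermodynamic profile** — two-point van't Hoff ΔH, ΔG = −RT·ln KA,
   ΔS = (ΔH − ΔG)/T, and sign-rule classification of the dominant
   non-covalent interaction (hydrophobic / H-bond+vdW / electrostatic).
5. **CD composition comparison** — α-helix / β-turn / random-coil deltas
   between native and inhibitor-bound enzyme, with a 100%-sum validity check.

See `vignettes/enzyme-inhibitor-characterization.Rmd` for the models,
estimator choices, and limitations.

## Worked example

Recover an inhibition constant from synthetic competitive-inhibition data
generated at the assay grids (substrate 1–10 mM; inhibitor 0, 3.1, 6.2,
12.4 µM), then profile the binding thermodynamics from two measured
association constants:

```r
library(enzchar)

vds <- gen_velocity_dataset(km_mM = 1, vmax = 1, ki_uM = 11,
                            s_grid_mM = 1:10, i_grid_uM = c(0, 3.1, 6.2, 12.4))
analyze_kinetics(vds)
#> <ki_result> Ki = 11 uM, Km = 1 mM, mode = competitive

thermodynamic_profile(ka1_per_M = 40.5e4, t1_K = 293,
                      ka2_per_M = 36.6e4, t2_K = 333)
#> <thermo_profile> dH = -2.05 kJ/mol, dG = -31.5 kJ/mol, dS = 100 J/(mol K) at 293 K -> electrostatic

fold_potency(750.0, 12.44)
#> [1] 60.28939
```

On noiseless data the kinetics pipeline returns the generating parameters
exactly (Ki = 11 µM, Km = 1 mM) and calls the competitive pattern from the
rising Km_app / steady Vmax trend. The thermodynamic profile reads: binding
is weakly exothermic (ΔH < 0) and entropy-driven (ΔS > 0), the sign pair
associated with electrostatic interactions, and ΔG < 0 means spontaneous
association. The fold-potency ratio says the compound is ~60.3× more potent
than the 750 µM reference inhibitor.

## The analysis workflow

Numbered drivers under `analysis/` run the whole characterization on
simulated raw data and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # assay, velocity, titration, CD CSVs
Rscript analysis/02_dose_response.R   # IC50s, fold potency, Welch test
Rscript analysis/03_kinetics.R        # LB fits, mode, Ki replot
Rscript analysis/04_binding_thermo.R  # KA/n per temperature, mechanism, dH/dG/dS
Rscript analysis/05_cd_comparison.R   # composition deltas
Rscript analysis/06_report.R          # assembled JSON compound report
```

A representative run prints, among other things:

```text
inhibition mode: competitive (Km_app rises, Vmax steady)
secondary replot: Km = 0.959 mM, Ki = 9.22 uM
quenching mechanism: static (KA falls with temperature)
dominant interaction: electrostatic
```

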