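# myotension

Quantitative analysis linking non-muscle myosin II motor activity to
epithelial tissue contraction, built around three measurements that span
the molecule-to-tissue scale:

1. **Steady-state ATPase kinetics** of a regulatory-light-chain (RLC)
   allelic series — Michaelis–Menten fits
   (`rate = k_basal + k_cat·[A]/(K_app + [A])`), identifiability flagging
   for near-linear actin dependence, endpoint activity `k_100`, fold
   activation by phosphorylation, and in vitro motility gliding speeds with
   stage-drift correction.
2. **Laser-ablation recoil** — wound-edge displacement extraction from
   kymographs, Kelvin–Voigt fits `x(t) = A(1 − e^(−t/τ))` giving the
   initial recoil velocity `v0 = A/τ` (a tension readout at constant
   viscosity) and time decay constant `τ`, plus power-law fits
   `x = β·t^α`, with an `R² > 0.5` acceptance filter.
3. **Apical constriction rates normalized to myosin accumulation** — trace
   smoothing, instantaneous rates, detection of accumulation instances
   whose rate lies 1–2 SD above the control-cohort mean, constriction rates
   conditioned on those instances, embryo alignment at constriction onset,
   and the time for mean apical area to halve.

A seeded synthetic-data generator emulates all three input classes with
known ground truth (Michaelis–Menten curves, Kelvin–Voigt traces and
rendered kymographs, coupled myosin-pulse/area traces with genotype-specific
motor-activity scaling), so the whole pipeline is testable without
microscopy data. Mann–Whitney comparisons and an end-to-end pipeline driver
with validated YAML configuration round it out. See the methods vignette
(`vignettes/myotension-methods.Rmd`) for the models, assumptions and
parameter choices.

## Worked example

```r
library(myotension)

# --- enzymology: fit a synthetic wild-type ATPase assay -------------------
ds <- gen_atpase_dataset(mm_params(0.010, 1.23, 38.9),
                         c(0, 2, 5, 10, 20, 40, 70, 100),
                         noise_sd = 0.02, n_replicates = 4, seed = 101,
                         variant = "RLC-TS")
fit_michaelis_menten(ds)
#> Michaelis-Menten fit (n = 32, R^2 = 0.9975)
#>   k_basal = 0.006364 +/- 0.0062 s^-1
#>   k_cat   = 1.225 +/- 0.021 s^-1
#>   K_app   = 37.92 +/- 2 uM

# --- recoil: fit a noisy ablation trace -----------------------------------
tr <- gen_displacement_trace(list(amplitude = 2, tau = 5), dt = 1.3,
                             duration = 26, noise_sd = 0.05, seed = 9)
fit <- fit_kelvin_voigt(tr)
sprintf("v0 = %.3f um/s, tau = %.2f s, R^2 = %.3f",
        initial_recoil_velocity(fit), time_decay_constant(fit),
        fit$r_squared)
#> "v0 = 0.397 um/s, tau = 5.05 s, R^2 = 0.992"
```

The fitted `k_cat` and `K_app` recover the generating truth (1.23 s⁻¹,
38.9 µM) within their standard errors; the recoil fit recovers the
generating `v0 = A/τ = 0.4` µm/s and `τ = 5` s from a trace with 0.05 µm
noise, and passes the `R² > 0.5` acceptance filter.

For the tissue-scale analysis, `run_pipeline()` generates a synthetic
allelic series with motor-activity factors per genotype, detects
accumulation events against the control statistics, and writes summary
tables — the `percent_of_control` column of `constriction_summary.tsv`
recovers the generating factors:

```r
out <- run_pipeline(list(out_dir = "demo-run", seed = 7))
read.delim("demo-run/constriction_summary.tsv")[, c("genotype",
  "motor_activity_factor", "n_events", "percent_of_control")]
#>   genotype motor_activity_factor n_events percent_of_control
#> 1   RLC-TS                  1.00      457          100.00000
#> 2   RLC-AS                  0.74      457           73.90974
#> 3   RLC-TA                  0.60      457           59.86114
#> 4   RLC-AE                  0.47      457           46.81601
```

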