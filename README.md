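# afmindent

Elastoviscoplastic analysis of AFM nanoindentation force curves, built
for stiff biological cells such as corneocytes (the keratin-filled dead
cells of the outermost skin layer), where a sharp tip driven to
micro-newton forces deforms the cell plastically and the usual Hertzian
cell-mechanics toolbox does not apply.

The package implements, end to end:

- **Tip-shape calibration** on a linear-elastic reference elastomer of
  known plane-strain modulus E\* via Sneddon contact mechanics for
  power-law indenters: from the smoothed loading curve, the local load
  index *m*(h) gives the profile index *n* = 1/(*m* − 1), the stiffness
  gives the contact radius *a* = *S*/2E\*, and the depth scaling
  κ(*n*) = √π Γ((n+2)/2)/Γ((n+1)/2) maps depth to contact depth; the tip
  radius function *a*(h_c) is fitted as a degree-6 polynomial plus a
  power-law cap h_c = c aⁿ near the apex.
- **Oliver–Pharr style unloading analysis**: quadratic unloading fit
  F = C_e(h − h_f)², stiffness S₀, sink-in h_s = φF_max/S₀ (φ = 0.73),
  contact depth h_c = h_max − h_s, Young's modulus
  E = (√π/2)(1 − ν²)S₀/√A_max and hardness H = F_max/A_max with
  σ_Y = H/ψ (ψ ≈ 3).
- **Prony relaxation** of the constant-position hold,
  F(t) = B₀ + B₁e^(−t/τ₁) + B₂e^(−t/τ₂), converted to hardness
  relaxation C_i = B_i/(πa²) with instantaneous / long-term hardness
  H₀ = ΣC_i and H∞ = C₀.
- **Herschel–Bulkley viscoplastic fitting** of the stress vs plastic
  strain-rate locus, σ = σ_Y + k (dε_p/dt)^j, with
  dε_p/dt = (3/E)(C₁/τ₁ e^(−t/τ₁) + C₂/τ₂ e^(−t/τ₂)).
- **A forward simulator** (`generate_dataset()`) producing
  loading–pause–unloading curves — 3 participants × 5 cells × 64-curve
  grids at 0.5 µm/s, 4 s dwell, 2 µN setpoint — with per-curve ground
  truth, so every stage is validated by parameter recovery.

## Worked example

Calibrate a tip from 64 simulated reference-elastomer curves, then
analyse one simulated corneocyte indentation:

```r
library(afmindent)
set.seed(42)

tip_true <- default_tip_truth()           # 15 nm truncated cone
refs <- generate_reference_curves(tip_true, n_curves = 64,
                                  noise_sd = 0.01 * 250e-9)
cal <- calibrate_tip(refs)

cell <- material_truth("viscoplastic", E = 1.18e9, nu = 0.4,
                       C0 = 151e6, C1 = 30e6, C2 = 17e6,
                       tau1 = 0.12, tau2 = 1.99)
cv <- elastoplastic_curve(cell, tip_true, f_max = 2e-6, dwell = 4,
                          noise_sd = 5e-9, curve_id = "demo")
cp <- detect_contact_point(cv)
ic <- to_indentation(cv, cp$z0_m, cp$f0_N)
ind <- analyze_indentation(ic, cal$tip); print(ind)
rel <- analyze_relaxation(ic, ind); print(rel)
```

```
<unloading_result> demo
  E = 1124.0 MPa, H = 140.0 MPa, S0 = 157.6 N/m
  h_max = 77.5 nm (h_c 70.4 + h_s 7.1), h_f = 58.1 nm, a = 58.9 nm
<relaxation_result> demo
  H0 = 183.3 MPa, H_inf = 140.2 MPa (tau1 = 0.119 s, tau2 = 1.95 s)
<hb_fit>
  sigma_Y = 47.7 MPa, k = 16.4 MPa s^j, j = 0.535 (R^2 = 0.990)
```

Reading the numbers: the Young's modulus (1.12 GPa vs the 1.18 GPa
ground truth) and the relaxation times (0.119 / 1.95 s vs 0.12 / 1.99 s)
are recovered within a few percent; H₀ is ~8% low because the contact
radius comes from the *calibrated* tip, whose pointwise-κ chain carries
a ~3% radius bias for non-power-law tips (see the methods vignette).
The yield stress σ_Y ≈ 48 MPa sits just below the long-term stress
C₀/ψ ≈ 50 MPa, as the Herschel–Bulkley limit requires.

A full dataset runs through the pipeline as:

```r
info <- generate_dataset("ds", seed = 1)          # 960 curves
tip  <- as_tip_profile(default_tip_truth())
b    <- run_pipeline(info$manifest, tip, out_dir = "out")
aggregate_results(b$results, "participant")       # medians and ranges
report_results(b, "report")                       # histograms, tables
```

or from the command line via `afm_cli()`: subcommands `simulate`,
`calibrate-tip`, `analyze-indent`, `analyze-relax`, `run-all`,
`report`.

## Documentation

The methods vignette (`vignettes/afmindent-methods.Rmd`) describes the
contact model and its assumptions, every tunable parameter with units
and defaults, what the synthetic world does and does not emulate, the
numerical choices (smoothing bases, bounded fits, tie-breaks), and the
known limitations.
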