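# shared fixtures, all generated in code

# standard material truth: glassy corneocyte-like viscoplastic cell
fixture_truth <- function(E = 1183e6, C0 = 151e6, C1 = 30e6, C2 = 17e6,
                          tau1 = 0.12, tau2 = 1.99) {
  material_truth("viscoplastic", E = E, nu = 0.4, C0 = C0, C1 = C1,
                 C2 = C2, tau1 = tau1, tau2 = tau2)
}

# a 15 nm truncated cone, the default simulator tip
fixture_tip <- function() default_tip_truth()

# a pure power-law tip with realistic scale (a = 60 nm at h_c = 70 nm)
fixture_powerlaw_tip <- function(n = 2.5) {
  indenter_truth("power_law", c_si = 70e-9 / (60e-9)^n, n = n)
}

# full synthetic curve in force units, optionally noisy
fixture_curve <- function(truth = fixture_truth(), dwell = 4,
                          noise_sd = 0, dt = 2e-3, ...) {
  elastoplastic_curve(truth, fixture_tip(), f_max = 2e-6, dwell = dwell,
                      dt = dt, noise_sd = noise_sd, ...)
}

# relative error helper
rel_err <- function(x, ref) abs(x - ref) / abs(ref)

# profile coefficient in the conventional um^(1-n) units used by
# tip-geometry tables (the natural scale of contact radii ~0.1 um)
c_um <- function(c_si, n) convert_profile_coefficient(c_si, n, "m", "um")
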