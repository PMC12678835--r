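# tip-shape calibration: depth-scaling closed forms, index mappings,
# smoothing, profile fitting and full-chain recovery

test_that("depth scaling factor has its closed-form values", {
  expect_equal(depth_scaling_kappa(2), 2, tolerance = 1e-13)
  expect_equal(depth_scaling_kappa(1), pi / 2, tolerance = 1e-13)
  expect_equal(depth_scaling_kappa(4), 8 / 3, tolerance = 1e-13)
  # kappa > 1 and increasing in n
  n <- seq(0.5, 20, by = 0.25)
  k <- depth_scaling_kappa(n)
  expect_true(all(k > 1))
  expect_true(all(diff(k) > 0))
  expect_error(depth_scaling_kappa(0), "> 0")
})

test_that("profile index and load index are mutual inverses", {
  expect_equal(profile_index(1.45), 2.22, tolerance = 2e-3)
  expect_equal(profile_index(1.663), 1.51, tolerance = 2e-3)
  expect_equal(profile_index(1.5), 2)
  expect_equal(profile_index(2), 1)
  expect_equal(load_index_from_profile(2), 1.5)
  m <- seq(1.1, 3, by = 0.05)
  expect_equal(load_index_from_profile(profile_index(m)), m,
               tolerance = 1e-12)
  expect_error(profile_index(1), "undefined")
})

test_that("profile coefficient unit conversion is involutive", {
  set.seed(2)
  for (n in c(1, 1.51, 4.62, 7.55)) {
    c_si <- 10^runif(1, -5, 12)
    c_um2 <- convert_profile_coefficient(c_si, n, "m", "um")
    expect_equal(convert_profile_coefficient(c_um2, n, "um", "m"), c_si,
                 tolerance = 1e-12)
    # the relation h_c = c a^n holds in both conventions
    a_m <- 60e-9
    hc_m <- c_si * a_m^n
    expect_equal(c_um2 * (a_m * 1e6)^n, hc_m * 1e6, tolerance = 1e-10)
  }
  expect_equal(convert_profile_coefficient(5, 1, "m", "um"), 5)
})

test_that("averaging handles identical, mixed and unsupported grids", {
  tip <- fixture_powerlaw_tip(2)
  cv <- sneddon_elastic_curve(tip, 3.79e6, 100e-9, n_points = 150)
  avg <- average_loading_curves(list(cv, cv, cv))
  expect_equal(stats::approx(cv$data$depth_m, cv$data$force_N,
                             xout = avg$h)$y, avg$F, tolerance = 1e-9)
  # mean of two different-modulus Hertz curves is the mean of closed forms
  cva <- sneddon_elastic_curve(tip, 2e6, 100e-9, n_points = 150)
  cvb <- sneddon_elastic_curve(tip, 6e6, 100e-9, n_points = 150)
  avg2 <- average_loading_curves(list(cva, cvb, cva, cvb))
  f_expect <- (power_law_elastic_force(2e6, tip$c_si, 2, avg2$h) +
                 power_law_elastic_force(6e6, tip$c_si, 2, avg2$h)) / 2
  expect_equal(avg2$F, f_expect, tolerance = 1e-3)
  expect_error(average_loading_curves(list(cv, cv)), "at least 3")
  expect_error(average_loading_curves(list(cv, cv, cv),
                                      grid = seq(1e-9, 1e-6, 1e-9)),
               "beyond the support")
  # short curves are excluded with a warning
  short <- sneddon_elastic_curve(tip, 3.79e6, 20e-9, n_points = 150)
  expect_warning(average_loading_curves(list(cv, cv, cv, short)),
                 "excluded")
})

test_that("linear-scale polynomial smoother recovers exact quadratics", {
  h <- seq(1e-9, 100e-9, length.out = 80)
  alpha <- 0.05       # N/m
  beta <- 2e6         # N/m^2: transition depth alpha/beta = 25 nm
  F <- alpha * h + beta * h^2
  fit <- smooth_load_curve(h, F, order = 2)
  expect_equal(predict(fit, h), F, tolerance = 1e-10)
  expect_equal(stiffness_profile(fit, h), alpha + 2 * beta * h,
               tolerance = 1e-8)
  # analytic load index for alpha h + beta h^2, with its two limits
  m <- load_index_profile(fit, h)
  expect_equal(m, (alpha + 2 * beta * h) / (alpha + beta * h),
               tolerance = 1e-8)
  expect_lt(m[1], 1.05)       # -> 1 near contact
  expect_gt(max(m), 1.7)      # -> 2 at depth
  expect_error(smooth_load_curve(h, F, order = 1), "order")
})

test_that("log-log smoother represents power laws exactly", {
  tip <- fixture_powerlaw_tip(2.5)
  h <- exp(seq(log(1e-9), log(300e-9), length.out = 200))
  F <- power_law_elastic_force(3.79e6, tip$c_si, 2.5, h)
  fit <- smooth_load_loglog(h, F, order = 3)
  expect_equal(predict(fit, h), F, tolerance = 1e-10)
  expect_equal(load_index_profile(fit, h), rep(1.4, 200),
               tolerance = 1e-8)
})

test_that("contact radius, depth map and their worked examples", {
  # S = 0.01 N/m at E* = 3.79 MPa -> a = 1.32 nm
  expect_equal(contact_radius_profile(0.01, 3.79e6), 1.3193e-9,
               tolerance = 1e-4)
  # Hertz R = 50 nm at h = 10 nm: S = 2 E* sqrt(R h / 2)
  e_star <- 3.79e6
  S <- 2 * e_star * sqrt(50e-9 * 10e-9 / 2)
  expect_equal(contact_radius_profile(S, e_star), sqrt(50e-9 * 10e-9 / 2))
  expect_error(contact_radius_profile(0.01, 0), "> 0")
  # paraboloid: h = 2 h_c; cone: h_c = 2h/pi
  expect_equal(contact_depth_map(40e-9, 2), 20e-9)
  expect_equal(contact_depth_map(40e-9, 1), 40e-9 * 2 / pi)
  expect_error(contact_depth_map(40e-9, -1), "finite and > 0")
})

test_that("fit_tip_profile recovers exact geometries from (h_c, a) points", {
  cfg <- calibration_config()
  # truncated cone: d0, d1 within 2%, higher terms negligible
  h_c <- seq(1e-9, 220e-9, length.out = 120)
  a <- 15e-9 + 0.6 * h_c
  tip <- fit_tip_profile(h_c, a, cfg)
  expect_equal(tip$d[1], 15e-9, tolerance = 0.02)
  expect_equal(tip$d[2], 0.6, tolerance = 0.02)
  a200 <- 15e-9 + 0.6 * 200e-9
  contrib <- abs(tip$d[3:7]) * (200e-9)^(2:6)
  expect_true(all(contrib < 0.01 * a200))
  # paraboloid: evaluate_tip at h_c = 20 nm gives sqrt(2 R h_c)
  R <- 50e-9
  a2 <- sqrt(2 * R * h_c)
  # the degree-6 polynomial cannot follow sqrt below the fit range, so
  # the splice diagnostic fires; that is expected for this geometry
  expect_warning(tip2 <- fit_tip_profile(h_c, a2, cfg), "splice")
  expect_equal(as.numeric(evaluate_tip(tip2, 20e-9)), sqrt(2 * R * 20e-9),
               tolerance = 0.02)
  expect_error(fit_tip_profile(h_c[1:5], a[1:5], cfg), "fewer than 20")
})

test_that("evaluate_tip: cap behaviour and extrapolation flags", {
  cfg <- calibration_config()
  h_c <- seq(1e-9, 220e-9, length.out = 120)
  tip <- suppressWarnings(fit_tip_profile(h_c, sqrt(2 * 50e-9 * h_c), cfg))
  expect_equal(as.numeric(evaluate_tip(tip, 0)), 0)   # cap through origin
  expect_error(evaluate_tip(tip, -1e-9), ">= 0")
  expect_warning(a_out <- evaluate_tip(tip, 2 * tip$hc_range[2]),
                 "extrapolated")
  expect_true(attr(a_out, "extrapolated"))
  expect_false(attr(evaluate_tip(tip, 50e-9), "extrapolated"))
})

test_that("full-chain recovery of a power-law tip is exact when noiseless", {
  n_true <- 2.5
  tip <- fixture_powerlaw_tip(n_true)
  refs <- generate_reference_curves(tip, n_curves = 8, noise_sd = 0)
  cal <- suppressWarnings(calibrate_tip(refs))
  pl <- cal$tip$powerlaw
  expect_lt(rel_err(pl$n, n_true), 0.02)
  expect_lt(rel_err(c_um(pl$c_si, pl$n), c_um(tip$c_si, n_true)), 0.02)
  # m(h) constant at 1 + 1/n along the chain
  expect_lt(max(abs(cal$profiles$m - 1.4)), 1e-3)
  # a(h_c) monotone increasing
  expect_true(all(diff(cal$profiles$a) > 0))
})

test_that("tip profile serialization round trips", {
  h_c <- seq(1e-9, 220e-9, length.out = 120)
  tip <- fit_tip_profile(h_c, 15e-9 + 0.6 * h_c, calibration_config())
  path <- withr::local_tempfile(fileext = ".json")
  write_tip_profile(tip, path)
  tip2 <- read_tip_profile(path)
  expect_equal(tip2$d, tip$d, tolerance = 1e-12)
  expect_equal(tip2$cap$n, tip$cap$n, tolerance = 1e-12)
  hc_test <- c(2e-9, 50e-9, 150e-9)
  expect_equal(as.numeric(evaluate_tip(tip2, hc_test)),
               as.numeric(evaluate_tip(tip, hc_test)), tolerance = 1e-10)
})
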