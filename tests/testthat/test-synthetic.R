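# forward simulator: closed forms, quadrature oracle, hysteresis,
# relaxation and dataset determinism

test_that("power-law elastic force reduces to Hertz at n = 2", {
  # F = (4/3) E* sqrt(R) h^(3/2) with c = 1/(2R)
  set.seed(1)
  for (i in 1:50) {
    e_star <- runif(1, 1e6, 1e10)
    R <- runif(1, 10e-9, 500e-9)
    h <- runif(1, 1e-10, 100e-9)
    expect_equal(power_law_elastic_force(e_star, 1 / (2 * R), 2, h),
                 4 / 3 * e_star * sqrt(R) * h^1.5,
                 tolerance = 1e-12)
  }
  # worked example: E* = 3.79 MPa, R = 50 nm, h = 10 nm -> 1.13 nN
  expect_equal(power_law_elastic_force(3.79e6, 1 / (2 * 50e-9), 2, 10e-9),
               1.129959685e-9, tolerance = 1e-9)
  expect_equal(power_law_elastic_force(3.79e6, 1e7, 2, 0), 0)
  expect_error(power_law_elastic_force(3.79e6, 1e7, 2, -1e-9), ">= 0")
})

test_that("generated load index matches 1 + 1/n by log-log regression", {
  for (n in c(1.3, 2, 3.1)) {
    tip <- fixture_powerlaw_tip(n)
    cv <- sneddon_elastic_curve(tip, 3.79e6, h_max = 200e-9,
                                n_points = 200)
    d <- cv$data[cv$data$depth_m > 0, ]
    m_fit <- unname(coef(lm(log(d$force_N) ~ log(d$depth_m)))[2])
    expect_equal(m_fit, 1 + 1 / n, tolerance = 1e-6)
  }
})

test_that("paraboloid curve is Hertzian and quadrature matches closed form", {
  tip <- indenter_truth("paraboloid", R_m = 53e-9)
  cv <- sneddon_elastic_curve(tip, 3.79e6, h_max = 100e-9, n_points = 120)
  d <- cv$data[cv$data$depth_m > 0, ]
  m_fit <- unname(coef(lm(log(d$force_N) ~ log(d$depth_m)))[2])
  expect_equal(m_fit, 1.5, tolerance = 1e-6)

  # truncated cone: numeric integration against a 10x-resolution oracle
  tip2 <- fixture_tip()
  cv2 <- sneddon_elastic_curve(tip2, 3.79e6, h_max = 300e-9,
                               n_points = 60, n_internal = 2000)
  oracle <- sneddon_elastic_curve(tip2, 3.79e6, h_max = 300e-9,
                                  n_points = 60, n_internal = 20000)
  f1 <- cv2$data$force_N[-1]
  f0 <- oracle$data$force_N[-1]
  expect_lt(max(abs(f1 - f0) / f0), 1e-3)
  expect_true(all(diff(cv2$data$force_N) > 0))
  expect_error(sneddon_elastic_curve(tip2, 3.79e6, 1e-7, n_points = 2),
               "too few samples")
})

test_that("elastoplastic curve has consistent S0, hysteresis and h_f", {
  # S0 = 2 a E / (1 - nu^2): a = 100 nm, E = 1 GPa, nu = 0.4 -> 238 N/m
  expect_equal(2 * 100e-9 * 1e9 / (1 - 0.4^2), 238.09524,
               tolerance = 1e-7)
  tr <- material_truth("elastoplastic", E = 1e9, nu = 0.4, H = 177e6)
  # F = pi a^2 H inversion: a at 2 uN, H = 177 MPa is about 60 nm
  cv <- elastoplastic_curve(tr, fixture_tip(), f_max = 2e-6)
  tt <- attr(cv, "truth")
  expect_equal(tt$a_max, sqrt(2e-6 / (pi * 177e6)), tolerance = 1e-12)
  expect_equal(tt$a_max, 59.97e-9, tolerance = 1e-3)
  expect_equal(tt$S0, 2 * tt$a_max * 1e9 / (1 - 0.16), tolerance = 1e-12)
  expect_gt(tt$h_f, 0)

  # hysteresis: unloading force below loading force at matched depths
  ic <- to_indentation(cv, 0, 0)
  app <- ic$data[ic$data$segment == "approach" & ic$data$depth_m > 0, ]
  ret <- ic$data[ic$data$segment == "retract" & ic$data$force_N > 0, ]
  f_load <- approx(app$depth_m, app$force_N, xout = ret$depth_m)$y
  expect_true(all(ret$force_N <= f_load + 1e-15))

  # raising H toward the fully-yielded validity boundary shrinks the
  # residual depth toward zero (elastic reversibility limit) ...
  ratio_at <- function(H) {
    tr2 <- material_truth("elastoplastic", E = 1e9, nu = 0.4, H = H)
    cv2 <- elastoplastic_curve(tr2, fixture_powerlaw_tip(2), f_max = 2e-6)
    attr(cv2, "truth")$h_f / attr(cv2, "truth")$h_max
  }
  r <- vapply(c(0.1e9, 0.25e9, 0.4e9), ratio_at, numeric(1))
  expect_true(all(diff(r) < 0))
  expect_lt(r[3], 0.12)
  # ... and beyond it the model degenerates and is rejected
  expect_error(ratio_at(0.6e9), "degenerate")
  expect_error(
    elastoplastic_curve(material_truth("elastoplastic", E = 1e8, H = 2e8),
                        fixture_tip(), 2e-6),
    "nonphysical")
})

test_that("relaxation curve obeys Prony limits and monotonicity", {
  tr <- fixture_truth()  # C0+C1+C2 = 198 MPa, H_inf = 151 MPa
  a <- 60e-9
  rc <- relaxation_curve(tr, a, dwell = 4, dt = 1e-3)
  expect_equal(rc$force_N[1], pi * a^2 * 198e6, tolerance = 1e-12)
  expect_equal(rc$force_N[1], 2.2393e-6, tolerance = 1e-4)
  expect_true(all(diff(rc$force_N) <= 0))
  # closed-form value at the end of the hold
  f4 <- pi * a^2 * (151e6 + 30e6 * exp(-4 / 0.12) + 17e6 * exp(-4 / 1.99))
  expect_equal(rc$force_N[nrow(rc)], f4, tolerance = 1e-12)
  # constant force when only C0 present
  tr2 <- material_truth("viscoplastic", E = 1e9, C0 = 100e6, C1 = 0,
                        C2 = 0, tau1 = 0.1, tau2 = 1)
  rc2 <- relaxation_curve(tr2, a, dwell = 2, dt = 1e-2)
  expect_equal(diff(range(rc2$force_N)), 0)
  expect_warning(relaxation_curve(tr, a, dwell = 4, dt = 0.5),
                 "identifiable")
})

test_that("generate_dataset is deterministic and writes coherent sidecars", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  i1 <- generate_dataset(d1, seed = 7, cells_per_participant = 1,
                         grid_dim = 2, dwell = 0.5)
  i2 <- generate_dataset(d2, seed = 7, cells_per_participant = 1,
                         grid_dim = 2, dwell = 0.5)
  expect_equal(i1$n_curves,
               nrow(default_participant_truth()) * 1 * 4)
  expect_identical(readLines(i1$manifest), readLines(i2$manifest))
  expect_identical(readLines(i1$truth), readLines(i2$truth))
  # a sampled curve file is byte-identical too
  man <- read.csv(i1$manifest)
  expect_identical(readLines(file.path(d1, man$file[1])),
                   readLines(file.path(d2, man$file[1])))
  # truth sidecar rows align with the manifest
  truth <- read.csv(i1$truth)
  expect_setequal(truth$curve_id, man$curve_id)
  expect_true(all(truth$tau1 < truth$tau2))
  expect_true(all(truth$H0 < truth$E))
})
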