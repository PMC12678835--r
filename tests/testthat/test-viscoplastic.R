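# relaxation and viscoplastic fitting: Prony, hardness relaxation,
# strain rates, stress series and Herschel-Bulkley

test_that("Prony fit recovers exact two-term relaxations", {
  t <- seq(0, 4, by = 1e-3)
  f <- (1.0 + 0.5 * exp(-t / 0.15) + 0.3 * exp(-t / 2.0)) * 1e-6
  pf <- fit_prony(t, f)
  expect_lt(rel_err(pf$B0, 1.0e-6), 0.01)
  expect_lt(rel_err(pf$B1, 0.5e-6), 0.01)
  expect_lt(rel_err(pf$B2, 0.3e-6), 0.01)
  expect_lt(rel_err(pf$tau1, 0.15), 0.01)
  expect_lt(rel_err(pf$tau2, 2.0), 0.01)
  expect_lt(pf$tau1, pf$tau2)
  expect_true(all(pf$identifiable))
  expect_gt(pf$r_squared, 0.999)
})

test_that("constant force gives the degenerate Prony fit", {
  t <- seq(0, 4, by = 1e-2)
  expect_warning(pf <- fit_prony(t, rep(1e-6, length(t))),
                 "no relaxation")
  expect_equal(pf$B0, 1e-6)
  expect_equal(pf$B1 + pf$B2, 0)
  expect_true(pf$degenerate)
  expect_error(fit_prony(1:3, c(1, 2, 3)), "too short")
})

test_that("Prony times are within 15% under stated noise and seed", {
  t <- seq(0, 4, by = 1e-3)
  f <- (1.0 + 0.5 * exp(-t / 0.15) + 0.3 * exp(-t / 2.0)) * 1e-6
  set.seed(42)
  pf <- fit_prony(t, f + rnorm(length(t), 0, 5e-9))
  expect_lt(rel_err(pf$tau1, 0.15), 0.15)
  expect_lt(rel_err(pf$tau2, 2.0), 0.15)
})

test_that("hardness relaxation coefficients and limits", {
  a <- 60e-9
  B <- c(151e6, 30e6, 17e6) * pi * a^2
  hr <- hardness_relaxation(B, a)
  expect_equal(hr$C0, 151e6, tolerance = 1e-10)
  expect_equal(hr$H0, 198e6, tolerance = 1e-10)
  expect_equal(hr$H_inf, 151e6, tolerance = 1e-10)
  # no exponential terms: H0 equals H_inf
  hr2 <- hardness_relaxation(c(1e-6, 0, 0), a)
  expect_equal(hr2$H0, hr2$H_inf)
  expect_error(hardness_relaxation(B, 0), "> 0")
  # H0 >= H_inf whenever the coefficients are non-negative (property)
  set.seed(5)
  for (i in 1:20) {
    hr3 <- hardness_relaxation(runif(3, 0, 1e-6), a)
    expect_gte(hr3$H0, hr3$H_inf)
  }
})

test_that("plastic strain rate: worked value, decay and degeneracy", {
  # E = 1 GPa, C1 = 30, C2 = 18 MPa, tau = 0.15, 2 s -> 0.627 1/s at t=0
  r0 <- plastic_strain_rate(30e6, 18e6, 0.15, 2, 1e9, 0)
  expect_equal(r0, 0.627, tolerance = 1e-6)
  r20 <- plastic_strain_rate(30e6, 18e6, 0.15, 2, 1e9, 20)
  expect_lt(r20, 1e-3 * r0)
  t <- seq(0, 4, by = 0.05)
  r <- plastic_strain_rate(30e6, 18e6, 0.15, 2, 1e9, t)
  expect_true(all(diff(r) < 0))
  expect_equal(plastic_strain_rate(0, 0, 0.15, 2, 1e9, t),
               rep(0, length(t)))
  expect_error(plastic_strain_rate(1, 1, 1, 2, 0, 0), "> 0")
})

test_that("stress series decays to C0/psi", {
  t <- seq(0, 60, by = 0.1)
  s <- stress_series(151e6, 30e6, 17e6, 0.12, 1.99, 3, t)
  expect_true(all(diff(s) < 0))
  expect_equal(s[1], 198e6 / 3, tolerance = 1e-12)
  expect_equal(s[length(s)], 151e6 / 3, tolerance = 1e-6)
  expect_equal(s[length(s)], 50.33e6, tolerance = 1e-3)
  # psi = 1 returns the hardness itself
  expect_equal(stress_series(151e6, 30e6, 17e6, 0.12, 1.99, 1, 0),
               198e6)
  expect_error(stress_series(1, 1, 1, 1, 2, 0, 0), "> 0")
})

test_that("Herschel-Bulkley round trip and Bingham restriction", {
  rate <- exp(seq(log(1e-3), log(1), length.out = 40))
  sigma <- (48 + 16 * rate^0.33) * 1e6
  hb <- fit_herschel_bulkley(sigma, rate)
  expect_lt(rel_err(hb$sigma_Y, 48e6), 0.01)
  expect_lt(rel_err(hb$k, 16e6), 0.01)
  expect_lt(rel_err(hb$j, 0.33), 0.01)
  # Bingham: j fixed at 1, k equals the linear-regression slope
  sigma2 <- (10 + 5 * rate) * 1e6
  hb2 <- fit_herschel_bulkley(sigma2, rate, fix_j = 1)
  lin <- coef(lm(sigma2 ~ rate))
  expect_equal(hb2$k, unname(lin[2]), tolerance = 1e-8)
  expect_equal(hb2$sigma_Y, unname(lin[1]), tolerance = 1e-8)
  expect_error(fit_herschel_bulkley(sigma[1:10], rate[1:10]),
               "at least 20")
  narrow <- seq(1, 2, length.out = 30)
  expect_error(fit_herschel_bulkley(narrow * 1e6, narrow),
               "insufficient rate coverage")
})

test_that("fitted yield stress approaches C0/psi for long dwells", {
  tau2 <- 1.99
  tg <- exp(seq(log(4e-3), log(20 * tau2), length.out = 100))
  sig <- stress_series(151e6, 30e6, 17e6, 0.12, tau2, 3, tg)
  rate <- plastic_strain_rate(30e6, 17e6, 0.12, tau2, 1183e6, tg)
  hb <- suppressWarnings(
    fit_herschel_bulkley(sig, rate, sigma_y0 = 151e6 / 3))
  expect_lt(rel_err(hb$sigma_Y, 151e6 / 3), 0.10)
})

test_that("the (rate, stress) locus is monotone on the hold", {
  tg <- exp(seq(log(4e-3), log(4), length.out = 60))
  sig <- stress_series(151e6, 30e6, 17e6, 0.12, 1.99, 3, tg)
  rate <- plastic_strain_rate(30e6, 17e6, 0.12, 1.99, 1183e6, tg)
  expect_true(all(diff(sig) < 0))
  expect_true(all(diff(rate) < 0))
})

test_that("analyze_relaxation recovers truth end to end", {
  tipX <- as_tip_profile(fixture_tip())
  cv <- fixture_curve(dwell = 4)
  ic <- to_indentation(cv, 0, 0)
  ind <- analyze_indentation(ic, tipX)
  rel <- analyze_relaxation(ic, ind)
  expect_lt(rel_err(rel$H0, 198e6), 0.05)
  expect_lt(rel_err(rel$H_inf, 151e6), 0.05)
  expect_lt(rel_err(rel$prony$tau1, 0.12), 0.02)
  expect_lt(rel_err(rel$prony$tau2, 1.99), 0.02)
  expect_true(rel$accepted)
  expect_gte(rel$H0, rel$H_inf)
  # yield stress close to the long-term stress C0/psi for this world
  expect_lt(rel_err(rel$hb$sigma_Y, rel$C0 / 3), 0.15)
})
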