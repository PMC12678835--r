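#' Ground-truth indenter geometry for the simulator
#'
#' @param kind `"power_law"` (profile \eqn{h_c = c a^n}),
#'   `"paraboloid"` (end radius `R_m`; equivalent to `c = 1/(2R)`,
#'   `n = 2`), or `"polynomial"`
#'   (\eqn{a = d_0 + d_1 h_c + \dots + d_6 h_c^6}; the first two terms
#'   describe a truncated cone).
#' @param c_si,n power-law parameters, SI units (`c_si` in m^(1-n)).
#' @param R_m paraboloid end radius, metres.
#' @param d polynomial coefficients `d0..dk` in SI units
#'   (`d[k]` in m^(1-k+1)); `d0` is the truncation radius in metres.
#' @return object of class `indenter_truth`.
#' @export
indenter_truth <- function(kind = c("power_law", "paraboloid", "polynomial"),
                           c_si = NULL, n = NULL, R_m = NULL, d = NULL) {
  kind <- match.arg(kind)
  if (kind == "paraboloid") {
    stopifnot(is.numeric(R_m), R_m > 0)
    c_si <- 1 / (2 * R_m)
    n <- 2
    kind <- "power_law"
  }
  if (kind == "power_law") {
    stopifnot(is.numeric(c_si), c_si > 0, is.numeric(n), n > 0)
    out <- list(kind = "power_law", c_si = c_si, n = n, R_m = R_m)
  } else {
    stopifnot(is.numeric(d), length(d) >= 2, d[2] > 0)
    out <- list(kind = "polynomial", d = d)
  }
  structure(out, class = "indenter_truth")
}

# contact radius at contact depth, SI
truth_a_of_hc <- function(profile, hc) {
  if (profile$kind == "power_law") {
    (hc / profile$c_si)^(1 / profile$n)
  } else {
    drop(outer(hc, seq_along(profile$d) - 1, "^") %*% profile$d)
  }
}

# inverse: contact depth at contact radius (vectorised; polynomial
# profiles are inverted on a dense monotone lookup grid)
truth_hc_of_a <- function(profile, a) {
  if (profile$kind == "power_law") {
    return(profile$c_si * a^profile$n)
  }
  amax <- max(a)
  if (amax <= profile$d[1]) return(rep(0, length(a)))
  hi <- 1e-9
  while (truth_a_of_hc(profile, hi) < amax) hi <- hi * 2
  hcg <- seq(0, hi, length.out = 8000L)
  ag <- truth_a_of_hc(profile, hcg)
  out <- stats::approx(ag, hcg, xout = pmax(a, profile$d[1]),
                       rule = 2)$y
  out[a <= profile$d[1]] <- 0
  out
}

# local profile index n(h_c) = dln(h_c)/dln(a)
truth_local_n <- function(profile, hc) {
  if (profile$kind == "power_law") {
    rep(profile$n, length(hc))
  } else {
    k <- seq_along(profile$d) - 1
    a <- truth_a_of_hc(profile, hc)
    dadh <- drop(outer(hc, pmax(k - 1, 0), "^") %*% (profile$d * k))
    pmin(a / pmax(hc * dadh, 1e-300), 1e6)
  }
}

#' Elastic indentation force for a power-law indenter
#'
#' Closed form obtained by integrating the Sneddon stiffness relation
#' \eqn{S = 2E^*a} for a rigid indenter with profile \eqn{h_c = c a^n}:
#' \deqn{F = \frac{2E^*n}{n+1}(\kappa c)^{-1/n}\, h^{(n+1)/n}}
#' with \eqn{\kappa} from [depth_scaling_kappa()].  At \eqn{n = 2},
#' \eqn{c = 1/(2R)} this reduces to the Hertzian
#' \eqn{F = (4/3)E^*\sqrt{R}h^{3/2}}.
#'
#' @param e_star plane-strain modulus, Pa.
#' @param c_si profile coefficient, m^(1-n).
#' @param n profile index (> 0).
#' @param h indentation depth(s), metres (>= 0).
#' @return force(s), newtons.
#' @export
power_law_elastic_force <- function(e_star, c_si, n, h) {
  stopifnot(e_star > 0, c_si > 0, n > 0)
  if (any(h < 0)) stop("indentation depth must be >= 0", call. = FALSE)
  kap <- depth_scaling_kappa(n)
  2 * e_star * n / (n + 1) * (kap * c_si)^(-1 / n) * h^((n + 1) / n)
}

#' Simulate a noiseless elastic loading curve for any indenter profile
#'
#' Power-law profiles use the closed form of
#' [power_law_elastic_force()]; other profiles are integrated
#' numerically: \eqn{dF = 2E^*a\,dh} with the depth mapping
#' \eqn{h = \kappa(n(h_c))\,h_c} applied pointwise using the local
#' profile exponent.
#'
#' @param profile an [indenter_truth()].
#' @param e_star plane-strain modulus, Pa.
#' @param h_max maximum depth, metres.
#' @param n_points number of samples on the depth grid (>= 10).
#' @param n_internal resolution of the internal quadrature grid.
#' @return an [indentation_curve()] (approach segment only) with depth
#'   grid `seq(0, h_max, length.out = n_points)`.
#' @export
sneddon_elastic_curve <- function(profile, e_star, h_max,
                                  n_points = 200L, n_internal = 4000L) {
  stopifnot(inherits(profile, "indenter_truth"), e_star > 0, h_max > 0)
  if (n_points < 10L) stop("too few samples: n_points must be >= 10",
                           call. = FALSE)
  h <- seq(0, h_max, length.out = n_points)
  if (profile$kind == "power_law") {
    f <- power_law_elastic_force(e_star, profile$c_si, profile$n, h)
  } else {
    hc_max <- hc_upper_bound(profile, h_max)
    hcg <- c(0, exp(seq(log(hc_max / n_internal), log(hc_max),
                        length.out = n_internal)))
    ag <- truth_a_of_hc(profile, hcg)
    if (any(diff(ag) <= 0)) stop("geometry error: profile a(h_c) is not ",
                                 "strictly increasing", call. = FALSE)
    nloc <- truth_local_n(profile, pmax(hcg, hcg[2] * 1e-6))
    hg <- depth_scaling_kappa(nloc) * hcg
    hg[1] <- 0
    fg <- cumtrapz(hg, 2 * e_star * ag)
    f <- stats::approx(hg, fg, xout = h, rule = 2)$y
    f[1] <- 0
  }
  indentation_curve("sneddon", time_s = seq_along(h) - 1, depth_m = h,
                    force_N = f, segment = rep("approach", length(h)))
}

# smallest h_c whose mapped depth reaches h_max (with margin)
hc_upper_bound <- function(profile, h_max) {
  f <- function(hc) {
    depth_scaling_kappa(truth_local_n(profile, hc)) * hc - h_max
  }
  upper <- h_max
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, c(h_max * 1e-8, upper), tol = 1e-18)$root * 1.0001
}

cumtrapz <- function(x, y) {
  c(0, cumsum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2))
}

#' Ground-truth material parameters for the simulator
#'
#' @param behaviour `"elastic"`, `"elastoplastic"` or `"viscoplastic"`.
#' @param E Young's modulus, Pa.
#' @param nu Poisson ratio.
#' @param H hardness, Pa (elastoplastic; ignored for viscoplastic where
#'   the instantaneous hardness is `C0 + C1 + C2`).
#' @param C0,C1,C2 Prony hardness coefficients, Pa (viscoplastic).
#' @param tau1,tau2 relaxation times, seconds (`tau1 < tau2`).
#' @return object of class `material_truth`.
#' @export
material_truth <- function(behaviour = c("elastoplastic", "elastic",
                                         "viscoplastic"),
                           E, nu = 0.4, H = NULL,
                           C0 = NULL, C1 = NULL, C2 = NULL,
                           tau1 = NULL, tau2 = NULL) {
  behaviour <- match.arg(behaviour)
  stopifnot(E > 0, nu >= 0, nu <= 0.5)
  if (behaviour == "viscoplastic") {
    stopifnot(!is.null(C0), !is.null(C1), !is.null(C2),
              !is.null(tau1), !is.null(tau2))
    if (any(c(C0, C1, C2) < 0)) stop("Prony coefficients must be >= 0",
                                     call. = FALSE)
    if (tau1 >= tau2) stop("relaxation times must satisfy tau1 < tau2",
                           call. = FALSE)
    H <- C0 + C1 + C2
  } else if (behaviour == "elastoplastic") {
    stopifnot(!is.null(H), H > 0)
  }
  structure(list(behaviour = behaviour, E = E, nu = nu, H = H,
                 C0 = C0, C1 = C1, C2 = C2, tau1 = tau1, tau2 = tau2),
            class = "material_truth")
}

# hardness relaxation H(t) of the truth, Pa
truth_H_of_t <- function(truth, t) {
  if (truth$behaviour == "viscoplastic") {
    truth$C0 + truth$C1 * exp(-t / truth$tau1) +
      truth$C2 * exp(-t / truth$tau2)
  } else {
    rep(truth$H, length(t))
  }
}

#' Simulate a full loading-pause-unloading force curve
#'
#' Forward model of an elastoplastic / viscoplastic indentation event:
#' loading is a fully yielded contact, \eqn{F = \pi a^2 H}, with elastic
#' sink-in \eqn{h_s = \phi F / S} (\eqn{S = 2 a E^*}) added to the
#' contact depth from the indenter profile; the constant-height pause
#' relaxes the hardness along the material's Prony series; unloading is
#' the elastic quadratic \eqn{F = C_e (h - h_f)^2} whose initial slope
#' equals \eqn{S_0 = 2 a_{max} E^*} at \eqn{h_{max}}.  The cantilever is
#' compliant: piezo height is depth plus deflection \eqn{F/k_c} plus the
#' contact offset.
#'
#' @param truth a [material_truth()] (`elastoplastic` or `viscoplastic`).
#' @param profile an [indenter_truth()].
#' @param f_max force setpoint, newtons.
#' @param speed piezo speed, m/s.
#' @param dwell pause duration, seconds (0 to skip the pause).
#' @param dt sample interval, seconds.
#' @param k_c cantilever spring constant, N/m.
#' @param phi sink-in geometric factor.
#' @param contact_offset_m free-air approach distance before contact.
#' @param noise_sd additive Gaussian force noise sd, newtons.
#' @param curve_id identifier for the generated curve.
#' @param metadata extra metadata entries merged into the curve.
#' @return a [force_curve()] in force units, carrying a `truth`
#'   attribute with the per-curve ground truth
#'   (`a_max`, `h_max`, `S0`, `h_f`, `h_s`, `H_load`, `H_end`, `F_end`).
#' @export
elastoplastic_curve <- function(truth, profile, f_max,
                                speed = 0.5e-6, dwell = 0, dt = 2e-3,
                                k_c = 28.5, phi = 0.73,
                                contact_offset_m = 5e-8,
                                noise_sd = 0, curve_id = "synthetic",
                                metadata = list()) {
  stopifnot(inherits(truth, "material_truth"),
            inherits(profile, "indenter_truth"), f_max > 0)
  H_load <- truth_H_of_t(truth, 0)
  if (H_load >= truth$E) {
    stop("nonphysical parameters: hardness must be below the Young's ",
         "modulus for this contact model", call. = FALSE)
  }
  e_star <- truth$E / (1 - truth$nu^2)
  a_max <- sqrt(f_max / (pi * H_load))
  hc_max <- truth_hc_of_a(profile, a_max)
  h_max <- hc_max + phi * pi * a_max * H_load / (2 * e_star)
  S0 <- 2 * a_max * e_star

  # loading lookup, parameterised by contact radius
  a_g <- seq(0, a_max, length.out = 1500L)
  F_g <- pi * a_g^2 * H_load
  h_g <- truth_hc_of_a(profile, a_g) + phi * pi * a_g * H_load / (2 * e_star)
  z_g <- h_g + F_g / k_c   # piezo travel past contact

  z_trig <- h_max + f_max / k_c
  t_app <- seq(0, (contact_offset_m + z_trig) / speed, by = dt)
  z_app <- -contact_offset_m + speed * t_app
  keep <- z_app <= z_trig
  t_app <- t_app[keep]; z_app <- z_app[keep]
  F_app <- ifelse(z_app <= 0, 0,
                  stats::approx(z_g, F_g, xout = pmin(z_app, z_trig),
                                rule = 2)$y)
  # close the approach exactly at the trigger point
  t_trig <- t_app[length(t_app)] + (z_trig - z_app[length(z_app)]) / speed
  t_app <- c(t_app, t_trig); z_app <- c(z_app, z_trig)
  F_app <- c(F_app, f_max)

  # pause at constant tip depth: the piezo tracks the small cantilever
  # relaxation (F/k_c) so that z = h + F/k_c stays consistent
  if (dwell > 0) {
    t_pau <- seq(dt, dwell, by = dt)
    F_pau <- pi * a_max^2 * truth_H_of_t(truth, t_pau)
    z_pau <- h_max + F_pau / k_c
  } else {
    t_pau <- numeric(0); F_pau <- numeric(0); z_pau <- numeric(0)
  }
  F_end <- if (dwell > 0) F_pau[length(F_pau)] else f_max
  t_end <- if (dwell > 0) t_trig + dwell else t_trig

  # elastic unloading quadratic from (h_max, F_end)
  h_e <- 2 * F_end / S0
  h_f <- h_max - h_e
  if (h_f < 0) stop("unloading model degenerate: elastic recovery exceeds ",
                    "total depth (increase hardness or setpoint)",
                    call. = FALSE)
  C_e <- S0^2 / (4 * F_end)
  h_u <- seq(h_max, h_f, length.out = 800L)
  F_u <- C_e * (h_u - h_f)^2
  z_u <- h_u + F_u / k_c
  z_end <- h_max + F_end / k_c   # piezo position after the hold
  t_ret <- seq(dt, (z_end + contact_offset_m) / speed, by = dt)
  z_ret <- z_end - speed * t_ret
  F_ret <- ifelse(z_ret >= h_f,
                  stats::approx(rev(z_u), rev(F_u), xout = pmin(z_ret, z_end),
                                rule = 2)$y,
                  0)
  t_ret <- t_ret + t_end

  time <- c(t_app, t_trig + t_pau, t_ret)
  z <- c(z_app, z_pau, z_ret)
  f <- c(F_app, F_pau, F_ret)
  seg <- c(rep("approach", length(t_app)), rep("pause", length(t_pau)),
           rep("retract", length(t_ret)))
  if (noise_sd > 0) f <- f + stats::rnorm(length(f), 0, noise_sd)

  md <- utils::modifyList(
    list(spring_constant_N_per_m = k_c, setpoint_N = f_max,
         speed_m_per_s = speed, dwell_s = dwell), metadata)
  out <- force_curve(curve_id, time, z, f, seg, force_unit = TRUE,
                     metadata = md)
  attr(out, "truth") <- list(
    a_max = a_max, h_max = h_max, h_c = hc_max, S0 = S0, h_f = h_f,
    h_s = phi * f_max / S0, H_load = H_load,
    H_end = F_end / (pi * a_max^2), F_end = F_end,
    E = truth$E, nu = truth$nu,
    C0 = truth$C0, C1 = truth$C1, C2 = truth$C2,
    tau1 = truth$tau1, tau2 = truth$tau2)
  out
}

#' Simulate a constant-contact force-relaxation series
#'
#' \eqn{F(t) = \pi a^2 H(t)} with the material's Prony hardness.  Checks
#' identifiability: relaxation times outside `(dt, 10 * dwell)` trigger a
#' warning.
#'
#' @param truth a [material_truth()] with Prony coefficients.
#' @param a contact radius, metres.
#' @param dwell hold duration, seconds.
#' @param dt sample interval, seconds.
#' @param noise_sd additive Gaussian force noise sd, newtons.
#' @return data.frame with `time_s` and `force_N`.
#' @export
relaxation_curve <- function(truth, a, dwell, dt, noise_sd = 0) {
  stopifnot(inherits(truth, "material_truth"), a > 0, dwell > 0, dt > 0)
  if (truth$behaviour == "viscoplastic") {
    taus <- c(truth$tau1, truth$tau2)
    if (any(taus < dt | taus > 10 * dwell)) {
      warning("relaxation time(s) outside the identifiable window (dt, ",
              "10*dwell)", call. = FALSE)
    }
  }
  t <- seq(0, dwell, by = dt)
  f <- pi * a^2 * truth_H_of_t(truth, t)
  if (noise_sd > 0) f <- f + stats::rnorm(length(f), 0, noise_sd)
  data.frame(time_s = t, force_N = f)
}

#' Simulate reference-elastomer calibration curves
#'
#' Noisy copies of the noiseless Sneddon loading curve on the reference
#' material (linear-elastic, known plane-strain modulus), as used for
#' tip-shape calibration.
#'
#' @param profile an [indenter_truth()].
#' @param n_curves number of replicate curves (a 64-curve grid by
#'   default).
#' @param e_star reference plane-strain modulus, Pa.
#' @param setpoint maximum force, newtons.
#' @param n_points samples per curve.
#' @param noise_sd additive Gaussian force noise sd, newtons.
#' @return list of [indentation_curve()] objects.
#' @export
generate_reference_curves <- function(profile, n_curves = 64,
                                      e_star = 3.79e6, setpoint = 250e-9,
                                      n_points = 400L, noise_sd = 0) {
  base <- sneddon_elastic_curve(profile, e_star,
                                h_max = depth_at_force(profile, e_star,
                                                       setpoint),
                                n_points = n_points)
  lapply(seq_len(n_curves), function(i) {
    cv <- base
    cv$curve_id <- sprintf("ref_%03d", i)
    if (noise_sd > 0) {
      cv$data$force_N <- cv$data$force_N +
        stats::rnorm(nrow(cv$data), 0, noise_sd)
    }
    cv
  })
}

# depth at which the elastic loading force reaches `setpoint`
depth_at_force <- function(profile, e_star, setpoint) {
  if (profile$kind == "power_law") {
    kap <- depth_scaling_kappa(profile$n)
    K <- 2 * e_star * profile$n / (profile$n + 1) *
      (kap * profile$c_si)^(-1 / profile$n)
    (setpoint / K)^(profile$n / (profile$n + 1))
  } else {
    f <- function(h) {
      cv <- sneddon_elastic_curve(profile, e_star, h, n_points = 50L,
                                  n_internal = 800L)
      max(cv$data$force_N) - setpoint
    }
    upper <- 1e-7
    while (f(upper) < 0) upper <- upper * 2
    stats::uniroot(f, c(1e-10, upper), tol = 1e-15)$root
  }
}
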