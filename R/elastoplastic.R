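#' Fit the elastic unloading quadratic
#'
#' Fits \eqn{F = C_e (h - h_f)^2} — the power-law unloading model with
#' index 2 — to the upper part of the unloading curve.  By default the
#' window is a force window: samples with \eqn{F \ge (1 -
#' fit\_fraction) F_{max}} (robust to adhesive tails); a depth window is
#' available via `method = "depth"`.  Adhesive (negative-force) samples
#' are always excluded.  The initial unloading stiffness follows from
#' the fit coefficients: \eqn{S_0 = 2 C_e (h_{max} - h_f)}.
#'
#' @param curve an [indentation_curve()] with a retract segment, or a
#'   list/data.frame with `depth_m` and `force_N` (treated as unloading
#'   data directly).
#' @param fit_fraction fraction of the unloading force (or depth) range
#'   used (default 0.8).
#' @param method `"force"` (default) or `"depth"` window.
#' @param k_c cantilever spring constant, N/m (defaults to the curve
#'   metadata).  When known, the quadratic is refitted in the noise-free
#'   piezo coordinate `u = h + F/k_c`, which removes the stiffness
#'   attenuation caused by force noise entering the depth through the
#'   deflection term.
#' @return list of class `unloading_fit`: `C_e` (N/m^2), `h_f` (m),
#'   `S0` (N/m), `h_max`, `F_max`, `r_squared`, `n_fit`.
#' @export
fit_unloading <- function(curve, fit_fraction = 0.8,
                          method = c("force", "depth"), k_c = NULL) {
  method <- match.arg(method)
  if (inherits(curve, "indentation_curve")) {
    d <- curve$data[curve$data$segment == "retract" &
                      !curve$data$adhesive, ]
    h <- d$depth_m; f <- d$force_N
    if (is.null(k_c)) {
      k_c <- curve$metadata$spring_constant_N_per_m
    }
  } else {
    h <- curve$depth_m; f <- curve$force_N
  }
  if (is.null(k_c)) k_c <- NA_real_
  ok <- is.finite(h) & is.finite(f) & f >= 0
  h <- h[ok]; f <- f[ok]
  if (!length(h)) stop("no unloading samples", call. = FALSE)
  F_max <- max(f); h_max <- h[which.max(f)]
  win <- if (method == "force") {
    f >= (1 - fit_fraction) * F_max
  } else {
    h >= h_max - fit_fraction * (h_max - min(h))
  }
  h_w <- h[win]; f_w <- f[win]
  if (length(h_w) < 10L) {
    stop("fewer than 10 samples in the unloading fit window", call. = FALSE)
  }
  # sqrt-linearisation: sqrt(F) = sqrt(C_e) (h - h_f) is exact for the
  # model and provides the start for the constrained nonlinear polish
  lin <- stats::lm.fit(cbind(1, h_w), sqrt(f_w))
  slope <- lin$coefficients[2]
  if (!is.finite(slope) || slope <= 0) {
    stop("unloading data do not decrease with depth; cannot fit",
         call. = FALSE)
  }
  ce0 <- unname(slope^2)
  hf0 <- unname(-lin$coefficients[1] / slope)
  hf0 <- min(max(hf0, 0), h_max * 0.999)
  # Depth carries force noise through the deflection term (-F/k_c), which
  # is anticorrelated with the force noise and attenuates the fitted
  # stiffness.  When the spring constant is known, refit in the noise-free
  # piezo coordinate u = h + F/k_c with the implicit model
  # F = C_e (u - F/k_c - h_f)^2, solved for F in closed form.
  fit <- NULL
  if (is.finite(k_c) && k_c > 0) {
    u_w <- (h_w + f_w / k_c) * 1e9       # nm
    f_nn <- f_w * 1e9                    # nN
    k_nn <- k_c                          # nN/nm == N/m
    model_f <- function(Ce, hf) {
      uu <- u_w - hf
      aa <- Ce / k_nn^2
      bb <- 2 * Ce * uu / k_nn + 1
      cc <- Ce * uu^2
      disc <- pmax(bb^2 - 4 * aa * cc, 0)
      (bb - sqrt(disc)) / (2 * aa)
    }
    fit <- tryCatch(
      suppressWarnings(stats::nls(f_nn ~ model_f(Ce, hf),
                 start = list(Ce = ce0 * 1e-9, hf = hf0 * 1e9),
                 lower = c(Ce = 0, hf = 0),
                 upper = c(Ce = Inf, hf = h_max * 1e9),
                 algorithm = "port",
                 control = stats::nls.control(warnOnly = TRUE,
                                              maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      cf <- stats::coef(fit)
      C_e <- unname(cf[["Ce"]]) * 1e9    # nN/nm^2 -> N/m^2
      h_f <- unname(cf[["hf"]]) * 1e-9
      resid <- stats::residuals(fit) * 1e-9
      # denoised endpoint: force and depth at the maximum piezo position
      F_max <- max(model_f(cf[["Ce"]], cf[["hf"]])) * 1e-9
      h_max <- max(u_w) * 1e-9 - F_max / k_c
    }
  }
  if (is.null(fit)) {
    fit2 <- tryCatch(
      suppressWarnings(stats::nls(f_w ~ Ce * (h_w - hf)^2,
                 start = list(Ce = ce0, hf = hf0),
                 lower = c(Ce = 0, hf = 0),
                 upper = c(Ce = Inf, hf = h_max),
                 algorithm = "port",
                 control = stats::nls.control(warnOnly = TRUE,
                                              maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit2)) {
      C_e <- ce0; h_f <- hf0
      resid <- f_w - C_e * (h_w - h_f)^2
    } else {
      cf <- stats::coef(fit2)
      C_e <- unname(cf[["Ce"]]); h_f <- unname(cf[["hf"]])
      resid <- stats::residuals(fit2)
    }
  }
  if (h_f >= h_max) stop("no residual depth: fitted h_f >= h_max",
                         call. = FALSE)
  if (h_f < 0) h_f <- 0
  r2 <- 1 - sum(resid^2) / sum((f_w - mean(f_w))^2)
  structure(list(C_e = C_e, h_f = h_f, S0 = 2 * C_e * (h_max - h_f),
                 h_max = h_max, F_max = F_max, r_squared = r2,
                 n_fit = length(h_w)),
            class = "unloading_fit")
}

#' Elastic sink-in depth at the contact perimeter
#'
#' \eqn{h_s = \phi F_{max} / S_0}, with geometric factor \eqn{\phi}
#' (0.73 for a conical indenter with unloading index near 2).
#'
#' @param F_max maximum force of the unloading curve, N.
#' @param S0 initial unloading stiffness, N/m (> 0).
#' @param phi geometric factor.
#' @return sink-in depth, metres.
#' @export
sink_in_depth <- function(F_max, S0, phi = 0.73) {
  if (any(S0 <= 0)) stop("stiffness must be > 0", call. = FALSE)
  phi * F_max / S0
}

#' Contact depth from total depth and sink-in
#'
#' \eqn{h_c = h_{max} - h_s}.  A sink-in equal to the total depth gives
#' the boundary value zero with a warning; larger sink-in is a
#' degenerate fit and an error.
#'
#' @param h_max maximum indentation depth, m.
#' @param h_s sink-in depth, m.
#' @return contact depth, m.
#' @export
contact_depth <- function(h_max, h_s) {
  if (any(h_s > h_max)) stop("sink-in exceeds depth (degenerate ",
                             "unloading fit)", call. = FALSE)
  if (any(h_s == h_max)) warning("zero contact depth (sink-in equals ",
                                 "total depth)", call. = FALSE)
  h_max - h_s
}

#' Young's modulus from unloading stiffness and contact area
#'
#' \deqn{E = \frac{\sqrt{\pi}}{2}(1-\nu^2)\frac{S_0}{\sqrt{A_{max}}}}
#' with \eqn{A_{max} = \pi a^2}; equivalently
#' \eqn{E = (1-\nu^2) S_0/(2a)}.
#'
#' @param S0 initial unloading stiffness, N/m.
#' @param A_max contact area, m^2 (> 0).
#' @param nu sample Poisson ratio.
#' @return Young's modulus, Pa.
#' @export
youngs_modulus <- function(S0, A_max, nu = 0.4) {
  if (any(A_max <= 0)) stop("contact area must be > 0", call. = FALSE)
  if (any(nu < 0 | nu >= 0.5)) stop("Poisson ratio must be in [0, 0.5)",
                                    call. = FALSE)
  sqrt(pi) / 2 * (1 - nu^2) * S0 / sqrt(A_max)
}

#' Hardness and static yield stress
#'
#' \eqn{H = F_{max}/A_{max}} (the mean contact stress of the fully
#' yielded contact) and \eqn{\sigma_Y = H/\psi} with constraint factor
#' \eqn{\psi \approx 3}.
#'
#' @param F_max maximum force, N.
#' @param A_max contact area, m^2 (> 0).
#' @param psi constraint factor.
#' @return list with `H` (Pa), `sigma_bar` (= H) and `sigma_Y_static`
#'   (Pa).
#' @export
hardness <- function(F_max, A_max, psi = 3) {
  if (any(A_max <= 0)) stop("contact area must be > 0", call. = FALSE)
  H <- F_max / A_max
  list(H = H, sigma_bar = H, sigma_Y_static = H / psi)
}

#' Full per-curve elastoplastic analysis
#'
#' Chains [fit_unloading()], [sink_in_depth()], [contact_depth()], the
#' calibrated tip radius function, [youngs_modulus()] and [hardness()].
#' Results carry flags: `extrapolated_tip` when the contact depth lies
#' beyond the calibrated tip range, `thickness_exceeded` when the depth
#' breaks the 10%-of-thickness guard (requires `thickness_m` metadata),
#' `adhesive_excluded` when negative-force retract samples were
#' dropped.
#'
#' @param curve an [indentation_curve()].
#' @param tip a `tip_profile`.
#' @param config a [calibration_config()].
#' @return list of class `unloading_result` with fields
#'   `C_e, h_f, S0, F_max, h_max, h_s, h_c, h_e, a, A_max, E, H,
#'   sigma_Y_static, r_squared, flags`.
#' @export
analyze_indentation <- function(curve, tip,
                                config = calibration_config()) {
  stopifnot(inherits(curve, "indentation_curve"),
            inherits(tip, "tip_profile"))
  uf <- fit_unloading(curve, fit_fraction = config$unloading_fit_fraction)
  h_s <- sink_in_depth(uf$F_max, uf$S0, config$phi)
  h_c <- contact_depth(uf$h_max, h_s)
  a <- evaluate_tip(tip, h_c, warn = FALSE)
  extrapolated <- attr(a, "extrapolated")
  a <- as.numeric(a)
  A_max <- pi * a^2
  E <- youngs_modulus(uf$S0, A_max, config$nu_sample)
  hd <- hardness(uf$F_max, A_max, config$psi)
  thick <- curve$metadata$thickness_m
  flags <- list(
    extrapolated_tip = isTRUE(extrapolated[1]),
    thickness_exceeded = !is.null(thick) &&
      uf$h_max > config$thickness_fraction_max * thick,
    adhesive_excluded = any(curve$data$adhesive))
  structure(list(curve_id = curve$curve_id,
                 C_e = uf$C_e, h_f = uf$h_f, S0 = uf$S0,
                 F_max = uf$F_max, h_max = uf$h_max, h_s = h_s,
                 h_c = h_c, h_e = uf$h_max - uf$h_f, a = a,
                 A_max = A_max, E = E, H = hd$H,
                 sigma_Y_static = hd$sigma_Y_static,
                 r_squared = uf$r_squared, flags = flags),
            class = "unloading_result")
}

#' @export
print.unloading_result <- function(x, ...) {
  cat("<unloading_result> ", x$curve_id, "\n", sep = "")
  cat(sprintf("  E = %.1f MPa, H = %.1f MPa, S0 = %.1f N/m\n",
              x$E / 1e6, x$H / 1e6, x$S0))
  cat(sprintf("  h_max = %.1f nm (h_c %.1f + h_s %.1f), h_f = %.1f nm, a = %.1f nm\n",
              x$h_max * 1e9, x$h_c * 1e9, x$h_s * 1e9, x$h_f * 1e9,
              x$a * 1e9))
  invisible(x)
}
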