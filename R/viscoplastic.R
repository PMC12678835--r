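#' Fit a two-term Prony series to a force-relaxation hold
#'
#' \deqn{F(t) = B_0 + B_1 e^{-t/\tau_1} + B_2 e^{-t/\tau_2}}
#' by bounded nonlinear least squares (coefficients >= 0, times > 0)
#' with multi-start over log-spaced relaxation-time guesses; for each
#' candidate time pair the coefficients are initialised by linear least
#' squares.  Relaxation times are returned ordered (`tau1 < tau2`);
#' terms with times outside `(dt/2, 5 * dwell)` are flagged
#' unidentifiable.  Non-relaxing data yield the degenerate fit
#' `B1 = B2 = 0` with a warning.
#'
#' @param time_s,force_N the hold samples; time is restarted at zero at
#'   hold onset internally.
#' @param tau_starts list of `c(tau1, tau2)` starting pairs, seconds.
#' @return list of class `prony_fit`: `B0, B1, B2` (N), `tau1, tau2`
#'   (s), `r_squared`, `identifiable` (logical, per exponential term),
#'   `degenerate`.
#' @export
fit_prony <- function(time_s, force_N,
                      tau_starts = list(c(0.05, 1), c(0.1, 2),
                                        c(0.5, 3))) {
  t <- time_s - time_s[1]
  f <- force_N
  ok <- is.finite(t) & is.finite(f)
  t <- t[ok]; f <- f[ok]
  dt <- stats::median(diff(t))
  if (length(t) < 5L || max(t) < 5 * dt) {
    stop("hold too short for a Prony fit", call. = FALSE)
  }
  dwell <- max(t)
  # degenerate: no measurable decay
  drop_total <- f[1] - f[length(f)]
  if (drop_total <= 0 || drop_total < 2 * stats::sd(diff(f)) / sqrt(2) &&
      stats::cor(t, f) > -0.2) {
    warning("no relaxation detected: returning degenerate fit with ",
            "B1 = B2 = 0", call. = FALSE)
    B0 <- mean(f)
    return(structure(list(B0 = B0, B1 = 0, B2 = 0,
                          tau1 = NA_real_, tau2 = NA_real_,
                          r_squared = 0, identifiable = c(FALSE, FALSE),
                          degenerate = TRUE), class = "prony_fit"))
  }
  best <- NULL; best_ss <- Inf
  for (tau0 in tau_starts) {
    X <- cbind(1, exp(-t / tau0[1]), exp(-t / tau0[2]))
    B_init <- pmax(stats::lm.fit(X, f)$coefficients, 0)
    fit <- tryCatch(
      suppressWarnings(stats::nls(f ~ b0 + b1 * exp(-t / t1) + b2 * exp(-t / t2),
                 start = list(b0 = B_init[1], b1 = max(B_init[2], 1e-12),
                              b2 = max(B_init[3], 1e-12),
                              t1 = tau0[1], t2 = tau0[2]),
                 lower = c(b0 = 0, b1 = 0, b2 = 0, t1 = dt / 10,
                           t2 = dt / 10),
                 upper = c(b0 = Inf, b1 = Inf, b2 = Inf,
                           t1 = 20 * dwell, t2 = 20 * dwell),
                 algorithm = "port",
                 control = stats::nls.control(warnOnly = TRUE,
                                              maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(stats::residuals(fit)^2)
    if (is.finite(ss) && ss < best_ss) {
      best <- fit; best_ss <- ss
    }
  }
  if (is.null(best)) stop("Prony fit failed from every start",
                          call. = FALSE)
  cf <- stats::coef(best)
  ord <- order(c(cf[["t1"]], cf[["t2"]]))
  taus <- c(cf[["t1"]], cf[["t2"]])[ord]
  Bs <- c(cf[["b1"]], cf[["b2"]])[ord]
  r2 <- 1 - best_ss / sum((f - mean(f))^2)
  identifiable <- taus > dt / 2 & taus < 5 * dwell
  structure(list(B0 = unname(cf[["b0"]]), B1 = unname(Bs[1]),
                 B2 = unname(Bs[2]), tau1 = unname(taus[1]),
                 tau2 = unname(taus[2]), r_squared = r2,
                 identifiable = unname(identifiable),
                 degenerate = FALSE),
            class = "prony_fit")
}

#' @export
print.prony_fit <- function(x, ...) {
  cat("<prony_fit>\n")
  cat(sprintf("  B0 = %.3g N, B1 = %.3g N (tau1 = %.3g s), B2 = %.3g N (tau2 = %.3g s)\n",
              x$B0, x$B1, x$tau1, x$B2, x$tau2))
  cat(sprintf("  R^2 = %.4f%s\n", x$r_squared,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Hardness relaxation coefficients from force coefficients
#'
#' \eqn{C_i = B_i / (\pi a^2)}; instantaneous hardness
#' \eqn{H_0 = \sum C_i}, long-term hardness \eqn{H_\infty = C_0}.
#'
#' @param prony a [fit_prony()] result, or a numeric vector
#'   `c(B0, B1, B2)` in newtons.
#' @param a contact radius of the same curve (from the unloading
#'   analysis), metres (> 0).
#' @return list: `C0, C1, C2` (Pa), `H0`, `H_inf` (Pa).
#' @export
hardness_relaxation <- function(prony, a) {
  if (any(a <= 0)) stop("contact radius must be > 0", call. = FALSE)
  B <- if (inherits(prony, "prony_fit")) {
    c(prony$B0, prony$B1, prony$B2)
  } else {
    prony
  }
  C <- B / (pi * a^2)
  list(C0 = C[1], C1 = C[2], C2 = C[3], H0 = sum(C), H_inf = C[1])
}

#' Plastic strain rate during the hold
#'
#' Uniaxial plastic strain rate implied by the hardness relaxation under
#' additive elastic/plastic strain decomposition at constant total
#' strain:
#' \deqn{\dot\varepsilon_p(t) = \frac{3}{E}\left(\frac{C_1}{\tau_1}
#'   e^{-t/\tau_1} + \frac{C_2}{\tau_2} e^{-t/\tau_2}\right).}
#' The factor 3 converts mean contact stress to uniaxial stress via the
#' constraint factor.
#'
#' @param C1,C2 hardness relaxation coefficients, Pa.
#' @param tau1,tau2 relaxation times, s.
#' @param E Young's modulus of the same curve, Pa (> 0).
#' @param t time grid, s.
#' @return strain rates, 1/s.
#' @export
plastic_strain_rate <- function(C1, C2, tau1, tau2, E, t) {
  if (E <= 0) stop("Young's modulus must be > 0", call. = FALSE)
  (3 / E) * (C1 / tau1 * exp(-t / tau1) + C2 / tau2 * exp(-t / tau2))
}

#' Uniaxial stress during the hold
#'
#' \eqn{\sigma(t) = H(t)/\psi} with the Prony hardness
#' \eqn{H(t) = C_0 + C_1 e^{-t/\tau_1} + C_2 e^{-t/\tau_2}}.
#'
#' @param C0,C1,C2 hardness coefficients, Pa.
#' @param tau1,tau2 relaxation times, s.
#' @param psi constraint factor (> 0).
#' @param t time grid, s.
#' @return stresses, Pa.
#' @export
stress_series <- function(C0, C1, C2, tau1, tau2, psi, t) {
  if (psi <= 0) stop("constraint factor must be > 0", call. = FALSE)
  (C0 + C1 * exp(-t / tau1) + C2 * exp(-t / tau2)) / psi
}

#' Fit the Herschel-Bulkley viscoplastic model
#'
#' \deqn{\sigma = \sigma_Y + k\,\dot\varepsilon_p^{\,j}}
#' by bounded nonlinear least squares (\eqn{\sigma_Y \ge 0},
#' \eqn{k \ge 0}, \eqn{j \in (0.05, 1]}).  Initial guesses: the supplied
#' `sigma_y0` (typically \eqn{C_0/\psi}), `j0 = 0.3`, and `k` from the
#' two-point slope of the extreme samples.  With `fix_j = 1` the model
#' reduces to Bingham and `k` is the linear-regression slope of stress
#' on rate.
#'
#' @param sigma stresses, Pa.
#' @param rate plastic strain rates, 1/s (same length, >= 20 pairs
#'   spanning at least one decade; less than 1.5 decades warns).
#' @param sigma_y0 starting yield stress, Pa.
#' @param j0 starting flow index.
#' @param fix_j optionally fix the flow index (e.g. 1 for Bingham).
#' @return list of class `hb_fit`: `sigma_Y` (Pa), `k` (Pa s^j), `j`,
#'   `r_squared`, `rate_range` (1/s).
#' @export
fit_herschel_bulkley <- function(sigma, rate, sigma_y0 = NULL, j0 = 0.3,
                                 fix_j = NULL) {
  ok <- is.finite(sigma) & is.finite(rate) & rate > 0
  sigma <- sigma[ok]; rate <- rate[ok]
  if (length(sigma) < 20L) stop("need at least 20 (stress, rate) pairs",
                                call. = FALSE)
  decades <- log10(max(rate) / min(rate))
  if (decades < 1) stop("insufficient rate coverage (", round(decades, 2),
                        " decades) - extend dwell", call. = FALSE)
  if (decades < 1.5) warning("rate range spans only ",
                             round(decades, 2), " decades", call. = FALSE)
  o <- order(rate)
  sigma <- sigma[o]; rate <- rate[o]
  if (!is.null(fix_j)) {
    X <- cbind(1, rate^fix_j)
    cf <- stats::lm.fit(X, sigma)$coefficients
    res <- sigma - X %*% cf
    r2 <- 1 - sum(res^2) / sum((sigma - mean(sigma))^2)
    return(structure(list(sigma_Y = unname(cf[1]), k = unname(cf[2]),
                          j = fix_j, r_squared = r2,
                          rate_range = range(rate)), class = "hb_fit"))
  }
  if (is.null(sigma_y0)) sigma_y0 <- 0.95 * min(sigma)
  n <- length(sigma)
  k0 <- (sigma[n] - sigma[1]) / max(rate[n]^j0 - rate[1]^j0, 1e-12)
  k0 <- max(k0, 1e-3 * sigma_y0)
  fit <- tryCatch(
    suppressWarnings(stats::nls(sigma ~ sy + k * rate^j,
               start = list(sy = sigma_y0, k = k0, j = j0),
               lower = c(sy = 0, k = 0, j = 0.05),
               upper = c(sy = Inf, k = Inf, j = 1),
               algorithm = "port",
               control = stats::nls.control(warnOnly = TRUE,
                                            maxiter = 200))),
    error = function(e) NULL)
  if (is.null(fit)) stop("Herschel-Bulkley fit failed", call. = FALSE)
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  r2 <- 1 - sum(res^2) / sum((sigma - mean(sigma))^2)
  structure(list(sigma_Y = unname(cf[["sy"]]), k = unname(cf[["k"]]),
                 j = unname(cf[["j"]]), r_squared = r2,
                 rate_range = range(rate)),
            class = "hb_fit")
}

#' @export
print.hb_fit <- function(x, ...) {
  cat("<hb_fit>\n")
  cat(sprintf("  sigma_Y = %.1f MPa, k = %.1f MPa s^j, j = %.3f (R^2 = %.3f)\n",
              x$sigma_Y / 1e6, x$k / 1e6, x$j, x$r_squared))
  invisible(x)
}

#' Full per-curve relaxation and viscoplastic analysis
#'
#' Fits the Prony series to the pause segment, converts to hardness
#' relaxation using the curve's contact radius, builds the stress /
#' plastic strain-rate locus on a log-spaced time grid over the hold,
#' and fits the Herschel-Bulkley model.  Curves whose Prony fit falls
#' below `config$prony_r2_min` are returned without a Herschel-Bulkley
#' fit (`hb = NULL`, `accepted = FALSE`).
#'
#' @param curve an [indentation_curve()] with a pause segment.
#' @param indent an `unloading_result` for the same curve (supplies the
#'   contact radius and Young's modulus).
#' @param config a [calibration_config()].
#' @param n_grid number of log-spaced time points of the
#'   Herschel-Bulkley locus.
#' @return list of class `relaxation_result`: the `prony_fit`, `C0, C1,
#'   C2, H0, H_inf`, the `hb_fit` (or `NULL`), `accepted`, and the
#'   locus (`t`, `sigma`, `rate`).
#' @export
analyze_relaxation <- function(curve, indent,
                               config = calibration_config(),
                               n_grid = 60L) {
  stopifnot(inherits(curve, "indentation_curve"),
            inherits(indent, "unloading_result"))
  pau <- curve$data[curve$data$segment == "pause", ]
  if (nrow(pau) < 10L) stop("curve '", curve$curve_id,
                            "' has no usable pause segment", call. = FALSE)
  pf <- fit_prony(pau$time_s, pau$force_N)
  hr <- hardness_relaxation(pf, indent$a)
  accepted <- !pf$degenerate && pf$r_squared >= config$prony_r2_min &&
    all(pf$identifiable)
  hb <- NULL; locus <- NULL
  if (accepted) {
    dt <- stats::median(diff(pau$time_s))
    dwell <- max(pau$time_s) - min(pau$time_s)
    tg <- exp(seq(log(2 * dt), log(dwell), length.out = n_grid))
    sig <- stress_series(hr$C0, hr$C1, hr$C2, pf$tau1, pf$tau2,
                         config$psi, tg)
    rate <- plastic_strain_rate(hr$C1, hr$C2, pf$tau1, pf$tau2,
                                indent$E, tg)
    locus <- data.frame(t = tg, sigma = sig, rate = rate)
    hb <- tryCatch(
      fit_herschel_bulkley(sig, rate, sigma_y0 = hr$C0 / config$psi),
      error = function(e) NULL)
    if (is.null(hb)) accepted <- FALSE
  }
  structure(list(curve_id = curve$curve_id, prony = pf,
                 C0 = hr$C0, C1 = hr$C1, C2 = hr$C2,
                 H0 = hr$H0, H_inf = hr$H_inf,
                 a = indent$a, E = indent$E,
                 hb = hb, locus = locus, accepted = accepted),
            class = "relaxation_result")
}

#' @export
print.relaxation_result <- function(x, ...) {
  cat("<relaxation_result> ", x$curve_id, "\n", sep = "")
  cat(sprintf("  H0 = %.1f MPa, H_inf = %.1f MPa (tau1 = %.3g s, tau2 = %.3g s)\n",
              x$H0 / 1e6, x$H_inf / 1e6, x$prony$tau1, x$prony$tau2))
  if (!is.null(x$hb)) print(x$hb) else cat("  no Herschel-Bulkley fit\n")
  invisible(x)
}
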