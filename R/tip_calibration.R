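#' Average loading curves onto a common depth grid
#'
#' Interpolates the contact (approach, depth >= 0) part of each curve
#' onto a shared depth grid and takes the pointwise mean, retaining the
#' between-curve standard deviation band.  Curves whose maximum depth is
#' below 50% of the grid maximum are excluded with a warning.
#'
#' @param curves list of [indentation_curve()] objects (>= 3).
#' @param grid depth grid in metres; default: 300 log-spaced points from
#'   1/500 of the median maximum depth up to the median maximum depth.
#' @param grid_points number of points of the default grid.
#' @return object of class `mean_load_curve`: list with `h`, `F`, `sd`
#'   (all SI) and `n_curves`.
#' @export
average_loading_curves <- function(curves, grid = NULL,
                                   grid_points = 300L) {
  if (length(curves) < 3L) stop("need at least 3 curves", call. = FALSE)
  pull <- function(cv) {
    d <- cv$data[cv$data$segment == "approach" & cv$data$depth_m > 0, ]
    d[order(d$depth_m), ]
  }
  segs <- lapply(curves, pull)
  hmaxs <- vapply(segs, function(d) max(d$depth_m), numeric(1))
  if (is.null(grid)) {
    hi <- stats::median(hmaxs)
    grid <- exp(seq(log(hi / 500), log(hi), length.out = grid_points))
    grid[length(grid)] <- hi
  }
  if (max(grid) > max(hmaxs) * (1 + 1e-12)) {
    stop("depth grid extends beyond the support of every curve",
         call. = FALSE)
  }
  ok <- hmaxs >= 0.5 * max(grid)
  if (any(!ok)) {
    warning(sum(!ok), " curve(s) excluded: maximum depth below 50% of ",
            "the grid", call. = FALSE)
  }
  segs <- segs[ok]
  if (length(segs) < 1L) stop("no curves span the depth grid",
                              call. = FALSE)
  # replicate curves on an identical grid (the common synthetic case)
  # are averaged without interpolation, which keeps the chain exact
  same_grid <- all(vapply(segs, function(d) {
    nrow(d) == nrow(segs[[1]]) &&
      isTRUE(all.equal(d$depth_m, segs[[1]]$depth_m, tolerance = 1e-12))
  }, logical(1)))
  if (same_grid && is.null(dim(grid))) {
    hh <- segs[[1]]$depth_m
    M <- vapply(segs, function(d) d$force_N, numeric(length(hh)))
    M <- matrix(M, nrow = length(hh))
    keep <- hh >= min(grid) & hh <= max(grid)
    return(structure(list(h = hh[keep],
                          F = rowMeans(M)[keep],
                          sd = apply(M, 1, stats::sd)[keep],
                          n_curves = length(segs)),
                     class = "mean_load_curve"))
  }
  M <- vapply(segs, function(d) {
    stats::approx(d$depth_m, d$force_N, xout = grid, rule = 1)$y
  }, numeric(length(grid)))
  M <- matrix(M, nrow = length(grid))
  n_contrib <- rowSums(is.finite(M))
  keep <- n_contrib >= pmax(1, ceiling(length(segs) / 2))
  structure(list(h = grid[keep], F = rowMeans(M, na.rm = TRUE)[keep],
                 sd = apply(M, 1, stats::sd, na.rm = TRUE)[keep],
                 n_curves = length(segs)),
            class = "mean_load_curve")
}

#' Polynomial smoothing of a loading curve (linear scale)
#'
#' Least-squares polynomial with zero intercept,
#' \eqn{\hat F(h) = \sum_{k=1}^{order} p_k h^k}, fitted in scaled units
#' (depth normalised by its maximum, force in nN) to keep the design
#' matrix well conditioned.  The analytic derivative provides the
#' smoothed stiffness \eqn{\hat S(h)}.
#'
#' @param h,F depth (m) and force (N); a `mean_load_curve` may be given
#'   as `h`, in which case `F` is ignored.
#' @param order polynomial order (>= 2: a first-order fit cannot
#'   represent loading curvature).
#' @return object of class `load_poly` with elements `coef_scaled`,
#'   `h_ref`, `residual_sd` (N) and a record of the fit range.
#' @export
smooth_load_curve <- function(h, F = NULL, order = 6L) {
  if (inherits(h, "mean_load_curve")) {
    F <- h$F; h <- h$h
  }
  if (order < 2) stop("order must be >= 2 (a linear fit cannot represent ",
                      "loading curvature)", call. = FALSE)
  stopifnot(length(h) == length(F), length(h) > order + 2)
  h_ref <- max(h)
  x <- h / h_ref
  X <- outer(x, seq_len(order), "^")
  if (kappa(crossprod(X)) > 1e14) {
    stop("ill-conditioned polynomial fit; rescale the data (nm/nN) or ",
         "reduce the order", call. = FALSE)
  }
  fit <- stats::lm.fit(X, F * 1e9)
  structure(list(coef_scaled = fit$coefficients, h_ref = h_ref,
                 order = order,
                 residual_sd = stats::sd(fit$residuals) * 1e-9,
                 h_range = range(h)),
            class = "load_poly")
}

#' @export
predict.load_poly <- function(object, h, ...) {
  x <- h / object$h_ref
  drop(outer(x, seq_len(object$order), "^") %*% object$coef_scaled) * 1e-9
}

#' Smoothed stiffness from a polynomial load-curve fit
#'
#' @param object a `load_poly` or `loglog_poly` fit.
#' @param h depths (m) at which to evaluate dF/dh.
#' @return stiffness in N/m.
#' @export
stiffness_profile <- function(object, h) {
  UseMethod("stiffness_profile")
}

#' @export
stiffness_profile.load_poly <- function(object, h) {
  x <- h / object$h_ref
  k <- seq_len(object$order)
  drop(outer(x, k - 1, "^") %*% (object$coef_scaled * k)) * 1e-9 /
    object$h_ref
}

#' Polynomial smoothing of a loading curve in log-log coordinates
#'
#' Fits \eqn{\ln F} as a polynomial in \eqn{\ln h}, weighted by
#' \eqn{F^2} (inverse variance of \eqn{\ln F} under additive force
#' noise).  Unlike a linear-scale polynomial, this basis represents
#' fractional power laws exactly, so the local load index
#' \eqn{m(h) = d\ln F/d\ln h} is unbiased near contact; it is the
#' default smoother of [calibrate_tip()].
#'
#' @param h,F depth (m) and force (N) (positive values only are used);
#'   a `mean_load_curve` may be given as `h`.
#' @param order polynomial order in log-log space (default 3).
#' @param weights `"force2"` (default) or `"none"`.
#' @param f_floor_N drop samples with force below this floor before
#'   taking logs (0 keeps all positive samples).
#' @return object of class `loglog_poly`.
#' @export
smooth_load_loglog <- function(h, F = NULL, order = 3L,
                               weights = c("force2", "none"),
                               f_floor_N = 0) {
  weights <- match.arg(weights)
  if (inherits(h, "mean_load_curve")) {
    F <- h$F; h <- h$h
  }
  ok <- is.finite(h) & is.finite(F) & h > 0 & F > max(f_floor_N, 0)
  h <- h[ok]; F <- F[ok]
  stopifnot(length(h) > order + 2)
  lx <- log(h * 1e9); ly <- log(F * 1e9)
  X <- outer(lx, 0:order, "^")
  w <- if (weights == "force2") (F * 1e9)^2 else rep(1, length(F))
  fit <- stats::lm.wfit(X, ly, w)
  structure(list(coef = fit$coefficients, order = order,
                 h_range = range(h),
                 residual_sd_log = stats::sd(fit$residuals)),
            class = "loglog_poly")
}

#' @export
predict.loglog_poly <- function(object, h, ...) {
  l <- log(h * 1e9)
  exp(drop(outer(l, 0:object$order, "^") %*% object$coef)) * 1e-9
}

#' @export
stiffness_profile.loglog_poly <- function(object, h) {
  load_index_profile(object, h) * predict(object, h) / h
}

#' Local load index m(h)
#'
#' The logarithmic derivative \eqn{m(h) = d\ln\hat F/d\ln h} of a
#' smoothed loading curve.  For power-law loading data m is constant;
#' for a truncated-cone tip m rises from near 1 at contact toward 2 at
#' depth.
#'
#' @param object a `load_poly` or `loglog_poly` smoothing fit.
#' @param h depths, metres.
#' @return load index values.
#' @export
load_index_profile <- function(object, h) {
  UseMethod("load_index_profile")
}

#' @export
load_index_profile.load_poly <- function(object, h) {
  h * stiffness_profile.load_poly(object, h) / predict(object, h)
}

#' @export
load_index_profile.loglog_poly <- function(object, h) {
  l <- log(h * 1e9)
  k <- seq_len(object$order)
  drop(outer(l, k - 1, "^") %*% (object$coef[-1] * k))
}

#' Contact radius from smoothed stiffness
#'
#' Sneddon's relation for a rigid axisymmetric indenter on an elastic
#' half-space: \eqn{a = S / (2E^*)}.
#'
#' @param S stiffness values, N/m, or a smoothing fit (then evaluated at
#'   `h`).
#' @param e_star plane-strain modulus of the reference, Pa.
#' @param h depths for evaluation when `S` is a fit object.
#' @return contact radii, metres; negative-stiffness entries are `NA`.
#' @export
contact_radius_profile <- function(S, e_star, h = NULL) {
  if (e_star <= 0) stop("plane-strain modulus must be > 0", call. = FALSE)
  if (!is.numeric(S)) S <- stiffness_profile(S, h)
  a <- S / (2 * e_star)
  a[S < 0] <- NA_real_
  a
}

#' Map total depth to contact depth with the local profile exponent
#'
#' \eqn{h_c = h / \kappa(n(h))}, applied pointwise.
#'
#' @param h total depths, metres.
#' @param n local profile index at each depth (same length or scalar).
#' @return contact depths, metres.
#' @export
contact_depth_map <- function(h, n) {
  if (any(!is.finite(n)) || any(n <= 0)) {
    stop("profile index must be finite and > 0 at every depth",
         call. = FALSE)
  }
  h / depth_scaling_kappa(n)
}

#' Fit the tip radius function a(h_c)
#'
#' Degree-`poly_order` polynomial fit of contact radius against contact
#' depth over the configured fit range, with a power-law cap
#' \eqn{h_c = c a^n} describing the near-apex region below the cap
#' limit, anchored by the points with \eqn{h_c} at or below the limit
#' (matching their value and local exponent by weighted log-log
#' regression).  A global power-law fit over the full validity range is
#' also stored (`powerlaw`): for a tip that truly is a power law it
#' estimates (c, n) from the highest-signal part of the data.
#'
#' @param h_c,a calibrated contact depths and radii, metres.
#' @param config a [calibration_config()].
#' @param weights optional fit weights (e.g. squared force).
#' @return object of class `tip_profile`: SI polynomial coefficients
#'   `d` (d0..dk), `hc_range`, `cap` (`c_si`, `n`, `limit_m`),
#'   `powerlaw` (`c_si`, `n`) and `diagnostics`.
#' @export
fit_tip_profile <- function(h_c, a, config = calibration_config(),
                            weights = NULL) {
  ok <- is.finite(h_c) & is.finite(a) & h_c > 0 & a > 0
  h_c <- h_c[ok]; a <- a[ok]
  if (is.null(weights)) weights <- rep(1, length(h_c))
  weights <- weights[ok]
  rng <- config$h_c_fit_range
  inr <- h_c >= rng[1] & h_c <= rng[2]
  if (sum(inr) < 20L) {
    stop("fewer than 20 calibrated points inside the polynomial fit ",
         "range [", rng[1] * 1e9, ", ", rng[2] * 1e9, "] nm", call. = FALSE)
  }
  ord <- config$poly_order
  # fit in nm to control conditioning, convert coefficients back to SI
  x <- h_c[inr] * 1e9; y <- a[inr] * 1e9
  X <- outer(x, 0:ord, "^")
  fit <- stats::lm.wfit(X, y, weights[inr])
  d_nm <- unname(fit$coefficients)
  d_nm[is.na(d_nm)] <- 0
  d_si <- d_nm * 1e-9 / (1e-9)^(0:ord)

  hc_max <- max(h_c[inr])
  dense <- seq(rng[1], hc_max, length.out = 500L)
  aval <- drop(outer(dense * 1e9, 0:ord, "^") %*% d_nm)
  # tolerate sub-0.5% endpoint wiggle of the high-order polynomial
  if (any(diff(aval) < -5e-3 * max(aval)) || any(aval <= 0)) {
    stop("fitted a(h_c) is not positive and non-decreasing over the ",
         "validity range; reduce the fit range or polynomial order",
         call. = FALSE)
  }

  cap <- powerlaw_from_points(h_c, a, weights, h_c <= config$h_c_cap_limit,
                              fallback_upper = rng[1])
  pl <- powerlaw_from_points(h_c, a, weights,
                             h_c >= config$h_c_cap_limit & h_c <= hc_max,
                             fallback_upper = hc_max)

  a_poly_spl <- drop(outer(config$h_c_cap_limit * 1e9, 0:ord, "^") %*% d_nm) * 1e-9
  a_cap_spl <- (config$h_c_cap_limit / cap$c_si)^(1 / cap$n)
  splice_mismatch <- abs(a_poly_spl - a_cap_spl) / a_cap_spl
  if (is.finite(splice_mismatch) && splice_mismatch > 0.05) {
    warning(sprintf(paste0("cap and polynomial disagree by %.1f%% at the ",
                           "splice point"), 100 * splice_mismatch),
            call. = FALSE)
  }
  structure(list(d = d_si, poly_order = ord,
                 hc_range = c(rng[1], hc_max),
                 cap = c(cap, list(limit_m = config$h_c_cap_limit)),
                 powerlaw = pl,
                 diagnostics = list(
                   residual_sd_m = stats::sd(fit$residuals) * 1e-9,
                   n_points = sum(inr),
                   splice_mismatch = splice_mismatch)),
            class = "tip_profile")
}

# weighted log-log regression of h_c = c a^n over a point subset
powerlaw_from_points <- function(h_c, a, w, sel, fallback_upper) {
  if (sum(sel) < 5L) sel <- h_c <= fallback_upper
  if (sum(sel) < 2L) return(list(c_si = NA_real_, n = NA_real_))
  fit <- stats::lm.wfit(cbind(1, log(a[sel])), log(h_c[sel]), w[sel])
  n <- unname(fit$coefficients[2])
  list(c_si = exp(unname(fit$coefficients[1])), n = n)
}

#' @export
print.tip_profile <- function(x, ...) {
  cat("<tip_profile>\n")
  cat(sprintf("  validity: h_c in [%.1f, %.1f] nm (%d points, residual sd %.2f nm)\n",
              x$hc_range[1] * 1e9, x$hc_range[2] * 1e9,
              x$diagnostics$n_points, x$diagnostics$residual_sd_m * 1e9))
  cat(sprintf("  cap below %.1f nm: n = %.3f, c = %.3g um^(1-n)\n",
              x$cap$limit_m * 1e9, x$cap$n,
              convert_profile_coefficient(x$cap$c_si, x$cap$n, "m", "um")))
  cat("  polynomial d0..d", x$poly_order, " (SI): ",
      paste(signif(x$d, 4), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Evaluate the calibrated tip radius function
#'
#' Power-law cap below the cap limit, polynomial above.  Contact depths
#' beyond the calibrated range are evaluated by polynomial extrapolation
#' and flagged in the `"extrapolated"` attribute (with a warning).
#'
#' @param tip a [fit_tip_profile()] result.
#' @param h_c contact depth(s), metres (>= 0).
#' @param warn warn when extrapolating?
#' @return contact radii, metres, with attribute `extrapolated`.
#' @export
evaluate_tip <- function(tip, h_c, warn = TRUE) {
  stopifnot(inherits(tip, "tip_profile"))
  if (any(h_c < 0)) stop("contact depth must be >= 0", call. = FALSE)
  out <- numeric(length(h_c))
  low <- h_c < tip$cap$limit_m
  if (any(low)) {
    out[low] <- (h_c[low] / tip$cap$c_si)^(1 / tip$cap$n)
  }
  if (any(!low)) {
    out[!low] <- drop(outer(h_c[!low] * 1e9, 0:tip$poly_order, "^") %*%
                        (tip$d * (1e-9)^(0:tip$poly_order) * 1e9)) * 1e-9
  }
  extr <- h_c > tip$hc_range[2]
  if (any(extr) && warn) {
    warning("tip radius extrapolated beyond the calibrated range for ",
            sum(extr), " point(s)", call. = FALSE)
  }
  attr(out, "extrapolated") <- extr
  out
}

#' Express a ground-truth indenter as a tip_profile
#'
#' Exact conversion of an [indenter_truth()] into the `tip_profile`
#' container, for analyses that should be isolated from calibration
#' error (the cap of a polynomial truth is fitted from the exact profile
#' just below the cap limit).
#'
#' @param profile an [indenter_truth()].
#' @param hc_range validity range to record, metres.
#' @param cap_limit_m cap boundary, metres.
#' @return a `tip_profile`.
#' @export
as_tip_profile <- function(profile, hc_range = c(5e-10, 500e-9),
                           cap_limit_m = 5e-10) {
  stopifnot(inherits(profile, "indenter_truth"))
  if (profile$kind == "power_law") {
    d <- NULL
    # represent the power law through the cap over the whole range
    tip <- structure(list(
      d = c(0, 0), poly_order = 1L, hc_range = hc_range,
      cap = list(c_si = profile$c_si, n = profile$n,
                 limit_m = Inf),
      powerlaw = list(c_si = profile$c_si, n = profile$n),
      diagnostics = list(residual_sd_m = 0, n_points = 0L,
                         splice_mismatch = 0)), class = "tip_profile")
    return(tip)
  }
  d <- profile$d
  ord <- length(d) - 1L
  hcg <- seq(cap_limit_m / 10, cap_limit_m, length.out = 50L)
  ag <- truth_a_of_hc(profile, hcg)
  cap <- powerlaw_from_points(hcg, ag, rep(1, 50L), rep(TRUE, 50L),
                              cap_limit_m)
  structure(list(d = c(d, rep(0, max(0, 6 - ord))),
                 poly_order = max(ord, 6L),
                 hc_range = hc_range,
                 cap = c(cap, list(limit_m = cap_limit_m)),
                 powerlaw = cap,
                 diagnostics = list(residual_sd_m = 0, n_points = 0L,
                                    splice_mismatch = 0)),
            class = "tip_profile")
}

#' Calibrate the effective tip geometry from reference-material curves
#'
#' Full calibration chain: average the loading curves, smooth them
#' (log-log polynomial by default, linear-scale polynomial via
#' `method = "linear"`), derive the stiffness, contact radius
#' \eqn{a = S/2E^*}, local load index \eqn{m(h)}, profile index
#' \eqn{n = 1/(m-1)}, depth scaling \eqn{\kappa(n)} and contact depth
#' \eqn{h_c = h/\kappa}, then fit the tip radius function
#' [fit_tip_profile()].
#'
#' @param curves list of [indentation_curve()] on the elastic reference.
#' @param config a [calibration_config()] (supplies the reference
#'   modulus and fit ranges).
#' @param method smoothing pathway: `"loglog"` (default) or `"linear"`.
#' @param grid optional common depth grid, metres.
#' @param n_eval number of evaluation depths for the profile chain.
#' @return object of class `elastic_calibration`: the mean curve, the
#'   smoothing fit, the per-depth profiles (`h`, `F`, `S`, `a`, `m`,
#'   `n`, `kappa`, `h_c`) and the fitted `tip` ([fit_tip_profile()]).
#' @export
calibrate_tip <- function(curves, config = calibration_config(),
                          method = c("loglog", "linear"), grid = NULL,
                          n_eval = 400L) {
  method <- match.arg(method)
  avg <- average_loading_curves(curves, grid = grid)
  # drop depths where the averaged force is within the noise floor
  noise_mean <- stats::median(avg$sd, na.rm = TRUE) /
    sqrt(max(avg$n_curves, 1))
  keep <- is.finite(avg$F) & avg$F > 5 * noise_mean & avg$h > 0
  h <- avg$h[keep]; F <- avg$F[keep]
  fit <- if (method == "loglog") {
    smooth_load_loglog(h, F, order = config$smoothing_order)
  } else {
    smooth_load_curve(h, F, order = max(config$smoothing_order, 2L))
  }
  hg <- exp(seq(log(min(h)), log(max(h)), length.out = n_eval))
  Fg <- predict(fit, hg)
  m <- load_index_profile(fit, hg)
  ok <- is.finite(m) & m > 1.02 & m < 3.5 & Fg > 0
  if (sum(ok) < 30L) {
    stop("load index outside (1, 3.5) almost everywhere; calibration ",
         "data look degenerate", call. = FALSE)
  }
  if (any(m[ok] > 3)) {
    warning("load index exceeds 3 over part of the fit range", call. = FALSE)
  }
  hg <- hg[ok]; Fg <- Fg[ok]; m <- m[ok]
  S <- stiffness_profile(fit, hg)
  a <- contact_radius_profile(S, config$e_star_ref)
  n <- profile_index(m)
  kap <- depth_scaling_kappa(n)
  h_c <- hg / kap
  tip <- fit_tip_profile(h_c, a, config, weights = Fg^2)
  structure(list(mean_curve = avg, fit = fit, method = method,
                 profiles = data.frame(h = hg, F = Fg, S = S, a = a,
                                       m = m, n = n, kappa = kap,
                                       h_c = h_c),
                 tip = tip, config = config),
            class = "elastic_calibration")
}

#' @export
print.elastic_calibration <- function(x, ...) {
  cat("<elastic_calibration> (", x$method, " smoothing, ",
      x$mean_curve$n_curves, " curves)\n", sep = "")
  print(x$tip)
  invisible(x)
}

#' Serialize / deserialize a tip profile
#'
#' Structured JSON with SI polynomial coefficients plus the
#' conventional um-based value of the cap coefficient for
#' cross-checking against published tables.
#'
#' @param tip a `tip_profile`.
#' @param path file path.
#' @return `path` (write) or a `tip_profile` (read).
#' @export
write_tip_profile <- function(tip, path) {
  stopifnot(inherits(tip, "tip_profile"))
  obj <- list(
    format = "afmindent-tip-profile-v1",
    poly_order = tip$poly_order, d_si = tip$d,
    hc_range_m = tip$hc_range,
    cap = list(c_si = tip$cap$c_si, n = tip$cap$n,
               limit_m = tip$cap$limit_m,
               c_um = convert_profile_coefficient(tip$cap$c_si,
                                                  tip$cap$n, "m", "um")),
    powerlaw = tip$powerlaw,
    diagnostics = tip$diagnostics)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_tip_profile
#' @export
read_tip_profile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "afmindent-tip-profile-v1")) {
    stop("not a tip-profile file: ", path, call. = FALSE)
  }
  structure(list(d = obj$d_si, poly_order = as.integer(obj$poly_order),
                 hc_range = obj$hc_range_m,
                 cap = list(c_si = obj$cap$c_si, n = obj$cap$n,
                            limit_m = obj$cap$limit_m),
                 powerlaw = obj$powerlaw,
                 diagnostics = obj$diagnostics),
            class = "tip_profile")
}
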