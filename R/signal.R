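#' Convert raw deflection (volts) to force (newtons)
#'
#' Standard optical-lever conversion: deflection in metres is
#' `sensitivity * volts`, force is `k_c * deflection`.  The original
#' volts trace is retained in the curve metadata.
#'
#' @param curve a [force_curve()] with the signal in volts.
#' @param sensitivity_m_per_V deflection sensitivity, m/V.  When missing
#'   it is taken from the curve metadata (`sensitivity_nm_per_V`).
#' @param k_c_N_per_m cantilever spring constant, N/m; defaults to the
#'   metadata value.
#' @return the curve with signal in newtons (`force_unit = TRUE`).
#' @export
convert_raw_signal <- function(curve, sensitivity_m_per_V = NULL,
                               k_c_N_per_m = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  if (curve$force_unit) {
    stop("curve '", curve$curve_id, "' is already in force units",
         call. = FALSE)
  }
  if (is.null(sensitivity_m_per_V)) {
    s_nm <- curve$metadata$sensitivity_nm_per_V
    if (is.null(s_nm)) stop("deflection sensitivity not supplied and not ",
                            "present in metadata", call. = FALSE)
    sensitivity_m_per_V <- s_nm * 1e-9
  }
  if (is.null(k_c_N_per_m)) {
    k_c_N_per_m <- curve$metadata$spring_constant_N_per_m
    if (is.null(k_c_N_per_m)) stop("spring constant not supplied and not ",
                                   "present in metadata", call. = FALSE)
  }
  if (sensitivity_m_per_V <= 0 || k_c_N_per_m <= 0) {
    stop("sensitivity and spring constant must be > 0", call. = FALSE)
  }
  volts <- curve$data$signal
  curve$data$signal <- k_c_N_per_m * sensitivity_m_per_V * volts
  curve$force_unit <- TRUE
  curve$metadata$raw_volts <- volts
  curve$metadata$sensitivity_nm_per_V <- sensitivity_m_per_V * 1e9
  curve$metadata$spring_constant_N_per_m <- k_c_N_per_m
  curve
}

#' Detect the contact point on the approach segment
#'
#' Fits a straight baseline (virtual deflection + offset) to the first
#' `baseline_fraction` of the approach samples, subtracts it, and takes
#' the first sample whose force exceeds
#' `max(threshold_multiplier * noise_sd, threshold_floor_N)`.  The
#' crossing is then refined by back-extrapolating a free-exponent power
#' law fitted over the first `refine_window_m` of contact to zero force.
#'
#' @param curve a [force_curve()] in force units.
#' @param noise_sd `"auto"` (residual sd of the baseline fit) or a force
#'   in newtons.
#' @param baseline_fraction fraction of approach samples used for the
#'   first-pass baseline; a second pass re-fits the baseline over
#'   everything safely before the detected contact.
#' @param threshold_multiplier multiple of the noise sd a sample must
#'   exceed to count as contact.
#' @param threshold_floor_N absolute force floor for the threshold.
#' @param refine_window_m depth window of the power-law refinement.
#' @return list with `z0_m` (surface position), `f0_N` (baseline force at
#'   contact), `noise_sd_N`, and `index` of the first contact sample.
#' @export
detect_contact_point <- function(curve, noise_sd = "auto",
                                 baseline_fraction = 0.2,
                                 threshold_multiplier = 5,
                                 threshold_floor_N = 1e-11,
                                 refine_window_m = 20e-9) {
  stopifnot(inherits(curve, "force_curve"))
  if (!curve$force_unit) {
    stop("convert the curve to force units first", call. = FALSE)
  }
  app <- segment_data(curve, "approach")
  nb <- max(floor(nrow(app) * baseline_fraction), 0L)
  if (nb < 10L) {
    stop("baseline region shorter than 10 samples in curve '",
         curve$curve_id, "'", call. = FALSE)
  }
  z <- app$height_m
  f <- app$signal
  find_contact <- function(nb_use) {
    base <- stats::lm.fit(cbind(1, z[seq_len(nb_use)]), f[seq_len(nb_use)])
    f_corr <- f - (base$coefficients[1] + base$coefficients[2] * z)
    sd_n <- if (identical(noise_sd, "auto")) {
      stats::sd(base$residuals)
    } else {
      as.numeric(noise_sd)
    }
    thr <- max(threshold_multiplier * sd_n, threshold_floor_N, na.rm = TRUE)
    # sustained exceedance guards against isolated noise spikes
    above <- f_corr > thr
    run <- which(above & c(above[-1], TRUE) & c(above[-(1:2)], TRUE, TRUE))
    run <- run[run > min(nb_use, 10L)]
    list(base = base, f_corr = f_corr, sd_n = sd_n,
         i0 = if (length(run)) run[1] else NA_integer_)
  }
  # pass 1 on a conservative initial window, pass 2 with the baseline
  # extended to everything safely before the detected contact
  p <- find_contact(nb)
  if (!is.na(p$i0)) {
    nb2 <- max(10L, p$i0 - 5L)
    p <- find_contact(nb2)
  }
  if (is.na(p$i0)) stop("no contact found in curve '", curve$curve_id,
                        "'", call. = FALSE)
  base <- p$base
  f_corr <- p$f_corr
  sd_n <- p$sd_n
  i0 <- p$i0
  z_thr <- z[i0]
  # refine: back-extrapolate F = A (z - z0)^p over the first few tens of
  # nanometres of contact; robust to blunt (p ~ 1) and sharp (p ~ 2) tips
  # refinement: change-point search.  A late crossing (gentle contact
  # under noise) can sit well past the true surface, so candidate
  # surface positions are scanned around the crossing.  Each candidate
  # scores the piecewise model — zero force before contact, power law
  # A (z - z0)^p after — by plain least squares in force space over a
  # window anchored at the crossing, with the exponent profiled on a
  # grid and the amplitude solved in closed form.
  z0 <- z_thr
  w <- refine_window_m
  cand <- z[z >= z_thr - 3 * w & z <= z_thr + 0.5 * w & z > min(z)]
  lo <- which(z >= z_thr - 3 * w)[1]
  hi_all <- which(z <= z_thr + 1.5 * w)
  if (length(cand) >= 3L && length(hi_all) && !is.na(lo)) {
    hi <- max(hi_all)
    zz <- z[lo:hi]
    ff <- f_corr[lo:hi]
    p_grid <- seq(0.5, 3, by = 0.1)
    sse <- vapply(cand, function(zc) {
      x <- pmax(zz - zc, 0) * 1e9
      if (sum(x > 0) < 6L) return(Inf)
      best <- Inf
      for (p in p_grid) {
        xp <- x^p
        A <- sum(ff * xp) / sum(xp^2)
        if (!is.finite(A) || A < 0) next
        s <- sum((ff - A * xp)^2)
        if (s < best) best <- s
      }
      best
    }, numeric(1))
    if (any(is.finite(sse))) z0 <- cand[which.min(sse)]
  }
  f0 <- base$coefficients[1] + base$coefficients[2] * z0
  list(z0_m = z0, f0_N = unname(f0), noise_sd_N = sd_n, index = i0)
}

#' Convert a force curve to indentation coordinates
#'
#' Computes the indentation depth
#' \eqn{h = (z - z_0) - (d - d_0)} where \eqn{d = F/k_c} is the
#' cantilever deflection: the tip displacement into the material equals
#' the piezo travel past contact minus the cantilever bending.  Force is
#' baseline-subtracted.  Retract samples with negative force are kept
#' but flagged adhesive.
#'
#' @param curve a [force_curve()] in force units.
#' @param z0_m,f0_N contact point, e.g. from [detect_contact_point()].
#' @param keep_precontact keep non-contact samples (with negative depth)?
#'   Default drops approach samples before contact.
#' @return an [indentation_curve()].
#' @export
to_indentation <- function(curve, z0_m, f0_N = 0, keep_precontact = FALSE) {
  stopifnot(inherits(curve, "force_curve"))
  if (!curve$force_unit) {
    stop("convert the curve to force units first", call. = FALSE)
  }
  dat <- curve$data
  if (z0_m < min(dat$height_m) || z0_m > max(dat$height_m)) {
    stop("z0 outside curve height range", call. = FALSE)
  }
  k_c <- curve$metadata$spring_constant_N_per_m
  if (is.null(k_c)) {
    stop("spring constant needed to compute deflection; none in metadata",
         call. = FALSE)
  }
  f <- dat$signal - f0_N
  h <- (dat$height_m - z0_m) - f / k_c
  keep <- if (keep_precontact) rep(TRUE, nrow(dat)) else
    !(dat$segment == "approach" & h < 0)
  indentation_curve(curve$curve_id, dat$time_s[keep], h[keep], f[keep],
                    dat$segment[keep], z0_m = z0_m, f0_N = f0_N,
                    metadata = curve$metadata)
}
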