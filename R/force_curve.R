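#' Force-curve container
#'
#' A single force-spectroscopy indentation event: time, piezo height and
#' cantilever signal sampled over three segments (approach, pause,
#' retract), plus the instrument metadata needed to convert and analyse
#' it.  The pause segment may be empty.  The cantilever signal is either
#' raw deflection in volts (`force_unit = FALSE`) or force in newtons
#' (`force_unit = TRUE`).
#'
#' Sign convention: compression positive; piezo height increases toward
#' the sample.
#'
#' @param curve_id character identifier.
#' @param time_s numeric, seconds, strictly increasing within a segment.
#' @param height_m numeric, piezo height in metres.
#' @param signal numeric, deflection (V) or force (N), see `force_unit`.
#' @param segment character or factor with values among
#'   `"approach"`, `"pause"`, `"retract"`.
#' @param force_unit logical; `TRUE` when `signal` is force in newtons.
#' @param metadata named list; recognised entries:
#'   `spring_constant_N_per_m`, `sensitivity_nm_per_V`, `setpoint_N`,
#'   `speed_m_per_s`, `dwell_s`, `position_x_m`, `position_y_m`,
#'   `thickness_m`.
#' @return object of class `force_curve`.
#' @export
force_curve <- function(curve_id, time_s, height_m, signal, segment,
                        force_unit = FALSE, metadata = list()) {
  seg <- as.character(segment)
  bad <- setdiff(unique(seg), c("approach", "pause", "retract"))
  if (length(bad)) {
    stop("unknown segment label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n <- length(time_s)
  if (length(height_m) != n || length(signal) != n || length(seg) != n) {
    stop("time, height, signal and segment must have equal length",
         call. = FALSE)
  }
  dat <- data.table::data.table(
    time_s = as.numeric(time_s),
    height_m = as.numeric(height_m),
    signal = as.numeric(signal),
    segment = seg
  )
  for (s in unique(seg)) {
    ts <- dat$time_s[dat$segment == s]
    if (length(ts) > 1L && any(diff(ts) <= 0)) {
      stop("non-monotone time in segment '", s, "' of curve '",
           curve_id, "'", call. = FALSE)
    }
  }
  structure(
    list(curve_id = as.character(curve_id), data = dat,
         force_unit = isTRUE(force_unit), metadata = metadata),
    class = "force_curve"
  )
}

#' @export
print.force_curve <- function(x, ...) {
  segs <- table(x$data$segment)
  cat("<force_curve> ", x$curve_id, "\n", sep = "")
  cat("  samples: ", paste(names(segs), segs, sep = "=", collapse = ", "),
      "\n", sep = "")
  cat("  signal:  ", if (x$force_unit) "force [N]" else
    "deflection [V] (needs conversion)", "\n", sep = "")
  kc <- x$metadata$spring_constant_N_per_m
  if (!is.null(kc)) cat("  k_c:     ", kc, " N/m\n", sep = "")
  invisible(x)
}

#' Does a raw curve still need volts-to-force conversion?
#'
#' @param curve a [force_curve()].
#' @return `TRUE` when the stored signal is deflection in volts.
#' @export
needs_conversion <- function(curve) {
  stopifnot(inherits(curve, "force_curve"))
  !curve$force_unit
}

segment_data <- function(curve, which) {
  curve$data[curve$data$segment == which, ]
}

#' Indentation-curve container
#'
#' A force curve expressed in material coordinates: indentation depth
#' \eqn{h = (z - z_0) - (d - d_0)} (piezo travel minus cantilever
#' deflection, both measured from the contact point) against force.
#' Retract samples with negative force are retained but flagged
#' `adhesive`; adhesive samples are excluded from all property fits.
#'
#' @param curve_id identifier.
#' @param time_s,depth_m,force_N numeric vectors of equal length.
#' @param segment segment labels as in [force_curve()].
#' @param z0_m contact offset (piezo height of first contact).
#' @param f0_N force baseline at contact.
#' @param metadata named list carried over from the parent curve.
#' @return object of class `indentation_curve`.
#' @export
indentation_curve <- function(curve_id, time_s, depth_m, force_N, segment,
                              z0_m = NA_real_, f0_N = 0,
                              metadata = list()) {
  dat <- data.table::data.table(
    time_s = as.numeric(time_s), depth_m = as.numeric(depth_m),
    force_N = as.numeric(force_N), segment = as.character(segment)
  )
  dat$adhesive <- dat$force_N < 0 & dat$segment == "retract"
  structure(
    list(curve_id = as.character(curve_id), data = dat,
         z0_m = z0_m, f0_N = f0_N, metadata = metadata),
    class = "indentation_curve"
  )
}

#' @export
print.indentation_curve <- function(x, ...) {
  cat("<indentation_curve> ", x$curve_id, "\n", sep = "")
  cat(sprintf("  h_max = %.1f nm, F_max = %.1f nN, %d samples (%d adhesive)\n",
              max(x$data$depth_m) * 1e9, max(x$data$force_N) * 1e9,
              nrow(x$data), sum(x$data$adhesive)))
  invisible(x)
}

#' Analysis configuration
#'
#' Bundles the material constants and fitting controls shared across the
#' pipeline.
#'
#' @param e_star_ref plane-strain modulus of the elastic reference
#'   material, Pa.  Default 3.79e6 (PDMS reference).
#' @param nu_ref Poisson ratio of the reference (0.5: incompressible
#'   elastomer).
#' @param nu_sample Poisson ratio of the cell material (0.4, keratin).
#' @param phi geometric sink-in factor in \eqn{h_s = \phi F_{max}/S_0}
#'   (0.73 for a conical indenter with unloading index near 2).
#' @param psi plasticity constraint factor relating hardness to uniaxial
#'   yield stress, \eqn{H = \psi \sigma_Y}; about 3 for a fully yielded
#'   contact.
#' @param unloading_fit_fraction force fraction of the unloading curve
#'   used in the stiffness fit (default 0.8: samples with
#'   \eqn{F \ge 0.2 F_{max}}).
#' @param h_c_fit_range metres; contact-depth range of the tip-shape
#'   polynomial fit.
#' @param h_c_cap_limit metres; below this contact depth the tip shape is
#'   described by a power-law cap instead of the polynomial.
#' @param smoothing_order polynomial order of the load-curve smoother.
#' @param poly_order polynomial degree of the tip-shape fit a(h_c).
#' @param prony_r2_min minimum Prony-fit R-squared for a relaxation curve
#'   to enter Herschel-Bulkley fitting.
#' @param thickness_fraction_max maximum allowed ratio of indentation
#'   depth to declared sample thickness (default 0.1).
#' @return object of class `calibration_config` (a named list).
#' @export
calibration_config <- function(e_star_ref = 3.79e6,
                               nu_ref = 0.5,
                               nu_sample = 0.4,
                               phi = 0.73,
                               psi = 3,
                               unloading_fit_fraction = 0.8,
                               h_c_fit_range = c(10e-9, 200e-9),
                               h_c_cap_limit = 5e-9,
                               smoothing_order = 3L,
                               poly_order = 6L,
                               prony_r2_min = 0.95,
                               thickness_fraction_max = 0.1) {
  stopifnot(e_star_ref > 0, phi > 0, psi > 0,
            unloading_fit_fraction > 0, unloading_fit_fraction <= 1,
            nu_ref >= 0, nu_ref <= 0.5, nu_sample >= 0, nu_sample <= 0.5,
            length(h_c_fit_range) == 2L, h_c_fit_range[1] < h_c_fit_range[2],
            h_c_cap_limit > 0, smoothing_order >= 1, poly_order >= 1)
  structure(
    list(e_star_ref = e_star_ref, nu_ref = nu_ref, nu_sample = nu_sample,
         phi = phi, psi = psi,
         unloading_fit_fraction = unloading_fit_fraction,
         h_c_fit_range = h_c_fit_range, h_c_cap_limit = h_c_cap_limit,
         smoothing_order = as.integer(smoothing_order),
         poly_order = as.integer(poly_order),
         prony_r2_min = prony_r2_min,
         thickness_fraction_max = thickness_fraction_max),
    class = "calibration_config"
  )
}
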