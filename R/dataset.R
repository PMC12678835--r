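#' Default per-participant material parameters for the simulator
#'
#' Median viscoplastic parameters typical of dry volar-forearm
#' corneocytes on a stiff (glass) substrate: Young's modulus in the
#' 0.4-1.2 GPa range, instantaneous hardness 130-200 MPa, two relaxation
#' times near 0.14 s and 2 s.
#'
#' @return data.frame with one row per participant (`E`, `C0`, `C1`,
#'   `C2` in Pa; `tau1`, `tau2` in seconds; `nu` dimensionless).
#' @export
default_participant_truth <- function() {
  data.frame(
    participant = c("P1", "P2", "P3"),
    E = c(1183e6, 424e6, 1105e6),
    nu = 0.4,
    C0 = c(151e6, 76e6, 92e6),
    C1 = c(30e6, 32e6, 42e6),
    C2 = c(17e6, 19e6, 25e6),
    tau1 = c(0.12, 0.16, 0.14),
    tau2 = c(1.99, 2.11, 2.40)
  )
}

#' Default ground-truth tip used by the simulator
#'
#' A truncated cone (`a = d0 + d1 * h_c`) with a 15 nm flat end and
#' slope 0.6, giving contact radii of roughly 30-130 nm over the
#' contact depths reached on corneocyte-like samples at a 2 uN setpoint.
#'
#' @return an [indenter_truth()].
#' @export
default_tip_truth <- function() {
  indenter_truth("polynomial", d = c(15e-9, 0.6))
}

#' Generate a synthetic force-curve dataset on disk
#'
#' Emulates the acquisition protocol of a corneocyte study: for each
#' participant and cell, an 8 x 8 grid of loading-pause-unloading curves
#' at 0.5 um/s, a 4 s dwell and a 2 uN setpoint.  Cell- and curve-level
#' biological variability is modelled as independent lognormal scatter
#' around the participant medians.  Per-curve ground truth is written to
#' a `truth.csv` sidecar for recovery tests.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed; the dataset is fully deterministic given
#'   the seed and configuration.
#' @param participants data.frame as [default_participant_truth()].
#' @param cells_per_participant,grid_dim grid layout (default 5 cells,
#'   8 x 8 curves per cell).
#' @param profile tip-geometry truth ([default_tip_truth()]).
#' @param setpoint,speed,dwell,dt,k_c acquisition parameters (SI).
#' @param noise_sd force noise sd in newtons; default 0.25% of the
#'   setpoint (5 nN at 2 uN), the thermal force noise of a ~30 N/m
#'   cantilever with ~0.2 nm deflection noise.
#' @param sensitivity_nm_per_V deflection sensitivity used when writing
#'   curves in volts.
#' @param signal write the raw signal as `"volts"` (instrument-like,
#'   default) or `"force"`.
#' @param cell_sdlog,curve_sdlog lognormal scatter (sd of log) applied
#'   to moduli/hardness coefficients at cell and curve level.
#' @param tau_sdlog lognormal scatter of the relaxation times.
#' @return invisibly, a list with `manifest` (path), `truth` (path) and
#'   `n_curves`.
#' @export
generate_dataset <- function(dir, seed,
                             participants = default_participant_truth(),
                             cells_per_participant = 5L, grid_dim = 8L,
                             profile = default_tip_truth(),
                             setpoint = 2e-6, speed = 0.5e-6, dwell = 4,
                             dt = 2e-3, k_c = 28.5,
                             noise_sd = 0.0025 * setpoint,
                             sensitivity_nm_per_V = 20,
                             signal = c("volts", "force"),
                             cell_sdlog = 0.15, curve_sdlog = 0.10,
                             tau_sdlog = 0.08) {
  signal <- match.arg(signal)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(seed))
  grid_xy <- expand.grid(grid_x = seq_len(grid_dim),
                         grid_y = seq_len(grid_dim))
  manifest <- list(); truth_rows <- list(); row <- 0L
  for (p in seq_len(nrow(participants))) {
    pt <- participants[p, ]
    for (cc in seq_len(cells_per_participant)) {
      cell_f <- exp(stats::rnorm(4, 0, cell_sdlog))  # E, C0, C1, C2
      tau_cf <- exp(stats::rnorm(2, 0, tau_sdlog))
      for (g in seq_len(nrow(grid_xy))) {
        row <- row + 1L
        cf <- exp(stats::rnorm(4, 0, curve_sdlog))
        tf <- exp(stats::rnorm(2, 0, tau_sdlog / 2))
        tau1 <- pt$tau1 * tau_cf[1] * tf[1]
        tau2 <- pt$tau2 * tau_cf[2] * tf[2]
        if (tau2 <= 1.5 * tau1) tau2 <- 1.5 * tau1  # keep terms separated
        tr <- material_truth("viscoplastic",
                             E = pt$E * cell_f[1] * cf[1], nu = pt$nu,
                             C0 = pt$C0 * cell_f[2] * cf[2],
                             C1 = pt$C1 * cell_f[3] * cf[3],
                             C2 = pt$C2 * cell_f[4] * cf[4],
                             tau1 = tau1, tau2 = tau2)
        id <- sprintf("%s_C%d_x%d_y%d", pt$participant, cc,
                      grid_xy$grid_x[g], grid_xy$grid_y[g])
        cv <- elastoplastic_curve(
          tr, profile, f_max = setpoint, speed = speed, dwell = dwell,
          dt = dt, k_c = k_c, noise_sd = noise_sd, curve_id = id,
          metadata = list(sensitivity_nm_per_V = sensitivity_nm_per_V,
                          participant = pt$participant, cell = cc))
        if (signal == "volts") {
          cv$data$signal <- cv$data$signal /
            (k_c * sensitivity_nm_per_V * 1e-9)
          cv$force_unit <- FALSE
        }
        fname <- paste0(id, ".tsv")
        write_force_curve(cv, file.path(dir, fname))
        manifest[[row]] <- data.frame(
          file = fname, curve_id = id, participant = pt$participant,
          cell = cc, grid_x = grid_xy$grid_x[g],
          grid_y = grid_xy$grid_y[g])
        tt <- attr(cv, "truth")
        truth_rows[[row]] <- data.frame(
          curve_id = id, participant = pt$participant, cell = cc,
          E = tr$E, nu = tr$nu, H0 = tr$C0 + tr$C1 + tr$C2,
          C0 = tr$C0, C1 = tr$C1, C2 = tr$C2,
          tau1 = tr$tau1, tau2 = tr$tau2,
          a_max = tt$a_max, h_max = tt$h_max, S0 = tt$S0,
          H_end = tt$H_end)
      }
    }
  }
  man_path <- file.path(dir, "manifest.csv")
  truth_path <- file.path(dir, "truth.csv")
  data.table::fwrite(data.table::rbindlist(manifest), man_path)
  data.table::fwrite(data.table::rbindlist(truth_rows), truth_path)
  invisible(list(manifest = man_path, truth = truth_path, n_curves = row))
}
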