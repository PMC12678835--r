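#' Run the full analysis pipeline over a curve manifest
#'
#' For every curve in the manifest: read, convert volts to force if
#' needed, detect the contact point, transform to indentation
#' coordinates, run the elastoplastic unloading analysis and — when a
#' usable pause segment is present — the relaxation / Herschel-Bulkley
#' analysis.  Curves failing any stage are recorded in a rejection log
#' with the stage and reason; rejection accounting conserves curve
#' counts.
#'
#' @param manifest path to a manifest CSV (see [read_force_curves()]).
#' @param tip a `tip_profile` (from [calibrate_tip()] /
#'   [read_tip_profile()]).
#' @param config a [calibration_config()].
#' @param out_dir optional output directory; when given, writes
#'   `results.csv`, `rejections.csv`, `summary_cell.csv`,
#'   `summary_participant.csv` and `provenance.json`.
#' @param nominal_dwell_s nominal hold duration; pauses shorter than 90%
#'   of it are excluded from relaxation analysis (flag, not error).
#' @return a results bundle (class `pipeline_result`): `results`
#'   (per-curve data.frame), `rejections`, `summary_cell`,
#'   `summary_participant`, `n_input`.
#' @export
run_pipeline <- function(manifest, tip, config = calibration_config(),
                         out_dir = NULL, nominal_dwell_s = 4) {
  stopifnot(inherits(tip, "tip_profile"))
  man <- data.table::fread(manifest)
  if (!"file" %in% names(man)) stop("manifest must contain a 'file' column",
                                    call. = FALSE)
  root <- dirname(manifest)
  n_input <- nrow(man)
  rows <- vector("list", n_input)
  rej <- list()
  for (i in seq_len(n_input)) {
    id <- if ("curve_id" %in% names(man)) man$curve_id[i] else man$file[i]
    meta <- list(participant = man$participant[i], cell = man$cell[i])
    res <- tryCatch(
      analyze_one_curve(file.path(root, man$file[i]), tip, config,
                        nominal_dwell_s),
      error = function(e) e)
    if (inherits(res, "error")) {
      rej[[length(rej) + 1L]] <- data.frame(
        curve_id = id, participant = meta$participant %||% NA,
        cell = meta$cell %||% NA, stage = "pipeline",
        reason = conditionMessage(res))
      next
    }
    rows[[i]] <- data.frame(
      curve_id = id,
      participant = meta$participant %||% NA, cell = meta$cell %||% NA,
      res$row)
  }
  results <- data.table::rbindlist(Filter(Negate(is.null), rows),
                                   fill = TRUE)
  rejections <- if (length(rej)) data.table::rbindlist(rej) else
    data.table::data.table(curve_id = character(0),
                           participant = character(0), cell = integer(0),
                           stage = character(0), reason = character(0))
  bundle <- structure(
    list(results = as.data.frame(results),
         rejections = as.data.frame(rejections),
         summary_cell = aggregate_results(as.data.frame(results), "cell"),
         summary_participant = aggregate_results(as.data.frame(results),
                                                 "participant"),
         n_input = n_input, config = config),
    class = "pipeline_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(bundle$results, file.path(out_dir, "results.csv"))
    data.table::fwrite(bundle$rejections,
                       file.path(out_dir, "rejections.csv"))
    data.table::fwrite(bundle$summary_cell,
                       file.path(out_dir, "summary_cell.csv"))
    data.table::fwrite(bundle$summary_participant,
                       file.path(out_dir, "summary_participant.csv"))
    jsonlite::write_json(list(config = unclass(config),
                              n_input = n_input,
                              n_accepted = nrow(bundle$results),
                              n_rejected = nrow(bundle$rejections)),
                         file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

analyze_one_curve <- function(path, tip, config, nominal_dwell_s) {
  cv <- read_force_curve(path)
  if (needs_conversion(cv)) cv <- convert_raw_signal(cv)
  cp <- detect_contact_point(cv)
  ic <- to_indentation(cv, cp$z0_m, cp$f0_N)
  ind <- analyze_indentation(ic, tip, config)
  pau <- ic$data[ic$data$segment == "pause", ]
  dwell_nominal <- ic$metadata$dwell_s %||% nominal_dwell_s
  pause_ok <- nrow(pau) >= 10L &&
    (max(pau$time_s) - min(pau$time_s)) >= 0.9 * dwell_nominal
  rel <- if (pause_ok) {
    tryCatch(analyze_relaxation(ic, ind, config), error = function(e) NULL)
  } else {
    NULL
  }
  row <- data.frame(
    z0 = cp$z0_m, E = ind$E, H = ind$H, S0 = ind$S0,
    C_e = ind$C_e, h_max = ind$h_max, h_c = ind$h_c, h_s = ind$h_s,
    h_f = ind$h_f, a = ind$a, A_max = ind$A_max,
    sigma_Y_static = ind$sigma_Y_static,
    unload_r2 = ind$r_squared,
    extrapolated_tip = ind$flags$extrapolated_tip,
    thickness_exceeded = ind$flags$thickness_exceeded,
    pause_ok = pause_ok,
    C0 = NA_real_, C1 = NA_real_, C2 = NA_real_,
    tau1 = NA_real_, tau2 = NA_real_, H0 = NA_real_, H_inf = NA_real_,
    prony_r2 = NA_real_, sigma_Y = NA_real_, k = NA_real_, j = NA_real_,
    hb_r2 = NA_real_, hb_accepted = FALSE)
  if (!is.null(rel)) {
    row$C0 <- rel$C0; row$C1 <- rel$C1; row$C2 <- rel$C2
    row$tau1 <- rel$prony$tau1; row$tau2 <- rel$prony$tau2
    row$H0 <- rel$H0; row$H_inf <- rel$H_inf
    row$prony_r2 <- rel$prony$r_squared
    row$hb_accepted <- rel$accepted
    if (!is.null(rel$hb)) {
      row$sigma_Y <- rel$hb$sigma_Y; row$k <- rel$hb$k; row$j <- rel$hb$j
      row$hb_r2 <- rel$hb$r_squared
    }
  }
  list(row = row, relaxation = rel)
}

#' Aggregate per-curve results to cell or participant level
#'
#' Median and range, following the reporting convention of
#' per-cell / per-participant tables.  Participant summaries pool all
#' accepted curves by default; `method = "cell_medians"` takes the
#' median of cell medians instead.
#'
#' @param results per-curve results data.frame (from [run_pipeline()]).
#' @param level `"cell"` or `"participant"`.
#' @param metrics columns to summarise.
#' @param method `"pooled"` (default) or `"cell_medians"`.
#' @param exclude_extrapolated drop curves whose tip evaluation was
#'   extrapolated (default TRUE).
#' @return data.frame: level keys, `metric`, `median`, `min`, `max`,
#'   `n`.
#' @export
aggregate_results <- function(results, level = c("participant", "cell"),
                              metrics = c("E", "H", "H0", "H_inf",
                                          "tau1", "tau2", "sigma_Y",
                                          "k", "j"),
                              method = c("pooled", "cell_medians"),
                              exclude_extrapolated = TRUE) {
  level <- match.arg(level)
  method <- match.arg(method)
  if (!nrow(results)) {
    return(data.frame(participant = character(0), metric = character(0),
                      median = numeric(0), min = numeric(0),
                      max = numeric(0), n = integer(0)))
  }
  metrics <- intersect(metrics, names(results))
  if (exclude_extrapolated && "extrapolated_tip" %in% names(results)) {
    results <- results[!isTRUE_vec(results$extrapolated_tip), ,
                       drop = FALSE]
  }
  keys <- if (level == "cell") c("participant", "cell") else "participant"
  split_keys <- interaction(results[keys], drop = TRUE)
  out <- list()
  for (g in levels(split_keys)) {
    sub <- results[split_keys == g, , drop = FALSE]
    for (mname in metrics) {
      v <- sub[[mname]]
      v <- v[is.finite(v)]
      if (!length(v)) next
      if (level == "participant" && method == "cell_medians") {
        v <- tapply(v, sub$cell[is.finite(sub[[mname]])], stats::median)
      }
      out[[length(out) + 1L]] <- data.frame(
        sub[1, keys, drop = FALSE], metric = mname,
        median = stats::median(v), min = min(v), max = max(v),
        n = length(v), row.names = NULL)
    }
  }
  if (!length(out)) {
    return(data.frame(participant = character(0), metric = character(0),
                      median = numeric(0), min = numeric(0),
                      max = numeric(0), n = integer(0)))
  }
  do.call(rbind, out)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Write report figures and tables for a pipeline run
#'
#' Per-cell histograms of Young's modulus and yield stress,
#' Herschel-Bulkley overlay plots (data solid, fit dashed) for one
#' representative accepted curve per cell, and the machine-readable
#' summary tables.  Sections without data are skipped with a note.
#'
#' @param bundle a `pipeline_result`.
#' @param out_dir output directory.
#' @return character vector of files written, invisibly.
#' @export
report_results <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "pipeline_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- bundle$results
  files <- character(0)
  if (!nrow(res)) {
    p <- file.path(out_dir, "EMPTY.txt")
    writeLines("no accepted curves; nothing to report", p)
    return(invisible(p))
  }
  groups <- unique(res[c("participant", "cell")])
  for (i in seq_len(nrow(groups))) {
    sub <- res[res$participant == groups$participant[i] &
                 res$cell == groups$cell[i], ]
    tag <- sprintf("%s_cell%s", groups$participant[i], groups$cell[i])
    f <- file.path(out_dir, paste0("hist_E_", tag, ".png"))
    grDevices::png(f, width = 600, height = 450)
    graphics::hist(sub$E / 1e6, breaks = 20, col = "grey70",
                   main = paste("Young's modulus -", tag),
                   xlab = "E (MPa)")
    grDevices::dev.off()
    files <- c(files, f)
    sy <- sub$sigma_Y[is.finite(sub$sigma_Y)]
    if (length(sy)) {
      f <- file.path(out_dir, paste0("hist_sigmaY_", tag, ".png"))
      grDevices::png(f, width = 600, height = 450)
      graphics::hist(sy / 1e6, breaks = 20, col = "grey70",
                     main = paste("Yield stress -", tag),
                     xlab = expression(sigma[Y] ~ "(MPa)"))
      grDevices::dev.off()
      files <- c(files, f)
      # HB overlay for the first accepted curve of the cell
      k <- which(isTRUE_vec(sub$hb_accepted))[1]
      if (!is.na(k)) {
        f <- file.path(out_dir, paste0("hb_fit_", tag, ".png"))
        grDevices::png(f, width = 600, height = 450)
        rate <- exp(seq(log(1e-4), log(1), length.out = 100))
        sig_fit <- sub$sigma_Y[k] + sub$k[k] * rate^sub$j[k]
        graphics::plot(rate, sig_fit / 1e6, type = "l", lty = 2,
                       log = "x", xlab = "plastic strain rate (1/s)",
                       ylab = "stress (MPa)",
                       main = paste("Herschel-Bulkley fit -", tag))
        grDevices::dev.off()
        files <- c(files, f)
      }
    }
  }
  for (lev in c("cell", "participant")) {
    f <- file.path(out_dir, paste0("summary_", lev, ".csv"))
    data.table::fwrite(bundle[[paste0("summary_", lev)]], f)
    files <- c(files, f)
  }
  if (all(!is.finite(res$sigma_Y))) {
    writeLines("no relaxation results: Herschel-Bulkley section omitted",
               file.path(out_dir, "NOTE_no_relaxation.txt"))
  }
  invisible(files)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d curves in, %d analysed, %d rejected\n",
              x$n_input, nrow(x$results), nrow(x$rejections)))
  invisible(x)
}
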