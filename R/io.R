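#' Write a force curve to the package's plain-text format
#'
#' One tab-separated file per curve: a `# key: value` metadata header
#' followed by the columns `time_s  height_m  force_N|deflection_V
#' segment`.  Numeric values are written with 15 significant digits so
#' that a read/write round trip is lossless to at least 12 digits.
#'
#' @param curve a [force_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  sig_col <- if (curve$force_unit) "force_N" else "deflection_V"
  meta <- curve$metadata
  hdr <- c(
    "# afm-force-curve: v1",
    paste0("# curve_id: ", curve$curve_id),
    vapply(names(meta), function(k) {
      v <- meta[[k]]
      paste0("# ", k, ": ",
             if (is.numeric(v)) format(v, digits = 15) else as.character(v))
    }, character(1))
  )
  dat <- curve$data
  out <- data.table::data.table(
    time_s = dat$time_s, height_m = dat$height_m, signal = dat$signal,
    segment = dat$segment
  )
  data.table::setnames(out, "signal", sig_col)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(out), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(out, function(col) {
    if (is.numeric(col)) format(col, digits = 15, scientific = TRUE,
                                trim = TRUE) else as.character(col)
  }), sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

parse_header <- function(lines) {
  kv <- sub("^#\\s*", "", lines)
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:\\s*", "", kv))
  out <- as.list(vals)
  names(out) <- trimws(keys)
  num <- suppressWarnings(lapply(out, as.numeric))
  for (k in names(out)) if (!is.na(num[[k]])) out[[k]] <- num[[k]]
  out
}

#' Read a single force curve
#'
#' Reads the format written by [write_force_curve()].  A missing pause or
#' retract block is tolerated (the curve is returned with that segment
#' empty, with a warning); missing mandatory columns are a format error.
#' Metadata absent from the header is defaulted with a warning.
#'
#' @param path file path.
#' @return a [force_curve()].
#' @export
read_force_curve <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 200L)
  hdr_n <- which(!startsWith(lines, "#"))[1] - 1L
  meta <- parse_header(lines[seq_len(hdr_n)])
  dat <- data.table::fread(path, skip = hdr_n, sep = "\t", header = TRUE)
  if (!all(c("time_s", "height_m", "segment") %in% names(dat))) {
    stop("format error in ", path,
         ": need columns time_s, height_m, segment", call. = FALSE)
  }
  force_unit <- "force_N" %in% names(dat)
  if (!force_unit && !"deflection_V" %in% names(dat)) {
    stop("format error in ", path,
         ": need a force_N or deflection_V column", call. = FALSE)
  }
  signal <- if (force_unit) dat$force_N else dat$deflection_V
  curve_id <- meta$curve_id
  meta$curve_id <- NULL
  if (is.null(curve_id)) curve_id <- basename(path)
  missing_seg <- setdiff(c("approach", "pause", "retract"),
                         unique(dat$segment))
  # pause may legitimately be empty; a missing retract is reported
  if ("retract" %in% missing_seg) {
    warning("curve '", curve_id, "' has no retract segment (truncated file?)",
            call. = FALSE)
  }
  if (!force_unit && (is.null(meta$sensitivity_nm_per_V) ||
                      is.null(meta$spring_constant_N_per_m))) {
    warning("curve '", curve_id, "' is in volts but lacks calibration ",
            "metadata; conversion will fail until supplied", call. = FALSE)
  }
  meta$`afm-force-curve` <- NULL
  force_curve(curve_id, dat$time_s, dat$height_m, signal, dat$segment,
              force_unit = force_unit, metadata = meta)
}

#' Read a set of force curves listed in a manifest
#'
#' The manifest is a CSV with at least a `file` column (paths relative to
#' the manifest's directory); `participant`, `cell`, `grid_x`, `grid_y`
#' columns are carried into each curve's metadata when present.
#'
#' @param manifest path to the manifest CSV.
#' @param on_error `"stop"` or `"skip"`; with `"skip"` unreadable files
#'   are dropped with a warning and recorded in the
#'   `"rejected"` attribute of the result.
#' @return list of [force_curve()] objects.
#' @export
read_force_curves <- function(manifest, on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  man <- data.table::fread(manifest)
  if (!"file" %in% names(man)) {
    stop("manifest must contain a 'file' column", call. = FALSE)
  }
  root <- dirname(manifest)
  extra <- intersect(c("participant", "cell", "grid_x", "grid_y"),
                     names(man))
  curves <- vector("list", nrow(man))
  rejected <- character(0)
  for (i in seq_len(nrow(man))) {
    path <- file.path(root, man$file[i])
    cv <- tryCatch(read_force_curve(path), error = function(e) e)
    if (inherits(cv, "error")) {
      if (on_error == "stop") stop(cv)
      warning("skipping unreadable curve file ", man$file[i], ": ",
              conditionMessage(cv), call. = FALSE)
      rejected <- c(rejected, man$file[i])
      next
    }
    for (k in extra) cv$metadata[[k]] <- man[[k]][i]
    curves[[i]] <- cv
  }
  curves <- Filter(Negate(is.null), curves)
  attr(curves, "rejected") <- rejected
  curves
}
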