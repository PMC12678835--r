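# curve containers, file round trips, signal conversion, contact
# detection and indentation coordinates

test_that("force-curve TSV round trip is lossless to 12 digits", {
  cv <- fixture_curve(dwell = 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_force_curve(cv, path)
  cv2 <- read_force_curve(path)
  expect_equal(cv2$curve_id, cv$curve_id)
  expect_equal(cv2$data$time_s, cv$data$time_s, tolerance = 1e-12)
  expect_equal(cv2$data$height_m, cv$data$height_m, tolerance = 1e-12)
  expect_equal(cv2$data$signal, cv$data$signal, tolerance = 1e-12)
  expect_identical(cv2$data$segment, cv$data$segment)
  expect_true(cv2$force_unit)
  expect_equal(cv2$metadata$spring_constant_N_per_m, 28.5)
})

test_that("volts curves are flagged for conversion; truncated files load", {
  cv <- fixture_curve(dwell = 0.5)
  cv$data$signal <- cv$data$signal / (28.5 * 20e-9)  # back to volts
  cv$force_unit <- FALSE
  cv$metadata$sensitivity_nm_per_V <- 20
  path <- withr::local_tempfile(fileext = ".tsv")
  write_force_curve(cv, path)
  cv2 <- read_force_curve(path)
  expect_true(needs_conversion(cv2))

  # delete the retract block: curve still loads, with a warning
  lines <- readLines(path)
  keep <- !grepl("\tretract$", lines)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines[keep], path2)
  expect_warning(cv3 <- read_force_curve(path2), "retract")
  expect_equal(sum(cv3$data$segment == "retract"), 0L)
  expect_gt(sum(cv3$data$segment == "approach"), 0L)
})

test_that("malformed files raise format errors, bad time a data error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# curve_id: x", "time_s\theight_m", "0\t0"), path)
  expect_error(read_force_curve(path), "format error")
  expect_error(
    force_curve("bad", c(0, 1, 1), c(0, 0, 0), c(0, 0, 0),
                rep("approach", 3), force_unit = TRUE),
    "non-monotone time.*bad")
  expect_error(
    force_curve("x", 0, 0, 0, "weird"), "segment")
})

test_that("convert_raw_signal applies F = k_c * s * V and is linear", {
  mk <- function(v) force_curve("v", seq_along(v) - 1, numeric(length(v)),
                                v, rep("approach", length(v)))
  cv <- convert_raw_signal(mk(c(0, 1.0)), sensitivity_m_per_V = 20e-9,
                           k_c_N_per_m = 28.5)
  expect_true(cv$force_unit)
  expect_equal(cv$data$signal[2], 5.70e-7, tolerance = 1e-12)
  expect_equal(cv$data$signal[1], 0)
  expect_identical(cv$metadata$raw_volts, c(0, 1.0))
  # linearity: doubling volts doubles force
  cv2 <- convert_raw_signal(mk(c(0, 2.0)), 20e-9, 28.5)
  expect_equal(cv2$data$signal[2], 2 * cv$data$signal[2])
  expect_error(convert_raw_signal(mk(c(0, 1)), -1, 28.5), "> 0")
  expect_error(convert_raw_signal(cv), "already in force units")
})

test_that("contact point is recovered on clean and noisy curves", {
  spacing <- 0.5e-6 * 2e-3  # speed * dt = 1 nm
  # noiseless Hertzian contact: recovered within one sample spacing
  hz <- sneddon_elastic_curve(indenter_truth("paraboloid", R_m = 50e-9),
                              3.79e6, 200e-9, n_points = 200)
  d <- hz$data
  z <- c(seq(0, 49e-9, length.out = 50),
         50e-9 + d$depth_m + d$force_N / 28.5)
  f <- c(rep(0, 50), d$force_N)
  cvh <- force_curve("hertz", seq_along(z) * 2e-3, z, f,
                     rep("approach", length(z)), force_unit = TRUE,
                     metadata = list(spring_constant_N_per_m = 28.5))
  cph <- detect_contact_point(cvh)
  expect_lt(abs(cph$z0_m - 50e-9), 1e-9)
  # blunt elastoplastic contact: within two spacings
  cv <- fixture_curve(dwell = 0)
  cp <- detect_contact_point(cv)
  expect_lt(abs(cp$z0_m), 2 * spacing)

  # noisy recovery property at fixed seeds, sd = 0.5 nN
  set.seed(101)
  errs <- replicate(5, {
    cvn <- fixture_curve(dwell = 0, noise_sd = 0.5e-9)
    detect_contact_point(cvn)$z0_m
  })
  expect_true(all(abs(errs) <= 2 * spacing))

  # pure-noise approach: no contact
  set.seed(3)
  flat <- force_curve("flat", seq(0, 1, by = 1e-3),
                      seq(0, 1e-7, length.out = 1001),
                      rnorm(1001, 0, 1e-10), rep("approach", 1001),
                      force_unit = TRUE)
  expect_error(detect_contact_point(flat), "no contact found")
})

test_that("to_indentation reproduces depth kinematics", {
  cv <- fixture_curve(dwell = 0)
  tt <- attr(cv, "truth")
  ic <- to_indentation(cv, 0, 0)
  app <- ic$data[ic$data$segment == "approach", ]
  # generator round trip: depth at trigger equals truth h_max
  expect_equal(max(app$depth_m), tt$h_max, tolerance = 1e-9)
  # depth is piezo travel minus deflection, so less than piezo travel
  z_travel <- max(cv$data$height_m)
  expect_lt(max(app$depth_m), z_travel)
  # infinitely stiff cantilever: h equals piezo travel past contact
  cvs <- cv
  cvs$metadata$spring_constant_N_per_m <- Inf
  ics <- to_indentation(cvs, 0, 0)
  apps <- ics$data[ics$data$segment == "approach", ]
  expect_equal(max(apps$depth_m), z_travel, tolerance = 1e-12)
  expect_error(to_indentation(cv, 1), "z0 outside")
})

test_that("negative-force retract samples are flagged adhesive", {
  ic <- indentation_curve("adh", time_s = 1:6, depth_m = (6:1) * 1e-9,
                          force_N = c(5, 4, 3, 2, -1, -2) * 1e-9,
                          segment = rep("retract", 6))
  expect_identical(ic$data$adhesive, c(rep(FALSE, 4), TRUE, TRUE))
  # approach samples with negative force are not adhesive-flagged
  ic2 <- indentation_curve("x", 1, 1e-9, -1e-9, "approach")
  expect_false(ic2$data$adhesive)
})

test_that("manifest reader tolerates unreadable files when asked", {
  dir <- withr::local_tempdir()
  cv <- fixture_curve(dwell = 0)
  write_force_curve(cv, file.path(dir, "good.tsv"))
  writeLines("garbage", file.path(dir, "bad.tsv"))
  man <- file.path(dir, "manifest.csv")
  data.table::fwrite(data.frame(file = c("good.tsv", "bad.tsv"),
                                participant = "P1", cell = 1),
                     man)
  expect_error(read_force_curves(man, on_error = "stop"))
  expect_warning(curves <- read_force_curves(man, on_error = "skip"),
                 "skipping")
  expect_length(curves, 1L)
  expect_identical(attr(curves, "rejected"), "bad.tsv")
  expect_equal(curves[[1]]$metadata$participant, "P1")
})
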