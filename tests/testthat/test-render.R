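empty_droplets <- function() {
  fl <- fluidic_config(gradient_duration = 0, inject_volume = 0,
                       substrate_stock = 1e-3, enzyme_initial = 1e-9)
  generate_droplets(fl)
}

test_that("a droplet-free trace is flat baseline with per-channel gains", {
  fl <- fluidic_config(substrate_stock = 1e-3, enzyme_initial = 1e-9)
  optics <- optical_config(n_channels = 3, noise_sd = 1e-3,
                           channel_gain = c(1, 0.85, 0.7))
  passes <- pass_schedule(n_passes = 2, n_channels = 3, total_duration = 300,
                          pass_interval = 120, calib_pass = NA)
  tr <- render_trace(empty_droplets(), kinetic_params(1, 1e-3), optics,
                     passes, fl, seed = 4)
  m <- rowMeans(tr$intensity)
  expect_equal(m / m[1], c(1, 0.85, 0.7), tolerance = 1e-3)
  expect_true(all(tr$intensity >= 0))
  expect_equal(ncol(tr$intensity), 300 * 200)
})

test_that("trough depth obeys the Beer-Lambert law (1 mM product, eps*l = 0.32 /mM)", {
  fl <- fluidic_config(substrate_stock = 1e-3, enzyme_initial = 1e-9,
                       gradient_duration = 0, inject_volume = 0)
  optics <- optical_config(n_channels = 1, noise_sd = 0, droplet_contrast = 0)
  passes <- pass_schedule(n_passes = 1, n_channels = 1, total_duration = 120,
                          first_arrival = 50, calib_pass = 1)
  cal <- calibration_droplets(fl, n = 1, conc = 1e-3)
  tr <- render_trace(empty_droplets(), kinetic_params(0, 1e-3), optics,
                     passes, fl, seed = 1, calib = cal)
  baseline <- optics$baseline_intensity
  expect_equal(min(tr$intensity) / baseline, 10^(-0.32), tolerance = 1e-12)
  # trough duration = droplet volume / draw rate = 0.45 s = 90 samples
  expect_equal(sum(tr$intensity < baseline * 0.9), 90)
})

test_that("a non-reacting droplet reads identically on the first and last pass", {
  fl <- fluidic_config(substrate_stock = 1e-3, enzyme_initial = 1e-9)
  optics <- optical_config(n_channels = 1, noise_sd = 0)
  passes <- pass_schedule(n_passes = 6, n_channels = 1, calib_pass = NA)
  dr <- generate_droplets(fl)
  tr <- render_trace(dr, kinetic_params(0, 1e-3), optics, passes, fl, seed = 1)
  sched <- attr(tr, "schedule")
  for (gi in c(0, 20, 59)) {
    s <- sched[sched$index == gi & sched$pass %in% c(1, 6), ]
    i <- round(s$t_center * tr$sample_rate) + 1
    expect_equal(tr$intensity[1, i[1]], tr$intensity[1, i[2]], tolerance = 1e-12)
  }
})

test_that("rendering is reproducible for a fixed seed and differs across seeds", {
  fl <- fluidic_config(substrate_stock = 500e-6, enzyme_initial = 5e-9)
  optics <- optical_config(n_channels = 1)
  passes <- pass_schedule(n_passes = 2, n_channels = 1, total_duration = 400,
                          calib_pass = 2)
  dr <- generate_droplets(fl)
  cal <- calibration_droplets(fl)
  k <- kinetic_params(23.1, 13.7e-6)
  t1 <- render_trace(dr, k, optics, passes, fl, seed = 11, calib = cal)
  t2 <- render_trace(dr, k, optics, passes, fl, seed = 11, calib = cal)
  t3 <- render_trace(dr, k, optics, passes, fl, seed = 12, calib = cal)
  expect_identical(t1$intensity, t2$intensity)
  expect_false(identical(t1$intensity, t3$intensity))
})

test_that("overlapping troughs in one channel are a schedule fault", {
  fl <- fluidic_config(substrate_stock = 1e-3, enzyme_initial = 1e-9)
  optics <- optical_config(n_channels = 1, noise_sd = 0)
  passes <- pass_schedule(n_passes = 2, n_channels = 1, total_duration = 300,
                          first_arrival = 60, pass_interval = 10,
                          calib_pass = NA)  # passes 10 s apart, trains 30 s long
  dr <- generate_droplets(fl)
  expect_error(render_trace(dr, kinetic_params(0, 1e-3), optics, passes, fl),
               "overlap")
})

test_that("trace CSV round-trips through its own reader", {
  fl <- fluidic_config(substrate_stock = 1e-3, enzyme_initial = 1e-9)
  optics <- optical_config(n_channels = 2, noise_sd = 1e-3)
  passes <- pass_schedule(n_passes = 1, n_channels = 2, total_duration = 150,
                          calib_pass = 1)
  tr <- render_trace(generate_droplets(fl), kinetic_params(0.4, 0.023),
                     optics, passes, fl, seed = 5,
                     calib = calibration_droplets(fl))
  path <- tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  header <- readLines(path, n = 1)
  expect_equal(header, "time_s,ch01,ch02")
  tr2 <- read_trace_csv(path)
  expect_equal(tr2$sample_rate, 200, tolerance = 1e-9)
  expect_equal(tr2$intensity, tr$intensity, tolerance = 1e-9,
               ignore_attr = TRUE)
  # a file without the time column is a parse fault
  bad <- tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), bad)
  expect_error(read_trace_csv(bad), "time_s")
})

test_that("ground-truth sidecar round-trips and matches the forward model", {
  fl <- fluidic_config(substrate_stock = 500e-6, enzyme_initial = 5e-9)
  k <- kinetic_params(23.1, 13.7e-6)
  passes <- pass_schedule(n_passes = 2, n_channels = 1, total_duration = 400,
                          calib_pass = NA)
  dr <- generate_droplets(fl)
  sched <- build_read_schedule(dr, k, passes, fl)
  path <- tempfile(fileext = ".json")
  write_ground_truth(dr, sched, k, path)
  gt <- read_ground_truth(path)
  expect_equal(gt$kinetics$kcat, 23.1)
  expect_equal(gt$droplets$S0, dr$S0)
  expect_equal(gt$reads$P, sched$P)
  # truth P values re-derive from progress_curve at the recorded read times
  i20 <- gt$reads$index == 20 & !gt$reads$is_calibration
  tr20 <- gt$reads$t_react[i20]
  pc <- progress_curve(dr[dr$index == 20, ], k, sort(tr20))
  expect_equal(sort(gt$reads$P[i20]), pc$P, tolerance = 1e-12)
  expect_error(read_ground_truth(path <- {
    p <- tempfile(fileext = ".json"); jsonlite::write_json(list(a = 1), p); p
  }), "sidecar")
})
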