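# one simulated channel at the full default geometry, reused across tests
sim_one_channel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fl <- fluidic_config(substrate_stock = 0.4, enzyme_initial = 1e-6)
      optics <- optical_config(n_channels = 1)
      passes <- pass_schedule(n_passes = 6, n_channels = 1)
      dr <- generate_droplets(fl)
      cal <- calibration_droplets(fl)
      tr <- render_trace(dr, kinetic_params(0.4, 0.023), optics, passes, fl,
                         seed = 21, calib = cal)
      cache <<- list(fl = fl, passes = passes, droplets = dr, trace = tr,
                     schedule = attr(tr, "schedule"))
    }
    cache
  }
})

test_that("six passes of 60 droplets segment into six clean segments plus the calibration train", {
  s <- sim_one_channel()
  det <- detect_droplets(s$trace, 1)
  seg <- segment_passes(det, s$passes)
  expect_equal(nrow(seg$segments), 6)
  expect_equal(seg$segments$n, rep(60, 6))
  expect_equal(seg$segments$direction, rep(c("pull", "push"), 3))
  expect_false(any(seg$segments$flag_count_deviation))
  expect_equal(nrow(seg$calibration), 15)
  expect_equal(seg$calibration$pass_index[1], 6)
})

test_that("a single pass segments into one segment", {
  fl <- fluidic_config(substrate_stock = 1e-3, enzyme_initial = 1e-9)
  passes <- pass_schedule(n_passes = 1, n_channels = 1, total_duration = 200,
                          calib_pass = NA)
  tr <- render_trace(generate_droplets(fl), kinetic_params(0, 1e-3),
                     optical_config(n_channels = 1), passes, fl, seed = 2)
  seg <- segment_passes(detect_droplets(tr, 1), passes)
  expect_equal(nrow(seg$segments), 1)
  expect_equal(seg$segments$n, 60)
})

test_that("one missing droplet flags its pass and leaves the others clean", {
  s <- sim_one_channel()
  tr <- s$trace
  # erase droplet 30 of pass 3 from the rendered intensity
  row <- s$schedule[s$schedule$pass == 3 & s$schedule$index == 30 &
                      !s$schedule$is_calibration, ]
  i0 <- round(row$t_start * tr$sample_rate)
  i1 <- i0 + round(droplet_transit(s$fl) * tr$sample_rate) + 2
  tr$intensity[1, i0:i1] <- optical_config(n_channels = 1)$baseline_intensity
  seg <- segment_passes(detect_droplets(tr, 1), s$passes)
  expect_equal(seg$segments$n[3], 59)
  expect_true(seg$segments$flag_count_deviation[3])
  expect_equal(seg$segments$n[-3], rep(60, 5))
  expect_false(any(seg$segments$flag_count_deviation[-3]))
  # indexing by anchor offset still maps the remaining droplets correctly
  mt <- match_tracks(seg)
  t3 <- mt$tracks[mt$tracks$pass == 3, ]
  expect_false(30 %in% t3$gradient_index)
  expect_equal(sort(t3$gradient_index), setdiff(0:59, 30))
})

test_that("the anchor is the temporal end on pull passes and start on push passes", {
  seg <- data.frame(channel = 1, t_center = c(10, 11, 12), absorbance = 1:3)
  expect_equal(anchor_gradient_end(seg, "pull"), 3)
  expect_equal(anchor_gradient_end(seg, "push"), 1)
  expect_equal(anchor_gradient_end(seg, "pull", override_time = 10.9), 2)
  expect_error(anchor_gradient_end(seg, "pull", override_time = 50), "outside")
})

test_that("anchored matching recovers every droplet's true generation index and absorbance", {
  s <- sim_one_channel()
  det <- detect_droplets(s$trace, 1)
  seg <- segment_passes(det, s$passes)
  mt <- match_tracks(seg)
  expect_equal(mt$n_droplets, 60)
  expect_equal(nrow(mt$dropped), 0)
  # compare each reading to the simulator truth by (pass, gradient_index)
  truth <- s$schedule[!s$schedule$is_calibration, ]
  el <- 16000 * 0.02
  contrast <- optical_config(n_channels = 1)$droplet_contrast
  m <- merge(mt$tracks, truth, by.x = c("pass", "gradient_index"),
             by.y = c("pass", "index"))
  expect_equal(nrow(m), 360)
  expect_equal(m$t, m$t_center, tolerance = 1e-2)
  expect_equal(m$absorbance, contrast + el * m$P, tolerance = 5e-3)
  # every track has one reading per pass, spanning the whole run
  n_reads <- table(mt$tracks$gradient_index)
  expect_true(all(n_reads == 6))
  tr20 <- mt$tracks[mt$tracks$gradient_index == 20, ]
  expect_equal(nrow(tr20), 6)
  expect_gt(max(tr20$t) - min(tr20$t), 1000)
})

test_that("pass reversal composed with matching is the identity on gradient index", {
  s <- sim_one_channel()
  seg <- segment_passes(detect_droplets(s$trace, 1), s$passes)
  mt <- match_tracks(seg)
  pull <- mt$tracks[mt$tracks$pass == 1, ]
  push <- mt$tracks[mt$tracks$pass == 2, ]
  pull <- pull[order(pull$t), ]
  push <- push[order(push$t), ]
  expect_equal(pull$gradient_index, 0:59)        # pull: generation order
  expect_equal(push$gradient_index, 59:0)        # push: reversed
  expect_equal(sort(push$gradient_index), pull$gradient_index)
})

test_that("a single droplet read on six passes forms one six-reading track", {
  fl <- fluidic_config(gradient_duration = 0.6, inject_rate = 10,
                       inject_volume = 0.1, substrate_stock = 1e-3,
                       enzyme_initial = 1e-9)
  passes <- pass_schedule(n_passes = 6, n_channels = 1, calib_pass = NA)
  dr <- generate_droplets(fl)
  expect_equal(nrow(dr), 1)
  tr <- render_trace(dr, kinetic_params(0, 1e-3),
                     optical_config(n_channels = 1), passes, fl, seed = 3)
  seg <- segment_passes(detect_droplets(tr, 1), passes)
  mt <- match_tracks(seg)
  expect_equal(mt$n_droplets, 1)
  expect_equal(nrow(mt$tracks), 6)
  expect_equal(unique(mt$tracks$gradient_index), 0)
})
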