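test_that("assigned concentrations reproduce the well oracle drop-by-drop", {
  fl <- fluidic_config(substrate_stock = 500e-6, enzyme_initial = 5e-9)
  ac <- assign_concentrations(0:59, fl)
  # first droplet: essentially substrate-free, enzyme at its initial value
  expect_lt(ac$S[1], 0.002 * fl$substrate_stock)
  expect_equal(ac$E[1], fl$enzyme_initial, tolerance = 1e-3)
  # last droplet agrees with the independent RK4 oracle at its aspiration time
  rk <- rk4_well(fl, ac$t_aspirate[60])
  expect_equal(ac$S[60] / rk$S_well, 1, tolerance = 1e-6)
  expect_equal(ac$E[60] / rk$E_well, 1, tolerance = 1e-6)
  # enzyme dilution bounded by mixing 5 uL into 40 uL
  expect_lt(ac$E[60] / ac$E[1], 1)
  expect_gt(ac$E[60] / ac$E[1], 40 / 45)
  expect_error(assign_concentrations(80, fl), "beyond")
})

test_that("assignment equals simulator truth under a shared fluidic config", {
  fl <- fluidic_config(substrate_stock = 0.1, enzyme_initial = 25e-9)
  dr <- generate_droplets(fl)
  ac <- assign_concentrations(dr$index, fl)
  expect_equal(ac$S, dr$S0, tolerance = 1e-12)
  expect_equal(ac$E, dr$E0, tolerance = 1e-12)
})

fake_cal <- function(slope = 320, lod = 4e-6, blank = 0) {
  structure(list(channel = 1, slope = slope, sigma_blank = lod * slope / 3.29,
                 LOD = lod, n_droplets = 15, blank_absorbance = blank),
            class = "calibration_result")
}

test_that("exactly linear readings give v0 = slope ratio with the linear method", {
  cal <- fake_cal()
  t <- c(60, 340, 620, 900, 1180, 1460)
  m <- 1.28e-4  # absorbance per s
  re <- estimate_v0(t, 0.12 + m * t, cal, t0 = 10)
  expect_equal(re$v0, m / 320, tolerance = 1e-12)
  expect_equal(re$method, "linear")
  expect_equal(re$r2, 1)
  expect_error(estimate_v0(t[1:2], (0.12 + m * t)[1:2], cal),
               class = "dropkin_rate_error")
})

test_that("noise-only tracks give v0 consistent with zero at calibrated coverage", {
  # with 6 reads the slope/se ratio is t-distributed with 4 df; the 95%
  # two-sided quantile is qt(.975, 4), not 2
  set.seed(42)
  t <- c(60, 340, 620, 900, 1180, 1460)
  cal <- fake_cal()
  hits <- vapply(1:200, function(i) {
    a <- 0.12 + rnorm(6, 0, 4e-4)
    re <- estimate_v0(t, a, cal, t0 = 10, method = "linear")
    abs(re$v0) <= qt(0.975, 4) * re$slope_se
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})

test_that("noiseless reads at S = KM give v0 within 2% of the true initial rate", {
  fl <- fluidic_config(substrate_stock = 0.4, enzyme_initial = 1e-6)
  k <- kinetic_params(0.4, 0.023)
  d <- list(S0 = 0.023, E0 = 1e-6)
  t0 <- 12
  t_reads <- c(60, 340, 620, 900, 1180, 1460)
  pc <- progress_curve(d, k, t_reads - t0)
  cal <- fake_cal()
  a <- 0.12 + cal$slope * pc$P
  re <- estimate_v0(t_reads, a, cal, t0 = t0, S_assigned = d$S0,
                    blank_absorbance = 0.12)
  v_true <- k$kcat * d$E0 * d$S0 / (k$KM + d$S0)
  expect_equal(re$v0 / v_true, 1, tolerance = 0.02)
})

test_that("heavily converting droplets switch to the progress fit and stay accurate", {
  # pNP-b-GlcA regime: reaction nearly complete between the first reads
  k <- kinetic_params(23.1, 13.7e-6)
  d <- list(S0 = 2e-5, E0 = 5e-9)
  t0 <- 10
  t_reads <- c(60, 340, 620, 900, 1180, 1460)
  pc <- progress_curve(d, k, t_reads - t0)
  cal <- fake_cal()
  a <- 0.12 + cal$slope * pc$P
  re <- estimate_v0(t_reads, a, cal, t0 = t0, S_assigned = d$S0,
                    blank_absorbance = 0.12)
  v_true <- k$kcat * d$E0 * d$S0 / (k$KM + d$S0)
  expect_equal(re$method, "progress")
  expect_true("high_conversion" %in% re$flags)
  expect_gt(re$conversion, 0.9)
  expect_equal(re$v0 / v_true, 1, tolerance = 0.02)
})

test_that("rates below the LOD-derived resolution are reported with a flag", {
  cal <- fake_cal(lod = 4e-6)
  t <- c(60, 340, 620, 900, 1180, 1460)
  m <- 1e-10 * cal$slope   # 0.1 nM/s, far below LOD/span
  re <- estimate_v0(t, 0.12 + m * t, cal, t0 = 10, method = "linear")
  expect_true("below_resolution" %in% re$flags)
  expect_equal(re$v0, 1e-10, tolerance = 1e-6)  # still reported
})

test_that("compile_dataset sorts by S, applies gates, and survives full flagging", {
  ann <- data.frame(
    gradient_index = 0:19,
    S = seq(1e-3, 45e-3, length.out = 20)[sample(20)],
    E = 1e-6, v0 = 1e-7, v0_se = 1e-9, r2 = 0.99, n_points = 6,
    method = "linear", conversion = 0.01, flags = ""
  )
  ds <- compile_dataset(ann, channel = 1)
  expect_true(all(diff(ds$S) > 0))
  expect_true(attr(ds, "fit_worthy"))
  # all droplets flagged as outliers: unfit, no crash
  ds2 <- compile_dataset(ann, channel = 1, outliers = 0:19)
  expect_false(attr(ds2, "fit_worthy"))
  expect_match(attr(ds2, "unfit_reason"), "usable")
  expect_false(is.null(fit_mm(ds2)))
  expect_false(fit_mm(ds2)$converged)
  # narrow substrate span: unfit
  ann3 <- ann
  ann3$S <- seq(10e-3, 12e-3, length.out = 20)
  ds3 <- compile_dataset(ann3, channel = 1)
  expect_false(attr(ds3, "fit_worthy"))
  expect_match(attr(ds3, "unfit_reason"), "span")
})
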