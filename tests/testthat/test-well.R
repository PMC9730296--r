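test_that("well volume follows the flow balance and ends at 43 uL", {
  fl <- fluidic_config(substrate_stock = 500e-6, enzyme_initial = 5e-9)
  ws <- simulate_well(fl)
  expect_equal(ws$volume[1], 40)
  expect_equal(ws$volume[nrow(ws)], 43, tolerance = 1e-10)
  expect_true(all(abs(ws$volume - (40 + (10 - 4) / 60 * ws$t)) < 1e-9))
  expect_true(all(ws$S_well >= 0 & ws$S_well <= fl$substrate_stock))
  expect_true(all(ws$E_well > 0 & ws$E_well <= fl$enzyme_initial + 1e-15))
})

test_that("with no substrate injection S stays zero and E is unchanged by withdrawal", {
  # withdrawal removes volume and enzyme mass proportionally, so the enzyme
  # *concentration* is constant (d(VE)/dt = -Q_draw * E implies dE/dt = 0)
  fl <- fluidic_config(inject_rate = 0, inject_volume = 0,
                       substrate_stock = 1e-3, enzyme_initial = 1e-6)
  ws <- simulate_well(fl)
  expect_true(all(ws$S_well == 0))
  expect_equal(ws$E_well, rep(1e-6, nrow(ws)), tolerance = 1e-9)
  expect_equal(ws$volume[nrow(ws)], 40 - 4 / 60 * 30, tolerance = 1e-9)
})

test_that("well solution matches the closed form and an RK4 oracle to 1e-6", {
  fl <- fluidic_config(substrate_stock = 500e-6, enzyme_initial = 5e-9)
  ws <- simulate_well(fl)
  cf <- well_closed_form(fl, ws$t)
  expect_equal(ws$S_well[-1], cf$S_well[-1], tolerance = 1e-8)
  expect_equal(ws$E_well, cf$E_well, tolerance = 1e-8)
  rk <- rk4_well(fl, 30)
  i_end <- nrow(ws)
  expect_equal(ws$S_well[i_end] / rk$S_well, 1, tolerance = 1e-6)
  expect_equal(ws$E_well[i_end] / rk$E_well, 1, tolerance = 1e-6)
})

test_that("substrate mass is conserved: injected = in well + withdrawn", {
  for (fl in list(fluidic_config(substrate_stock = 500e-6, enzyme_initial = 5e-9),
                  fluidic_config(inject_rate = 20, inject_volume = 10,
                                 draw_rate = 8, substrate_stock = 0.1,
                                 enzyme_initial = 1e-6))) {
    ws <- simulate_well(fl)
    injected <- fl$inject_rate / 60 * ws$t * fl$substrate_stock
    in_well <- ws$S_well * ws$volume
    ledger <- in_well + ws$withdrawn_S
    scale <- max(injected)
    expect_true(all(abs(ledger - injected) <= 1e-6 * scale))
  }
})

test_that("a draw that exhausts the well is an infeasible-config fault", {
  fl <- fluidic_config(well_volume_initial = 1, inject_rate = 0,
                       inject_volume = 0, draw_rate = 4,
                       substrate_stock = 1e-3, enzyme_initial = 1e-9)
  expect_error(simulate_well(fl), "exhausts")
  expect_error(simulate_well(fluidic_config(), dt = 0.1), "dt")
})

test_that("well_at interpolates within range and faults outside", {
  fl <- fluidic_config(substrate_stock = 500e-6, enzyme_initial = 5e-9)
  ws <- simulate_well(fl)
  w <- well_at(ws, c(0.2475, 29.45))
  cf <- well_closed_form(fl, c(0.2475, 29.45))
  expect_equal(w$S_well, cf$S_well, tolerance = 1e-6)
  expect_error(well_at(ws, 31), "outside")
})
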