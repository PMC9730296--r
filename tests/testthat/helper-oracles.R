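# Independent oracles, kept deliberately separate from the package's own
# numerical paths (the package integrates ODEs with deSolve and solves the
# integrated rate law via Lambert W; these use closed forms, a hand-rolled
# RK4, and stats::uniroot).

# Closed-form solution of the stirred-well mass balance with constant rates.
# Rates in uL/min as in fluidic_config; returns concentrations in M.
well_closed_form <- function(fluidics, t) {
  qi <- fluidics$inject_rate / 60
  qd <- fluidics$draw_rate / 60
  v0 <- fluidics$well_volume_initial
  cs <- fluidics$substrate_stock
  e0 <- fluidics$enzyme_initial
  r <- qi - qd
  V <- v0 + r * t
  if (abs(r) > 1e-12) {
    frac <- (v0 / V)^(qi / r)
  } else {
    frac <- exp(-qi * t / v0)
  }
  data.frame(t = t, volume = V, S_well = cs * (1 - frac), E_well = e0 * frac)
}

# Fixed-step RK4 integration of the same mass balance (states V, V*S, V*E).
rk4_well <- function(fluidics, t_end, dt = 1e-4) {
  qi <- fluidics$inject_rate / 60
  qd <- fluidics$draw_rate / 60
  cs <- fluidics$substrate_stock
  deriv <- function(y) {
    c(qi - qd,
      qi * cs - qd * y[2] / y[1],
      -qd * y[3] / y[1])
  }
  y <- c(fluidics$well_volume_initial, 0,
         fluidics$enzyme_initial * fluidics$well_volume_initial)
  n <- round(t_end / dt)
  for (i in seq_len(n)) {
    k1 <- deriv(y)
    k2 <- deriv(y + dt / 2 * k1)
    k3 <- deriv(y + dt / 2 * k2)
    k4 <- deriv(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  list(volume = y[1], S_well = y[2] / y[1], E_well = y[3] / y[1])
}

# Root-solve of the implicit integrated Michaelis-Menten form
# KM log(S0/S) + (S0 - S) = kcat E0 t.
mm_implicit_S <- function(S0, E0, kcat, KM, t) {
  vapply(t, function(ti) {
    if (ti <= 0 || kcat == 0 || E0 == 0 || S0 == 0) return(S0)
    f <- function(s) KM * log(S0 / s) + (S0 - s) - kcat * E0 * ti
    stats::uniroot(f, c(S0 * 1e-18, S0), tol = S0 * 1e-14)$root
  }, numeric(1))
}

# Synthetic one-channel square-wave trace with known trough positions.
make_square_trace <- function(n_troughs, absorbance, width = 90, gap = 9,
                              baseline = 1000, pad = 4000, rate = 200,
                              noise_sd = 0, gain = 1, seed = 1) {
  set.seed(seed)
  a <- rep(absorbance, length.out = n_troughs)
  n <- 2 * pad + n_troughs * (width + gap)
  x <- rep(baseline * gain, n)
  starts <- integer(n_troughs)
  pos <- pad + 1
  for (i in seq_len(n_troughs)) {
    starts[i] <- pos
    x[pos:(pos + width - 1)] <- baseline * gain * 10^(-a[i])
    pos <- pos + width + gap
  }
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd * baseline)
  trace <- structure(list(time = (seq_len(n) - 1) / rate,
                          intensity = matrix(x, nrow = 1),
                          sample_rate = rate),
                     class = "raw_trace")
  list(trace = trace, starts = starts, width = width, absorbance = a)
}

# Compact run configuration for pipeline tests: same droplet geometry as the
# full instrument, but 3 passes over 7 minutes and few channels.
small_run_config <- function(substrates, n_channels = 2, seed = 1,
                             optics = list(), analysis = list()) {
  optics$n_channels <- n_channels
  run_config(
    optics = optics,
    passes = list(n_passes = 3, n_channels = n_channels, total_duration = 420,
                  first_arrival = 45, channel_lag = 5, pass_interval = 120,
                  calib_pass = 3),
    substrates = substrates,
    analysis = analysis,
    seed = seed
  )
}

xyl_substrate <- function(channels = 1:2) {
  list(name = "pNP-b-Xyl", substrate_stock = 0.4, enzyme_initial = 1e-6,
       channels = channels, kcat = 0.4, KM = 0.023)
}
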