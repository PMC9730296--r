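#' Generate the droplet train from the simulated well gradient
#'
#' Droplets are aspirated at a fixed period of
#' `(droplet_volume + spacer_volume) / draw_rate`; droplet `i` (0-based,
#' generation order) carries the well composition at the midpoint of its
#' aspiration window, `t_aspirate = (i + 0.5) * period`. The count is
#' `floor(gradient_duration / period)` (60 at the default geometry).
#'
#' @param fluidics A [fluidic_config()].
#' @param well A `well_states` data.frame covering `[0, gradient_duration]`,
#'   from [simulate_well()]; computed on the fly if omitted.
#' @return A data.frame of class `droplet_events` with columns `index`
#'   (0-based), `t_aspirate` (s), `S0` (M), `E0` (M), `volume` (nL),
#'   `is_calibration` (logical).
#' @export
generate_droplets <- function(fluidics, well = NULL) {
  stopifnot(inherits(fluidics, "fluidic_config"))
  period <- droplet_period(fluidics)
  n <- floor(fluidics$gradient_duration / period)
  if (n < 1) {
    if (fluidics$gradient_duration > 0)
      stop("generate_droplets: droplet period exceeds gradient duration ",
           "(empty gradient)", call. = FALSE)
    n <- 0
  }
  if (n == 0) {
    out <- data.frame(index = integer(), t_aspirate = numeric(),
                      S0 = numeric(), E0 = numeric(), volume = numeric(),
                      is_calibration = logical())
    class(out) <- c("droplet_events", "data.frame")
    return(out)
  }
  if (is.null(well)) well <- simulate_well(fluidics)
  if (max(well$t) < fluidics$gradient_duration - 1e-9)
    stop("generate_droplets: well states do not cover the gradient window",
         call. = FALSE)
  t_asp <- (seq_len(n) - 0.5) * period
  w <- well_at(well, t_asp)
  out <- data.frame(
    index = seq_len(n) - 1L,
    t_aspirate = t_asp,
    S0 = w$S_well,
    E0 = w$E_well,
    volume = rep(fluidics$droplet_volume, n),
    is_calibration = FALSE
  )
  class(out) <- c("droplet_events", "data.frame")
  out
}

#' Calibration droplet train
#'
#' A short train of droplets generated from a product solution of known
#' concentration (1 mM pNP by default), used to measure the per-channel
#' absorbance-to-concentration slope. They contain no enzyme or substrate;
#' their rendered absorbance is constant in time.
#'
#' @param fluidics A [fluidic_config()].
#' @param n Number of calibration droplets.
#' @param conc Product concentration in M.
#' @return A `droplet_events` data.frame with `is_calibration = TRUE` and the
#'   fixed product concentration stored in the `P_fixed` column.
#' @export
calibration_droplets <- function(fluidics, n = 15, conc = 1e-3) {
  period <- droplet_period(fluidics)
  out <- data.frame(
    index = seq_len(n) - 1L,
    t_aspirate = NA_real_,
    S0 = 0,
    E0 = 0,
    volume = rep(fluidics$droplet_volume, n),
    is_calibration = TRUE,
    P_fixed = conc
  )
  attr(out, "period") <- period
  class(out) <- c("droplet_events", "data.frame")
  out
}

#' In-droplet reaction progress
#'
#' Integrates the Michaelis-Menten rate law inside one droplet,
#' \eqn{dS/dt = -k_{cat} E_0 S / (K_M + S)}, from the droplet's initial
#' substrate concentration, and returns product \eqn{P = S_0 - S}. Enzyme
#' concentration is constant within a droplet (no inactivation), so P is
#' monotone nondecreasing and bounded by S0. Time is measured from droplet
#' formation (the contents start reacting at mixing).
#'
#' @param droplet A single row of a `droplet_events` data.frame (or any list
#'   with `S0` and `E0` in M).
#' @param k A [kinetic_params()].
#' @param t_grid Nondecreasing times in s, >= 0.
#' @return A data.frame with columns `t`, `S`, `P` (all M except `t`).
#' @export
progress_curve <- function(droplet, k, t_grid) {
  stopifnot(inherits(k, "kinetic_params"))
  if (any(t_grid < 0) || is.unsorted(t_grid))
    stop("progress_curve: t_grid must be nondecreasing and >= 0", call. = FALSE)
  S0 <- droplet$S0
  E0 <- droplet$E0
  if (S0 < 0 || E0 < 0)
    stop("progress_curve: negative initial concentration", call. = FALSE)
  if (k$kcat == 0 || E0 == 0 || S0 == 0) {
    return(data.frame(t = t_grid, S = rep(S0, length(t_grid)),
                      P = rep(0, length(t_grid))))
  }
  times <- t_grid
  prepend <- times[1] > 0
  if (prepend) times <- c(0, times)
  rhs <- function(t, y, parms) {
    s <- max(y[1], 0)
    list(-k$kcat * E0 * s / (k$KM + s))
  }
  sol <- deSolve::ode(c(S = S0), times, rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-11, atol = S0 * 1e-13)
  S <- pmin(pmax(sol[, "S"], 0), S0)
  if (prepend) S <- S[-1]
  data.frame(t = t_grid, S = S, P = S0 - S)
}
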