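#' Fluidic configuration of the droplet generator
#'
#' Describes the stirred-well gradient formation and droplet generation
#' geometry: a syringe pump withdraws liquid from a microtiter well at
#' `draw_rate` while a second pump injects substrate stock at `inject_rate`,
#' so the well behaves as a continuously stirred tank with changing volume.
#' The withdrawn stream breaks into monodisperse aqueous plugs of
#' `droplet_volume` separated by `spacer_volume` of carrier oil.
#'
#' @param well_volume_initial Initial well volume in uL (enzyme solution).
#' @param inject_rate Substrate injection rate in uL/min.
#' @param inject_volume Total injected substrate volume in uL. Must equal
#'   `inject_rate * gradient_duration / 60` (checked to 1e-6 relative).
#' @param draw_rate Withdrawal (droplet generation) rate in uL/min.
#' @param gradient_duration Duration of the injection/generation window in s.
#' @param droplet_volume Aqueous plug volume in nL.
#' @param spacer_volume Carrier-oil spacer volume between plugs in nL.
#' @param substrate_stock Substrate stock concentration in M (in the injector).
#' @param enzyme_initial Enzyme concentration in M initially in the well.
#'
#' @return An object of class `fluidic_config` (a validated list).
#' @examples
#' fl <- fluidic_config(substrate_stock = 400e-3, enzyme_initial = 1e-6)
#' droplet_period(fl)  # ~0.495 s per droplet-plus-spacer
#' @export
fluidic_config <- function(well_volume_initial = 40,
                           inject_rate = 10,
                           inject_volume = 5,
                           draw_rate = 4,
                           gradient_duration = 30,
                           droplet_volume = 30,
                           spacer_volume = 3,
                           substrate_stock = 500e-6,
                           enzyme_initial = 5e-9) {
  cfg <- list(
    well_volume_initial = well_volume_initial,
    inject_rate = inject_rate,
    inject_volume = inject_volume,
    draw_rate = draw_rate,
    gradient_duration = gradient_duration,
    droplet_volume = droplet_volume,
    spacer_volume = spacer_volume,
    substrate_stock = substrate_stock,
    enzyme_initial = enzyme_initial
  )
  class(cfg) <- "fluidic_config"
  validate_fluidic_config(cfg)
  cfg
}

validate_fluidic_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("well_volume_initial", "draw_rate", "droplet_volume",
              "substrate_stock", "enzyme_initial")) {
    if (!num1(cfg[[f]]) || cfg[[f]] <= 0)
      stop("fluidic_config: '", f, "' must be a positive number", call. = FALSE)
  }
  for (f in c("inject_rate", "inject_volume", "gradient_duration", "spacer_volume")) {
    if (!num1(cfg[[f]]) || cfg[[f]] < 0)
      stop("fluidic_config: '", f, "' must be a non-negative number", call. = FALSE)
  }
  # injection consistency: volume = rate x duration (rate in uL/min, duration s)
  if (cfg$inject_rate > 0 && cfg$inject_volume > 0 && cfg$gradient_duration > 0) {
    expected <- cfg$inject_rate * cfg$gradient_duration / 60
    if (abs(cfg$inject_volume - expected) > 1e-6 * max(1, expected))
      stop("fluidic_config: inject_volume (", cfg$inject_volume,
           " uL) inconsistent with inject_rate x gradient_duration (",
           expected, " uL)", call. = FALSE)
  }
  if (cfg$gradient_duration > 0 &&
      droplet_period(cfg) > cfg$gradient_duration)
    stop("fluidic_config: droplet-plus-spacer period exceeds gradient_duration; ",
         "no droplet fits in the gradient", call. = FALSE)
  invisible(cfg)
}

#' Droplet generation period and transit time
#'
#' `droplet_period()` is the time to aspirate one droplet plus its oil spacer;
#' `droplet_transit()` is the time an aqueous plug takes to cross a fixed
#' point at the withdrawal rate (its optical trough duration).
#'
#' @param fluidics A [fluidic_config()].
#' @return Time in seconds.
#' @export
droplet_period <- function(fluidics) {
  (fluidics$droplet_volume + fluidics$spacer_volume) * 1e-3 /
    (fluidics$draw_rate / 60)
}

#' @rdname droplet_period
#' @export
droplet_transit <- function(fluidics) {
  fluidics$droplet_volume * 1e-3 / (fluidics$draw_rate / 60)
}

#' Michaelis-Menten kinetic parameters
#'
#' @param kcat Turnover number in 1/s (>= 0).
#' @param KM Michaelis constant in M (> 0).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(kcat, KM) {
  if (!is.numeric(kcat) || length(kcat) != 1L || kcat < 0 || !is.finite(kcat))
    stop("kinetic_params: kcat must be a single number >= 0", call. = FALSE)
  if (!is.numeric(KM) || length(KM) != 1L || KM <= 0 || !is.finite(KM))
    stop("kinetic_params: KM must be a single number > 0", call. = FALSE)
  structure(list(kcat = kcat, KM = KM), class = "kinetic_params")
}

#' Optical configuration of the line-camera detector
#'
#' The line camera records transmitted light at `sample_rate` for
#' `n_channels` detection points. Illumination is not perfectly uniform
#' across the line: `channel_gain` holds per-channel relative illumination
#' factors whose spread must stay within the ~30% deviation observed between
#' detection points. Aqueous plugs transmit slightly less light than the
#' carrier oil even with refractive-index matching; `droplet_contrast` is
#' that residual plug/oil contrast expressed as an absorbance offset, and is
#' what makes product-free droplets detectable at all.
#'
#' @param n_channels Number of detection points.
#' @param sample_rate Acquisition rate in Hz.
#' @param path_length Optical path length in cm (tubing inner diameter).
#' @param epsilon Molar absorptivity of the product at the LED wavelength,
#'   1/(M cm). The analysis never uses it directly: calibration cancels it.
#' @param channel_gain Per-channel relative illumination factors; default is
#'   a linear ramp from 1 down to 0.7.
#' @param noise_sd Additive Gaussian intensity noise, relative to
#'   `baseline_intensity` (per sample).
#' @param baseline_intensity Droplet-free transmitted intensity, arbitrary
#'   units, for a channel with gain 1.
#' @param droplet_contrast Absorbance offset of any aqueous plug relative to
#'   carrier oil (unitless A405).
#' @param edge_artifact Optional intensity spike amplitude at plug edges
#'   (relative to baseline), default 0: the carrier oil is refractive-index
#'   matched. Nonzero values exist for segmentation stress tests.
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(n_channels = 12,
                           sample_rate = 200,
                           path_length = 0.02,
                           epsilon = 16000,
                           channel_gain = NULL,
                           noise_sd = 0.001,
                           baseline_intensity = 40000,
                           droplet_contrast = 0.12,
                           edge_artifact = 0) {
  if (is.null(channel_gain))
    channel_gain <- seq(1, 0.7, length.out = n_channels)
  cfg <- list(
    n_channels = as.integer(n_channels),
    sample_rate = sample_rate,
    path_length = path_length,
    epsilon = epsilon,
    channel_gain = channel_gain,
    noise_sd = noise_sd,
    baseline_intensity = baseline_intensity,
    droplet_contrast = droplet_contrast,
    edge_artifact = edge_artifact
  )
  class(cfg) <- "optical_config"
  validate_optical_config(cfg)
  cfg
}

validate_optical_config <- function(cfg) {
  if (cfg$n_channels < 1) stop("optical_config: n_channels must be >= 1", call. = FALSE)
  if (cfg$sample_rate <= 0) stop("optical_config: sample_rate must be > 0", call. = FALSE)
  if (length(cfg$channel_gain) != cfg$n_channels)
    stop("optical_config: channel_gain must have one entry per channel", call. = FALSE)
  if (any(cfg$channel_gain <= 0))
    stop("optical_config: channel gains must be positive", call. = FALSE)
  ratio <- max(cfg$channel_gain) / min(cfg$channel_gain)
  if (ratio > 1 / (1 - 0.30) + 1e-9)
    stop("optical_config: channel_gain spread exceeds the ~30% illumination ",
         "deviation bound (max/min = ", signif(ratio, 4), ")", call. = FALSE)
  if (cfg$noise_sd < 0 || cfg$path_length <= 0 || cfg$epsilon <= 0 ||
      cfg$baseline_intensity <= 0 || cfg$droplet_contrast < 0)
    stop("optical_config: invalid optical parameter", call. = FALSE)
  invisible(cfg)
}

#' Flow-reversal pass schedule
#'
#' One "pass" is a transit of the droplet train through the detection
#' points; after each pass the syringe pump reverses between pulling and
#' pushing, so the train is re-read in reversed order. The schedule stores
#' the arrival time of the train at every (pass, channel) pair. The default
#' builder spaces passes uniformly: pass p starts at
#' `first_arrival + (p-1) * pass_interval`, and within a pass the train
#' reaches successive detection points `channel_lag` seconds apart, in
#' channel order on pull passes and reversed channel order on push passes.
#'
#' @param n_passes Number of passes (directions alternate, starting "pull").
#' @param n_channels Number of detection points.
#' @param total_duration Total acquisition time in s.
#' @param first_arrival Arrival of the train at the first detection point on
#'   pass 1, in s after the start of gradient generation.
#' @param channel_lag Travel time between adjacent detection points, s.
#' @param pass_interval Time between the starts of consecutive passes, s.
#' @param calib_pass Pass index on which the calibration train is read
#'   (generated late, so by default the final push pass); `NA` for none.
#' @param arrival Optional explicit arrival matrix (n_passes x n_channels),
#'   overriding the uniform construction.
#' @return An object of class `pass_schedule` with elements `n_passes`,
#'   `n_channels`, `directions` ("pull"/"push"), `arrival`, `total_duration`,
#'   `calib_pass`.
#' @export
pass_schedule <- function(n_passes = 6,
                          n_channels = 12,
                          total_duration = 1800,
                          first_arrival = 60,
                          channel_lag = 10,
                          pass_interval = 280,
                          calib_pass = n_passes,
                          arrival = NULL) {
  n_passes <- as.integer(n_passes)
  n_channels <- as.integer(n_channels)
  directions <- rep(c("pull", "push"), length.out = n_passes)
  if (is.null(arrival)) {
    arrival <- matrix(NA_real_, n_passes, n_channels)
    for (p in seq_len(n_passes)) {
      base <- first_arrival + (p - 1) * pass_interval
      lag <- if (directions[p] == "pull") (seq_len(n_channels) - 1)
             else (n_channels - seq_len(n_channels))
      arrival[p, ] <- base + lag * channel_lag
    }
  }
  sched <- list(
    n_passes = n_passes,
    n_channels = n_channels,
    directions = directions,
    arrival = arrival,
    total_duration = total_duration,
    first_arrival = first_arrival,
    channel_lag = channel_lag,
    pass_interval = pass_interval,
    calib_pass = if (is.null(calib_pass) || is.na(calib_pass)) NA_integer_
                 else as.integer(calib_pass)
  )
  class(sched) <- "pass_schedule"
  validate_pass_schedule(sched)
  sched
}

validate_pass_schedule <- function(sched) {
  if (sched$n_passes < 1) stop("pass_schedule: n_passes must be >= 1", call. = FALSE)
  if (!identical(dim(sched$arrival), c(sched$n_passes, sched$n_channels)))
    stop("pass_schedule: arrival matrix must be n_passes x n_channels", call. = FALSE)
  if (any(sched$arrival < 0) || any(sched$arrival >= sched$total_duration))
    stop("pass_schedule: all arrival times must lie in [0, total_duration)",
         call. = FALSE)
  # arrival order over channels must reverse with direction
  for (p in seq_len(sched$n_passes)) {
    ord <- order(sched$arrival[p, ])
    want <- if (sched$directions[p] == "pull") seq_len(sched$n_channels)
            else rev(seq_len(sched$n_channels))
    if (sched$n_channels > 1 && !identical(ord, want))
      stop("pass_schedule: channel arrival order on pass ", p,
           " does not match its direction", call. = FALSE)
  }
  if (!is.na(sched$calib_pass) &&
      (sched$calib_pass < 1 || sched$calib_pass > sched$n_passes))
    stop("pass_schedule: calib_pass out of range", call. = FALSE)
  invisible(sched)
}

#' Analysis thresholds
#'
#' Tunable parameters of the trace-processing and quantitation pipeline.
#'
#' @param window_samples Centered moving-average window for boundary
#'   detection, samples. Must be at least 3 and shorter than the inter-droplet
#'   oil gap (spacer_volume/draw_rate, 9 samples at the default geometry).
#' @param threshold_frac Detection threshold as a fraction of the local
#'   dynamic range (baseline minus deepest smoothed intensity).
#' @param baseline_window Rolling-median window (samples) for the droplet-free
#'   baseline estimate.
#' @param min_trough_samples Minimum trough duration, samples.
#' @param gap_factor Pass segmentation: a time gap larger than `gap_factor`
#'   times the median inter-droplet gap starts a new cluster.
#' @param outlier_rms Droplets deviating by more than this multiple of the
#'   gradient-profile RMS are flagged as outliers.
#' @param conversion_threshold Fraction of assigned substrate converted over
#'   the read window above which the initial-rate estimate switches from the
#'   linear fit to the integrated progress-curve fit.
#' @param lod_z Multiplier for the limit of detection, LOD = lod_z *
#'   sigma_blank / slope. 3.29 corresponds to alpha = beta = 0.05.
#' @param calib_scatter_max Maximum tolerated relative scatter of the
#'   calibration absorbances before the channel is declared unstable.
#' @param auc_mode If TRUE, droplet absorbance is the trough-integrated value
#'   (area under the curve between refined boundaries, divided by width);
#'   default uses the mean over the central 50% of the trough.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(window_samples = 7,
                            threshold_frac = 0.2,
                            baseline_window = 20001,
                            min_trough_samples = 5,
                            gap_factor = 5,
                            outlier_rms = 4,
                            conversion_threshold = 0.1,
                            lod_z = 3.29,
                            calib_scatter_max = 0.2,
                            auc_mode = FALSE) {
  if (window_samples < 3) stop("analysis_config: window_samples must be >= 3",
                               call. = FALSE)
  structure(list(window_samples = as.integer(window_samples),
                 threshold_frac = threshold_frac,
                 baseline_window = as.integer(baseline_window),
                 min_trough_samples = as.integer(min_trough_samples),
                 gap_factor = gap_factor,
                 outlier_rms = outlier_rms,
                 conversion_threshold = conversion_threshold,
                 lod_z = lod_z,
                 calib_scatter_max = calib_scatter_max,
                 auc_mode = auc_mode),
            class = "analysis_config")
}

#' @export
print.fluidic_config <- function(x, ...) {
  cat("<fluidic_config>\n")
  cat(sprintf("  well %g uL + %g uL @ %g uL/min in, %g uL/min out over %g s\n",
              x$well_volume_initial, x$inject_volume, x$inject_rate,
              x$draw_rate, x$gradient_duration))
  cat(sprintf("  droplets %g nL + %g nL spacer (period %.3f s)\n",
              x$droplet_volume, x$spacer_volume, droplet_period(x)))
  cat(sprintf("  substrate stock %g M, enzyme %g M\n",
              x$substrate_stock, x$enzyme_initial))
  invisible(x)
}

#' @export
print.pass_schedule <- function(x, ...) {
  cat(sprintf("<pass_schedule> %d passes x %d channels over %g s (%s...)\n",
              x$n_passes, x$n_channels, x$total_duration,
              paste(utils::head(x$directions, 4), collapse = "/")))
  invisible(x)
}
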