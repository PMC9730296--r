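#' Simulate a full multi-substrate run
#'
#' Runs the well model and droplet generation for every substrate entry of
#' the configuration, renders all channels into one multi-channel trace
#' (each substrate's droplet train appears only on its own detection
#' points), and returns the ground truth alongside.
#'
#' @param config A [run_config()]; every substrate entry must carry `kcat`
#'   and `KM` (the simulation truth).
#' @param seed Seed for the noise realization (defaults to `config$seed`).
#' @return A list of class `sim_run`: `trace` (a `raw_trace`), `truth` (per
#'   substrate: `droplets`, `reads`, `kinetics`, `channels`), `config`.
#' @export
simulate_run <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "run_config"))
  scheds <- list()
  truth <- list()
  for (i in seq_along(config$substrates)) {
    s <- config$substrates[[i]]
    if (is.null(s$kcat) || is.null(s$KM))
      stop("simulate_run: substrate '", s$name,
           "' has no kinetic truth (kcat, KM)", call. = FALSE)
    k <- kinetic_params(s$kcat, s$KM)
    fl <- config$substrate_fluidics[[i]]
    well <- simulate_well(fl)
    dr <- generate_droplets(fl, well)
    cal <- calibration_droplets(fl, n = config$calibration$n_droplets,
                                conc = config$calibration$conc)
    sc <- build_read_schedule(dr, k, config$passes, fl, calib = cal,
                              calib_gap = config$calibration$gap,
                              channels = s$channels)
    scheds[[i]] <- sc
    truth[[s$name]] <- list(droplets = as.data.frame(dr), reads = sc,
                            kinetics = list(kcat = s$kcat, KM = s$KM),
                            channels = s$channels)
  }
  sched <- do.call(rbind, scheds)
  # all generators share the droplet geometry, so any substrate's fluidics
  # sets the transit time
  trace <- render_from_schedule(sched, config$optics, config$passes,
                                config$substrate_fluidics[[1]], seed)
  structure(list(trace = trace, truth = truth, config = config),
            class = "sim_run")
}

#' Analyze one detection point
#'
#' The per-channel pipeline: boundary detection, pass segmentation,
#' cross-pass track matching, blank estimation from the earliest pass's
#' gradient-profile offset, calibration against the known-product train,
#' fluidics-based concentration assignment, per-droplet initial rates, and
#' the Michaelis-Menten fit.
#'
#' @param trace A `raw_trace`.
#' @param channel Channel to analyze.
#' @param fluidics The [fluidic_config()] of the generator feeding this
#'   channel.
#' @param passes The [pass_schedule()].
#' @param cfg An [analysis_config()].
#' @param calib_conc Calibration product concentration, M.
#' @param well Optional precomputed [simulate_well()] solution.
#' @param anchor_times Optional manual anchor times (see [match_tracks()]).
#' @return A list of class `channel_analysis`: `channel`, `segments`,
#'   `tracks`, `calibration` (a `calibration_result`), `blank_absorbance`,
#'   `outliers`, `dataset` (a `kinetic_dataset`), `fit` (an `mm_fit`),
#'   `log` (character records of exclusions and warnings).
#' @export
analyze_channel <- function(trace, channel, fluidics, passes,
                            cfg = analysis_config(), calib_conc = 1e-3,
                            well = NULL, anchor_times = NULL) {
  log <- character(0)
  det <- detect_droplets(trace, channel, cfg)
  if (!nrow(det))
    stop_dropkin("channel", sprintf("channel %d: no droplets detected", channel))
  seg <- segment_passes(det, passes, cfg)
  log <- c(log, seg$warnings)
  mt <- match_tracks(seg, anchor_times = anchor_times)
  if (nrow(mt$dropped))
    log <- c(log, sprintf("channel %d: %d detection(s) dropped (off the droplet grid)",
                          channel, nrow(mt$dropped)))
  tracks <- mt$tracks

  # blank (product-free plug) absorbance from the earliest pass: the well
  # holds no substrate at t = 0 and droplet i samples it at (i + 0.5) periods,
  # so the product-free point sits at index -0.5; extrapolate the gradient
  # profile there rather than taking the first droplet (which already carries
  # product when the reaction is fast).
  first_pass <- min(tracks$pass)
  tp <- tracks[tracks$pass == first_pass, , drop = FALSE]
  blank <- min(tp$absorbance)
  gf <- tryCatch(fit_gradient_profile(tp$gradient_index, tp$absorbance),
                 error = function(e) NULL)
  if (!is.null(gf) && isTRUE(gf$available) && is.finite(gf$offset) &&
      !isTRUE(gf$degenerate)) {
    ext <- gf$offset - gf$amplitude * (exp(gf$rate_constant / 2) - 1)
    if (is.finite(ext)) blank <- min(blank, max(ext, 0))
  }
  blank <- max(blank, 0)

  if (nrow(mt$calibration) < 3)
    stop_dropkin("calibration",
                 sprintf("channel %d: no calibration train found", channel))
  cal <- calibrate_channel(mt$calibration$absorbance, calib_conc,
                           sigma_blank = attr(det, "sigma_blank"),
                           blank_absorbance = blank, channel = channel,
                           cfg = cfg)
  outliers <- flag_profile_outliers(tracks, cfg)
  if (length(outliers))
    log <- c(log, sprintf("channel %d: droplet(s) %s flagged off the gradient profile",
                          channel, paste(outliers, collapse = ",")))

  conc <- assign_concentrations(0:(mt$n_droplets - 1L), fluidics, well = well)
  rows <- vector("list", mt$n_droplets)
  for (gi in 0:(mt$n_droplets - 1L)) {
    tr <- tracks[tracks$gradient_index == gi, , drop = FALSE]
    ci <- which(conc$gradient_index == gi)
    if (nrow(tr) < 3) {
      log <- c(log, sprintf(
        "channel %d: droplet %d excluded (%d reading(s), need 3)",
        channel, gi, nrow(tr)))
      next
    }
    re <- tryCatch(
      estimate_v0(tr$t, tr$absorbance, cal, t0 = conc$t_aspirate[ci],
                  S_assigned = conc$S[ci], blank_absorbance = blank,
                  cfg = cfg),
      error = function(e) NULL)
    if (is.null(re)) {
      log <- c(log, sprintf("channel %d: droplet %d rate estimation failed",
                            channel, gi))
      next
    }
    rows[[gi + 1L]] <- data.frame(
      gradient_index = gi, S = conc$S[ci], E = conc$E[ci],
      v0 = re$v0, v0_se = re$slope_se, r2 = re$r2, n_points = re$n_points,
      method = re$method, conversion = re$conversion,
      flags = paste(re$flags, collapse = ";")
    )
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    stop_dropkin("channel", sprintf("channel %d: no rate estimates", channel))
  annotated <- do.call(rbind, rows)
  dataset <- compile_dataset(annotated, channel = channel, outliers = outliers)
  if (!attr(dataset, "fit_worthy"))
    log <- c(log, sprintf("channel %d: dataset unfit for fitting (%s)",
                          channel, attr(dataset, "unfit_reason")))
  fit <- fit_mm(dataset)
  structure(list(channel = channel, segments = seg$segments, tracks = tracks,
                 calibration = cal, blank_absorbance = blank,
                 outliers = outliers, dataset = dataset, fit = fit,
                 log = log),
            class = "channel_analysis")
}

#' Analyze a full multi-channel trace
#'
#' Runs [analyze_channel()] on every detection point declared in the
#' configuration's substrate layout and aggregates the converged fits per
#' substrate. Channels that fail (no droplets, no calibration train) are
#' skipped with a log record, never fatally.
#'
#' @param trace A `raw_trace` (e.g. from [read_trace_csv()]).
#' @param config A [run_config()]; kinetic truth entries, if present, are
#'   ignored.
#' @return A list of class `trace_analysis`: `channels` (per-channel
#'   results), `fits` (list of `mm_fit`), `fit_table` (data.frame),
#'   `summary` (per-substrate [aggregate_fits()]), `log`.
#' @export
analyze_trace <- function(trace, config) {
  stopifnot(inherits(trace, "raw_trace"), inherits(config, "run_config"))
  results <- list()
  fits <- list()
  groups <- character(0)
  log <- character(0)
  for (i in seq_along(config$substrates)) {
    s <- config$substrates[[i]]
    fl <- config$substrate_fluidics[[i]]
    well <- simulate_well(fl)
    for (ch in s$channels) {
      res <- tryCatch(
        analyze_channel(trace, ch, fl, config$passes, cfg = config$analysis,
                        calib_conc = config$calibration$conc, well = well),
        dropkin_calibration_error = function(e) e,
        dropkin_channel_error = function(e) e)
      if (inherits(res, "condition")) {
        log <- c(log, sprintf("channel %d skipped: %s", ch,
                              conditionMessage(res)))
        next
      }
      log <- c(log, res$log)
      key <- sprintf("ch%02d", ch)
      results[[key]] <- res
      fits[[key]] <- res$fit
      groups <- c(groups, s$name)
    }
  }
  fit_table <- do.call(rbind, lapply(seq_along(fits), function(j) {
    f <- fits[[j]]
    data.frame(channel = f$channel, substrate = groups[j],
               kcat = f$kcat, KM = f$KM, se_kcat = f$se_kcat,
               se_KM = f$se_KM, kcat_over_KM = f$kcat_over_KM,
               n_points = f$n_points, rss = f$rss, converged = f$converged)
  }))
  summary <- if (length(fits)) aggregate_fits(unname(fits), group = groups)
             else NULL
  structure(list(channels = results, fits = fits, fit_table = fit_table,
                 summary = summary, log = log),
            class = "trace_analysis")
}

#' @export
print.trace_analysis <- function(x, ...) {
  cat(sprintf("<trace_analysis> %d channel(s) analyzed, %d log record(s)\n",
              length(x$channels), length(x$log)))
  if (!is.null(x$summary)) {
    cat("per-substrate summary:\n")
    print(as.data.frame(x$summary))
  }
  invisible(x)
}
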