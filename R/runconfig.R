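#' Full run configuration
#'
#' Bundles everything one experiment needs: the shared fluidic geometry, the
#' optical setup, the pass schedule, the calibration train, the analysis
#' thresholds, and the substrate layout. Each substrate entry describes one
#' droplet generator: its stock and enzyme concentrations, the detection
#' points its tubing feeds (e.g. a serpentine through channels 1-4), and -
#' for simulation only - the true kinetic parameters. The true parameters are
#' never consulted by the analysis mode.
#'
#' @param fluidics List of [fluidic_config()] arguments shared by all
#'   generators (per-substrate `substrate_stock`/`enzyme_initial` are taken
#'   from the substrate entries).
#' @param optics List of [optical_config()] arguments.
#' @param passes List of [pass_schedule()] arguments.
#' @param substrates List of substrate entries, each a list with `name`,
#'   `substrate_stock` (M), `enzyme_initial` (M), `channels` (integer
#'   vector), and optionally `kcat` (1/s) and `KM` (M).
#' @param calibration List with `conc` (M), `n_droplets`, `gap` (s).
#' @param analysis List of [analysis_config()] arguments.
#' @param seed Default seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(fluidics = list(), optics = list(), passes = list(),
                       substrates,
                       calibration = list(conc = 1e-3, n_droplets = 15, gap = 10),
                       analysis = list(), seed = 1L) {
  opt <- do.call(optical_config, optics)
  if (is.null(passes$n_channels)) passes$n_channels <- opt$n_channels
  sch <- do.call(pass_schedule, passes)
  ana <- do.call(analysis_config, analysis)
  if (missing(substrates) || !length(substrates))
    stop("run_config: at least one substrate entry is required", call. = FALSE)
  if (!is.null(names(substrates)) && all(nzchar(names(substrates))))
    substrates <- unname(substrates)
  used <- integer(0)
  fls <- list()
  for (i in seq_along(substrates)) {
    s <- substrates[[i]]
    if (is.null(s$name)) s$name <- paste0("substrate", i)
    if (is.null(s$channels))
      stop("run_config: substrate '", s$name, "' has no channels", call. = FALSE)
    s$channels <- as.integer(s$channels)
    if (any(s$channels < 1) || any(s$channels > opt$n_channels) ||
        any(s$channels %in% used))
      stop("run_config: invalid or overlapping channel assignment for '",
           s$name, "'", call. = FALSE)
    used <- c(used, s$channels)
    fl_args <- fluidics
    fl_args$substrate_stock <- s$substrate_stock
    fl_args$enzyme_initial <- s$enzyme_initial
    fls[[i]] <- do.call(fluidic_config, fl_args)
    substrates[[i]] <- s
  }
  calibration$conc <- calibration$conc %||% 1e-3
  calibration$n_droplets <- calibration$n_droplets %||% 15
  calibration$gap <- calibration$gap %||% 10
  structure(list(fluidics = fluidics, optics = opt, passes = sch,
                 substrates = substrates, substrate_fluidics = fls,
                 calibration = calibration, analysis = ana,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read / write a run configuration file
#'
#' The on-disk format is structured key-value text (YAML) whose keys mirror
#' the constructor argument names exactly.
#'
#' @param path Config file path.
#' @return `read_run_config` returns a [run_config()]; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(fluidics = y$fluidics %||% list(),
             optics = y$optics %||% list(),
             passes = y$passes %||% list(),
             substrates = y$substrates,
             calibration = y$calibration %||% list(),
             analysis = y$analysis %||% list(),
             seed = y$seed %||% 1L)
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  strip <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.null, logical(1))]
  }
  y <- list(
    seed = config$seed,
    fluidics = config$fluidics,
    optics = strip(config$optics),
    passes = strip(config$passes)[c("n_passes", "n_channels", "total_duration",
                                    "first_arrival", "channel_lag",
                                    "pass_interval", "calib_pass")],
    calibration = config$calibration,
    analysis = strip(config$analysis),
    substrates = lapply(config$substrates, strip)
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %d substrate(s), %d channels, %d passes, seed %d\n",
              length(x$substrates), x$optics$n_channels, x$passes$n_passes,
              x$seed))
  for (s in x$substrates)
    cat(sprintf("  %s: stock %g M, enzyme %g M, channels %s%s\n",
                s$name, s$substrate_stock, s$enzyme_initial,
                paste(s$channels, collapse = ","),
                if (!is.null(s$kcat)) sprintf(" (sim truth kcat %g /s, KM %g M)",
                                              s$kcat, s$KM) else ""))
  invisible(x)
}
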