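#' Calibrate a detection point against the known-product droplet train
#'
#' Converts the calibration train's absorbances into the channel's
#' absorbance-per-concentration slope (the product calibration slope
#' dA/dc). The detector responds linearly up to beyond the calibration
#' concentration, so a single-level, zero-intercept calibration suffices:
#' \deqn{slope = (\bar A_{calib} - A_{blank}) / c_{calib}.}
#' `A_blank` is the absorbance of a product-free aqueous plug (plug/oil
#' contrast); passing 0 reproduces a plain ratio calibration. The limit of
#' detection follows from the droplet-free baseline absorbance scatter as
#' \eqn{LOD = z \sigma_{blank} / slope} with z = 3.29 (alpha = beta = 0.05,
#' i.e. 95% confidence both ways).
#'
#' A multi-level mode is available for linearity checks: supply a vector of
#' `conc` matching `absorbance`, and the slope is the zero-intercept
#' least-squares slope of (A - blank) on c.
#'
#' @param absorbance Calibration droplet absorbances (>= 3 readings).
#' @param conc Calibration product concentration(s), M. Scalar for the
#'   single-level mode, or one value per reading for the multi-level mode.
#' @param sigma_blank Baseline absorbance scatter (from [detect_droplets()]
#'   attributes).
#' @param blank_absorbance Absorbance of a product-free plug.
#' @param channel Channel label carried through to the result.
#' @param cfg An [analysis_config()] (stability threshold, LOD multiplier).
#' @return A list of class `calibration_result`: `channel`, `slope` (1/M),
#'   `sigma_blank`, `LOD` (M), `n_droplets`, `blank_absorbance`.
#' @export
calibrate_channel <- function(absorbance, conc, sigma_blank,
                              blank_absorbance = 0, channel = NA_integer_,
                              cfg = analysis_config()) {
  if (length(absorbance) < 3)
    stop_dropkin("calibration", "need at least 3 calibration droplet readings")
  a <- absorbance - blank_absorbance
  if (length(conc) == 1L) {
    if (conc <= 0) stop_dropkin("calibration", "calibration concentration must be > 0")
    scatter <- stats::sd(a) / abs(mean(a))
    if (!is.finite(scatter) || scatter > cfg$calib_scatter_max)
      stop_dropkin("calibration", sprintf(
        "calibration unstable: relative scatter %.1f%% exceeds %.0f%%",
        100 * scatter, 100 * cfg$calib_scatter_max))
    slope <- mean(a) / conc
  } else {
    if (length(conc) != length(absorbance))
      stop_dropkin("calibration", "conc must be scalar or match absorbance length")
    slope <- sum(a * conc) / sum(conc^2)
    scatter <- stats::sd(a - slope * conc) / abs(mean(a))
  }
  if (!is.finite(slope) || slope <= 0)
    stop_dropkin("calibration", "non-positive calibration slope")
  out <- list(channel = channel, slope = slope, sigma_blank = sigma_blank,
              LOD = cfg$lod_z * sigma_blank / slope,
              n_droplets = length(absorbance),
              blank_absorbance = blank_absorbance)
  class(out) <- "calibration_result"
  out
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> channel %s: slope %.4g /M (%.4g /mM), LOD %.3g uM (n = %d)\n",
    x$channel, x$slope, x$slope / 1000, x$LOD * 1e6, x$n_droplets))
  invisible(x)
}

# classed conditions so the pipeline can skip a channel instead of dying
stop_dropkin <- function(kind, msg) {
  stop(structure(class = c(paste0("dropkin_", kind, "_error"),
                           "error", "condition"),
                 list(message = msg, call = NULL)))
}
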