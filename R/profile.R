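#' Fit the exponential gradient profile of one pass
#'
#' The stirred-well dilution gradient gives the droplet train a saturating
#' absorbance profile over generation index,
#' \deqn{A(i) = \mathrm{offset} + \mathrm{amplitude}\,(1 - e^{-\kappa i}),}
#' which is fitted by least squares. The fit serves two purposes: outlier
#' screening (droplets far off the profile are flagged) and a diagnostic
#' estimate of the blank (product-free) droplet absorbance via `offset` on
#' the earliest pass. It is never used to assign concentrations, which come
#' from the fluidic parameters instead.
#'
#' @param index Generation indices (0-based).
#' @param absorbance Per-droplet absorbances of one pass.
#' @return A list of class `gradient_fit`: `offset`, `amplitude`,
#'   `rate_constant`, `rms` (residual RMS), `residuals`, `degenerate`
#'   (amplitude indistinguishable from the residual scatter), `available`
#'   (FALSE when the fit did not converge).
#' @export
fit_gradient_profile <- function(index, absorbance) {
  if (length(index) < 10)
    stop("fit_gradient_profile: need at least 10 droplets", call. = FALSE)
  df <- data.frame(i = as.numeric(index), A = absorbance)
  a0 <- min(df$A)
  amp0 <- max(df$A) - a0
  fail <- list(offset = NA_real_, amplitude = NA_real_,
               rate_constant = NA_real_, rms = NA_real_,
               residuals = rep(NA_real_, nrow(df)),
               degenerate = NA, available = FALSE)
  if (amp0 <= 0) {
    res <- df$A - mean(df$A)
    out <- list(offset = mean(df$A), amplitude = 0, rate_constant = NA_real_,
                rms = sqrt(mean(res^2)), residuals = res,
                degenerate = TRUE, available = TRUE)
    class(out) <- "gradient_fit"
    return(out)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      A ~ offset + amplitude * (1 - exp(-rate * i)), data = df,
      start = list(offset = a0, amplitude = amp0, rate = 2 / max(df$i + 1)),
      lower = c(-Inf, 0, 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # a near-constant profile often defeats the exponential fit outright;
    # report it as degenerate rather than unavailable when the total spread
    # is within the point-to-point scatter
    scatter <- stats::sd(diff(df$A)) / sqrt(2)
    if (is.finite(scatter) && amp0 < 6 * scatter) {
      res <- df$A - mean(df$A)
      out <- list(offset = mean(df$A), amplitude = 0, rate_constant = NA_real_,
                  rms = sqrt(mean(res^2)), residuals = res,
                  degenerate = TRUE, available = TRUE)
      class(out) <- "gradient_fit"
      return(out)
    }
    class(fail) <- "gradient_fit"
    return(fail)
  }
  co <- stats::coef(fit)
  res <- stats::residuals(fit)
  rms <- sqrt(mean(res^2))
  out <- list(offset = unname(co["offset"]),
              amplitude = unname(co["amplitude"]),
              rate_constant = unname(co["rate"]),
              rms = rms, residuals = as.numeric(res),
              degenerate = unname(co["amplitude"]) < 3 * rms,
              available = TRUE)
  class(out) <- "gradient_fit"
  out
}

#' Flag droplets deviating from the per-pass gradient profile
#'
#' Fits the exponential profile independently on every pass of a channel and
#' flags a droplet as an outlier when its residual exceeds `outlier_rms`
#' times the profile RMS in more than half of the passes where it was read.
#' Flagged droplets are excluded from kinetics downstream but retained in
#' outputs.
#'
#' @param tracks Track data.frame from [match_tracks()].
#' @param cfg An [analysis_config()].
#' @return Integer vector of flagged `gradient_index` values (possibly empty).
#' @export
flag_profile_outliers <- function(tracks, cfg = analysis_config()) {
  votes <- list()
  reads <- list()
  for (p in unique(tracks$pass)) {
    s <- tracks[tracks$pass == p, , drop = FALSE]
    if (nrow(s) < 10) next
    gf <- tryCatch(fit_gradient_profile(s$gradient_index, s$absorbance),
                   error = function(e) NULL)
    for (gi in s$gradient_index) {
      key <- as.character(gi)
      reads[[key]] <- (reads[[key]] %||% 0L) + 1L
    }
    if (is.null(gf) || !gf$available || gf$degenerate) next
    bad <- s$gradient_index[abs(gf$residuals) > cfg$outlier_rms * gf$rms]
    for (gi in bad) {
      key <- as.character(gi)
      votes[[key]] <- (votes[[key]] %||% 0L) + 1L
    }
  }
  if (!length(votes)) return(integer(0))
  flagged <- vapply(names(votes), function(key) {
    votes[[key]] > (reads[[key]] %||% 1L) / 2
  }, logical(1))
  sort(as.integer(names(votes)[flagged]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
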