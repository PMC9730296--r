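#' Assign substrate and enzyme concentrations from the fluidic parameters
#'
#' The analysis-side inverse of the gradient model: each droplet's content is
#' fixed by its position in the generation order, so re-solving the stirred
#' well mass balance with the known fluidic parameters and evaluating it at
#' the droplet's aspiration time (the midpoint of its aspiration window,
#' `(index + 0.5) * period`) recovers (S, E) without any access to simulator
#' ground truth.
#'
#' @param gradient_index 0-based generation indices.
#' @param fluidics The [fluidic_config()] used for the run (with the
#'   substrate stock and initial enzyme concentrations of this train).
#' @param well Optional precomputed [simulate_well()] solution (re-solved if
#'   omitted).
#' @return A data.frame with columns `gradient_index`, `t_aspirate`, `S`,
#'   `E` (M).
#' @export
assign_concentrations <- function(gradient_index, fluidics, well = NULL) {
  period <- droplet_period(fluidics)
  t_asp <- (gradient_index + 0.5) * period
  if (any(gradient_index < 0) ||
      any(t_asp > fluidics$gradient_duration + 1e-9))
    stop("assign_concentrations: gradient index beyond the droplet count ",
         "supported by the gradient duration", call. = FALSE)
  if (is.null(well)) well <- simulate_well(fluidics)
  w <- well_at(well, t_asp)
  data.frame(gradient_index = gradient_index, t_aspirate = t_asp,
             S = w$S_well, E = w$E_well)
}

#' Estimate the initial rate of one droplet
#'
#' Default ("linear"): ordinary least squares of absorbance against read
#' time; `v0 = slope / calibration slope`, with the regression standard
#' error and r-squared. This is exact while substrate consumption over the
#' read window stays small. When the observed conversion of the droplet
#' exceeds `conversion_threshold` (so the linear model is known to
#' underestimate the initial slope), the estimator switches to an integrated
#' Michaelis-Menten progress fit: product concentrations
#' `P = (A - blank)/slope` are fitted against reaction time with the
#' droplet's assigned substrate concentration held fixed and two free
#' parameters, the initial rate `v0` and an apparent Michaelis constant;
#' `v0` is then the exact t = 0 slope of the fitted progress curve. A
#' single-exponential progress fit is the fallback if that fit fails.
#' Method choice is recorded in the result; `method` can force either path.
#'
#' @param t Read times, s (absolute; the reaction clock starts at `t0`).
#' @param absorbance Absorbance readings, one per pass.
#' @param cal A [calibrate_channel()] result.
#' @param t0 Reaction start (the droplet's aspiration time), s.
#' @param S_assigned The droplet's assigned substrate concentration, M (used
#'   by the conversion check and the progress fit; `NA` forces linear).
#' @param blank_absorbance Product-free plug absorbance.
#' @param cfg An [analysis_config()].
#' @param method `"auto"`, `"linear"`, or `"progress"`.
#' @return A list of class `rate_estimate`: `v0`, `slope_se` (both M/s),
#'   `r2`, `n_points`, `conversion` (observed fraction of S converted),
#'   `method` (method actually used), `flags` (character vector; may contain
#'   `"high_conversion"`, `"below_resolution"`, and `"unresolved_fast"` for
#'   droplets whose reaction completed before the first read, whose rate is
#'   therefore unidentifiable).
#' @export
estimate_v0 <- function(t, absorbance, cal, t0 = 0, S_assigned = NA_real_,
                        blank_absorbance = cal$blank_absorbance,
                        cfg = analysis_config(),
                        method = c("auto", "linear", "progress")) {
  method <- match.arg(method)
  if (length(t) < 3)
    stop_dropkin("rate", "need at least 3 readings to estimate a rate")
  ord <- order(t)
  t <- t[ord]; absorbance <- absorbance[ord]
  tau <- t - t0
  flags <- character(0)

  fit_lm <- stats::lm(absorbance ~ tau)
  sm <- summary(fit_lm)
  m <- sm$coefficients["tau", "Estimate"]
  m_se <- sm$coefficients["tau", "Std. Error"]
  r2 <- sm$r.squared
  v0 <- m / cal$slope
  v0_se <- m_se / cal$slope
  used <- "linear"

  conversion <- NA_real_
  if (is.finite(S_assigned) && S_assigned > 0) {
    conversion <- (max(absorbance) - blank_absorbance) /
      (cal$slope * S_assigned)
    if (is.finite(conversion) && conversion > cfg$conversion_threshold)
      flags <- c(flags, "high_conversion")
  }
  want_progress <- method == "progress" ||
    (method == "auto" && "high_conversion" %in% flags && length(t) >= 4)
  if (want_progress && is.finite(S_assigned) && S_assigned > 0) {
    P_obs <- (absorbance - blank_absorbance) / cal$slope
    pf <- fit_progress_v0(tau, P_obs, S_assigned)
    if (!is.null(pf)) {
      v0 <- pf$v0; v0_se <- pf$se; r2 <- pf$r2
      used <- pf$method
      if (isTRUE(pf$saturated)) flags <- c(flags, "unresolved_fast")
    }
  }
  dt_span <- max(t) - min(t)
  if (is.finite(cal$LOD) && dt_span > 0 && v0 < cal$LOD / dt_span)
    flags <- c(flags, "below_resolution")
  structure(list(v0 = v0, slope_se = v0_se, r2 = r2, n_points = length(t),
                 conversion = conversion, method = used, flags = flags),
            class = "rate_estimate")
}

# Integrated Michaelis-Menten progress fit of one droplet: P(tau) with fixed
# S0, free (v0, apparent K, baseline c0). The free baseline makes the t = 0
# slope insensitive to errors in the estimated blank absorbance, which matter
# exactly for the low-substrate droplets where P is smallest. Returns NULL if
# nothing fits.
fit_progress_v0 <- function(tau, P_obs, S0) {
  P <- pmin(pmax(P_obs, -0.2 * S0), S0 * 1.2)
  pos <- which(tau > 0 & P > 0)
  if (length(pos) < 3) return(NULL)
  v0_start <- max(P[pos[1]] / tau[pos[1]], 1e-3 * max(P) / max(tau))
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                     ptol = 1e-14, gtol = 0)
  n <- length(tau)
  # parameters on log scale (v0, K) plus a free baseline; the log scale keeps
  # the Jacobian well conditioned across the >1e6-fold span of rates, and the
  # Michaelis parameter may legitimately run off to +Inf in the first-order
  # regime without destabilizing v0
  resid_fn <- function(par) {
    P - (par[3] + mm_progress(tau, exp(par[1]), exp(par[2]), S0))
  }
  out <- tryCatch(
    minpack.lm::nls.lm(par = c(log(v0_start), log(S0), 0), fn = resid_fn,
                       lower = c(log(v0_start) - 12, log(S0 * 1e-4), -S0),
                       upper = c(log(v0_start) + 12, log(S0 * 1e6), S0),
                       control = ctrl),
    error = function(e) NULL)
  if (!is.null(out) && out$info %in% 1:4) {
    par <- out$par
    v0 <- exp(par[1])
    # conversion already reached at the first read, per the fitted curve: the
    # likelihood is flat upward in v0 and the rate is unidentifiable
    tau1 <- min(tau[tau > 0])
    sat_frac <- mm_progress(tau1, v0, exp(par[2]), S0) / S0
    # standard error from the numeric Jacobian at the optimum
    se <- tryCatch({
      J <- vapply(1:3, function(j) {
        h <- c(1e-6, 1e-6, 1e-9 + 1e-6 * abs(par[3]))[j]
        pp <- par; pp[j] <- pp[j] + h
        (resid_fn(pp) - out$fvec) / h
      }, numeric(n))
      s2 <- sum(out$fvec^2) / max(n - 3, 1)
      v0 * sqrt(s2 * solve(crossprod(J))[1, 1])
    }, error = function(e) NA_real_)
    ss_tot <- sum((P - mean(P))^2)
    return(list(v0 = v0, se = se,
                r2 = if (ss_tot > 0) 1 - sum(out$fvec^2) / ss_tot else NA_real_,
                method = "progress", saturated = sat_frac > 0.9))
  }
  # fallback: single-exponential progress (first-order regime)
  fit2 <- tryCatch(
    minpack.lm::nlsLM(P ~ c0 + S0 * (1 - exp(-k * tau)),
                      data = data.frame(tau = tau, P = P),
                      start = list(k = v0_start / S0, c0 = 0),
                      lower = c(1e-12, -S0), upper = c(Inf, S0),
                      control = ctrl),
    error = function(e) NULL)
  if (is.null(fit2)) return(NULL)
  k <- unname(stats::coef(fit2)["k"])
  kse <- tryCatch(sqrt(stats::vcov(fit2)["k", "k"]), error = function(e) NA_real_)
  ss_res <- sum(stats::residuals(fit2)^2)
  ss_tot <- sum((P - mean(P))^2)
  list(v0 = k * S0, se = kse * S0,
       r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       method = "progress_exp")
}

#' Compile the kinetic dataset of one detection point
#'
#' Joins assigned concentrations with per-droplet rate estimates into the
#' ordered (S, E, v0) triples that feed the Michaelis-Menten fit, sorted by
#' substrate concentration. Droplets flagged as gradient-profile outliers are
#' excluded from the fit but retained with their flags; the dataset is marked
#' unfit for fitting when fewer than `min_droplets` usable droplets remain or
#' the usable substrate range spans less than `min_span`-fold.
#'
#' @param annotated Data.frame with one row per droplet: `gradient_index`,
#'   `S`, `E`, `v0`, `v0_se`, `r2`, `n_points`, `method`, `conversion`,
#'   `flags` (comma-joined string).
#' @param channel Channel label.
#' @param outliers Gradient indices flagged by [flag_profile_outliers()].
#' @param min_droplets,min_span Fit-worthiness gates.
#' @return A data.frame of class `kinetic_dataset`, sorted by `S`, with a
#'   logical `usable` column and attributes `channel`, `fit_worthy`,
#'   `unfit_reason`.
#' @export
compile_dataset <- function(annotated, channel = NA_integer_,
                            outliers = integer(0),
                            min_droplets = 8, min_span = 4) {
  d <- as.data.frame(annotated)
  d$flag_outlier <- d$gradient_index %in% outliers
  # droplets whose reaction finished before the first read carry no rate
  # information; like profile outliers they are retained but not fitted
  d$usable <- !d$flag_outlier & d$n_points >= 3 & is.finite(d$v0) &
    !grepl("unresolved_fast", d$flags)
  d <- d[order(d$S), , drop = FALSE]
  rownames(d) <- NULL
  u <- d[d$usable, , drop = FALSE]
  reason <- NULL
  if (nrow(u) < min_droplets) {
    reason <- sprintf("only %d usable droplets (need %d)", nrow(u), min_droplets)
  } else {
    s_pos <- u$S[u$S > 0]
    if (!length(s_pos) || max(s_pos) / min(s_pos) <= min_span)
      reason <- sprintf("substrate span below %g-fold", min_span)
  }
  structure(d, class = c("kinetic_dataset", "data.frame"),
            channel = channel, fit_worthy = is.null(reason),
            unfit_reason = reason)
}
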