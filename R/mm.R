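#' Integrated Michaelis-Menten progress curve
#'
#' Closed-form product concentration at time `t` for a batch reaction obeying
#' \eqn{dS/dt = -v_{max} S/(K+S)}, parameterized by the initial rate
#' \eqn{v_0 = v_{max} S_0/(K+S_0)} so that the fitted quantity is directly
#' the t = 0 slope. Uses the Lambert-W solution of the implicit integrated
#' form \eqn{K \ln(S_0/S) + (S_0 - S) = v_{max} t}.
#'
#' @param t Times, s (>= 0).
#' @param v0 Initial rate, M/s.
#' @param K Michaelis constant, M.
#' @param S0 Initial substrate concentration, M.
#' @return Product concentrations P(t), M.
#' @export
mm_progress <- function(t, v0, K, S0) {
  if (S0 <= 0 || v0 <= 0) return(rep(0, length(t)))
  vmax <- v0 * (K + S0) / S0
  y <- log(S0 / K) + (S0 - vmax * t) / K
  S <- K * lambert_w_exp(y)
  pmin(pmax(S0 - S, 0), S0)
}

# Vectorized W(e^y): solves w + log(w) = y via Newton on x = log(w),
# g(x) = e^x + x - y (convex, monotone), safe for very large/negative y.
lambert_w_exp <- function(y) {
  x <- ifelse(y > 1, log(pmax(y, 1)), y - 1)
  for (i in 1:50) {
    ex <- exp(x)
    step <- (ex + x - y) / (ex + 1)
    x <- x - step
    if (all(abs(step) < 1e-15 * pmax(1, abs(x)))) break
  }
  exp(x)
}

#' Fit Michaelis-Menten parameters to one kinetic dataset
#'
#' Nonlinear least squares of \eqn{v_0 = k_{cat} E_i S_i / (K_M + S_i)} over
#' the usable droplets of one detection point, with each droplet's own
#' enzyme concentration \eqn{E_i} (the enzyme is diluted along the gradient,
#' so a single E would bias kcat). Residuals are unweighted by default;
#' `weighted = TRUE` uses 1/se^2 weights from the rate estimates. Starting
#' values are `kcat0 = max(v0)/min(E)` and `KM0` = substrate concentration at
#' half-maximal v0/E. Standard errors come from the Jacobian at the optimum;
#' non-convergence is reported, never silently clamped.
#'
#' @param dataset A [compile_dataset()] result (or any data.frame with `S`,
#'   `E`, `v0` and optionally `usable`, `v0_se`).
#' @param weighted Use 1/se^2 weights.
#' @param start Optional list with `kcat` and `KM` overriding the defaults.
#' @param model Rate law: plain Michaelis-Menten (default), substrate
#'   inhibition \eqn{v = k_{cat} E S/(K_M + S + S^2/K_i)}, or Hill
#'   cooperativity \eqn{v = k_{cat} E S^n/(K^n + S^n)}. The alternative laws
#'   are optional variants, not the default analysis path; their extra
#'   parameter is returned in `extra`.
#' @return A list of class `mm_fit`: `channel`, `kcat`, `KM`, `se_kcat`,
#'   `se_KM`, `kcat_over_KM`, `n_points`, `rss`, `converged`, `diagnostic`,
#'   `model`, `extra` (named list with `Ki` or `n` and its se, when fitted).
#' @export
fit_mm <- function(dataset, weighted = FALSE, start = NULL,
                   model = c("mm", "substrate_inhibition", "hill")) {
  model <- match.arg(model)
  d <- as.data.frame(dataset)
  if ("usable" %in% names(d)) d <- d[d$usable, , drop = FALSE]
  channel <- attr(dataset, "channel") %||% NA_integer_
  bad <- function(diag) {
    structure(list(channel = channel, kcat = NA_real_, KM = NA_real_,
                   se_kcat = NA_real_, se_KM = NA_real_,
                   kcat_over_KM = NA_real_, n_points = nrow(d),
                   rss = NA_real_, converged = FALSE, diagnostic = diag),
              class = "mm_fit")
  }
  if (isFALSE(attr(dataset, "fit_worthy")))
    return(bad(attr(dataset, "unfit_reason")))
  if (nrow(d) < 3) return(bad("fewer than 3 usable droplets"))
  if (all(d$v0 <= 0) || max(d$v0) <= 0) return(bad("no positive rates"))

  vref <- max(d$v0)
  d$v0s <- d$v0 / vref
  kcat0 <- start$kcat %||% (max(d$v0) / min(d$E))
  vE <- d$v0 / d$E
  KM0 <- start$KM %||% d$S[which.min(abs(vE - max(vE) / 2))]
  s_pos <- d$S[d$S > 0]
  KM0 <- min(max(KM0, min(s_pos) / 10), max(s_pos) * 10)
  w <- if (weighted && "v0_se" %in% names(d) && all(is.finite(d$v0_se)) &&
           all(d$v0_se > 0)) 1 / d$v0_se^2 else rep(1, nrow(d))

  spec <- switch(model,
    mm = list(formula = v0s ~ kcat_s * E * S / (KM + S),
              start = list(kcat_s = kcat0 / vref, KM = KM0),
              lower = c(0, min(s_pos) * 1e-6)),
    substrate_inhibition = list(
      formula = v0s ~ kcat_s * E * S / (KM + S + S^2 / Ki),
      start = list(kcat_s = kcat0 / vref, KM = KM0, Ki = max(s_pos)),
      lower = c(0, min(s_pos) * 1e-6, min(s_pos) * 1e-6)),
    hill = list(formula = v0s ~ kcat_s * E * S^n / (KM^n + S^n),
                start = list(kcat_s = kcat0 / vref, KM = KM0, n = 1),
                lower = c(0, min(s_pos) * 1e-6, 0.2)))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      spec$formula, data = d,
      start = spec$start,
      weights = w,
      lower = spec$lower,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) return(bad("nonlinear least squares failed"))
  co <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(diag(vc))))
    return(bad("singular Jacobian: no curvature information (S range << KM?)"))
  kcat <- unname(co["kcat_s"]) * vref
  KM <- unname(co["KM"])
  if (kcat <= 0 || KM <= 0)
    return(bad("fit pinned at a non-physical boundary"))
  extra <- NULL
  if (model == "substrate_inhibition")
    extra <- list(Ki = unname(co["Ki"]), se_Ki = sqrt(vc["Ki", "Ki"]))
  if (model == "hill")
    extra <- list(n = unname(co["n"]), se_n = sqrt(vc["n", "n"]))
  structure(list(
    channel = channel,
    kcat = kcat, KM = KM,
    se_kcat = sqrt(vc["kcat_s", "kcat_s"]) * vref,
    se_KM = sqrt(vc["KM", "KM"]),
    cov_kcat_KM = vc["kcat_s", "KM"] * vref,
    kcat_over_KM = kcat / KM,
    n_points = nrow(d),
    rss = sum(stats::residuals(fit)^2) * vref^2,
    converged = isTRUE(fit$convInfo$isConv),
    diagnostic = NULL,
    model = model,
    extra = extra
  ), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<mm_fit> not converged:", x$diagnostic %||% "", "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<mm_fit> channel %s: kcat = %.3g +/- %.2g /s, KM = %.3g +/- %.2g mM, kcat/KM = %.3g /M/s (n = %d)\n",
    x$channel, x$kcat, x$se_kcat, x$KM * 1e3, x$se_KM * 1e3,
    x$kcat_over_KM, x$n_points))
  invisible(x)
}

#' Specificity constant
#'
#' @param kcat Turnover number(s), 1/s (>= 0).
#' @param KM Michaelis constant(s), M (> 0).
#' @return kcat/KM in 1/(M s).
#' @examples
#' specificity_constant(0.4, 21.9e-3)   # ~18 /M/s
#' @export
specificity_constant <- function(kcat, KM) {
  if (any(KM <= 0)) stop("specificity_constant: KM must be > 0", call. = FALSE)
  if (any(kcat < 0)) stop("specificity_constant: kcat must be >= 0", call. = FALSE)
  kcat / KM
}

#' Aggregate replicate Michaelis-Menten fits
#'
#' Treats each detection point as a replicate and reports, per group
#' (typically per substrate), the arithmetic mean, sample standard deviation
#' (n - 1) and relative standard deviation of kcat and KM across converged
#' fits, plus the specificity constant of the means.
#'
#' @param fits A list of `mm_fit` objects.
#' @param group Optional grouping vector (one label per fit); a single group
#'   is assumed when omitted.
#' @return A data.frame of class `replicate_summary`: one row per group with
#'   `n_fits`, `mean_kcat`, `sd_kcat`, `rsd_kcat`, `mean_KM`, `sd_KM`,
#'   `rsd_KM`, `kcat_over_KM`. SDs are `NA` when fewer than 2 converged fits
#'   contribute. The contributing fits are attached as attribute `members`.
#' @export
aggregate_fits <- function(fits, group = NULL) {
  if (inherits(fits, "mm_fit")) fits <- list(fits)
  if (is.null(group)) group <- rep("all", length(fits))
  stopifnot(length(group) == length(fits))
  groups <- unique(group)
  rows <- lapply(groups, function(g) {
    fs <- fits[group == g]
    fs <- fs[vapply(fs, function(f) isTRUE(f$converged), logical(1))]
    n <- length(fs)
    kc <- vapply(fs, `[[`, numeric(1), "kcat")
    km <- vapply(fs, `[[`, numeric(1), "KM")
    sd_or_na <- function(x) if (length(x) >= 2) stats::sd(x) else NA_real_
    data.frame(
      group = g, n_fits = n,
      mean_kcat = if (n) mean(kc) else NA_real_,
      sd_kcat = sd_or_na(kc),
      rsd_kcat = if (n >= 2) stats::sd(kc) / mean(kc) else NA_real_,
      mean_KM = if (n) mean(km) else NA_real_,
      sd_KM = sd_or_na(km),
      rsd_KM = if (n >= 2) stats::sd(km) / mean(km) else NA_real_,
      kcat_over_KM = if (n) mean(kc) / mean(km) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("replicate_summary", "data.frame"), members = fits)
}

#' Fold-span of specificity constants
#'
#' @param kcat_over_KM Specificity constants (1/(M s)) of two or more
#'   substrates (e.g. the `kcat_over_KM` column of [aggregate_fits()]).
#' @return A list with `fold` (max/min) and `log10_fold`.
#' @export
dynamic_range_report <- function(kcat_over_KM) {
  x <- kcat_over_KM[is.finite(kcat_over_KM) & kcat_over_KM > 0]
  if (!length(x)) stop("dynamic_range_report: no positive constants", call. = FALSE)
  fold <- max(x) / min(x)
  list(fold = fold, log10_fold = log10(fold))
}

#' Data-point throughput of a run
#'
#' One data point is one droplet read once at one detection point; a run of
#' `n_passes` flow reversals over `duration_s` seconds reads every droplet of
#' every channel once per pass.
#'
#' @param n_channels Detection points.
#' @param n_droplets Droplets per gradient.
#' @param n_passes Reads per droplet per channel.
#' @param duration_s Run duration, s.
#' @return Data points per hour.
#' @examples
#' data_throughput(12, 60, 6, 1800)  # 8640
#' @export
data_throughput <- function(n_channels, n_droplets, n_passes, duration_s) {
  n_channels * n_droplets * n_passes / (duration_s / 3600)
}
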