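#' Detect droplet troughs in one channel of a raw trace
#'
#' Boundary detection works on a centered moving average of the intensity to
#' prevent single-sample noise from splitting or spuriously creating
#' droplets. A droplet is a maximal run where the smoothed intensity drops
#' below `baseline - threshold_frac * (baseline - min)`; the baseline is a
#' rolling median over droplet-free spans. Boundaries are then refined on the
#' raw signal by the half-depth crossing, and the absorbance of the droplet
#' is computed from the mean raw intensity over the central 50% of the trough
#' (avoiding edge transients), `A = log10(I_baseline / I_trough)`. An
#' integrated mode (`auc_mode`) averaging absorbance across the full trough
#' is available for fidelity with area-under-the-curve acquisition.
#'
#' The moving-average window must be shorter than the inter-droplet oil gap
#' (spacer volume / draw rate; 45 ms = 9 samples at the default geometry),
#' otherwise adjacent troughs merge, and longer than 3 samples so that it
#' actually suppresses noise.
#'
#' @param trace A `raw_trace`.
#' @param channel Channel number (1-based row of the intensity matrix).
#' @param cfg An [analysis_config()] (window, threshold, baseline window,
#'   minimum trough duration, AUC mode).
#' @return A data.frame of class `droplet_detections` with columns `channel`,
#'   `start_sample`, `end_sample` (half-open, i.e. first sample after the
#'   trough), `t_center` (s), `absorbance`, `depth` (relative intensity),
#'   `n_samples`. Attributes: `baseline` (median droplet-free intensity),
#'   `sigma_blank` (sd of per-sample baseline absorbance; feeds the limit of
#'   detection), `noise_sd` (raw per-sample intensity noise estimate).
#' @export
detect_droplets <- function(trace, channel, cfg = analysis_config()) {
  stopifnot(inherits(trace, "raw_trace"))
  x <- trace$intensity[channel, ]
  n <- length(x)
  w <- cfg$window_samples
  if (w < 3 || w >= n)
    stop("detect_droplets: window_samples must be >= 3 and shorter than the trace",
         call. = FALSE)
  sm <- data.table::frollmean(x, n = w, align = "center")
  sm[is.na(sm)] <- x[is.na(sm)]

  # raw per-sample noise from first differences (troughs are sparse edges)
  noise_sd <- stats::mad(diff(x)) / sqrt(2)
  # droplets only dim the signal, so the bright quantile seeds the baseline
  # even when troughs dominate the duty cycle
  b0 <- stats::quantile(x, 0.995, names = FALSE)
  dyn <- b0 - min(sm)
  empty <- structure(
    data.frame(channel = integer(), start_sample = integer(),
               end_sample = integer(), t_center = numeric(),
               absorbance = numeric(), depth = numeric(),
               n_samples = integer()),
    class = c("droplet_detections", "data.frame"),
    baseline = b0, sigma_blank = noise_sd / (b0 * log(10)), noise_sd = noise_sd)
  # a real droplet must stand clear of the smoothed noise floor
  if (dyn <= 15 * noise_sd / sqrt(w)) return(empty)

  cand <- sm < (b0 - cfg$threshold_frac * dyn)
  # droplet-free spans: dilate the candidate mask by one window
  occ <- cand
  shift_or <- function(m, k) {
    out <- m
    if (k > 0) out[(1 + k):n] <- out[(1 + k):n] | m[1:(n - k)]
    if (k < 0) out[1:(n + k)] <- out[1:(n + k)] | m[(1 - k):n]
    out
  }
  for (k in c(-w, w)) occ <- shift_or(occ, k)
  free <- which(!occ)
  if (length(free) < max(0.01 * n, 2 * w))
    stop("detect_droplets: no droplet-free baseline estimable; trace saturated",
         call. = FALSE)
  bw <- min(cfg$baseline_window, length(free))
  if (bw %% 2 == 0) bw <- bw - 1
  base_free <- if (bw >= 3) stats::runmed(x[free], bw, endrule = "median")
               else x[free]
  baseline <- stats::approx(free, base_free, xout = seq_len(n), rule = 2)$y
  b_med <- stats::median(base_free)
  sigma_blank <- stats::sd(log10(baseline[free] / pmax(x[free], 1e-12 * b_med)))

  thr <- baseline - cfg$threshold_frac * (b_med - min(sm))
  runs <- rle(as.vector(sm < thr))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  starts <- starts[keep]; ends <- ends[keep]

  out <- vector("list", length(starts))
  prev_end <- 0L
  for (j in seq_along(starts)) {
    rs <- starts[j]; re <- ends[j]
    lo <- max(rs - w, prev_end + 1L, 1L)
    hi <- min(re + w, n)
    seg <- x[lo:hi]
    B <- baseline[(rs + re) %/% 2]
    depth_i <- B - min(seg)
    half <- B - depth_i / 2
    below <- seg < half
    imin <- which.min(seg)
    if (!below[imin]) next
    s <- imin; while (s > 1 && below[s - 1]) s <- s - 1
    e <- imin; while (e < length(seg) && below[e + 1]) e <- e + 1
    s <- lo + s - 1L; e <- lo + e - 1L
    len <- e - s + 1L
    if (len < cfg$min_trough_samples) next
    if (cfg$auc_mode) {
      a_val <- mean(log10(B / pmax(x[s:e], 1e-12 * B)))
    } else {
      trim <- len %/% 4
      core <- x[(s + trim):(e - trim)]
      a_val <- log10(B / mean(core))
    }
    out[[j]] <- data.frame(
      channel = channel, start_sample = s, end_sample = e + 1L,
      t_center = (trace$time[s] + trace$time[e]) / 2,
      absorbance = a_val, depth = depth_i / B, n_samples = len
    )
    prev_end <- e
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  structure(res, class = c("droplet_detections", "data.frame"),
            baseline = b_med, sigma_blank = sigma_blank, noise_sd = noise_sd)
}
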