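#' Per-read schedule of droplet transits
#'
#' Expands a droplet train and a pass schedule into one record per
#' (droplet, pass, channel): when the droplet's optical trough starts at that
#' detection point, the read time (trough center), the droplet's reaction age
#' at the read, and its product concentration. Droplet order within a pass
#' follows the flow direction: the first-generated droplet leads the train on
#' pull passes and trails it on push passes. A calibration train, generated
#' after the gradient, sits at the generator-side end of the tubing: it trails
#' the gradient on pull passes and leads it on push passes, separated by
#' `calib_gap` seconds of oil.
#'
#' @param droplets Gradient `droplet_events` from [generate_droplets()].
#' @param k [kinetic_params()] governing the in-droplet reaction.
#' @param passes A [pass_schedule()].
#' @param fluidics The [fluidic_config()] (sets trough duration and period).
#' @param calib Optional [calibration_droplets()] train, rendered only on
#'   `passes$calib_pass`.
#' @param calib_gap Oil gap between gradient and calibration trains, s.
#' @param channels Channels to include (default all).
#' @return A data.frame with columns `pass`, `channel`, `direction`, `index`
#'   (generation index, 0-based; calibration droplets numbered separately),
#'   `is_calibration`, `t_start`, `t_center`, `t_react`, `P` (M).
#' @export
build_read_schedule <- function(droplets, k, passes, fluidics,
                                calib = NULL, calib_gap = 10,
                                channels = seq_len(passes$n_channels)) {
  period <- droplet_period(fluidics)
  transit <- droplet_transit(fluidics)
  n <- nrow(droplets)
  ncal <- if (is.null(calib)) 0L else nrow(calib)
  rows <- vector("list", passes$n_passes * length(channels))
  ri <- 0L
  for (p in seq_len(passes$n_passes)) {
    dir <- passes$directions[p]
    has_cal <- ncal > 0 && !is.na(passes$calib_pass) && p == passes$calib_pass
    for (ch in channels) {
      a <- passes$arrival[p, ch]
      if (n > 0) {
        slot <- if (dir == "pull") droplets$index
                else (n - 1L - droplets$index)
        grad_offset <- if (has_cal && dir == "push")
          ncal * period + calib_gap else 0
        t_start <- a + grad_offset + slot * period
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          pass = p, channel = ch, direction = dir,
          index = droplets$index, is_calibration = FALSE,
          t_start = t_start, t_center = t_start + transit / 2,
          t_react = t_start + transit / 2 - droplets$t_aspirate,
          P = NA_real_
        )
      }
      if (has_cal) {
        cal_offset <- if (dir == "pull") n * period + calib_gap else 0
        t_start <- a + cal_offset + (seq_len(ncal) - 1) * period
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          pass = p, channel = ch, direction = dir,
          index = calib$index, is_calibration = TRUE,
          t_start = t_start, t_center = t_start + transit / 2,
          t_react = NA_real_, P = calib$P_fixed
        )
      }
    }
  }
  sched <- do.call(rbind, rows[seq_len(ri)])
  if (is.null(sched)) return(sched)
  if (any(sched$t_react[!sched$is_calibration] < 0))
    stop("build_read_schedule: a droplet would be read before its aspiration; ",
         "first_arrival is too early", call. = FALSE)
  if (any(sched$t_start + transit > passes$total_duration))
    stop("build_read_schedule: a trough extends beyond total_duration",
         call. = FALSE)
  # reaction progress per gradient droplet, one ODE solve each
  if (n > 0) {
    for (i in seq_len(n)) {
      sel <- which(!sched$is_calibration & sched$index == droplets$index[i])
      if (!length(sel)) next
      tr <- sched$t_react[sel]
      ord <- order(tr)
      pc <- progress_curve(droplets[i, ], k, tr[ord])
      sched$P[sel[ord]] <- pc$P
    }
  }
  sched
}

#' Render a multi-channel transmitted-light trace
#'
#' Optical forward model: each droplet transit produces a rectangular trough
#' in transmitted intensity of duration `droplet_volume/draw_rate`. Trough
#' depth follows the Beer-Lambert law,
#' \eqn{I = g_c I_0 10^{-(A_{plug} + \epsilon \ell P)}}, where
#' \eqn{A_{plug}} is the plug/oil contrast, \eqn{\epsilon \ell} the
#' absorptivity-pathlength product, and P the product concentration at the
#' read time (held at the trough-center value over the transit, which lasts
#' well under a second). Additive Gaussian noise of sd
#' `noise_sd * baseline_intensity` is applied to every sample.
#'
#' @inheritParams build_read_schedule
#' @param optics An [optical_config()].
#' @param seed Integer seed fixing the noise realization.
#' @param junk_segments Optional data.frame (`t_start`, `duration`,
#'   `absorbance`) of spurious pre-gradient segments (e.g. priming debris)
#'   added to every channel, for segmentation stress tests.
#' @return A `raw_trace` object: list with `time` (s), `intensity`
#'   (n_channels x n_samples matrix), `sample_rate`, and the read schedule as
#'   attribute `"schedule"`.
#' @export
render_trace <- function(droplets, k, optics, passes, fluidics, seed = 1L,
                         calib = NULL, calib_gap = 10, junk_segments = NULL) {
  stopifnot(inherits(optics, "optical_config"),
            inherits(passes, "pass_schedule"))
  if (passes$n_channels != optics$n_channels)
    stop("render_trace: optics and schedule disagree on channel count",
         call. = FALSE)
  sched <- build_read_schedule(droplets, k, passes, fluidics,
                               calib = calib, calib_gap = calib_gap)
  trace <- render_from_schedule(sched, optics, passes, fluidics, seed,
                                junk_segments = junk_segments)
  attr(trace, "schedule") <- sched
  trace
}

# Internal: turn a read schedule (possibly spanning several droplet trains
# mapped to disjoint channel sets) into the sampled intensity matrix.
render_from_schedule <- function(sched, optics, passes, fluidics, seed,
                                 junk_segments = NULL) {
  rate <- optics$sample_rate
  n_samples <- round(passes$total_duration * rate)
  time <- (seq_len(n_samples) - 1) / rate
  transit <- droplet_transit(fluidics)
  el <- optics$epsilon * optics$path_length
  if (!is.null(seed)) set.seed(as.integer(seed))
  intensity <- matrix(NA_real_, optics$n_channels, n_samples)
  for (ch in seq_len(optics$n_channels)) {
    A <- numeric(n_samples)
    edges <- integer(0)
    s <- if (is.null(sched)) NULL else sched[sched$channel == ch, , drop = FALSE]
    if (!is.null(s) && nrow(s)) {
      s <- s[order(s$t_start), , drop = FALSE]
      t_end <- s$t_start + transit
      if (any(s$t_start[-1] < t_end[-nrow(s)] - 1e-9))
        stop("render_trace: overlapping droplet troughs on channel ", ch,
             "; infeasible pass schedule", call. = FALSE)
      i0 <- ceiling(s$t_start * rate + 1 - 1e-9)
      i1 <- ceiling((s$t_start + transit) * rate + 1 - 1e-9) - 1L
      a_drop <- optics$droplet_contrast + el * s$P
      for (j in seq_len(nrow(s))) {
        if (i1[j] >= i0[j]) A[i0[j]:i1[j]] <- a_drop[j]
        edges <- c(edges, i0[j] - 1L, i1[j] + 1L)
      }
    }
    if (!is.null(junk_segments) && nrow(junk_segments)) {
      for (j in seq_len(nrow(junk_segments))) {
        j0 <- ceiling(junk_segments$t_start[j] * rate + 1 - 1e-9)
        j1 <- ceiling((junk_segments$t_start[j] + junk_segments$duration[j]) *
                        rate + 1 - 1e-9) - 1L
        j0 <- max(j0, 1L); j1 <- min(j1, n_samples)
        if (j1 >= j0) A[j0:j1] <- junk_segments$absorbance[j]
      }
    }
    sig <- optics$channel_gain[ch] * optics$baseline_intensity * 10^(-A)
    if (optics$edge_artifact > 0 && length(edges)) {
      edges <- edges[edges >= 1 & edges <= n_samples]
      sig[edges] <- sig[edges] +
        optics$edge_artifact * optics$baseline_intensity
    }
    if (optics$noise_sd > 0)
      sig <- sig + stats::rnorm(n_samples, 0,
                                optics$noise_sd * optics$baseline_intensity)
    intensity[ch, ] <- pmax(sig, 0)
  }
  structure(list(time = time, intensity = intensity, sample_rate = rate),
            class = "raw_trace")
}

#' @export
print.raw_trace <- function(x, ...) {
  cat(sprintf("<raw_trace> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$intensity), ncol(x$intensity), x$sample_rate,
              ncol(x$intensity) / x$sample_rate))
  invisible(x)
}
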