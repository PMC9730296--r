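#' Segment detections into passes
#'
#' Clusters the time-ordered detections of one channel into droplet-train
#' passes by gap thresholding: a gap exceeding `gap_factor` times the median
#' inter-droplet gap starts a new cluster. Clusters beyond the scheduled pass
#' count are treated as extra trains: the temporally last extra cluster is
#' routed to the calibration collection (the calibration train is generated
#' after the gradient), any others (e.g. priming debris) are flagged and set
#' aside. Passes whose droplet count deviates from the modal count are
#' flagged, not dropped.
#'
#' @param detections A `droplet_detections` data.frame (one channel).
#' @param passes The [pass_schedule()] (provides expected pass count and the
#'   alternating directions).
#' @param cfg An [analysis_config()].
#' @return A list with elements `detections` (input rows augmented with
#'   `pass_index`, `direction`, `cluster`), `segments` (one row per pass:
#'   `pass_index`, `direction`, `n`, `t_start`, `t_end`,
#'   `flag_count_deviation`), `calibration` (detections of the calibration
#'   train, or empty), `extra` (other unassigned detections), and `warnings`
#'   (character).
#' @export
segment_passes <- function(detections, passes, cfg = analysis_config()) {
  d <- as.data.frame(detections)
  if (!nrow(d)) stop("segment_passes: no detections", call. = FALSE)
  d <- d[order(d$t_center), , drop = FALSE]
  warnings <- character()
  if (nrow(d) == 1) {
    cluster <- 1L
  } else {
    gaps <- diff(d$t_center)
    med_gap <- stats::median(gaps)
    cluster <- cumsum(c(1L, as.integer(gaps > cfg$gap_factor * med_gap)))
  }
  d$cluster <- cluster
  n_clusters <- max(cluster)
  n_expected <- passes$n_passes
  if (n_clusters < n_expected) {
    # too few droplets per pass for gap statistics (e.g. one droplet per
    # train): fall back to the scheduled arrival windows
    arr <- passes$arrival[, d$channel[1]]
    guess <- vapply(d$t_center, function(tc) {
      ok <- which(arr <= tc + 1e-9)
      if (!length(ok)) 1L else ok[which.max(arr[ok])]
    }, integer(1))
    if (!is.unsorted(guess) && length(unique(guess)) == n_expected) {
      d$cluster <- cluster <- match(guess, sort(unique(guess)))
      n_clusters <- max(cluster)
      warnings <- c(warnings, sprintf(
        "channel %d: passes assigned from the schedule (gap clustering found %d)",
        d$channel[1], length(unique(guess))))
    }
  }
  counts <- tabulate(cluster)

  extra_ids <- integer(0)
  if (n_clusters > n_expected) {
    # peel off the smallest clusters as extra trains
    ord <- order(counts)
    extra_ids <- sort(ord[seq_len(n_clusters - n_expected)])
    warnings <- c(warnings, sprintf(
      "channel %d: %d extra droplet cluster(s) beyond the %d scheduled passes",
      d$channel[1], length(extra_ids), n_expected))
  } else if (n_clusters < n_expected) {
    warnings <- c(warnings, sprintf(
      "channel %d: found %d passes, schedule expects %d",
      d$channel[1], n_clusters, n_expected))
  }
  main_ids <- setdiff(seq_len(n_clusters), extra_ids)
  calib <- d[0, ]
  extra <- d[0, ]
  if (length(extra_ids)) {
    # last extra cluster in time = calibration train
    last_extra <- extra_ids[which.max(vapply(
      extra_ids, function(id) max(d$t_center[d$cluster == id]), numeric(1)))]
    calib <- d[d$cluster == last_extra, , drop = FALSE]
    extra <- d[d$cluster %in% setdiff(extra_ids, last_extra), , drop = FALSE]
  }
  dm <- d[d$cluster %in% main_ids, , drop = FALSE]
  pass_of_cluster <- stats::setNames(seq_along(main_ids), main_ids)
  dm$pass_index <- as.integer(pass_of_cluster[as.character(dm$cluster)])
  dm$direction <- passes$directions[pmin(dm$pass_index, passes$n_passes)]

  seg_counts <- tabulate(dm$pass_index, nbins = length(main_ids))
  mode_n <- as.integer(names(which.max(table(seg_counts))))
  segments <- data.frame(
    pass_index = seq_along(main_ids),
    direction = passes$directions[seq_along(main_ids)],
    n = seg_counts,
    t_start = vapply(seq_along(main_ids),
                     function(p) min(dm$t_center[dm$pass_index == p]), numeric(1)),
    t_end = vapply(seq_along(main_ids),
                   function(p) max(dm$t_center[dm$pass_index == p]), numeric(1)),
    flag_count_deviation = seg_counts != mode_n
  )
  if (any(segments$flag_count_deviation))
    warnings <- c(warnings, sprintf(
      "channel %d: pass(es) %s deviate from the modal droplet count (%d)",
      d$channel[1],
      paste(segments$pass_index[segments$flag_count_deviation], collapse = ","),
      mode_n))
  # calibration train assigned to the pass whose window it is nearest to
  if (nrow(calib)) {
    tmid <- stats::median(calib$t_center)
    calib$pass_index <- segments$pass_index[
      which.min(pmin(abs(segments$t_start - tmid), abs(segments$t_end - tmid)))]
  }
  list(detections = dm, segments = segments, calibration = calib,
       extra = extra, mode_count = mode_n, warnings = warnings)
}

#' Anchor the generation-order end of a droplet train
#'
#' The last-generated droplet of the gradient marks its high-concentration
#' end and anchors the mapping from detection order to generation order. On
#' pull passes it is the temporal end of the train; on push passes, the
#' temporal start (the train passes in reversed order). A manual anchor time
#' can be supplied, mirroring interactive end-time identification.
#'
#' @param segment Detections of one pass (rows of `segment_passes()$detections`
#'   with a single `pass_index`).
#' @param direction `"pull"` or `"push"`.
#' @param override_time Optional manual anchor time in s; must fall within
#'   the segment's time span (plus one droplet period of slack).
#' @return The row index (within `segment`) of the anchor detection.
#' @export
anchor_gradient_end <- function(segment, direction = c("pull", "push"),
                                override_time = NULL) {
  direction <- match.arg(direction)
  if (!nrow(segment)) stop("anchor_gradient_end: empty segment", call. = FALSE)
  ord <- order(segment$t_center)
  if (!is.null(override_time)) {
    span <- range(segment$t_center)
    slack <- stats::median(diff(sort(segment$t_center)))
    if (is.na(slack)) slack <- 0
    if (override_time < span[1] - slack || override_time > span[2] + slack)
      stop("anchor_gradient_end: override time outside the segment",
           call. = FALSE)
    return(which.min(abs(segment$t_center - override_time)))
  }
  if (direction == "pull") ord[length(ord)] else ord[1]
}

#' Match detections across passes into droplet tracks
#'
#' Assigns every detection a generation-order index by its time offset from
#' the pass anchor, in units of the droplet period estimated from the
#' segment's own inter-droplet spacing. Because generation order reverses
#' with flow direction, the offset is counted backwards from the anchor on
#' pull passes and forwards on push passes; composing two reversals is the
#' identity, so the same `gradient_index` refers to the same physical droplet
#' in every pass. Detections whose timing misfits the droplet grid by more
#' than 30% of a period are dropped with a log record.
#'
#' @param seg Result of [segment_passes()].
#' @param anchor_times Optional named numeric vector of manual anchor times
#'   per pass (names = pass index).
#' @return A list with `tracks` (data.frame: `channel`, `gradient_index`,
#'   `pass`, `direction`, `t`, `absorbance`), `n_droplets` (modal train
#'   length), `dropped` (misfit detections), `calibration` (pass-through of
#'   calibration detections).
#' @export
match_tracks <- function(seg, anchor_times = NULL) {
  dm <- seg$detections
  n_track <- seg$mode_count
  out <- vector("list", nrow(seg$segments))
  dropped <- dm[0, ]
  for (p in seg$segments$pass_index) {
    s <- dm[dm$pass_index == p, , drop = FALSE]
    s <- s[order(s$t_center), , drop = FALSE]
    dir <- seg$segments$direction[seg$segments$pass_index == p]
    ov <- if (!is.null(anchor_times) && as.character(p) %in% names(anchor_times))
      anchor_times[[as.character(p)]] else NULL
    ai <- anchor_gradient_end(s, dir, override_time = ov)
    period <- stats::median(diff(s$t_center))
    if (is.na(period) || period <= 0) period <- 1
    delta <- if (dir == "pull") s$t_center[ai] - s$t_center
             else s$t_center - s$t_center[ai]
    offset <- round(delta / period)
    resid <- abs(delta - offset * period)
    ok <- resid <= 0.3 * period & offset >= 0 & offset <= n_track - 1
    if (any(!ok)) dropped <- rbind(dropped, s[!ok, , drop = FALSE])
    s <- s[ok, , drop = FALSE]
    out[[p]] <- data.frame(
      channel = s$channel,
      gradient_index = (n_track - 1L) - offset[ok],
      pass = p, direction = dir, t = s$t_center,
      absorbance = s$absorbance
    )
  }
  tracks <- do.call(rbind, out)
  tracks <- tracks[order(tracks$gradient_index, tracks$pass), , drop = FALSE]
  rownames(tracks) <- NULL
  list(tracks = tracks, n_droplets = n_track, dropped = dropped,
       calibration = seg$calibration)
}
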