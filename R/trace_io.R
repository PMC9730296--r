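#' Write and read the raw trace CSV
#'
#' The on-disk format mirrors the acquisition software's single-file layout:
#' a header row, column 1 `time_s`, then one intensity column per detection
#' point named `ch01`, `ch02`, ... at the acquisition rate.
#'
#' @param trace A `raw_trace` object.
#' @param path Output CSV path.
#' @return `write_trace_csv` returns `path` invisibly; `read_trace_csv`
#'   returns a `raw_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "raw_trace"))
  n_ch <- nrow(trace$intensity)
  dt <- data.table::as.data.table(t(trace$intensity))
  data.table::setnames(dt, sprintf("ch%02d", seq_len(n_ch)))
  dt <- cbind(data.table::data.table(time_s = trace$time), dt)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  dt <- data.table::fread(path)
  if (!"time_s" %in% names(dt))
    stop("read_trace_csv: missing 'time_s' column", call. = FALSE)
  ch_cols <- grep("^ch[0-9]+$", names(dt), value = TRUE)
  if (!length(ch_cols))
    stop("read_trace_csv: no channel columns (ch01, ch02, ...) found",
         call. = FALSE)
  ch_cols <- ch_cols[order(as.integer(sub("^ch", "", ch_cols)))]
  time <- dt$time_s
  if (length(time) < 2)
    stop("read_trace_csv: trace too short", call. = FALSE)
  rate <- 1 / stats::median(diff(time))
  structure(list(time = time,
                 intensity = t(as.matrix(dt[, ch_cols, with = FALSE])),
                 sample_rate = rate),
            class = "raw_trace")
}

#' Ground-truth sidecar
#'
#' Serializes the simulator's per-droplet truth (S0, E0, aspiration time, and
#' per-pass/per-channel read times with the true product concentration at
#' each read) for recovery testing. The analysis pipeline never reads this
#' file. Round-trips losslessly (full double precision JSON).
#'
#' @param droplets Gradient `droplet_events`.
#' @param schedule Read schedule from [build_read_schedule()] (also attached
#'   to rendered traces as attribute `"schedule"`).
#' @param k The true [kinetic_params()].
#' @param path Output JSON path.
#' @return `write_ground_truth` returns `path` invisibly; `read_ground_truth`
#'   a list with `droplets`, `reads`, `kinetics`.
#' @export
write_ground_truth <- function(droplets, schedule, k, path) {
  obj <- list(
    format = "dropkin-ground-truth",
    version = 1L,
    kinetics = list(kcat = k$kcat, KM = k$KM),
    droplets = as.data.frame(droplets),
    reads = schedule[, c("pass", "channel", "direction", "index",
                         "is_calibration", "t_start", "t_center",
                         "t_react", "P")]
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "dropkin-ground-truth"))
    stop("read_ground_truth: not a ground-truth sidecar", call. = FALSE)
  obj$droplets <- as.data.frame(obj$droplets)
  obj$reads <- as.data.frame(obj$reads)
  obj
}

#' Write a detections table
#'
#' Flat CSV of per-droplet detections after tracking: channel, pass,
#' gradient index, center time, absorbance and flags.
#'
#' @param detections A data.frame with at least columns `channel`, `pass`,
#'   `gradient_index`, `t_center`, `absorbance`.
#' @param path Output CSV path.
#' @export
write_detections_csv <- function(detections, path) {
  data.table::fwrite(detections, path)
  invisible(path)
}
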