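#' Reference kinetic parameters of the SN243 glycosidase substrate panel
#'
#' `glycosidase_panel()` returns the published Michaelis-Menten parameters of
#' the metagenome-derived glycosidase SN243 against six pNP-glycoside
#' substrates, as determined both in droplets (mean +/- sd over 12 detection
#' points) and in the microtiter plate, together with the assay
#' concentrations (substrate stock injected, enzyme in the well). These serve
#' as simulation ground truths and as worked-example inputs for
#' [specificity_constant()] and [dynamic_range_report()].
#'
#' `detection_point_table()` returns the per-detection-point parameters of
#' the parallel three-substrate run (four detection points per substrate).
#'
#' @return A data.frame. Concentration columns are in the units given by
#'   their names (mM, nM); rates in 1/s; specificity constants in 1/(M s).
#' @export
glycosidase_panel <- function() {
  path <- system.file("extdata", "sn243_glycosidase_panel.csv",
                      package = "dropkin", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname glycosidase_panel
#' @export
detection_point_table <- function() {
  path <- system.file("extdata", "sn243_detection_points.csv",
                      package = "dropkin", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Build a simulation run configuration for one panel substrate
#'
#' Convenience wrapper assembling a [run_config()] whose ground truth is a
#' panel substrate's plate-reader parameters and whose concentrations are the
#' panel's assay conditions, on `n_channels` detection points fed by a single
#' droplet generator.
#'
#' @param substrate Substrate name as in [glycosidase_panel()].
#' @param n_channels Number of detection points to simulate.
#' @param source `"plate"` or `"droplets"` parameter column.
#' @param optics,passes,analysis Optional argument lists passed through.
#' @param seed Seed.
#' @return A [run_config()].
#' @export
panel_run_config <- function(substrate, n_channels = 4,
                             source = c("plate", "droplets"),
                             optics = list(), passes = list(),
                             analysis = list(), seed = 1L) {
  source <- match.arg(source)
  panel <- glycosidase_panel()
  row <- panel[panel$substrate == substrate, , drop = FALSE]
  if (nrow(row) != 1)
    stop("panel_run_config: unknown substrate '", substrate, "'", call. = FALSE)
  kcat <- row[[paste0("kcat_", source, "_per_s")]]
  KM <- row[[paste0("KM_", source, "_mM")]] * 1e-3
  optics$n_channels <- n_channels
  passes$n_channels <- n_channels
  run_config(
    optics = optics, passes = passes, analysis = analysis, seed = seed,
    substrates = list(list(
      name = substrate,
      substrate_stock = row$substrate_stock_mM * 1e-3,
      enzyme_initial = row$enzyme_nM * 1e-9,
      channels = seq_len(n_channels),
      kcat = kcat, KM = KM
    ))
  )
}
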