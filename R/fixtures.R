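## Accessors for the packaged reference tables of the worked UAE-UHPLC
## example: the three extraction factors, the 17-run design with its
## overall-desirability responses, the eleven-analyte calibration summary
## and the 24-batch content table.

extdata <- function(file) {
  path <- system.file("extdata", file, package = "phytoqc")
  if (!nzchar(path)) stop("packaged file not found: ", file)
  path
}

#' The three ultrasound-assisted extraction factors
#'
#' Methanol-water proportion (50/70/90 %), liquid-to-solid ratio
#' (30/50/70 mL/g) and extraction time (20/35/50 min), each as a
#' [factor_spec()].
#'
#' @return Named list of three `factor_spec` objects.
#' @export
ch_factors <- function() {
  tab <- utils::read.csv(extdata("factor_levels.csv"))
  out <- lapply(seq_len(nrow(tab)), function(i)
    factor_spec(tab$name[i], tab$low[i], tab$high[i],
                center = tab$center[i], unit = tab$unit[i]))
  names(out) <- tab$name
  out
}

#' The packaged 17-run Box-Behnken experiment with OD responses
#'
#' The three-factor design (12 edge runs + 5 center replicates) together
#' with the measured overall-desirability response of each run, as used
#' throughout the worked example.
#'
#' @return List with `design` (a `bbd_design`) and `od` (length-17 numeric
#'   response vector).
#' @export
ch_bbd_experiment <- function() {
  tab <- utils::read.csv(extdata("bbd_od.csv"))
  design <- code_design(tab[c("run_id", "methanol", "ratio", "time")],
                        ch_factors())
  list(design = design, od = tab$od)
}

#' The eleven-analyte calibration and validation summary
#'
#' Per analyte: calibration slope/intercept, linear range (ug/mL), R2,
#' LOQ/LOD (ug/mL), stability/precision/repeatability RSDs (%) and spike
#' recovery mean and RSD (%). These are reported summary statistics; the
#' raw replicate data behind them are not part of the package.
#'
#' @return A `data.frame`, one row per analyte.
#' @export
ch_calibration_table <- function() {
  utils::read.csv(extdata("calibration_table.csv"), check.names = FALSE)
}

#' Calibration curves of the eleven marker analytes
#'
#' @return Named list of [calibration_curve()] objects built from
#'   [ch_calibration_table()].
#' @export
ch_calibration_curves <- function() {
  tab <- ch_calibration_table()
  out <- lapply(seq_len(nrow(tab)), function(i)
    calibration_curve(tab$slope[i], tab$intercept[i],
                      c(tab$range_low[i], tab$range_high[i]),
                      analyte = tab$analyte[i],
                      r_squared = tab$r_squared[i],
                      lod = tab$lod_ug_ml[i], loq = tab$loq_ug_ml[i]))
  names(out) <- tab$analyte
  out
}

#' The 24-batch, eleven-analyte content table
#'
#' Mean and sd (n = 3 replicate injections) of each analyte's content in
#' mg per g dry material, batches labelled `<site>/<Month>` across three
#' harvest periods (June/July/August) at eight sites.
#'
#' @return Long-format `data.frame` with columns `batch`, `analyte`,
#'   `mean`, `sd`.
#' @export
ch_content_table <- function() {
  utils::read.csv(extdata("content_table.csv"), check.names = FALSE)
}
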