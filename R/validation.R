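## Analytical method-validation statistics: calibration linearity, limits
## of detection/quantification, replicate precision (RSD) and spike
## recovery, as reported for a validated UHPLC-DAD assay.

#' Fit a linear calibration curve
#'
#' Unweighted ordinary least squares of peak area on concentration
#' (`area = slope * conc + intercept`), the standard external-calibration
#' model. A `1/x` weighting is available for heteroscedastic data but is
#' off by default.
#'
#' @param concentration Concentrations, ug/mL (>= 3 distinct values; six
#'   levels are typical).
#' @param area Peak areas, same length.
#' @param analyte Optional analyte label.
#' @param weighted If `TRUE`, weight each point by `1/concentration`.
#' @return An object of class `calibration_curve`: `slope`, `intercept`,
#'   `r_squared`, `range` (low, high in ug/mL), `analyte`, `n`, plus
#'   `lod`/`loq` slots filled by [lod_loq()].
#' @examples
#' conc <- c(2.86, 5.7, 11.4, 35.8, 71.5, 143)
#' fit_calibration(conc, 13.984 * conc - 3.0103, analyte = "cynaroside")
#' @export
fit_calibration <- function(concentration, area, analyte = NA_character_,
                            weighted = FALSE) {
  concentration <- as.numeric(concentration)
  area <- as.numeric(area)
  if (length(concentration) != length(area))
    stop("concentration and area lengths differ")
  if (length(unique(concentration)) < 3L)
    stop("need >= 3 distinct concentrations (got ",
         length(unique(concentration)), ")")
  w <- if (weighted) 1 / concentration else rep(1, length(area))
  fit <- stats::lm(area ~ concentration, weights = w)
  # direct weighted R2 (summary.lm warns on exact synthetic fits)
  r2 <- 1 - sum(w * stats::resid(fit)^2) /
    sum(w * (area - stats::weighted.mean(area, w))^2)
  structure(list(
    analyte = analyte,
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = r2,
    range = range(concentration),
    n = length(concentration),
    lod = NA_real_, loq = NA_real_,
    lm = fit
  ), class = "calibration_curve")
}

#' Construct a calibration curve from published parameters
#'
#' Builds a `calibration_curve` directly from a known slope/intercept (for
#' example a curve printed in a validation report) without raw points.
#'
#' @param slope,intercept Line parameters (peak area per ug/mL; area units).
#' @param range Linear range `c(low, high)` in ug/mL; normalized so
#'   low < high whichever order is given.
#' @param analyte,r_squared,lod,loq Optional metadata.
#' @return A `calibration_curve`.
#' @export
calibration_curve <- function(slope, intercept, range,
                              analyte = NA_character_,
                              r_squared = NA_real_, lod = NA_real_,
                              loq = NA_real_) {
  if (slope == 0) stop("slope must be nonzero")
  range <- sort(as.numeric(range))
  if (range[1] >= range[2]) stop("range low must be below range high")
  structure(list(analyte = analyte, slope = slope, intercept = intercept,
                 r_squared = r_squared, range = range, n = NA_integer_,
                 lod = lod, loq = loq, lm = NULL),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration> %s: area = %.4g * C %+.4g (R2 = %s), range %g-%g ug/mL\n",
              x$analyte, x$slope, x$intercept,
              ifelse(is.na(x$r_squared), "?", sprintf("%.4f", x$r_squared)),
              x$range[1], x$range[2]))
  invisible(x)
}

#' Limits of detection and quantification from baseline noise
#'
#' `LOD = k_lod * noise_sd / |slope|`, `LOQ = k_loq * noise_sd / |slope|`,
#' in concentration units. The multipliers default to the ICH values 3.3
#' and 10 but are explicit parameters, since reported limits in the
#' literature frequently follow other conventions (signal-to-noise 3 and
#' 10, or ratios near 2:1).
#'
#' @param curve A `calibration_curve`.
#' @param noise_sd Baseline noise standard deviation, peak-area units
#'   (>= 0).
#' @param k_lod,k_loq Multipliers, `k_loq >= k_lod > 0`.
#' @return The curve with `lod`/`loq` filled (ug/mL).
#' @export
lod_loq <- function(curve, noise_sd, k_lod = 3.3, k_loq = 10) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!(k_loq >= k_lod && k_lod > 0))
    stop("need k_loq >= k_lod > 0")
  if (curve$slope == 0) stop("zero slope")
  curve$lod <- k_lod * noise_sd / abs(curve$slope)
  curve$loq <- k_loq * noise_sd / abs(curve$slope)
  curve
}

#' Relative standard deviation of replicates
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation — the
#' standard precision/repeatability/stability metric of analytical
#' validation.
#'
#' @param values Numeric replicate measurements (n >= 2, nonzero mean).
#' @return RSD in percent.
#' @examples
#' rsd(c(98, 100, 102))  # 2
#' @export
rsd <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need >= 2 replicates")
  m <- mean(values)
  if (m == 0) stop("mean is zero; RSD undefined")
  100 * stats::sd(values) / m
}

#' Spike recovery
#'
#' `100 * (found - original) / added`: the percentage of a known spiked
#' amount recovered by the assay.
#'
#' @param original Analyte amount in the unspiked sample.
#' @param added Spiked amount (> 0).
#' @param found Amount measured in the spiked sample.
#' @return Recovery in percent (vectorized).
#' @export
recovery <- function(original, added, found) {
  if (any(added <= 0)) stop("added amount must be > 0")
  100 * (found - original) / added
}

#' Aggregate a spike-recovery experiment
#'
#' The customary design spikes at three levels (e.g. 0.5:1, 1:1, 1.5:1
#' standard:sample) with three replicates each and reports the mean
#' recovery and its RSD over all nine determinations.
#'
#' @param original,added,found Vectors over all spiked determinations.
#' @return List with `recoveries`, `mean` (%), `rsd` (%), `n`.
#' @export
recovery_summary <- function(original, added, found) {
  r <- recovery(original, added, found)
  list(recoveries = r, mean = mean(r), rsd = rsd(r), n = length(r))
}
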