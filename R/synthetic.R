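## Seeded generators for every input the pipeline consumes: designed-
## experiment responses from a known quadratic truth, calibration points,
## and variable-wavelength chromatograms built from Gaussian peaks.

#' Simulate responses of a designed experiment from a known surface
#'
#' Draws `Y = quadratic(beta, x) + N(0, noise_sd)` per run — the ground
#' truth against which fitting, ANOVA and optimization are verified.
#'
#' @param design A `bbd_design`.
#' @param beta Numeric vector of the 10 coded-scale coefficients in model-
#'   matrix order: intercept, linear (per factor), interactions (pairs
#'   i<j), quadratics.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed; required so every draw is reproducible.
#' @return Numeric response vector, one value per run.
#' @export
simulate_bbd_responses <- function(design, beta, noise_sd, seed) {
  x <- coded_matrix(design)
  X <- quadratic_model_matrix(x)
  beta <- as.numeric(beta)
  if (length(beta) != ncol(X))
    stop("beta must have ", ncol(X), " coefficients (got ",
         length(beta), ")")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(as.integer(seed))
  drop(X %*% beta) + stats::rnorm(nrow(X), 0, noise_sd)
}

#' Variable-wavelength detection schedule
#'
#' An ordered set of contiguous retention-time segments, each monitored at
#' one detector wavelength. Segments must tile the run without gaps or
#' overlap.
#'
#' @param t_start,t_end Segment boundaries, minutes.
#' @param wavelength Detection wavelength per segment, nm.
#' @return A `wavelength_schedule` data frame.
#' @export
wavelength_schedule <- function(t_start, t_end, wavelength) {
  stopifnot(length(t_start) == length(t_end),
            length(t_end) == length(wavelength))
  if (any(t_end <= t_start)) stop("each segment needs t_end > t_start")
  o <- order(t_start)
  t_start <- t_start[o]; t_end <- t_end[o]; wavelength <- wavelength[o]
  if (length(t_start) > 1L &&
      any(abs(t_start[-1L] - t_end[-length(t_end)]) > 1e-9))
    stop("segments must be contiguous (t_start[j+1] == t_end[j])")
  structure(data.frame(t_start = t_start, t_end = t_end,
                       wavelength = wavelength),
            class = c("wavelength_schedule", "data.frame"))
}

#' The default six-segment detection schedule
#'
#' The segmental monitoring program used for the eleven marker compounds:
#' 348 nm over 0-7.3 min, 284 nm over 7.3-9.0 min, 330 nm over 9.0-13.0
#' min, 270 nm over 13.0-23.3 min, 250 nm over 23.3-24.7 min and 280 nm
#' over 24.7-28 min.
#'
#' @return A `wavelength_schedule`.
#' @export
default_wavelength_schedule <- function() {
  wavelength_schedule(
    t_start = c(0, 7.3, 9.0, 13.0, 23.3, 24.7),
    t_end = c(7.3, 9.0, 13.0, 23.3, 24.7, 28.0),
    wavelength = c(348, 284, 330, 270, 250, 280)
  )
}

segment_index <- function(t, schedule) {
  idx <- findInterval(t, schedule$t_start, rightmost.closed = FALSE)
  idx[t >= schedule$t_end[nrow(schedule)]] <- nrow(schedule)
  pmax(idx, 1L)
}

#' Simulate a variable-wavelength chromatogram
#'
#' The signal is a sum of Gaussian peaks plus additive baseline noise. Each
#' peak carries one response factor per detection wavelength, so its
#' apparent height depends on the active segment — the detector switches
#' wavelength exactly at the segment boundaries, which lets segment-switch
#' handling in downstream integration be exercised deliberately.
#'
#' @param peaks Data frame with columns `rt` (retention time, min),
#'   `height` (peak height at its reference response factor 1) and `sigma`
#'   (Gaussian width sd, min); optionally a `response` list-column of named
#'   numeric vectors mapping wavelength (as character, nm) to a response
#'   factor (default 1 at every wavelength).
#' @param schedule A [wavelength_schedule()].
#' @param baseline_sd Baseline noise sd, absorbance units (default 0).
#' @param step_min Time-grid step, minutes (default 0.01).
#' @param seed Integer seed for the baseline noise (required when
#'   `baseline_sd > 0`).
#' @return A `sim_chromatogram`: list with `time`, `signal`, `peaks`,
#'   `schedule`, `step_min`.
#' @export
simulate_chromatogram <- function(peaks, schedule, baseline_sd = 0,
                                  step_min = 0.01, seed = NULL) {
  stopifnot(inherits(schedule, "wavelength_schedule"))
  run_end <- schedule$t_end[nrow(schedule)]
  if (nrow(peaks) > 0 &&
      (any(peaks$rt < 0) || any(peaks$rt > run_end)))
    stop("peak retention times must lie within [0, ", run_end, "] min")
  time <- seq(0, run_end, by = step_min)
  seg <- segment_index(time, schedule)
  wl <- as.character(schedule$wavelength[seg])
  signal <- numeric(length(time))
  if (nrow(peaks) > 0) {
    for (p in seq_len(nrow(peaks))) {
      rf <- rep(1, length(time))
      if (!is.null(peaks$response)) {
        rmap <- peaks$response[[p]]
        if (!is.null(rmap)) {
          hit <- match(wl, names(rmap))
          rf <- ifelse(is.na(hit), 1, rmap[hit])
        }
      }
      signal <- signal + rf * peaks$height[p] *
        exp(-(time - peaks$rt[p])^2 / (2 * peaks$sigma[p]^2))
    }
  }
  if (baseline_sd > 0) {
    if (is.null(seed)) stop("supply a seed when baseline_sd > 0")
    set.seed(as.integer(seed))
    signal <- signal + stats::rnorm(length(time), 0, baseline_sd)
  }
  structure(list(time = time, signal = signal, peaks = peaks,
                 schedule = schedule, step_min = step_min),
            class = "sim_chromatogram")
}

#' Integrate chromatographic peaks over retention-time windows
#'
#' Baseline-corrected trapezoidal integration: within each window the
#' baseline is the straight line between the signal values at the window
#' endpoints, and the area is the trapezoidal integral of the signal above
#' that line. Windows must not overlap.
#'
#' @param chrom A `sim_chromatogram` (or any list with `time` and
#'   `signal`).
#' @param windows Two-column matrix/data frame of `(t_lo, t_hi)` per peak.
#' @return Numeric vector of areas (signal units x min).
#' @export
integrate_peaks <- function(chrom, windows) {
  windows <- as.matrix(windows)
  if (ncol(windows) != 2L) stop("windows must have two columns")
  if (any(windows[, 2] <= windows[, 1]))
    stop("each window needs t_hi > t_lo")
  o <- order(windows[, 1])
  if (nrow(windows) > 1L &&
      any(windows[o, 1][-1L] < windows[o, 2][-nrow(windows)]))
    stop("windows overlap")
  rng <- range(chrom$time)
  if (any(windows < rng[1] - 1e-9) || any(windows > rng[2] + 1e-9))
    stop("window outside the time grid")
  vapply(seq_len(nrow(windows)), function(i) {
    sel <- chrom$time >= windows[i, 1] & chrom$time <= windows[i, 2]
    t <- chrom$time[sel]; s <- chrom$signal[sel]
    base <- s[1L] + (s[length(s)] - s[1L]) *
      (t - t[1L]) / (t[length(t)] - t[1L])
    y <- s - base
    sum(diff(t) * (y[-1L] + y[-length(y)]) / 2)
  }, numeric(1))
}

#' Simulate calibration points from a known line
#'
#' `area = slope * C + intercept + N(0, noise_sd)` at the given
#' concentrations.
#'
#' @param slope,intercept True line parameters.
#' @param concentrations Numeric vector (>= 3 values).
#' @param noise_sd Gaussian noise sd in area units (>= 0).
#' @param seed Integer seed.
#' @return Data frame with `concentration` and `area`.
#' @export
simulate_calibration <- function(slope, intercept, concentrations,
                                 noise_sd, seed) {
  concentrations <- as.numeric(concentrations)
  if (length(concentrations) < 3L) stop("need >= 3 concentrations")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(as.integer(seed))
  data.frame(
    concentration = concentrations,
    area = slope * concentrations + intercept +
      stats::rnorm(length(concentrations), 0, noise_sd)
  )
}
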