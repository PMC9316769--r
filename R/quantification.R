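## Peak area -> concentration -> content (mg per g dry herb), and batch /
## harvest-period summaries over a multi-analyte content table.

#' Describe how a sample was prepared
#'
#' @param mass_g Dry powder mass extracted, g (> 0).
#' @param volume_ml Extract volume, mL (> 0).
#' @param dilution Dilution factor applied before injection (>= 1).
#' @return A `sample_prep` object.
#' @examples
#' sample_prep(0.1, 7)  # 0.1 g powder in 7 mL solvent
#' @export
sample_prep <- function(mass_g, volume_ml, dilution = 1) {
  if (mass_g <= 0) stop("mass_g must be > 0")
  if (volume_ml <= 0) stop("volume_ml must be > 0")
  if (dilution < 1) stop("dilution must be >= 1")
  structure(list(mass_g = mass_g, volume_ml = volume_ml,
                 dilution = dilution), class = "sample_prep")
}

#' Invert a calibration curve: peak area to concentration
#'
#' `C = (area - intercept) / slope`, flagging values outside the curve's
#' linear range rather than dropping them — out-of-range analytes are still
#' needed for batch totals.
#'
#' @param area Peak area(s).
#' @param curve A `calibration_curve`.
#' @return Data frame with `concentration` (ug/mL) and logical `in_range`.
#' @export
area_to_concentration <- function(area, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("zero slope")
  conc <- (as.numeric(area) - curve$intercept) / curve$slope
  data.frame(concentration = conc,
             in_range = conc >= curve$range[1] & conc <= curve$range[2])
}

#' Convert extract concentration to dry-herb content
#'
#' `content (mg/g) = C (ug/mL) * volume (mL) * dilution / mass (g) / 1000`.
#'
#' @param concentration Concentration in the injected extract, ug/mL.
#' @param prep A [sample_prep()].
#' @return Content in mg per g dry material (vectorized).
#' @examples
#' concentration_to_content(698.11, sample_prep(0.1, 7))  # ~48.87 mg/g
#' @export
concentration_to_content <- function(concentration, prep) {
  stopifnot(inherits(prep, "sample_prep"))
  as.numeric(concentration) * prep$volume_ml * prep$dilution /
    prep$mass_g / 1000
}

#' Summarize replicate contents per batch and analyte
#'
#' @param records Data frame with columns `batch`, `analyte`, `content`
#'   (mg/g), one row per replicate determination.
#' @return Data frame with per batch-analyte `mean`, `sd` (n-1) and `n`.
#' @export
content_summary <- function(records) {
  stopifnot(all(c("batch", "analyte", "content") %in% names(records)))
  agg <- stats::aggregate(content ~ batch + analyte, data = records,
                          FUN = function(v) c(mean = mean(v),
                                              sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(batch = agg$batch, analyte = agg$analyte,
                    mean = agg$content[, "mean"],
                    sd = agg$content[, "sd"], n = agg$content[, "n"])
  out[order(out$batch, out$analyte), , drop = FALSE]
}

parse_batch_id <- function(batch) {
  parts <- strsplit(as.character(batch), "/", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad))
    stop("batch id(s) not in '<site>/<Month>' form: ",
         paste(unique(batch[bad]), collapse = ", "))
  data.frame(site = vapply(parts, `[[`, character(1), 1L),
             period = vapply(parts, `[[`, character(1), 2L))
}

#' Batch totals and harvest-period comparison
#'
#' Sums the per-analyte mean contents within each batch, parses batch ids
#' of the form `<site>/<Month>` (e.g. `"S2/July"`), and flags the period
#' with the highest total per site — the quantity used to recommend a
#' harvest window.
#'
#' @param summaries Data frame with columns `batch`, `analyte`, `mean`
#'   (mg/g), as from [content_summary()] or an ingested content table.
#' @return List with `totals` (batch, site, period, total mg/g) and
#'   `best_period` (per site, the period maximizing the total).
#' @examples
#' batch_summary(ch_content_table())$best_period
#' @export
batch_summary <- function(summaries) {
  stopifnot(all(c("batch", "analyte", "mean") %in% names(summaries)))
  if (anyDuplicated(summaries[c("batch", "analyte")]))
    stop("duplicated batch-analyte pairs")
  tot <- stats::aggregate(mean ~ batch, data = summaries, FUN = sum)
  names(tot)[2L] <- "total"
  tot <- cbind(tot, parse_batch_id(tot$batch))
  tot <- tot[order(tot$site, tot$period), c("batch", "site", "period",
                                            "total")]
  rownames(tot) <- NULL
  best <- do.call(rbind, lapply(split(tot, tot$site), function(g) {
    g[which.max(g$total), c("site", "period", "total")]
  }))
  rownames(best) <- NULL
  list(totals = tot, best_period = best)
}
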