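#' Define an experimental factor with coded levels
#'
#' A factor specification maps the coded levels -1/0/+1 of a three-level
#' design onto actual units (e.g. percent methanol, mL/g, minutes).
#'
#' @param name Factor label, e.g. `"methanol"`.
#' @param low Actual value at coded level -1.
#' @param high Actual value at coded level +1.
#' @param center Actual value at coded level 0. Defaults to the midpoint
#'   `(low + high) / 2`. A warning (not an error) is issued when the supplied
#'   center is off-midpoint, since coding then ceases to be symmetric.
#' @param unit Unit string, used only for labelling.
#'
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("methanol", 50, 90, unit = "%")
#' @export
factor_spec <- function(name, low, high, center = (low + high) / 2,
                        unit = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  vals <- c(low = low, center = center, high = high)
  if (!all(is.finite(vals)))
    stop("factor '", name, "': levels must be finite numbers")
  if (!(low < center && center < high))
    stop("factor '", name, "': levels must satisfy low < center < high")
  mid <- (low + high) / 2
  if (abs(center - mid) > 1e-9 * max(abs(c(low, high, 1))))
    warning("factor '", name, "': center ", center,
            " is not the midpoint of (low, high); coding will be asymmetric")
  structure(
    list(name = name, unit = unit, low = low, center = center, high = high),
    class = "factor_spec"
  )
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("<factor> %s [%s]: -1 = %g, 0 = %g, +1 = %g\n",
              x$name, x$unit, x$low, x$center, x$high))
  invisible(x)
}

half_range <- function(spec) (spec$high - spec$low) / 2

#' Convert actual factor levels to coded units
#'
#' Coded level `x = (X - center) / ((high - low) / 2)`, so that low, center
#' and high map to -1, 0 and +1.
#'
#' @param X Numeric vector of actual levels.
#' @param spec A [factor_spec()].
#' @return Numeric vector of coded levels.
#' @seealso [decode_levels()] for the inverse.
#' @examples
#' sp <- factor_spec("methanol", 50, 90, unit = "%")
#' code_levels(90, sp)  # +1
#' code_levels(65, sp)  # -0.25
#' @export
code_levels <- function(X, spec) {
  stopifnot(inherits(spec, "factor_spec"))
  h <- half_range(spec)
  if (h == 0) stop("factor '", spec$name, "': zero half-range")
  (X - spec$center) / h
}

#' Convert coded factor levels back to actual units
#'
#' @param x Numeric vector of coded levels.
#' @param spec A [factor_spec()].
#' @return Numeric vector of actual levels.
#' @export
decode_levels <- function(x, spec) {
  stopifnot(inherits(spec, "factor_spec"))
  spec$center + x * half_range(spec)
}

# Canonical edge-point block of the 3-factor Box-Behnken design: the three
# factor pairs in order (1,2), (1,3), (2,3); within a pair the sign
# combinations (-,-), (+,-), (-,+), (+,+); the off-pair factor at 0.
bbd3_edge_rows <- function() {
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  signs <- rbind(c(-1L, -1L), c(1L, -1L), c(-1L, 1L), c(1L, 1L))
  rows <- matrix(0L, nrow = 12L, ncol = 3L)
  r <- 0L
  for (p in pairs) {
    for (s in seq_len(4L)) {
      r <- r + 1L
      rows[r, p] <- signs[s, ]
    }
  }
  rows
}

#' Generate a three-factor Box-Behnken design
#'
#' Builds the 12 edge points (each factor pair at the four +-1 sign
#' combinations with the remaining factor at its center) followed by
#' `n_center` replicated center runs. With `n_center = 5` this is the
#' classical 17-run layout. Coded levels are stored as exact integers so
#' orthogonality checks are free of floating-point drift. Runs are emitted
#' in a fixed canonical order; analyses of the design are order-invariant.
#'
#' @param factors List of exactly three [factor_spec()] objects. Only the
#'   three-factor design is supported; other factor counts are rejected.
#' @param n_center Number of replicated center runs (>= 1), default 5.
#'
#' @return A `data.frame` of class `bbd_design` with columns `run_id`, one
#'   coded column `x.<name>` per factor and one actual-unit column `<name>`
#'   per factor. The factor specifications are attached as attribute
#'   `"factors"`.
#' @examples
#' fs <- list(factor_spec("methanol", 50, 90, unit = "%"),
#'            factor_spec("ratio", 30, 70, unit = "mL/g"),
#'            factor_spec("time", 20, 50, unit = "min"))
#' bbd_design(fs)
#' @export
bbd_design <- function(factors, n_center = 5L) {
  if (!is.list(factors) || length(factors) != 3L ||
      !all(vapply(factors, inherits, logical(1), "factor_spec")))
    stop("bbd_design() requires a list of exactly 3 factor_spec objects; ",
         "designs for other factor counts are not supported")
  n_center <- as.integer(n_center)
  if (is.na(n_center) || n_center < 1L)
    stop("n_center must be an integer >= 1")

  coded <- rbind(bbd3_edge_rows(),
                 matrix(0L, nrow = n_center, ncol = 3L))
  nm <- vapply(factors, `[[`, character(1), "name")
  colnames(coded) <- nm
  actual <- vapply(seq_len(3L),
                   function(j) decode_levels(coded[, j], factors[[j]]),
                   numeric(nrow(coded)))
  colnames(actual) <- nm

  out <- data.frame(run_id = seq_len(nrow(coded)), check.names = FALSE)
  for (j in seq_len(3L)) out[[paste0("x.", nm[j])]] <- coded[, j]
  for (j in seq_len(3L)) out[[nm[j]]] <- actual[, j]
  structure(out, factors = factors, class = c("bbd_design", "data.frame"))
}

#' Extract the coded design matrix from a design
#'
#' @param design A `bbd_design` or any data frame holding coded columns.
#' @return Numeric matrix of coded levels, one column per factor.
#' @export
coded_matrix <- function(design) {
  fs <- attr(design, "factors")
  nm <- vapply(fs, `[[`, character(1), "name")
  m <- as.matrix(as.data.frame(design)[paste0("x.", nm)])
  colnames(m) <- nm
  storage.mode(m) <- "double"
  m
}

#' Attach coded columns to a design table holding actual levels
#'
#' Given a data frame with actual-unit factor columns, computes the coded
#' columns `x.<name>` from the factor specifications. The inverse of the
#' decoding performed by [bbd_design()].
#'
#' @param design Data frame containing one column per factor name.
#' @param factors List of [factor_spec()] objects.
#' @return The design with coded columns added and class `bbd_design`.
#' @export
code_design <- function(design, factors) {
  stopifnot(is.data.frame(design))
  for (f in factors) {
    if (!f$name %in% names(design))
      stop("design has no column '", f$name, "'")
    design[[paste0("x.", f$name)]] <- code_levels(design[[f$name]], f)
  }
  if (!"run_id" %in% names(design)) design$run_id <- seq_len(nrow(design))
  structure(design, factors = factors, class = c("bbd_design", "data.frame"))
}
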