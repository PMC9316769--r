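#' Describe how each quality index maps to a desirability
#'
#' Each index (e.g. the extraction yield of one marker compound) is scored on
#' a 0-1 desirability scale by linear min-max normalization: for a
#' larger-is-better index `d = (Y - Ymin) / (Ymax - Ymin)`; for a
#' smaller-is-better index the mirrored form `d = (Ymax - Y) / (Ymax - Ymin)`.
#' By default the bounds `Ymin`, `Ymax` are the observed minimum and maximum
#' of the index over the runs of the experiment being scored; fixed bounds
#' can be supplied instead.
#'
#' @param directions Named character vector, one element per index, each
#'   `"larger_better"` or `"smaller_better"`. Names are the index names.
#' @param bounds Optional named list of `c(min, max)` pairs fixing the
#'   normalization bounds for some or all indices.
#' @return An object of class `desirability_spec`.
#' @export
desirability_spec <- function(directions, bounds = NULL) {
  directions <- unlist(directions)
  if (is.null(names(directions)) || any(!nzchar(names(directions))))
    stop("directions must be a named vector (one name per index)")
  ok <- directions %in% c("larger_better", "smaller_better")
  if (!all(ok))
    stop("unknown direction(s): ", paste(directions[!ok], collapse = ", "))
  if (!is.null(bounds)) {
    for (nm in names(bounds)) {
      b <- bounds[[nm]]
      if (length(b) != 2L || !all(is.finite(b)) || b[2] <= b[1])
        stop("bounds for index '", nm, "' must be c(min, max) with max > min")
    }
  }
  structure(list(directions = directions, bounds = bounds),
            class = "desirability_spec")
}

di_one_index <- function(y, direction, b, index_name) {
  ymin <- b[1]; ymax <- b[2]
  if (ymax == ymin)
    stop("index '", index_name,
         "' is constant; supply fixed bounds to score it")
  d <- if (direction == "larger_better") (y - ymin) / (ymax - ymin)
       else (ymax - y) / (ymax - ymin)
  if (any(d < 0 | d > 1)) {
    warning("index '", index_name,
            "': values outside bounds clamped to [0, 1]")
    d <- pmin(pmax(d, 0), 1)
  }
  d
}

#' Per-index desirabilities and the overall desirability (OD)
#'
#' Scores every run of a multi-index response table. Each index column is
#' normalized to a desirability `d` in `[0, 1]` per its direction; the
#' overall desirability of a run is the unweighted geometric mean
#' `OD = (d1 * d2 * ... * dn)^(1/n)`. A run at the worst observed level of
#' any index has `d = 0` for that index and hence `OD = 0` exactly — no
#' epsilon floor is applied.
#'
#' @param values Numeric matrix or data frame, runs in rows, one column per
#'   index named as in `spec`. At least two runs are required when bounds
#'   are taken from the data.
#' @param spec A [desirability_spec()].
#' @return An object of class `desirability_result`: list with elements
#'   `d` (run-by-index desirability matrix), `od` (per-run OD vector),
#'   `bounds` (per-index `c(min, max)` used), `n_index`, and `values` (the
#'   input, as a matrix).
#' @examples
#' v <- cbind(yield = c(1, 3), purity = c(2, 4))
#' sp <- desirability_spec(c(yield = "larger_better",
#'                           purity = "larger_better"))
#' compute_desirability(v, sp)$od  # 0 and 1
#' @export
compute_desirability <- function(values, spec) {
  stopifnot(inherits(spec, "desirability_spec"))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  idx <- names(spec$directions)
  if (!all(idx %in% colnames(values)))
    stop("values is missing index column(s): ",
         paste(setdiff(idx, colnames(values)), collapse = ", "))
  values <- values[, idx, drop = FALSE]
  if (anyNA(values) || !all(is.finite(values)))
    stop("values must be finite and complete")
  if (nrow(values) < 2L && is.null(spec$bounds))
    stop("need >= 2 runs to take bounds from the data")

  n <- length(idx)
  d <- matrix(NA_real_, nrow(values), n, dimnames = list(NULL, idx))
  used <- vector("list", n); names(used) <- idx
  for (j in idx) {
    b <- spec$bounds[[j]]
    if (is.null(b)) b <- range(values[, j])
    used[[j]] <- b
    d[, j] <- di_one_index(values[, j], spec$directions[[j]], b, j)
  }
  od <- apply(d, 1L, function(r) prod(r)^(1 / n))
  structure(list(d = d, od = od, bounds = used, n_index = n,
                 values = values),
            class = "desirability_result")
}

#' @export
print.desirability_result <- function(x, ...) {
  cat("<desirability> ", nrow(x$d), " runs x ", x$n_index, " indices\n",
      sep = "")
  print(cbind(round(x$d, 4), OD = round(x$od, 4)))
  invisible(x)
}

#' Overall desirability along a single-factor profile
#'
#' Scores a one-factor-at-a-time experiment: each row of `values` holds the
#' index measurements at one level of the varied factor. Bounds are taken
#' over the levels of this experiment only. Returns the per-level OD and the
#' level maximizing it.
#'
#' @param levels Numeric vector of factor settings (>= 2 levels).
#' @param values Matrix/data frame of index values, one row per level.
#' @param spec A [desirability_spec()].
#' @return List with `profile` (data frame of level and OD), `best_level`
#'   (the argmax level) and `result` (the full [compute_desirability()]
#'   output).
#' @export
single_factor_profile <- function(levels, values, spec) {
  levels <- as.numeric(levels)
  if (length(levels) < 2L) stop("need >= 2 levels")
  values <- as.matrix(values)
  if (nrow(values) != length(levels))
    stop("values must have one row per level")
  res <- compute_desirability(values, spec)
  list(profile = data.frame(level = levels, od = res$od),
       best_level = levels[which.max(res$od)],
       result = res)
}
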