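## Bounded maximization of the fitted quadratic surface. The interesting
## case in practice is an optimum on a face of the design cube (here the
## liquid-to-solid ratio sits at its +1 bound), so the search must be
## boundary-aware: L-BFGS-B from every point of the {-1,0,1}^k lattice,
## with a deterministic shrinking-grid coordinate refinement as fallback.

surface_value <- function(model, x) {
  qf <- quadratic_form(model)
  qf$c + sum(qf$b * x) + drop(t(x) %*% qf$A %*% x)
}

refine_on_grid <- function(model, lower, upper, n_coarse = 101L,
                           n_rounds = 6L) {
  k <- length(model$factor_names)
  centre <- (lower + upper) / 2
  width <- (upper - lower) / 2
  best <- centre
  for (r in seq_len(n_rounds)) {
    for (j in seq_len(k)) {
      s <- seq(max(lower[j], best[j] - width[j]),
               min(upper[j], best[j] + width[j]), length.out = n_coarse)
      pts <- matrix(rep(best, each = n_coarse), n_coarse, k)
      pts[, j] <- s
      vals <- predict(model, pts)
      best[j] <- s[which.max(vals)]
    }
    width <- width / 4
  }
  best
}

#' Maximize a fitted response surface over a coded box
#'
#' Finds the factor settings maximizing the predicted response inside box
#' constraints (default the coded design cube `[-1, 1]^k`). Multi-start
#' bounded quasi-Newton (one start per point of the `{-1, 0, 1}^k` lattice)
#' with a shrinking-grid coordinate refinement as a derivative-free
#' fallback; results are deterministic given the model and bounds. Ties
#' across starts are broken by the coded-lexicographically smallest point.
#'
#' @param model A fitted `quadratic_model`.
#' @param lower,upper Coded bounds, recycled to the number of factors;
#'   default the coded design cube `[-1, 1]^k`. Infinite bounds are an
#'   error unless the quadratic form is negative definite (otherwise the
#'   maximum is unbounded).
#' @return An object of class `optimum_result`: coded optimum `x`, actual
#'   optimum `X` (when factor specs are stored), `predicted` response,
#'   per-factor `at_boundary` flags, and the stationary-point
#'   `classification` (`"maximum"`, `"saddle"` or `"minimum"`) from the
#'   eigenvalues of the quadratic-form matrix.
#' @examples
#' exper <- ch_bbd_experiment()
#' maximize_surface(fit_quadratic(exper$design, exper$od))
#' @export
maximize_surface <- function(model, lower = -1, upper = 1) {
  stopifnot(inherits(model, "quadratic_model"))
  k <- length(model$factor_names)
  qf <- quadratic_form(model)
  ev <- eigen(qf$A, symmetric = TRUE, only.values = TRUE)$values
  lower <- rep_len(as.numeric(lower), k)
  upper <- rep_len(as.numeric(upper), k)
  if ((any(!is.finite(lower)) || any(!is.finite(upper))) &&
      max(ev) >= -1e-12)
    stop("quadratic form is not negative definite: the unconstrained ",
         "maximum is unbounded; supply finite bounds")
  if (any(lower >= upper)) stop("lower bounds must be below upper bounds")

  neg <- function(x) -surface_value(model, x)
  grad_neg <- function(x) -(qf$b + 2 * drop(qf$A %*% x))

  starts <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), k)))
  starts <- sweep(sweep(starts, 2, pmax(lower, -1), pmax), 2,
                  pmin(upper, 1), pmin)
  cand <- list()
  for (s in seq_len(nrow(starts))) {
    o <- tryCatch(
      stats::optim(starts[s, ], neg, grad_neg, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 10, pgtol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(o)) cand[[length(cand) + 1L]] <- o$par
  }
  if (all(is.finite(lower)) && all(is.finite(upper)))
    cand[[length(cand) + 1L]] <- refine_on_grid(model, lower, upper)
  # interior stationary point, if it lies inside the box
  if (abs(det(qf$A)) > 1e-14) {
    xs <- drop(solve(2 * qf$A, -qf$b))
    if (all(xs >= lower - 1e-12) && all(xs <= upper + 1e-12))
      cand[[length(cand) + 1L]] <- pmin(pmax(xs, lower), upper)
  }
  # Exact active-set polish: with the bound-active coordinates pinned, the
  # free coordinates of a quadratic maximum solve a linear system; apply it
  # to every candidate so position accuracy is limited only by arithmetic,
  # not by optimizer stopping rules.
  polish <- function(x) {
    act <- which(abs(x - lower) <= 1e-6 | abs(x - upper) <= 1e-6)
    free <- setdiff(seq_along(x), act)
    if (length(free)) {
      Aff <- qf$A[free, free, drop = FALSE]
      rhs <- -(qf$b[free] +
                 2 * qf$A[free, act, drop = FALSE] %*% x[act])
      xf <- tryCatch(drop(solve(2 * Aff, rhs)), error = function(e) NULL)
      if (!is.null(xf) && all(xf >= lower[free] - 1e-9) &&
          all(xf <= upper[free] + 1e-9)) {
        y <- x
        y[free] <- pmin(pmax(xf, lower[free]), upper[free])
        if (surface_value(model, y) >= surface_value(model, x)) x <- y
      }
    }
    x
  }
  cand <- lapply(cand, polish)
  vals <- vapply(cand, function(x) surface_value(model, x), numeric(1))
  best_val <- max(vals)
  near <- which(vals >= best_val - 1e-12 * max(1, abs(best_val)))
  ord <- do.call(order, as.data.frame(do.call(rbind, cand[near])))
  x_opt <- cand[[near[ord[1L]]]]
  names(x_opt) <- model$factor_names

  X_opt <- NULL
  if (!is.null(model$factors))
    X_opt <- stats::setNames(
      vapply(seq_len(k),
             function(j) decode_levels(x_opt[j], model$factors[[j]]),
             numeric(1)),
      model$factor_names)

  structure(list(
    x = x_opt,
    X = X_opt,
    predicted = surface_value(model, x_opt),
    at_boundary = stats::setNames(
      abs(x_opt - lower) <= 1e-9 | abs(x_opt - upper) <= 1e-9,
      model$factor_names),
    classification = if (max(ev) < 0) "maximum"
                     else if (min(ev) > 0) "minimum" else "saddle",
    lower = lower, upper = upper,
    model = model
  ), class = "optimum_result")
}

#' @export
print.optimum_result <- function(x, ...) {
  cat("Surface optimum (", x$classification, " stationary form)\n", sep = "")
  cat("  coded:  ", paste(sprintf("%s = %.4f%s", names(x$x), x$x,
                                  ifelse(x$at_boundary, " [bound]", "")),
                          collapse = ", "), "\n")
  if (!is.null(x$X))
    cat("  actual: ", paste(sprintf("%s = %.4g", names(x$X), x$X),
                            collapse = ", "), "\n")
  cat(sprintf("  predicted response = %.4f\n", x$predicted))
  invisible(x)
}

snap_to <- function(value, quantum) {
  if (is.null(quantum) || is.na(quantum) || quantum <= 0) return(value)
  round(value / quantum) * quantum
}

#' Round an optimum to operable factor settings
#'
#' Laboratory practice rarely uses settings like 64.63%: this snaps each
#' actual-unit coordinate of an optimum to a per-factor quantum (e.g.
#' nearest 5% solvent, nearest 5 min) and re-predicts the response at the
#' snapped point. Factors without a rule are left untouched.
#'
#' @param opt An [maximize_surface()] result whose model carries factor
#'   specifications.
#' @param rules Named numeric vector of rounding quanta in actual units,
#'   names matching factor names; e.g. `c(methanol = 5, time = 5)`.
#' @return A new `optimum_result` at the snapped point.
#' @export
round_to_practice <- function(opt, rules) {
  stopifnot(inherits(opt, "optimum_result"))
  if (is.null(opt$X))
    stop("optimum carries no actual-unit levels to round")
  model <- opt$model
  X <- opt$X
  for (nm in names(rules)) {
    if (!nm %in% names(X)) stop("no factor named '", nm, "'")
    X[nm] <- snap_to(X[nm], rules[[nm]])
  }
  x <- stats::setNames(
    vapply(seq_along(X),
           function(j) code_levels(X[j], model$factors[[j]]), numeric(1)),
    names(X))
  if (any(x < opt$lower - 1e-9 | x > opt$upper + 1e-9))
    stop("snapped point falls outside the optimization bounds")
  out <- opt
  out$x <- x
  out$X <- X
  out$predicted <- surface_value(model, x)
  out$at_boundary <- stats::setNames(
    abs(x - opt$lower) <= 1e-9 | abs(x - opt$upper) <= 1e-9, names(x))
  out
}
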