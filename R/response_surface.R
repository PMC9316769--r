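## Second-order response surface fitting on coded variables, with the full
## designed-experiment ANOVA (drop-one term sums of squares, lack-of-fit /
## pure-error split from replicated center runs).

# Model matrix of the full second-degree polynomial in k coded variables:
# intercept, linear terms, pairwise interactions (i < j), pure quadratics.
quadratic_model_matrix <- function(x) {
  x <- as.matrix(x)
  k <- ncol(x)
  nm <- colnames(x)
  if (is.null(nm)) nm <- paste0("x", seq_len(k))
  cols <- list(`(Intercept)` = rep(1, nrow(x)))
  for (i in seq_len(k)) cols[[nm[i]]] <- x[, i]
  if (k > 1L) {
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k))
      cols[[paste0(nm[i], ":", nm[j])]] <- x[, i] * x[, j]
  }
  for (i in seq_len(k)) cols[[paste0(nm[i], "^2")]] <- x[, i]^2
  do.call(cbind, cols)
}

#' Fit a second-degree polynomial response surface
#'
#' Ordinary least squares of the response on the 10-column coded model
#' matrix (intercept, 3 linear, 3 interaction, 3 quadratic terms for a
#' three-factor design): `Y = b0 + sum bi xi + sum bij xi xj + sum bii xi^2`.
#' Fitting is always on the coded scale; the attached factor specifications
#' let [predict.quadratic_model()] accept actual units.
#'
#' @param design A `bbd_design` (see [bbd_design()] / [code_design()]).
#' @param response Numeric response vector, one value per run (here
#'   typically the overall desirability).
#' @return An object of class `quadratic_model`: coefficients split into
#'   `beta0`, `beta_linear`, `beta_inter`, `beta_quad`, plus the underlying
#'   `lm` fit, the coded matrix and the factor specs.
#' @examples
#' exper <- ch_bbd_experiment()
#' fit <- fit_quadratic(exper$design, exper$od)
#' coef(fit$lm)
#' @export
fit_quadratic <- function(design, response) {
  x <- coded_matrix(design)
  response <- as.numeric(response)
  if (length(response) != nrow(x))
    stop("response length ", length(response), " does not match ",
         nrow(x), " runs")
  if (anyNA(response) || !all(is.finite(response)))
    stop("response must be finite and complete")
  X <- quadratic_model_matrix(x)
  if (nrow(X) < ncol(X))
    stop("need at least ", ncol(X), " runs to fit ", ncol(X), " terms")
  df <- as.data.frame(X[, -1, drop = FALSE], check.names = FALSE)
  df$.y <- response
  fml <- stats::as.formula(paste(
    ".y ~", paste(sprintf("`%s`", colnames(X)[-1]), collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  if (fit$rank < ncol(X))
    stop("rank-deficient model matrix (rank ", fit$rank, " < ", ncol(X), ")")

  k <- ncol(x); nm <- colnames(x)
  beta <- stats::coef(fit)
  names(beta) <- colnames(X)
  inter_nm <- colnames(X)[(k + 2L):(k + 1L + k * (k - 1L) / 2L)]
  structure(list(
    beta0 = unname(beta[1L]),
    beta_linear = beta[nm],
    beta_inter = beta[inter_nm],
    beta_quad = beta[paste0(nm, "^2")],
    coef = beta,
    factor_names = nm,
    factors = attr(design, "factors"),
    lm = fit,
    coded = x,
    response = response
  ), class = "quadratic_model")
}

#' @export
print.quadratic_model <- function(x, digits = 4, ...) {
  cat("Second-order response surface on coded variables (",
      paste(x$factor_names, collapse = ", "), ")\n", sep = "")
  print(round(x$coef, digits))
  invisible(x)
}

#' Predict from a fitted response surface
#'
#' @param object A `quadratic_model`.
#' @param newdata Matrix/data frame (or single vector) of factor settings,
#'   one row per point, columns in factor order.
#' @param coded Logical; if `FALSE`, `newdata` is in actual units and is
#'   coded internally via the stored factor specifications.
#' @param ... Unused.
#' @return Numeric vector of predicted responses. A warning is issued for
#'   points far outside the coded design cube (any `|x| > 1.5`).
#' @export
predict.quadratic_model <- function(object, newdata, coded = TRUE, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  k <- length(object$factor_names)
  if (ncol(newdata) != k)
    stop("newdata must have ", k, " columns (one per factor)")
  colnames(newdata) <- object$factor_names
  if (!coded) {
    if (is.null(object$factors))
      stop("model carries no factor specifications; supply coded levels")
    for (j in seq_len(k))
      newdata[, j] <- code_levels(newdata[, j], object$factors[[j]])
  }
  if (any(abs(newdata) > 1.5))
    warning("prediction point(s) far outside the coded design cube")
  unname(drop(quadratic_model_matrix(newdata) %*% object$coef))
}

# Quadratic-form pieces of the surface: Y = c + b'x + x'Ax with A symmetric
# (A_ii = beta_ii, A_ij = beta_ij / 2).
quadratic_form <- function(model) {
  k <- length(model$factor_names)
  A <- diag(as.numeric(model$beta_quad), k)
  idx <- 0L
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    idx <- idx + 1L
    A[i, j] <- A[j, i] <- model$beta_inter[[idx]] / 2
  }
  list(A = A, b = as.numeric(model$beta_linear), c = model$beta0)
}

#' Designed-experiment ANOVA of a fitted response surface
#'
#' Produces the full variance decomposition customary for a Box-Behnken
#' analysis: the 9-df model row, one drop-one (partial) row per term, the
#' residual, and — when replicated runs are present — the split of the
#' residual into lack of fit and pure error. Pure-error SS is the sum of
#' squared deviations of replicate responses about their group mean, groups
#' being runs with identical coded rows. Term and model F ratios use the
#' residual mean square; the lack-of-fit F uses the pure-error mean square.
#'
#' @param model A fitted `quadratic_model`.
#' @return A `data.frame` of class `rsm_anova` with columns `source`, `SS`,
#'   `df`, `MS`, `F`, `p`, and attributes `R2` and `R2_adj`.
#' @examples
#' exper <- ch_bbd_experiment()
#' rsm_anova(fit_quadratic(exper$design, exper$od))
#' @export
rsm_anova <- function(model) {
  stopifnot(inherits(model, "quadratic_model"))
  y <- model$response
  n <- length(y)
  X <- quadratic_model_matrix(model$coded)
  p <- ncol(X)
  sse <- sum(stats::resid(model$lm)^2)
  sst <- sum((y - mean(y))^2)
  ssm <- sst - sse
  df_mod <- p - 1L
  df_res <- n - p
  ms_res <- sse / df_res

  term_names <- colnames(X)[-1L]
  term_ss <- vapply(seq_along(term_names), function(j) {
    red <- stats::lm.fit(X[, -(j + 1L), drop = FALSE], y)
    sum(red$residuals^2) - sse
  }, numeric(1))

  rows <- data.frame(
    source = c("model", term_names),
    SS = c(ssm, term_ss),
    df = c(df_mod, rep(1L, length(term_names))),
    stringsAsFactors = FALSE
  )
  rows$MS <- rows$SS / rows$df
  rows$F <- rows$MS / ms_res
  rows$p <- stats::pf(rows$F, rows$df, df_res, lower.tail = FALSE)

  res_row <- data.frame(source = "residual", SS = sse, df = df_res,
                        MS = ms_res, F = NA_real_, p = NA_real_)

  # Replicate groups: identical coded rows (exact match — coded levels of
  # generated designs are integers).
  key <- apply(model$coded, 1L, paste, collapse = "|")
  reps <- split(y, key)
  reps <- reps[vapply(reps, length, integer(1)) > 1L]
  lof_rows <- NULL
  if (length(reps) == 0L) {
    warning("no replicated runs: lack-of-fit/pure-error split omitted")
  } else {
    sspe <- sum(vapply(reps, function(g) sum((g - mean(g))^2), numeric(1)))
    df_pe <- sum(vapply(reps, length, integer(1))) - length(reps)
    sslof <- sse - sspe
    df_lof <- df_res - df_pe
    lof_rows <- data.frame(
      source = c("lack_of_fit", "pure_error"),
      SS = c(sslof, sspe), df = c(df_lof, df_pe),
      MS = c(sslof / df_lof, sspe / df_pe),
      F = c((sslof / df_lof) / (sspe / df_pe), NA_real_),
      p = c(stats::pf((sslof / df_lof) / (sspe / df_pe), df_lof, df_pe,
                      lower.tail = FALSE), NA_real_)
    )
  }
  tot_row <- data.frame(source = "corrected_total", SS = sst,
                        df = n - 1L, MS = NA_real_, F = NA_real_,
                        p = NA_real_)
  tab <- rbind(rows, res_row, lof_rows, tot_row)
  rownames(tab) <- NULL
  structure(tab,
            R2 = 1 - sse / sst,
            R2_adj = 1 - (sse / df_res) / (sst / (n - 1L)),
            class = c("rsm_anova", "data.frame"))
}

#' @export
print.rsm_anova <- function(x, ...) {
  df <- as.data.frame(x)
  df$SS <- round(df$SS, 4)
  df$MS <- round(df$MS, 4)
  df$F <- round(df$F, 2)
  df$p <- round(df$p, 4)
  print(df, row.names = FALSE)
  cat(sprintf("R2 = %.4f, adjusted R2 = %.4f\n",
              attr(x, "R2"), attr(x, "R2_adj")))
  invisible(x)
}

#' Rectangular grid of surface predictions over two factors
#'
#' Evaluates the fitted surface on a coded grid over two free factors with
#' all remaining factors held fixed (default: the 0 level, i.e. the factor
#' centers) — the raw material for contour and 3D surface displays.
#'
#' @param model A `quadratic_model`.
#' @param factor_i,factor_j Indices (1-based) or names of the two free
#'   factors; must be distinct.
#' @param fixed Coded levels of the remaining factors (default 0).
#' @param resolution Points per axis (default 41).
#' @return List with vectors `xi`, `xj` and the `resolution x resolution`
#'   prediction matrix `z` (`z[a, b]` at `xi[a]`, `xj[b]`).
#' @export
surface_grid <- function(model, factor_i, factor_j, fixed = 0,
                         resolution = 41L) {
  nm <- model$factor_names
  k <- length(nm)
  to_idx <- function(f) if (is.character(f)) match(f, nm) else as.integer(f)
  i <- to_idx(factor_i); j <- to_idx(factor_j)
  if (is.na(i) || is.na(j) || i < 1L || j < 1L || i > k || j > k)
    stop("factor index out of range")
  if (i == j) stop("the two free factors must be distinct")
  others <- setdiff(seq_len(k), c(i, j))
  fixed <- rep_len(fixed, length(others))
  s <- seq(-1, 1, length.out = resolution)
  pts <- matrix(0, resolution^2, k)
  pts[, i] <- rep(s, times = resolution)
  pts[, j] <- rep(s, each = resolution)
  for (a in seq_along(others)) pts[, others[a]] <- fixed[a]
  z <- matrix(predict(model, pts), resolution, resolution)
  list(xi = s, xj = s, z = z, factor_i = nm[i], factor_j = nm[j])
}
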