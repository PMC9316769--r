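# Shared builders: the three extraction factors, models with known
# coefficients (fitted to exact data, so recovery is to machine precision),
# and random concave quadratic surfaces.

uae_factors <- function() {
  list(factor_spec("methanol", 50, 90, unit = "%"),
       factor_spec("ratio", 30, 70, unit = "mL/g"),
       factor_spec("time", 20, 50, unit = "min"))
}

quad_mm <- function(x) phytoqc:::quadratic_model_matrix(x)

# Coefficient order: intercept, x1, x2, x3, x1:x2, x1:x3, x2:x3,
# x1^2, x2^2, x3^2.
model_from_beta <- function(beta, factors = uae_factors(), n_center = 5) {
  design <- bbd_design(factors, n_center)
  y <- drop(quad_mm(coded_matrix(design)) %*% beta)
  fit_quadratic(design, y)
}

# The fitted surface of the worked example, rounded as printed.
printed_beta <- c(0.81, -0.22, 0.2, 0.084, 0.012, 0.076, -0.014,
                  -0.33, -0.031, -0.069)

# Random coefficients whose quadratic-form matrix is negative definite,
# so the surface has a unique unconstrained maximum.
rand_concave_beta <- function() {
  repeat {
    bq <- -runif(3, 0.3, 1.5)
    bi <- runif(3, -0.2, 0.2)
    bl <- runif(3, -0.8, 0.8)
    A <- diag(bq)
    A[1, 2] <- A[2, 1] <- bi[1] / 2
    A[1, 3] <- A[3, 1] <- bi[2] / 2
    A[2, 3] <- A[3, 2] <- bi[3] / 2
    if (max(eigen(A, symmetric = TRUE, only.values = TRUE)$values) < -1e-2)
      return(c(runif(1), bl, bi, bq))
  }
}

# Stationary point -A^{-1} b / 2 of the surface with coefficients beta.
stationary_point <- function(beta) {
  A <- diag(beta[8:10])
  A[1, 2] <- A[2, 1] <- beta[5] / 2
  A[1, 3] <- A[3, 1] <- beta[6] / 2
  A[2, 3] <- A[3, 2] <- beta[7] / 2
  drop(solve(2 * A, -beta[2:4]))
}
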