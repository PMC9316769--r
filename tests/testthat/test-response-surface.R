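test_that("noise-free surfaces are recovered to machine precision", {
  fit <- model_from_beta(printed_beta)
  expect_equal(unname(fit$coef), printed_beta, tolerance = 1e-10)
  expect_equal(unname(fit$beta_quad["methanol^2"]), -0.33,
               tolerance = 1e-10)
  # exact fit: zero residual SS, R2 = 1
  a <- suppressWarnings(rsm_anova(fit))
  expect_lt(a$SS[a$source == "residual"], 1e-20)
  expect_equal(attr(a, "R2"), 1, tolerance = 1e-12)
})

test_that("a constant response yields only an intercept", {
  d <- bbd_design(uae_factors(), 5)
  fit <- fit_quadratic(d, rep(0.7, 17))
  expect_equal(fit$beta0, 0.7, tolerance = 1e-12)
  expect_equal(max(abs(fit$coef[-1])), 0, tolerance = 1e-12)
})

test_that("OLS matches the normal-equation solve and leaves orthogonal residuals", {
  set.seed(101)
  d <- bbd_design(uae_factors(), 5)
  X <- quad_mm(coded_matrix(d))
  for (i in 1:20) {
    y <- rnorm(17)
    fit <- fit_quadratic(d, y)
    beta_ne <- unname(drop(solve(crossprod(X), crossprod(X, y))))
    expect_equal(unname(fit$coef), beta_ne, tolerance = 1e-9)
    expect_lt(max(abs(crossprod(X, y - X %*% fit$coef))), 1e-9)
  }
})

test_that("fit rejects malformed inputs", {
  d <- bbd_design(uae_factors(), 5)
  expect_error(fit_quadratic(d, rnorm(16)), "does not match")
  expect_error(fit_quadratic(d, c(rnorm(16), NA)), "finite")
})

test_that("the designed-experiment ANOVA satisfies its decompositions", {
  e <- ch_bbd_experiment()
  fit <- fit_quadratic(e$design, e$od)
  a <- rsm_anova(fit)
  g <- function(src, col) a[[col]][a$source == src]

  expect_equal(g("model", "SS") + g("residual", "SS"),
               g("corrected_total", "SS"), tolerance = 1e-9)
  expect_equal(g("lack_of_fit", "SS") + g("pure_error", "SS"),
               g("residual", "SS"), tolerance = 1e-12)
  expect_equal(c(g("model", "df"), g("residual", "df"),
                 g("lack_of_fit", "df"), g("pure_error", "df")),
               c(9, 7, 3, 4))
  expect_equal(attr(a, "R2"),
               1 - g("residual", "SS") / g("corrected_total", "SS"))

  # drop-one SS of a linear term on this orthogonal design is 8 * beta^2
  for (nm in c("methanol", "ratio", "time"))
    expect_equal(g(nm, "SS"), 8 * fit$coef[[nm]]^2, tolerance = 1e-9)
  # p-values come from the F survival function
  expect_equal(g("methanol", "p"),
               pf(g("methanol", "F"), 1, 7, lower.tail = FALSE))
})

test_that("lack of fit is omitted with a warning when nothing replicates", {
  d <- bbd_design(uae_factors(), 1)
  set.seed(5)
  fit <- fit_quadratic(d, rnorm(13))
  expect_warning(a <- rsm_anova(fit), "no replicated runs")
  expect_false(any(a$source %in% c("lack_of_fit", "pure_error")))
})

test_that("prediction evaluates the polynomial on coded or actual scales", {
  fit <- model_from_beta(printed_beta)
  expect_equal(predict(fit, c(0, 0, 0)), fit$beta0)
  # hand evaluation at coded (1, -1, 0)
  hand <- 0.81 - 0.22 * 1 + 0.2 * (-1) + 0.012 * (1 * -1) - 0.33 - 0.031
  expect_equal(predict(fit, c(1, -1, 0)), hand, tolerance = 1e-10)
  # actual units go through the stored factor coding
  expect_equal(predict(fit, c(65, 70, 40), coded = FALSE),
               predict(fit, c(-0.25, 1, 1 / 3)), tolerance = 1e-12)
  expect_warning(predict(fit, c(2, 0, 0)), "outside")
  expect_error(predict(fit, c(0, 0)), "3 columns")
})

test_that("surface grids agree with predict() and reflect model symmetry", {
  fit <- model_from_beta(printed_beta)
  g <- surface_grid(fit, "methanol", "time", resolution = 2)
  corners <- rbind(c(-1, 0, -1), c(1, 0, -1), c(-1, 0, 1), c(1, 0, 1))
  expect_equal(c(g$z), unname(predict(fit, corners)), tolerance = 1e-12)

  # purely quadratic surface: grid invariant under sign flip of both axes
  sym <- model_from_beta(c(1, 0, 0, 0, 0, 0, 0, -0.5, -0.2, -0.1))
  gs <- surface_grid(sym, 1, 2, resolution = 11)
  expect_equal(gs$z, gs$z[11:1, 11:1], tolerance = 1e-12)

  # grid max over (methanol, time) at center ratio sits near the
  # stationary point of that 2D slice
  gf <- surface_grid(fit, 1, 3, resolution = 201)
  ij <- which(gf$z == max(gf$z), arr.ind = TRUE)
  A2 <- matrix(c(-0.33, 0.076 / 2, 0.076 / 2, -0.069), 2)
  sp <- drop(solve(2 * A2, -c(-0.22, 0.084)))
  expect_lt(abs(gf$xi[ij[1]] - sp[1]), 0.011)
  expect_lt(abs(gf$xj[ij[2]] - sp[2]), 0.011)
  expect_error(surface_grid(fit, 1, 1), "distinct")
  expect_error(surface_grid(fit, 1, 9), "out of range")
})
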