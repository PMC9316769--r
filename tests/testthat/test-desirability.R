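two_up <- desirability_spec(c(a = "larger_better", b = "larger_better"))

test_that("OD is the geometric mean and hits 0 and 1 at the extremes", {
  # a run at the observed minimum of any larger-is-better index scores 0
  v <- cbind(a = c(1, 2, 3), b = c(5, 9, 7))
  res <- compute_desirability(v, two_up)
  expect_equal(unname(res$d[1, "a"]), 0)
  expect_equal(res$od[1], 0)
  # all indices at their maxima -> every d = 1, OD = 1
  expect_equal(unname(res$d[3, "a"]), 1)
  expect_equal(compute_desirability(cbind(a = c(0, 1), b = c(0, 1)),
                                    two_up)$od[2], 1)
  # two indices with d = (0.25, 1) -> OD = 0.5
  spec_fixed <- desirability_spec(
    c(a = "larger_better", b = "larger_better"),
    bounds = list(a = c(0, 1), b = c(0, 1)))
  res2 <- compute_desirability(cbind(a = 0.25, b = 1), spec_fixed)
  expect_equal(res2$od, 0.5)
  # OD never exceeds the largest single desirability
  expect_true(all(res$od <= apply(res$d, 1, max) + 1e-12))
})

test_that("geometric-mean OD obeys AM-GM and [0,1] bounds on random tables", {
  set.seed(7)
  for (i in 1:25) {
    v <- matrix(rnorm(8 * 3, 10, 3), 8, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    spec <- desirability_spec(c(a = "larger_better", b = "smaller_better",
                                c = "larger_better"))
    res <- compute_desirability(v, spec)
    expect_true(all(res$d >= 0 & res$d <= 1))
    expect_true(all(res$od <= rowMeans(res$d) + 1e-12))
  }
})

test_that("desirabilities are invariant under positive affine rescaling", {
  set.seed(11)
  v <- matrix(runif(10 * 2), 10, 2, dimnames = list(NULL, c("a", "b")))
  base <- compute_desirability(v, two_up)
  v2 <- v
  v2[, "a"] <- 3.7 * v[, "a"] + 12
  expect_equal(compute_desirability(v2, two_up)$d, base$d,
               tolerance = 1e-12)
})

test_that("reversing an index direction mirrors its desirability", {
  set.seed(3)
  v <- matrix(runif(12), 6, 2, dimnames = list(NULL, c("a", "b")))
  up <- compute_desirability(v, two_up)
  down <- compute_desirability(
    v, desirability_spec(c(a = "smaller_better", b = "larger_better")))
  expect_equal(down$d[, "a"], 1 - up$d[, "a"])
})

test_that("degenerate and out-of-bounds inputs are handled explicitly", {
  v <- cbind(a = c(1, 1, 1), b = c(1, 2, 3))
  expect_error(compute_desirability(v, two_up), "'a'")
  spec_fixed <- desirability_spec(c(a = "larger_better"),
                                  bounds = list(a = c(0, 1)))
  expect_warning(res <- compute_desirability(cbind(a = c(0.5, 2)),
                                             spec_fixed), "clamped")
  expect_equal(unname(res$d[2, "a"]), 1)
  expect_error(compute_desirability(cbind(a = 1), two_up))
  expect_error(desirability_spec(c(a = "bigger")), "unknown direction")
  expect_error(desirability_spec(c(a = "larger_better"),
                                 bounds = list(a = c(2, 1))), "max > min")
})

test_that("single-factor profiles locate the dominating level", {
  # one level dominates every index -> OD = 1 there, and it is the argmax
  v <- rbind(c(1, 1), c(2, 3), c(5, 8))
  colnames(v) <- c("a", "b")
  prof <- single_factor_profile(c(40, 50, 60), v, two_up)
  expect_equal(prof$best_level, 60)
  expect_equal(prof$profile$od[3], 1)

  # two levels, two indices, values [[1,2],[3,4]] -> ODs 0 and 1
  prof2 <- single_factor_profile(c(10, 20),
                                 rbind(c(a = 1, b = 2), c(a = 3, b = 4)),
                                 two_up)
  expect_equal(prof2$profile$od, c(0, 1))

  # unimodal index curves sharing a peak level -> that level is the argmax
  lev <- seq(30, 70, by = 10)
  curve <- function(h) h - (lev - 50)^2 / 100
  v3 <- cbind(a = curve(5), b = curve(9))
  expect_equal(single_factor_profile(lev, v3, two_up)$best_level, 50)

  expect_error(single_factor_profile(1, cbind(a = 1, b = 2), two_up),
               ">= 2 levels")
})
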