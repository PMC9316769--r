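test_that("designed-experiment simulation is seeded and exact at zero noise", {
  d <- bbd_design(uae_factors(), 5)
  y1 <- simulate_bbd_responses(d, printed_beta, 0.02, seed = 7)
  y2 <- simulate_bbd_responses(d, printed_beta, 0.02, seed = 7)
  expect_identical(y1, y2)
  expect_false(identical(y1, simulate_bbd_responses(d, printed_beta, 0.02,
                                                    seed = 8)))

  y0 <- simulate_bbd_responses(d, printed_beta, 0, seed = 1)
  fit <- fit_quadratic(d, y0)
  expect_equal(unname(fit$coef), printed_beta, tolerance = 1e-10)
  expect_error(simulate_bbd_responses(d, printed_beta[1:9], 0, 1),
               "10 coefficients")
})

test_that("wavelength schedules must tile the run", {
  sch <- default_wavelength_schedule()
  expect_equal(nrow(sch), 6)
  expect_equal(sch$t_end[6], 28)
  expect_equal(sch$t_start[-1], sch$t_end[-6])
  expect_error(wavelength_schedule(c(0, 5), c(4, 8), c(300, 310)),
               "contiguous")
  expect_error(wavelength_schedule(0, 0, 300), "t_end > t_start")
})

test_that("a unit-area Gaussian integrates to 1 within 0.1%", {
  sigma <- 0.1
  peaks <- data.frame(rt = 5, height = 1 / (sigma * sqrt(2 * pi)),
                      sigma = sigma)
  chrom <- simulate_chromatogram(peaks, default_wavelength_schedule(),
                                 step_min = 0.001)
  area <- integrate_peaks(chrom, cbind(5 - 5 * sigma, 5 + 5 * sigma))
  expect_equal(area, 1, tolerance = 1e-3)
})

test_that("integration error shrinks with the grid step", {
  sigma <- 0.08
  peaks <- data.frame(rt = 10, height = 1 / (sigma * sqrt(2 * pi)),
                      sigma = sigma)
  err <- vapply(c(0.02, 0.005, 0.001), function(step) {
    chrom <- simulate_chromatogram(peaks, default_wavelength_schedule(),
                                   step_min = step)
    abs(integrate_peaks(chrom, cbind(10 - 0.5, 10 + 0.5)) - 1)
  }, numeric(1))
  expect_true(all(diff(err) <= 1e-12))
})

test_that("peak area is linear in height and zero off-peak", {
  sch <- default_wavelength_schedule()
  p1 <- data.frame(rt = 5, height = 2, sigma = 0.1)
  p2 <- data.frame(rt = 5, height = 4, sigma = 0.1)
  w <- cbind(4, 6)
  a1 <- integrate_peaks(simulate_chromatogram(p1, sch, step_min = 0.002), w)
  a2 <- integrate_peaks(simulate_chromatogram(p2, sch, step_min = 0.002), w)
  expect_equal(a2, 2 * a1, tolerance = 1e-10)

  # an empty window on a noisy baseline integrates to nearly nothing
  chrom <- simulate_chromatogram(p1, sch, baseline_sd = 0.01,
                                 step_min = 0.01, seed = 3)
  a0 <- integrate_peaks(chrom, cbind(15, 17))
  expect_lt(abs(a0), 3 * 0.01 * 2)

  flat <- simulate_chromatogram(p1[0, ], sch)
  expect_true(all(flat$signal == 0))
  expect_error(integrate_peaks(chrom, rbind(c(4, 6), c(5, 7))), "overlap")
  expect_error(simulate_chromatogram(data.frame(rt = 99, height = 1,
                                                sigma = 0.1), sch),
               "within")
})

test_that("segment switches scale a boundary peak between its two responses", {
  sch <- default_wavelength_schedule()
  # response factor 5 at 348 nm (before 7.3 min), 1 at 284 nm (after)
  mk <- function(rt) {
    p <- data.frame(rt = rt, height = 1, sigma = 0.05)
    p$response <- list(c(`348` = 5, `284` = 1))
    p
  }
  area_at <- function(rt) {
    chrom <- simulate_chromatogram(mk(rt), sch, step_min = 0.001)
    integrate_peaks(chrom, cbind(rt - 0.4, rt + 0.4))
  }
  lo <- area_at(8.0)   # fully in the 284 nm segment
  hi <- area_at(5.0)   # fully in the 348 nm segment
  mid <- area_at(7.3)  # straddles the switch
  expect_equal(hi / lo, 5, tolerance = 1e-3)
  expect_gt(mid, lo)
  expect_lt(mid, hi)
})

test_that("simulated calibration points reproduce their truth", {
  conc <- c(2.86, 5.72, 14.3, 35.75, 71.5, 143)
  pts <- simulate_calibration(13.984, -3.0103, conc, 0, seed = 1)
  fit <- fit_calibration(pts$concentration, pts$area)
  expect_equal(fit$slope, 13.984, tolerance = 1e-10)
  expect_identical(pts, simulate_calibration(13.984, -3.0103, conc, 0,
                                             seed = 1))
  expect_error(simulate_calibration(1, 0, c(1, 2), 0, 1), ">= 3")
})

test_that("the pipeline recovers a known optimum from low-noise data", {
  d <- bbd_design(uae_factors(), 5)
  truth <- model_from_beta(printed_beta)
  opt_truth <- maximize_surface(truth)
  y <- simulate_bbd_responses(d, printed_beta, 0.01, seed = 2024)
  opt_fit <- maximize_surface(fit_quadratic(d, y))
  expect_lt(max(abs(opt_fit$x - opt_truth$x)), 0.05)
})
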