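# Sensitivity fits, baseline noise, detection limits, the theoretical
# gamma sensitivity procedure and the concentration LOD.

test_that("sensitivity fitting is exact on collinear data and errors otherwise", {
  n <- seq(1.333, 1.3495, length.out = 6)
  y <- 244.7 * n + 3.2
  fit <- fit_sensitivity(n, y)
  expect_equal(fit$slope, 244.7, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit_sensitivity(n, rep(5, 6))$slope, 0, tolerance = 1e-12)
  expect_error(fit_sensitivity(1.333, 590), "two distinct")
  expect_error(fit_sensitivity(rep(1.333, 4), 1:4), "two distinct")

  # sampling-distribution oracle: with known noise the OLS slope lands
  # within two standard errors of the generating slope
  sigma <- 0.3
  x <- seq(1.333, 1.3495, length.out = 30)
  withr::with_seed(4, yn <- 244.7 * x + rnorm(30, sd = sigma))
  se_theory <- sigma / sqrt(sum((x - mean(x))^2))
  fitn <- fit_sensitivity(x, yn)
  expect_lt(abs(fitn$slope - 244.7), 2 * se_theory)
  expect_equal(fitn$slope_se, se_theory, tolerance = 0.5)
})

test_that("baseline noise is the windowed sample standard deviation", {
  expect_equal(baseline_noise(rep(1.7, 10)), 0)
  expect_equal(baseline_noise(c(0, 2)), sqrt(2), tolerance = 1e-15)
  withr::with_seed(12, v <- rnorm(30, sd = 1e-4))
  est <- baseline_noise(v)
  # chi-squared interval for a sample SD at n = 30
  expect_gt(est, 0.6e-4)
  expect_lt(est, 1.4e-4)
  expect_equal(baseline_noise(c(5, 5, 0, 2), window = c(3, 4)), sqrt(2))
  expect_error(baseline_noise(1:10, window = c(5, 20)), "window")
})

test_that("detection limit follows the noise-over-sensitivity convention", {
  expect_equal(detection_limit(0, 244.7), 0)
  expect_equal(detection_limit(1, -2), 0.5)
  expect_error(detection_limit(0.4, 0), "zero sensitivity")
  expect_error(detection_limit(-0.1, 2), ">= 0")
  res <- calibration_result("gamma", sensitivity = 2.25,
                            baseline_noise = 1.23e-4, response_unit = "a.u.")
  expect_equal(res$lod, 1.23e-4 / 2.25, tolerance = 1e-15)
})

test_that("theoretical gamma sensitivity behaves like the forward model", {
  sc <- test_scene()
  # no wavelength response -> no gamma response
  still <- theoretical_gamma_sensitivity(sc$filter_A, sc$filter_AB, sc$dip,
                                         sensitivity_nm_riu = 0, n_points = 9)
  expect_equal(still$slope, 0, tolerance = 1e-12)
  # aligned default configuration responds positively to a red shift
  th <- theoretical_gamma_sensitivity(sc$filter_A, sc$filter_AB, sc$dip,
                                      n_points = 20)
  expect_gt(th$slope, 0)
  expect_gt(th$r_squared, 0.95)
  # a dip pushed past the wide passband is flagged
  runaway <- dip_model(lambda0 = 597, sensitivity_nm_riu = 2000)
  expect_warning(
    theoretical_gamma_sensitivity(sc$filter_A, sc$filter_AB, runaway,
                                  n_points = 5),
    "leaves the wide passband")
})

test_that("concentration LOD matches the hand-solved examples", {
  lin <- concentration_lod(c(1, 10), c(0.01, 0.1), noise = 0.001, k = 3,
                           mode = "linear")
  expect_equal(lin$c_lod, 0.3, tolerance = 1e-12)
  expect_true(lin$extrapolated)
  expect_equal(concentration_lod(c(1, 10), c(0.01, 0.1), noise = 0,
                                 mode = "linear")$c_lod, 0)
  expect_error(concentration_lod(c(1, 10), c(0.1, 0.01), noise = 1e-3),
               "positive")
  # log mode: solving the fitted response at the k-sigma threshold
  conc <- c(1, 3, 10)
  dg <- 0.02 * log10(conc) + 0.005
  lg <- concentration_lod(conc, dg, noise = 0.001, k = 3)
  expect_equal(10^((3 * 0.001 - 0.005) / 0.02), lg$c_lod, tolerance = 1e-9)
})

test_that("staircase calibration recovers slopes from both channels", {
  proto <- ri_staircase(c(1.333, 1.341, 1.3495), 300)
  states <- protocol_states(proto)
  dip <- dip_model()
  readout <- simulate_dip_readout(proto, dip, period_s = 60, seed = 5L)
  cal <- calibrate_dip(readout, states)
  expect_s3_class(cal, "calibration_result")
  expect_equal(cal$sensitivity, 244.7, tolerance = 0.01 * 244.7)
  expect_gt(cal$baseline_noise, 0)
  expect_equal(cal$lod, cal$baseline_noise / cal$sensitivity, tolerance = 1e-15)

  # gamma channel: synthetic series with known slope and noise
  times <- seq(10, 890, by = 20)
  nvals <- evaluate_protocol(proto, times)
  withr::with_seed(8, gvals <- -0.4 + 2.8 * (nvals - 1.333) +
                     rnorm(length(times), sd = 5e-4))
  ser <- structure(data.frame(time_s = times, gamma_mean = gvals,
                              gamma_sd = 5e-4, n_valid = 100L),
                   class = c("gamma_series", "data.frame"))
  calg <- calibrate_gamma(ser, states)
  expect_equal(calg$sensitivity, 2.8, tolerance = 0.1)
  expect_equal(calg$baseline_noise, 5e-4, tolerance = 0.5)
})
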