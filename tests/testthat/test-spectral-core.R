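# Wavelength-domain forward model: passbands, dip model, band integrals,
# gamma, dip localisation and Gaussian fitting.

test_that("passband has the documented edge geometry and plateau", {
  g <- wavelength_grid(555, 605, 0.5)  # cut-on/cut-off fall on grid samples
  fA <- make_passband(583, 598, peak = 0.85, edge_width = 4.5, grid = g)
  lam <- g$values
  # exactly peak at the band midpoint, half of peak at the 50 % points
  expect_equal(fA$values[lam == 590.5], 0.85, tolerance = 1e-12)
  expect_equal(fA$values[lam == 583], 0.85 / 2, tolerance = 1e-12)
  expect_equal(fA$values[lam == 598], 0.85 / 2, tolerance = 1e-12)
  # transmittance above 80 % across the central plateau
  expect_true(all(fA$values[lam >= 588.5 & lam <= 592.5] >= 0.80))
  # monotone rising and falling edges
  expect_true(all(diff(fA$values[lam >= 578 & lam <= 590]) >= 0))
  expect_true(all(diff(fA$values[lam >= 591 & lam <= 603]) <= 0))
  # the quoted steepness metric: 50 % -> 0.005 % of peak spans edge_width
  edge <- function(target) {
    f <- function(x) {
      u <- pmin(pmax((583 + 0.5 * (4.5 / ((2 / pi) * acos(sqrt(5e-5)) - 0.5)) - x) /
                       (4.5 / ((2 / pi) * acos(sqrt(5e-5)) - 0.5)), 0), 1)
      0.85 * cos(pi * u / 2)^2 - target
    }
    stats::uniroot(f, c(570, 590.5), tol = 1e-10)$root
  }
  expect_equal(edge(0.85 / 2) - edge(0.85 * 5e-5), 4.5, tolerance = 1e-6)
})

test_that("passband construction rejects invalid geometry", {
  g <- test_grid()
  expect_error(make_passband(598, 583, grid = g), "cut_on")
  expect_error(make_passband(540, 590, grid = g), "outside")
  expect_error(make_passband(583, 586, edge_width = 4.5, grid = g), "narrow")
})

test_that("SPR spectrum shifts linearly with refractive index", {
  g <- test_grid()
  dip <- dip_model(lambda0 = 590, sensitivity_nm_riu = 244.7)
  s0 <- spr_spectrum(dip, dip$n0, g)
  expect_equal(g$values[which.min(s0$values)], 590, tolerance = g$step / 2)
  s1 <- spr_spectrum(dip, dip$n0 + 0.01, g)
  expect_equal(g$values[which.min(s1$values)], 590 + 2.447, tolerance = g$step / 2)
  flat <- spr_spectrum(dip_model(depth = 0, baseline = 0.9), 1.335, g)
  expect_equal(flat$values, rep(0.9, length(g$values)), tolerance = 1e-12)
  expect_error(spr_spectrum(dip, 1.5, g), "range")
})

test_that("band intensity matches geometric and closed-form oracles", {
  # unit reflectance x unit illumination through a 15 nm rectangle -> 15
  rect <- rect_band_spectrum(583, 598)
  ones <- new_spectrum(rect$grid, rep(1, length(rect$grid$values)))
  expect_equal(band_intensity(ones, rect, ones), 15, tolerance = 1e-9)

  # dip centred on the boundary of two equal ideal bands -> equal intensities
  g <- wavelength_grid(570, 610, 0.1)
  dip <- dip_model(lambda0 = 590, width_nm = 6)
  refl <- spr_spectrum(dip, dip$n0, g)
  band1 <- new_spectrum(g, as.numeric(g$values >= 590 & g$values <= 605))
  band2 <- new_spectrum(g, as.numeric(g$values >= 575 & g$values <= 590))
  expect_equal(band_intensity(refl, band1), band_intensity(refl, band2),
               tolerance = 1e-10)

  # Gaussian x rectangle against the erf closed form
  gg <- wavelength_grid(583, 598, 0.02)
  mu <- 590; sig <- 8; depth <- 0.5; base <- 0.9
  refl2 <- new_spectrum(gg, base - depth * exp(-(gg$values - mu)^2 / (2 * sig^2)))
  rect2 <- new_spectrum(gg, rep(1, length(gg$values)))
  analytic <- base * 15 -
    depth * sig * sqrt(2 * pi) * (pnorm((598 - mu) / sig) - pnorm((583 - mu) / sig))
  expect_equal(band_intensity(refl2, rect2), analytic, tolerance = 1e-6)

  # mismatched grids are rejected
  expect_error(band_intensity(refl, rect2), "grid")
})

test_that("gamma identities, bounds and invariances hold", {
  expect_identical(gamma_value(0.5, 1), 0)
  expect_identical(gamma_value(1, 1), 1)
  expect_equal(gamma_value(0.6, 1), 0.2, tolerance = 1e-15)
  set.seed(11)
  I_AB <- runif(200, 0.1, 10)
  I_A <- runif(200) * I_AB
  I_B <- I_AB - I_A
  # the two published algebraic forms agree
  expect_equal(gamma_value(I_A, I_AB), (I_A - I_B) / (I_A + I_B),
               tolerance = 1e-12)
  # antisymmetry under band swap, scale invariance, and [-1, 1] bounds
  expect_equal(gamma_value(I_B, I_AB), -gamma_value(I_A, I_AB), tolerance = 1e-12)
  expect_equal(gamma_value(3.7 * I_A, 3.7 * I_AB), gamma_value(I_A, I_AB),
               tolerance = 1e-12)
  expect_true(all(abs(gamma_value(I_A, I_AB)) <= 1 + 1e-12))
  expect_error(gamma_value(0.5, 0), "positive")
  expect_error(gamma_value(-0.1, 1), "non-negative")
})

test_that("find_dip locates the in-band minimum and flags boundary hits", {
  g <- test_grid()
  dip <- dip_model(lambda0 = 590)
  for (n in seq(1.333, 1.3495, length.out = 7)) {
    s <- spr_spectrum(dip, n, g)
    expect_equal(as.numeric(find_dip(s, band = c(562, 598))),
                 dip_center(dip, n), tolerance = g$step / 2 + 1e-9)
  }
  # dip outside the band: the minimum pins to the boundary and is flagged
  out <- spr_spectrum(dip_model(lambda0 = 600), 1.333, g)
  expect_warning(res <- find_dip(out, band = c(562, 598)), "boundary")
  expect_true(attr(res, "on_boundary"))
  flat <- new_spectrum(g, rep(0.5, length(g$values)))
  expect_error(find_dip(flat), "constant")
})

test_that("quadratic refinement beats the raw grid minimum", {
  coarse <- wavelength_grid(562, 598, 0.5)
  true_center <- 590.23  # deliberately off-grid
  s <- new_spectrum(coarse,
                    0.9 - 0.5 * exp(-(coarse$values - true_center)^2 / (2 * 36)))
  # brute-force oracle: argmin of the same analytic curve on a 100x finer grid
  fine <- seq(562, 598, by = 0.005)
  oracle <- fine[which.min(0.9 - 0.5 * exp(-(fine - true_center)^2 / (2 * 36)))]
  refined <- as.numeric(find_dip(s, band = c(562, 598), refine = TRUE))
  expect_lt(abs(refined - oracle), 0.5 * coarse$step)
  raw <- as.numeric(find_dip(s, band = c(562, 598), refine = FALSE))
  expect_lte(abs(refined - true_center), abs(raw - true_center))
})

test_that("Gaussian dip fitting recovers parameters and rejects bad input", {
  g <- test_grid()
  s <- spr_spectrum(dip_model(lambda0 = 590, width_nm = 8, depth = 0.5,
                              baseline = 0.9), 1.333, g)
  fit <- fit_gaussian_dip(s)
  expect_equal(fit$lambda0, 590, tolerance = 1e-6)
  expect_equal(fit$width_nm, 8, tolerance = 1e-6)
  expect_equal(fit$depth, 0.5, tolerance = 1e-6)
  expect_equal(fit$baseline, 0.9, tolerance = 1e-6)
  expect_lt(attr(fit, "residual_norm"), 1e-8)

  noisy <- withr::with_seed(7, new_spectrum(
    g, s$values + rnorm(length(g$values), sd = 0.01)))
  fitn <- fit_gaussian_dip(noisy)
  expect_lt(abs(fitn$lambda0 - 590), 0.2)

  ramp <- new_spectrum(g, seq(0, 1, length.out = length(g$values)))
  expect_error(fit_gaussian_dip(ramp), "minimum")
  flat <- new_spectrum(g, rep(0.4, length(g$values)))
  expect_error(fit_gaussian_dip(flat), "flat")
})

test_that("spectra survive a CSV round trip", {
  g <- wavelength_grid(560, 600, 0.5)
  s <- make_passband(570, 590, grid = g)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(s, path)
  back <- read_spectrum_csv(path)
  expect_equal(back$grid$values, g$values, tolerance = 1e-9)
  expect_equal(back$values, s$values, tolerance = 1e-12)
  onto <- read_spectrum_csv(path, grid = wavelength_grid(565, 595, 0.25))
  expect_equal(length(onto$values), length(onto$grid$values))
})
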