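# Synthetic DBSI generation: mosaic geometry, refractive-index protocols,
# frame rendering against the scalar optical model, and noise behaviour.

test_that("mosaic geometry follows the checkerboard parity rule", {
  geom <- mosaic_geometry(4, 4, 4, 0)
  tiles <- tile_class_map(geom)
  px <- pixel_class_map(geom)
  expect_identical(dim(px), c(16L, 16L))
  expect_true(tiles[1, 1])    # tile (0, 0) carries filter A
  expect_false(tiles[1, 2])   # tile (0, 1) carries filter AB
  expect_identical(tiles, t(tiles))
  single <- mosaic_geometry(1, 1, 10, 0)
  expect_true(all(pixel_class_map(single)))
  expect_error(mosaic_geometry(2, 2, 0, 0), "tile_px")
  # flipping parity inverts every tile class
  expect_identical(tile_class_map(mosaic_geometry(4, 4, 4, 1)), !tiles)
})

test_that("protocols evaluate to the closed-form index trajectories", {
  p1 <- ri_protocol(ri_step(100, 1.333))
  expect_equal(evaluate_protocol(p1, c(0, 50, 100)), rep(1.333, 3))
  expect_error(evaluate_protocol(p1, 150), "span")

  k_obs <- 0.02; dn <- 0.004
  p2 <- ri_protocol(ri_step(60, 1.333), ri_langmuir(600, dn, k_obs))
  # value at one time constant, and approach to the asymptote
  expect_equal(evaluate_protocol(p2, 60 + 1 / k_obs),
               1.333 + dn * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(evaluate_protocol(p2, 660), 1.333 + dn, tolerance = dn * 1e-4)

  p3 <- ri_protocol(ri_step(60, 1.333), ri_langmuir(300, dn, k_obs),
                    ri_wash(600, k_obs, residual_fraction = 0.25))
  n_end_assoc <- evaluate_protocol(p3, 360)
  # wash decays toward baseline plus the residual bound fraction
  target <- 1.333 + 0.25 * (n_end_assoc - 1.333)
  expect_equal(evaluate_protocol(p3, 960), target,
               tolerance = (n_end_assoc - target) * 1e-4 + 1e-12)
  expect_error(ri_protocol(ri_langmuir(60, dn, k_obs)), "step")
  expect_error(ri_protocol(ri_step(100, 1.333), ri_langmuir(600, 0.1, 0.02)),
               "range")
})

test_that("rendered tiles reproduce the scalar optical model exactly", {
  sc <- test_scene()
  geom <- mosaic_geometry(6, 6, 4, 0)
  gain <- 120
  fr <- render_frame(geom, 1.340, sc$dip, sc$filter_A, sc$filter_AB,
                     gain = gain, artifact_width = 0, noise = NULL)
  px <- pixel_class_map(geom)
  # direct composition oracle: band_intensity through the same filters
  refl <- spr_spectrum(sc$dip, 1.340, sc$grid)
  expect_equal(unique(as.numeric(fr[px])),
               gain * band_intensity(refl, sc$filter_A), tolerance = 1e-12)
  expect_equal(unique(as.numeric(fr[!px])),
               gain * band_intensity(refl, sc$filter_AB), tolerance = 1e-12)
  # narrow-band tiles are uniformly darker than wide-band tiles
  expect_true(max(fr[px]) < min(fr[!px]))
  # spatial homogeneity within each class
  expect_length(unique(as.numeric(fr[px])), 1L)
  expect_length(unique(as.numeric(fr[!px])), 1L)
})

test_that("artifact band takes the configured mixture of class values", {
  sc <- test_scene()
  geom <- mosaic_geometry(4, 4, 4, 0)
  fr0 <- render_frame(geom, 1.335, sc$dip, sc$filter_A, sc$filter_AB,
                      gain = 100, artifact_width = 0)
  fr1 <- render_frame(geom, 1.335, sc$dip, sc$filter_A, sc$filter_AB,
                      gain = 100, artifact_width = 1, artifact_mix = 0.5)
  px <- pixel_class_map(geom)
  vA <- unique(as.numeric(fr0[px])); vAB <- unique(as.numeric(fr0[!px]))
  boundary <- fr1 != fr0
  expect_true(any(boundary))
  expect_equal(unique(as.numeric(fr1[boundary])), (vA + vAB) / 2,
               tolerance = 1e-12)
  # interior pixels are untouched by the artifact band
  expect_identical(as.numeric(fr1[!boundary]), as.numeric(fr0[!boundary]))
})

test_that("rendering is deterministic under a fixed noise seed", {
  sc <- test_scene()
  geom <- mosaic_geometry(4, 4, 4, 0)
  nm <- noise_model(read_sigma = 2, shot = TRUE, seed = 99L)
  f1 <- render_frame(geom, 1.335, sc$dip, sc$filter_A, sc$filter_AB, noise = nm)
  f2 <- render_frame(geom, 1.335, sc$dip, sc$filter_A, sc$filter_AB, noise = nm)
  expect_identical(unclass(f1), unclass(f2))
  f3 <- render_frame(geom, 1.335, sc$dip, sc$filter_A, sc$filter_AB,
                     noise = noise_model(2, TRUE, 100L))
  expect_false(identical(as.numeric(f1), as.numeric(f3)))
  expect_true(all(f1 >= 0 & f1 <= 2^12 - 1))
})

test_that("filter nesting is enforced at render time", {
  sc <- test_scene()
  geom <- mosaic_geometry(2, 2, 4, 0)
  expect_error(
    render_frame(geom, 1.335, sc$dip, filter_A = sc$filter_AB,
                 filter_AB = sc$filter_A),
    "nested")
})

test_that("sequences follow the protocol and carry a consistent truth table", {
  sc <- test_scene()
  geom <- mosaic_geometry(4, 4, 4, 0)
  const <- ri_protocol(ri_step(100, 1.335))
  seq1 <- render_sequence(geom, const, sc$dip, sc$filter_A, sc$filter_AB,
                          frame_period_s = 20, noise = NULL)
  expect_length(seq1$frames, 5L)
  for (f in seq1$frames[-1]) expect_equal(unclass(f), unclass(seq1$frames[[1]]),
                                          ignore_attr = TRUE)

  two <- ri_protocol(ri_step(60, 1.334), ri_step(60, 1.340))
  seq2 <- render_sequence(geom, two, sc$dip, sc$filter_A, sc$filter_AB,
                          frame_period_s = 20, noise = NULL)
  vals <- vapply(seq2$frames, function(f) f[1, 1], numeric(1))
  expect_length(unique(vals), 2L)
  expect_identical(which(diff(vals) != 0), 3L)  # change at the step time

  # ground-truth gamma is self-consistent with the stored intensities
  expect_equal(seq2$truth$gamma,
               gamma_value(seq2$truth$I_A, seq2$truth$I_AB), tolerance = 1e-12)

  # monotone staircase -> non-decreasing true gamma
  stair <- ri_staircase(seq(1.333, 1.3495, length.out = 5), 60)
  seq3 <- render_sequence(geom, stair, sc$dip, sc$filter_A, sc$filter_AB,
                          frame_period_s = 30, noise = NULL)
  expect_true(all(diff(seq3$truth$gamma) >= 0))
  expect_error(render_sequence(geom, ri_protocol(ri_step(5, 1.333)), sc$dip,
                               sc$filter_A, sc$filter_AB, frame_period_s = 20),
               "too short")
})

test_that("gamma noise shrinks with tile size as 1/tile_px", {
  sc <- test_scene(step = 0.2)
  const <- ri_protocol(ri_step(1600, 1.335))
  frame_gamma_sd <- function(tile_px) {
    geom <- mosaic_geometry(8, 8, tile_px, 0)
    stk <- render_sequence(geom, const, sc$dip, sc$filter_A, sc$filter_AB,
                           frame_period_s = 20, artifact_width = 0,
                           noise = noise_model(2, TRUE, 123L))
    gm <- vapply(stk$frames, function(f) {
      b <- demosaic_frame(f, tile_px = tile_px, parity = 0)
      mean(gamma_map(b), na.rm = TRUE)
    }, numeric(1))
    sd(gm)
  }
  ratio <- frame_gamma_sd(2) / frame_gamma_sd(4)
  # expected factor 2 (four times the averaged pixels); generous band
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.8)
})
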