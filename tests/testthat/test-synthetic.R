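test_that("voltammogram generator reproduces its building blocks", {
  # null signal
  v0 <- gen_voltammogram()
  expect_length(v0$potential, 261L)
  expect_true(all(v0$current == 0))

  # Gaussian apex lands on the grid point at the peak center
  v1 <- gen_voltammogram(list(peak_spec(0.34, 1.0, 0.03)))
  expect_equal(max(v1$current), 1.0, tolerance = 1e-12)
  expect_equal(v1$potential[which.max(v1$current)], 0.34,
               tolerance = 1e-9)

  # two peaks recovered by detection within one grid step
  v2 <- gen_voltammogram(list(peak_spec(0.34, 0.50, 0.03),
                              peak_spec(0.50, 0.80, 0.03)))
  p <- detect_peaks(v2)
  expect_lt(abs(p$e1 - 0.34), 0.005 + 1e-12)
  expect_lt(abs(p$e2 - 0.50), 0.005 + 1e-12)

  # a peak outside the scan range is refused by name
  expect_error(gen_voltammogram(list(peak_spec(1.5, 1, 0.03))),
               "peak 1")
})

test_that("seeded generators are reproducible bit for bit", {
  v1 <- gen_voltammogram(list(peak_spec(0.4, 1)), noise_sd = 0.05,
                         seed = 7)
  v2 <- gen_voltammogram(list(peak_spec(0.4, 1)), noise_sd = 0.05,
                         seed = 7)
  expect_identical(v1$current, v2$current)

  sc <- toast_scenario("light", seed = 11)
  expect_identical(gen_eci_series(sc)$eci, gen_eci_series(sc)$eci)

  ts <- texture_preset("medium", seed = 3)
  expect_identical(gen_texture_image(ts), gen_texture_image(ts))
})

test_that("ECI series generator matches the closed-form kinetic model", {
  # amplitudes zero: constant at the equilibrium level
  sc0 <- kinetic_scenario(0.4, 0, 0.3, 0, 0.3, noise_sd = 0)
  s0 <- gen_eci_series(sc0, 0:20)
  expect_true(all(s0$eci == 0.4))

  # light-toast scenario, zero noise: pointwise equal to the model with
  # canonical signs, rising from ~0 with a first-week maximum, relaxing
  # toward the published equilibrium 0.168
  sc <- toast_scenario("light", noise_sd = 0, late_slope = 0)
  days <- 0:90
  s <- gen_eci_series(sc, days)
  p <- toast_kinetic_params("light")
  expect_equal(s$eci, eci_model(p, days), tolerance = 1e-15)
  expect_equal(s$eci[1], 0.168 - 20.848 + 20.651, tolerance = 1e-12)
  expect_lt(which.max(s$eci), 9)          # peak within the first week
  expect_equal(eci_model(p, 1e6), 0.168, tolerance = 1e-12)

  # the late ramp is additive beyond its onset
  sc_ramp <- toast_scenario("light", noise_sd = 0, late_slope = 0.002,
                            late_onset = 60)
  s_ramp <- gen_eci_series(sc_ramp, days)
  expect_equal(s_ramp$eci - s$eci, pmax(days - 60, 0) * 0.002,
               tolerance = 1e-12)
})

test_that("texture generator spans the heterogeneity of toast levels", {
  # degenerate scenario: constant image at the base level
  flat <- texture_scenario(image_size = 32, grain_amplitude = 0,
                           speckle_density = 0, noise_sd = 0,
                           base_level = 140)
  img <- gen_texture_image(flat)
  expect_true(all(img == 140L))

  # char-speckled "intense" preset is higher-contrast and less
  # homogeneous than "light", on average over seeds
  stats_for <- function(level, seed) {
    m <- glcm_features(gen_texture_image(
      texture_preset(level, image_size = 64, seed = seed)))$average
    c(contrast = m$contrast, homogeneity = m$homogeneity)
  }
  light <- vapply(1:10, function(s) stats_for("light", s), numeric(2))
  intense <- vapply(1:10, function(s) stats_for("intense", s), numeric(2))
  expect_gt(mean(intense["contrast", ]), mean(light["contrast", ]))
  expect_lt(mean(intense["homogeneity", ]), mean(light["homogeneity", ]))
})

test_that("feature matrix assembly honours the canonical layout", {
  fm <- assemble_feature_matrix()
  expect_identical(dim(fm), c(3L, 11L))
  expect_identical(rownames(fm), c("light", "medium", "intense"))
  expect_identical(colnames(fm), feature_variables())
  expect_equal(unname(fm[, "A1"]), c(20.848, 16.810, 8.187))
  expect_equal(unname(fm[, "Raman_G"]), c(1.14, 1.09, 4.32))

  # omitting a descriptor is an error naming the variable
  desc <- default_descriptors()
  desc$Entropy <- NULL
  expect_error(assemble_feature_matrix(descriptors = desc), "Entropy")
})
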