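test_that("peak detection recovers synthetic peaks and flags absences", {
  v <- gen_voltammogram(list(peak_spec(0.34, 0.5, 0.03),
                             peak_spec(0.50, 0.8, 0.03)))
  p <- detect_peaks(v)
  expect_lt(abs(p$e1 - 0.34), 0.005 + 1e-12)
  expect_lt(abs(p$e2 - 0.50), 0.005 + 1e-12)
  # the neighbouring Gaussian's tail contributes ~5e-7 uA at 0.34 V
  expect_lt(abs(p$i1 - 0.5), 1e-5)
  expect_lt(abs(p$i2 - 0.8), 1e-5)
  expect_true(p$present1 && p$present2)

  # flat zero scan: both peaks absent with zero current
  flat <- voltammogram(seq(-0.3, 1, 0.005), rep(0, 261))
  pf <- detect_peaks(flat)
  expect_false(pf$present1)
  expect_false(pf$present2)
  expect_identical(c(pf$i1, pf$i2), c(0, 0))

  # windows must stay inside the scan range
  short <- voltammogram(seq(0.3, 0.52, 0.005),
                        rep(1, length(seq(0.3, 0.52, 0.005))))
  expect_error(detect_peaks(short), "outside the scan range")
})

test_that("linear baseline correction removes drift and offsets", {
  base <- gen_voltammogram(list(peak_spec(0.34, 0.5, 0.03),
                                peak_spec(0.50, 0.8, 0.03)))
  p0 <- detect_peaks(base)

  drift <- gen_voltammogram(list(peak_spec(0.34, 0.5, 0.03),
                                 peak_spec(0.50, 0.8, 0.03)),
                            baseline_slope = 0.1)
  pd <- detect_peaks(drift, baseline = "linear")
  expect_equal(pd$i1, p0$i1, tolerance = 1e-6)
  expect_equal(pd$i2, p0$i2, tolerance = 1e-6)

  # invariance to a constant current offset
  off <- voltammogram(base$potential, base$current + 3.7)
  po <- detect_peaks(off, baseline = "linear")
  pb <- detect_peaks(base, baseline = "linear")
  expect_equal(po$i1, pb$i1, tolerance = 1e-9)
  expect_equal(po$i2, pb$i2, tolerance = 1e-9)
})

test_that("the index is the sum of current/potential ratios", {
  expect_equal(compute_eci(peak_set(0.34, 0, 0.50, 0,
                                    present1 = FALSE,
                                    present2 = FALSE)), 0)
  expect_equal(compute_eci(peak_set(0.34, 0.34, 0.50, 0.50)), 2.0)
  expect_equal(compute_eci(peak_set(0.34, 0.12, 0.50, 0.20)),
               0.12 / 0.34 + 0.20 / 0.50, tolerance = 1e-12)
  expect_error(peak_set(-0.1, 1, 0.5, 1), "positive")

  # degree-1 homogeneity in the currents, random peak pairs
  set.seed(42)
  for (i in 1:25) {
    e <- sort(runif(2, 0.1, 0.9))
    cur <- runif(2, 0, 5)
    p1 <- peak_set(e[1], cur[1], e[2], cur[2])
    p2 <- peak_set(e[1], 2 * cur[1], e[2], 2 * cur[2])
    expect_equal(compute_eci(p2), 2 * compute_eci(p1), tolerance = 1e-12)
  }
})

test_that("ECI time series assembly sorts, validates and round-trips", {
  vs <- lapply(3:1, function(d) {
    gen_voltammogram(list(peak_spec(0.34, 0.1 * d, 0.03)), day = d,
                     toast_level = "light")
  })
  s <- eci_timeseries(vs)
  expect_s3_class(s, "eci_series")
  expect_identical(nrow(s), 3L)
  expect_identical(s$day, c(1, 2, 3))

  # duplicate (day, replicate) measurements are refused
  expect_error(eci_timeseries(c(vs, vs[1])), "duplicate")

  # empty input gives an empty series
  expect_identical(nrow(eci_timeseries(list())), 0L)

  # end-to-end: voltammograms tracking the light-toast curve reproduce
  # the generated kinetics within peak-detection tolerance
  sc <- toast_scenario("light", noise_sd = 0, late_slope = 0)
  days <- 1:20
  vs2 <- gen_voltammogram_series(sc, days, toast_level = "light")
  got <- eci_timeseries(vs2)
  want <- gen_eci_series(sc, days, toast_level = "light")
  expect_equal(got$eci, want$eci, tolerance = 1e-4)
})

test_that("CSV round trips preserve scans, series and the index", {
  d <- withr::local_tempdir()
  v <- gen_voltammogram(list(peak_spec(0.34, 0.5, 0.03),
                             peak_spec(0.50, 0.8, 0.03)),
                        noise_sd = 0.01, seed = 5, day = 3,
                        toast_level = "medium")
  f <- file.path(d, "v.csv")
  write_voltammogram(v, f)
  v2 <- read_voltammogram(f)
  expect_equal(compute_eci(detect_peaks(v2)),
               compute_eci(detect_peaks(v)), tolerance = 1e-12)
  expect_identical(v2$toast_level, "medium")

  s <- gen_eci_series(toast_scenario("medium", seed = 1), 0:30,
                      toast_level = "medium")
  f2 <- file.path(d, "s.csv")
  write_eci_series(s, f2)
  s2 <- read_eci_series(f2)
  expect_equal(s2$eci, s$eci, tolerance = 1e-12)
  expect_error(read_eci_series(file.path(d, "nope.csv")), "nope.csv")
})
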