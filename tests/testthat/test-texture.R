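test_that("quantization maps bit depths onto 256 levels", {
  img8 <- matrix(c(0, 17, 128, 255), 2, 2)
  expect_identical(quantize(img8), matrix(as.integer(img8), 2, 2))

  img16 <- matrix(c(0, 65535, 0, 65535), 2, 2)
  expect_identical(unique(as.vector(quantize(img16))), c(0L, 255L))

  # 32768/65535 * 255 = 127.50194 rounds (half-even rule) to 128
  expect_true(all(quantize(matrix(32768, 3, 3)) == 128L))

  expect_error(quantize(array(0, c(4, 4, 3))), "grayscale")
})

test_that("co-occurrence matrices match hand enumeration", {
  # constant 2x2 image: all mass at P(0,0)
  g <- compute_glcm(matrix(0L, 2, 2), angle = 0)
  expect_equal(g$probabilities[1, 1], 1)
  expect_equal(sum(g$probabilities), 1)

  # 1x3 gradient at 0 degrees, symmetrized: pairs (0,1),(1,2) plus their
  # transposes, each with probability 1/4
  g2 <- compute_glcm(matrix(c(0L, 1L, 2L), 1, 3), angle = 0)
  P <- g2$probabilities
  expect_equal(P[1, 2], 0.25)
  expect_equal(P[2, 1], 0.25)
  expect_equal(P[2, 3], 0.25)
  expect_equal(P[3, 2], 0.25)
  expect_equal(sum(P), 1)

  # symmetrized GLCMs equal their transpose exactly; probabilities are a
  # distribution for every angle
  set.seed(1)
  img <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
  for (a in c(0, 45, 90, 135)) {
    ga <- compute_glcm(img, a)
    expect_identical(ga$probabilities, t(ga$probabilities))
    expect_lt(abs(sum(ga$probabilities) - 1), 1e-9)
  }

  expect_error(compute_glcm(matrix(0L, 1, 1), 0), "too small")
  expect_error(compute_glcm(img, 30), "angle")
})

test_that("texture metrics agree with direct hand evaluation", {
  # degenerate one-cell distribution
  P1 <- matrix(0, 256, 256)
  P1[5, 5] <- 1
  expect_warning(m1 <- texture_metrics(P1), "undefined")
  expect_equal(m1$entropy, 0)
  expect_equal(m1$energy, 1)
  expect_equal(m1$homogeneity, 1)
  expect_equal(m1$contrast, 0)
  expect_true(is.na(m1$correlation))

  # uniform distribution over all cells
  Pu <- matrix(1 / 256^2, 256, 256)
  mu <- texture_metrics(Pu)
  expect_equal(mu$entropy, 16, tolerance = 1e-9)
  expect_equal(mu$energy, 256^-2, tolerance = 1e-15)

  # the 1x3 gradient case, evaluated over its four equal cells by hand
  m3 <- texture_metrics(compute_glcm(matrix(c(0L, 1L, 2L), 1, 3), 0))
  expect_equal(m3$contrast, 1.0)
  expect_equal(m3$homogeneity, 0.5)
  expect_equal(m3$energy, 0.25)
  expect_equal(m3$entropy, 2)
})

test_that("metrics match the brute-force oracle on random images", {
  set.seed(99)
  for (rep_ in 1:8) {
    img <- matrix(sample(0:255, 16 * 16, replace = TRUE), 16, 16)
    a <- sample(c(0, 45, 90, 135), 1)
    P <- compute_glcm(img, a)$probabilities
    got <- texture_metrics(P)
    want <- oracle_texture_metrics(P)
    for (nm in c("contrast", "entropy", "homogeneity", "energy",
                 "correlation")) {
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-10)
    }
  }
})

test_that("direction averaging is an arithmetic mean with NA contamination", {
  m <- function(con) {
    structure(list(contrast = con, entropy = 1, homogeneity = 0.5,
                   energy = 0.1, correlation = 0.2),
              class = "texture_metrics")
  }
  avg <- direction_average(list(m(1), m(2), m(3), m(4)))
  expect_equal(avg$contrast, 2.5)
  expect_equal(avg$entropy, 1)

  four_same <- direction_average(list(m(2), m(2), m(2), m(2)))
  expect_equal(four_same$contrast, 2)

  bad <- m(1)
  bad$correlation <- NA_real_
  expect_true(is.na(direction_average(list(m(1), m(2), m(3),
                                           bad))$correlation))
  expect_error(direction_average(list(m(1), m(2), m(3))), "four")

  # direction-averaged contrast is invariant under image transposition
  set.seed(7)
  img <- matrix(sample(0:63, 32 * 32, replace = TRUE), 32, 32)
  c1 <- glcm_features(img)$average$contrast
  c2 <- glcm_features(t(img))$average$contrast
  expect_equal(c1, c2, tolerance = 1e-12)
})

test_that("heterogeneity map is a windowed standard deviation", {
  expect_true(all(heterogeneity_map(matrix(7, 20, 20), 5) == 0))
  expect_error(heterogeneity_map(matrix(0, 10, 10), 4), "odd")

  # step edge: maxima sit along the edge; values match brute force
  img <- cbind(matrix(0, 32, 16), matrix(100, 32, 16))
  hm <- heterogeneity_map(img, 5)
  expect_true(all(hm >= 0))
  expect_true(all(which(hm == max(hm), arr.ind = TRUE)[, "col"] %in%
                    15:18))
  expect_equal(hm, oracle_local_sd(img, 5), tolerance = 1e-10)

  set.seed(3)
  rnd <- matrix(runif(32 * 32, 0, 255), 32, 32)
  expect_equal(heterogeneity_map(rnd, 7), oracle_local_sd(rnd, 7),
               tolerance = 1e-9)
})

test_that("gray PNG files round-trip through disk", {
  d <- withr::local_tempdir()
  img <- gen_texture_image(texture_preset("light", image_size = 48,
                                          seed = 2))
  f <- file.path(d, "stave.png")
  write_gray_png(img, f)
  expect_identical(read_gray_png(f), img)
})
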