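ref <- reference_kinetics()

test_that("standardization centers and scales with the n-1 convention", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  z <- standardize_features(m)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_equal(colMeans(z), c(a = 0, b = 0), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), c(a = 1, b = 1), tolerance = 1e-12)

  # idempotence
  expect_equal(standardize_features(z), z, tolerance = 1e-12)

  # the published A1 column standardizes with light most positive
  zA <- standardize_features(cbind(A1 = ref$A1))
  expect_equal(mean(zA), 0, tolerance = 1e-12)
  expect_equal(sd(zA), 1, tolerance = 1e-12)
  expect_identical(which.max(zA), 1L)  # light row

  expect_error(standardize_features(cbind(ok = 1:3, flat = c(2, 2, 2))),
               "flat")
})

test_that("PCA of three observations spans exactly two components", {
  set.seed(5)
  m <- matrix(rnorm(33), 3, 11,
              dimnames = list(c("light", "medium", "intense"),
                              paste0("v", 1:11)))
  p <- run_pca(m)
  expect_identical(ncol(p$loadings), 2L)
  expect_equal(sum(p$explained_pct), 100, tolerance = 1e-6)

  # loadings are orthonormal and reconstruct the standardized data
  expect_equal(crossprod(p$loadings), diag(2), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(p$scores %*% t(p$loadings), standardize_features(m),
               tolerance = 1e-9, ignore_attr = TRUE)

  # sign convention: the largest-magnitude loading entry is positive
  for (j in 1:2) {
    expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  }

  # two perfectly correlated variables collapse onto one component
  m2 <- cbind(x = c(1, 2, 4), y = c(2, 4, 8))
  p2 <- run_pca(m2)
  expect_equal(p2$explained_pct[1], 100, tolerance = 1e-6)

  expect_error(run_pca(m[1, , drop = FALSE]), "2 observations")
})

test_that("Spearman's rho reproduces monotone trends in the parameter table", {
  expect_equal(spearman_rho(ref$A1, ref$A2), 1.0)
  expect_equal(spearman_rho(ref$A1, ref$k1), -1.0)
  x <- c(3, 1, 2)
  expect_equal(spearman_rho(x, x), 1.0)

  # invariance under strictly monotone transforms
  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(7)
    b <- rnorm(7)
    rho <- spearman_rho(a, b)
    expect_equal(spearman_rho(exp(a), b), rho, tolerance = 1e-12)
    expect_equal(spearman_rho(a, b^3), rho, tolerance = 1e-12)
  }

  # tie handling matches the first-principles oracle
  for (i in 1:20) {
    a <- sample(1:4, 8, replace = TRUE)
    b <- sample(1:4, 8, replace = TRUE)
    if (var(a) == 0 || var(b) == 0) next
    expect_equal(spearman_rho(a, b), oracle_spearman(a, b),
                 tolerance = 1e-12)
  }

  # every printed-column pair of the parameter table agrees with the
  # oracle ranks
  cols <- c("ECI_eq", "A1", "k1", "A2", "k2")
  for (i in seq_along(cols)) {
    for (j in seq_along(cols)) {
      if (i < j) {
        expect_equal(spearman_rho(ref[[cols[i]]], ref[[cols[j]]]),
                     oracle_spearman(ref[[cols[i]]], ref[[cols[j]]]),
                     tolerance = 1e-12)
      }
    }
  }

  expect_warning(r0 <- spearman_rho(c(1, 1, 1), 1:3), "undefined")
  expect_true(is.na(r0))
  expect_error(spearman_rho(1:3, 1:4), "equal length")
})

test_that("one-way ANOVA matches the textbook decomposition", {
  # hand-computed case: SSb = 4, SSw = 1.5, F = (4/2)/(1.5/3) = 4
  an <- one_way_anova(list(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(an$f_stat, 4.0, tolerance = 1e-12)
  expect_identical(an$df_between, 2L)
  expect_identical(an$df_within, 3L)
  expect_equal(an$p_value, stats::pf(4, 2, 3, lower.tail = FALSE),
               tolerance = 1e-12)

  # identical groups: no between-group variance
  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$f_stat, 0)

  # zero within-group variance with distinct means is degenerate
  deg <- one_way_anova(list(c(0, 0), c(1, 1)))
  expect_true(deg$degenerate)
  expect_identical(deg$f_stat, Inf)

  expect_error(one_way_anova(list(1, c(1, 2))), "at least 2 values")
})

test_that("permuted null data give a central F on average", {
  set.seed(31)
  vals <- rnorm(30)
  fs <- replicate(500, {
    lab <- sample(rep(1:3, each = 10))
    one_way_anova(split(vals, lab))$f_stat
  })
  df_w <- 27
  expect_lt(abs(mean(fs) - df_w / (df_w - 2)) / (df_w / (df_w - 2)), 0.15)
})
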