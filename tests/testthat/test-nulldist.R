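test_that("angle density matches closed forms and special values", {
  # k = 2: uniform on [0, pi]
  expect_equal(dangle(c(0.1, 1.234, 3), 2), rep(1 / pi, 3))
  # k = 3: sin(theta)/2, equatorial peak 0.5
  expect_equal(dangle(pi / 2, 3), 0.5)
  expect_equal(dangle(pi / 4, 3), sin(pi / 4) / 2)
  # k = 76 peak, frozen from a log-beta special-function evaluation
  expect_equal(dangle(pi / 2, 76), 3.443445, tolerance = 1e-6)
  # symmetry about pi/2
  th <- seq(0.1, 1.5, by = 0.2)
  for (k in c(2, 5, 76))
    expect_equal(dangle(th, k), dangle(pi - th, k))
  expect_error(dangle(-0.1, 5), "theta")
  expect_error(dangle(1, 1), "k")
})

test_that("angle density integrates to one across dimensionalities", {
  for (k in c(2, 3, 5, 10, 76, 500)) {
    expect_equal(
      integrate(dangle, 0, pi, k = k, rel.tol = 1e-10)$value, 1,
      tolerance = 1e-8)
  }
})

test_that("correlation density matches closed forms and handles boundaries", {
  # k = 3: constant 1/2 on [-1, 1]
  expect_equal(dveccor(c(-0.9, 0, 0.7), 3), rep(0.5, 3))
  # k = 5 at r = 0: 1/B(1/2, 2) = 3/4 (normalization of (1 - r^2) on [-1,1])
  expect_equal(dveccor(0, 5), 0.75)
  expect_equal(integrate(function(r) (1 - r^2), -1, 1)$value * 0.75, 1)
  # symmetry in r
  expect_equal(dveccor(0.6, 10), dveccor(-0.6, 10))
  # k = 2 singularity at the boundary: +Inf sentinel, finite inside
  expect_identical(dveccor(1, 2), Inf)
  expect_true(is.finite(dveccor(0.999999, 2)))
  expect_error(dveccor(1.5, 3), "r")
  # densities of r integrate to 1
  for (k in c(3, 5, 10, 76))
    expect_equal(integrate(dveccor, -1, 1, k = k, rel.tol = 1e-10)$value,
                 1, tolerance = 1e-8)
})

test_that("angle CDF follows the t-distribution map and closed k = 2, 3 forms", {
  for (k in c(2, 3, 10, 76)) expect_equal(pangle(pi / 2, k), 0.5)
  # k = 2: theta / pi
  th <- c(0.3, 1, 2.5)
  expect_equal(pangle(th, 2), th / pi)
  # k = 3: spherical-cap area fraction (1 - cos)/2
  expect_equal(pangle(th, 3), (1 - cos(th)) / 2)
  expect_equal(pangle(c(0, pi), 7), c(0, 1))
  # monotone, and consistent with quadrature of the density (the grid stays
  # away from the tails, where the CDF saturates in double precision for
  # large k)
  for (k in c(2, 5, 76)) {
    grid <- seq(0.9, pi - 0.9, length.out = 9)
    p <- pangle(grid, k)
    expect_true(all(diff(p) > 0))
    quad <- vapply(grid, function(t)
      integrate(dangle, 0, t, k = k, rel.tol = 1e-10)$value, numeric(1))
    expect_equal(p, quad, tolerance = 1e-8)
  }
})

test_that("qangle inverts pangle", {
  for (k in c(2, 3, 10, 76)) {
    # angles where the CDF does not saturate in double precision at this k
    th <- if (k <= 10) c(0.2, 1.1, pi / 2, 2.8) else c(0.9, 1.3, pi / 2, 2.2)
    expect_equal(qangle(pangle(th, k), k), th, tolerance = 1e-8)
    expect_equal(qangle(0.5, k), pi / 2)
    expect_equal(qangle(c(0, 1), k), c(0, pi))
  }
})

test_that("angle_test covers alternatives, closed forms and input contracts", {
  # null median: two-sided p = 1 at orthogonality
  for (k in c(2, 10, 76))
    expect_equal(angle_test(theta = pi / 2, k = k)$p_value, 1)
  # perfect parallelism
  expect_equal(angle_test(theta = 0, k = 10,
                          alternative = "parallel")$p_value, 0)
  # closed-form k = 3 parallel p at pi/3
  expect_equal(angle_test(theta = pi / 3, k = 3,
                          alternative = "parallel")$p_value, 0.25)
  # antiparallel is the complementary tail
  expect_equal(angle_test(theta = pi / 3, k = 3,
                          alternative = "antiparallel")$p_value, 0.75)
  # axial alternative = upper beta tail of cos^2
  th <- 0.8
  expect_equal(angle_test(theta = th, k = 10, alternative = "axial")$p_value,
               pbeta(cos(th)^2, 0.5, 4.5, lower.tail = FALSE))
  # r input route agrees with theta route and records both scales
  tt <- angle_test(r = 0.5, k = 20)
  expect_equal(tt$statistic, acos(0.5))
  expect_equal(tt$details$theta_deg, 60)
  expect_equal(tt$details$t, sqrt(19) * 0.5 / sqrt(0.75))
  # contracts
  expect_error(angle_test(theta = 1, r = 0.5, k = 5), "exactly one")
  expect_error(angle_test(r = 1.01, k = 5), "tolerance")
  expect_silent(angle_test(r = 1 + 1e-13, k = 5))
})

test_that("effect size standardization is correct and asymptotically normal", {
  expect_equal(angle_effect_size(pi / 2, 100), 0)
  expect_equal(angle_effect_size(pi / 4, 3), pi / 4)
  expect_error(angle_effect_size(1, 2), "k")
  # at k = 500, uniform angles give effect sizes with mean 0, variance 1;
  # cosines drawn by the independent symmetric-beta oracle
  es <- parevo:::with_seed(SEED, {
    angle_effect_size(acos(oracle_cosines(1e5, 500)), 500)
  })
  expect_lt(abs(mean(es)), 0.02)
  expect_lt(abs(var(es) - 1), 0.05)
})

test_that("squared-correlation null moments match the beta law", {
  m <- sqcor_moments(76)
  expect_equal(unname(m["mean"]), 1 / 76)
  expect_equal(unname(m["variance"]), 2 * 75 / (76^2 * 78))
  # numeric moment integration of Beta(1/2, 37.5) as an independent check;
  # substituting s = u^2 removes the s^(-1/2) endpoint singularity so the
  # quadrature is accurate
  mu <- integrate(function(u) u^2 * dbeta(u^2, 0.5, 37.5) * 2 * u,
                  0, 1, rel.tol = 1e-12)$value
  v <- integrate(function(u) (u^2 - mu)^2 * dbeta(u^2, 0.5, 37.5) * 2 * u,
                 0, 1, rel.tol = 1e-12)$value
  expect_equal(unname(m["mean"]), mu, tolerance = 1e-8)
  expect_equal(unname(m["variance"]), v, tolerance = 1e-8)
  # k = 2: arcsine-law moments
  expect_equal(unname(sqcor_moments(2)), c(0.5, 0.125))
  # both moments shrink monotonically in k
  ks <- c(2, 3, 5, 10, 50, 200)
  mm <- t(vapply(ks, sqcor_moments, numeric(2)))
  expect_true(all(diff(mm[, 1]) < 0))
  expect_true(all(diff(mm[, 2]) < 0))
})

test_that("simulated uniform pairs follow the beta and t null laws", {
  # moderate-size KS screens; the full-size versions run in the acceptance
  # suite
  parevo:::with_seed(SEED + 1, {
    for (k in c(3, 10)) {
      X <- matrix(rnorm(2e4 * k), ncol = k)
      Y <- matrix(rnorm(2e4 * k), ncol = k)
      r <- rowSums(X * Y) /
        sqrt(rowSums(X^2) * rowSums(Y^2))
      expect_gt(ks.test(r^2, pbeta, 0.5, (k - 1) / 2)$p.value, 0.01)
      tstat <- sqrt(k - 1) * r / sqrt(1 - r^2)
      expect_gt(ks.test(tstat, pt, df = k - 1)$p.value, 0.01)
    }
  })
})

test_that("effective_dim converts lost degrees of freedom", {
  expect_identical(effective_dim(80, 4), 76L)
  expect_identical(effective_dim(10), 10L)
  expect_error(effective_dim(3, 2), "lost_df")
})
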