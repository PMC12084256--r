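test_that("derived constants follow their definitions and K_M = K_S + K", {
  p <- rate_constants(1, 1, 1, 6)
  expect_equal(derived_constants(p), list(K_M = 2, K_S = 1, K = 1))

  p2 <- rate_constants(0.1, 1, 1, 6)
  dc <- derived_constants(p2)
  expect_equal(dc$K, 10)
  expect_equal(dc$K_S, 10)
  expect_equal(dc$K_M, 20)

  p3 <- rate_constants(2, 3, 0, 1)
  expect_equal(p3$K, 0)
  expect_equal(p3$K_M, p3$K_S)

  for (p in random_params(200)) {
    expect_equal(p$K_M, p$K_S + p$K, tolerance = 1e-14)
  }
  expect_error(rate_constants(0, 1, 1, 1), "strictly positive")
  expect_error(rate_constants(-1, 1, 1, 1), "strictly positive")
  expect_error(rate_constants(1, -1, 1, 1), "nonnegative")
})

test_that("mass-action vector field has the stated structure", {
  p <- rate_constants(2, 3, 5, 4)
  # on the s-axis binding and complex formation are opposite
  f <- mass_action_rhs(c(1, 2.5), c(0, 0), p)
  expect_equal(f$ds, -p$k1 * p$e0 * c(1, 2.5))
  expect_equal(f$dc, -f$ds)
  # origin is stationary
  f0 <- mass_action_rhs(0, 0, p)
  expect_equal(c(f0$ds, f0$dc), c(0, 0))
  # the c-nullcline annihilates dc
  s <- c(0.1, 1, 7, 40)
  cc <- p$e0 * s / (p$K_M + s)
  expect_equal(mass_action_rhs(s, cc, p)$dc, rep(0, 4), tolerance = 1e-12)
})

test_that("origin spectrum matches the eigendecomposition oracle", {
  # reference parameter set k1 = k_neg1 = k2 = 1, e0 = 6:
  # lambda_pm = -4 +/- sqrt(10), m = 2 + sqrt(10) in closed form
  p <- rate_constants(1, 1, 1, 6)
  sp <- origin_spectrum(p)
  expect_equal(sp$lambda_plus, -4 + sqrt(10), tolerance = 1e-12)
  expect_equal(sp$lambda_minus, -4 - sqrt(10), tolerance = 1e-12)
  expect_equal(sp$m, 2 + sqrt(10), tolerance = 1e-12)

  # J (1, m)^T = lambda_plus (1, m)^T against numeric eigenpairs
  for (p in random_params(50, seed = 99)) {
    sp <- origin_spectrum(p)
    J <- matrix(c(-p$k1 * p$e0, p$k1 * p$e0,
                  p$k_neg1, -(p$k_neg1 + p$k2)), 2, 2)
    v <- c(1, sp$m)
    expect_equal(as.numeric(J %*% v), sp$lambda_plus * v,
                 tolerance = 1e-8)
  }

  # singular limit e0 -> 0: lambda_plus -> 0, lambda_minus -> -k1*K_M,
  # m -> 0
  p <- rate_constants(1, 2, 3, 1e-10)
  sp <- origin_spectrum(p)
  expect_lt(abs(sp$lambda_plus), 1e-9)
  expect_equal(sp$lambda_minus, -p$k1 * p$K_M, tolerance = 1e-9)
  expect_lt(sp$m, 1e-9)
  expect_error(origin_spectrum(rate_constants(1, 1, 1, 0)), "e0 > 0")
})

test_that("spectral identities hold to 1e-10 over 1000 draws", {
  for (p in random_params(1000, seed = 2024)) {
    sp <- origin_spectrum(p)
    expect_equal(sp$lambda_plus + sp$lambda_minus,
                 -p$k1 * (p$K_M + p$e0), tolerance = 1e-10)
    expect_equal(sp$lambda_plus * sp$lambda_minus,
                 p$k1^2 * p$K * p$e0, tolerance = 1e-10)
    expect_equal(p$k1 * p$e0 - p$k_neg1 * sp$m, -sp$lambda_plus,
                 tolerance = 1e-10)
    # node never becomes a focus
    expect_lte(4 * p$K * p$e0 / (p$K_M + p$e0)^2, 1 + 1e-14)
  }
})

test_that("cancellation-safe m stays accurate for tiny k1*e0", {
  p <- rate_constants(1e-6, 50, 30, 1e-4)   # k1*e0 = 1e-10 << k_neg1+k2
  sp <- origin_spectrum(p)
  # identity m = (k1*e0 + lambda_plus)/k_neg1 with independently
  # computed eigenvalues ties the conjugate form to the naive one
  ev <- eigen(matrix(c(-p$k1 * p$e0, p$k1 * p$e0,
                       p$k_neg1, -(p$k_neg1 + p$k2)), 2, 2))$values
  lam_plus <- max(ev)
  expect_equal(p$k1 * p$e0 - p$k_neg1 * sp$m, -lam_plus,
               tolerance = 1e-6)
  expect_gt(sp$m, 0)
})

test_that("indicators return the five dimensionless ratios", {
  p0 <- rate_constants(1, 1, 1, 0)
  ind0 <- indicators(p0)
  expect_true(all(unlist(ind0) == 0))

  # large-dissociation predominance comparison parameters
  p <- rate_constants(1, 100, 10, 6)
  ind <- indicators(p)
  expect_equal(ind$eps_RS, 6 / 110)
  expect_equal(ind$eps_K, 0.6)
  expect_equal(ind$delta, 6 / 110 * 10 / 110)
  expect_equal(ind$node_disc, 4 * 10 * 6 / (110 + 6)^2)

  # mu maximized at eps_RS = 1
  p1 <- rate_constants(1, 1, 1, 2)       # K_M = 2, e0 = 2
  expect_equal(indicators(p1)$mu, 0.25)

  # k2 = 0 leaves the predominance ratio infinite
  expect_identical(indicators(rate_constants(1, 1, 0, 2))$eps_K, Inf)
})
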