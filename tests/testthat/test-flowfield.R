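test_that("magnitude and NaN propagation", {
  f <- vector_field2d(matrix(3, 4, 4), matrix(4, 4, 4), dx = 8)
  expect_equal(magnitude(f), matrix(5, 4, 4))
  u <- matrix(0, 4, 4); u[2, 3] <- NA
  f <- vector_field2d(u, matrix(0, 4, 4), dx = 8)
  m <- magnitude(f)
  expect_true(is.na(m[2, 3]))
  expect_equal(sum(is.na(m)), 1)
  expect_error(vector_field2d(matrix(0, 2, 2), matrix(0, 3, 3), 1),
               "same shape")
})

test_that("subtract_drift zeroes component means and is shift-invariant", {
  set.seed(4)
  u <- matrix(rnorm(64), 8, 8); v <- matrix(rnorm(64), 8, 8)
  f <- vector_field2d(u, v, dx = 10)
  g <- subtract_drift(f)
  expect_equal(mean(g$u), 0, tolerance = 1e-12)
  expect_equal(mean(g$v), 0, tolerance = 1e-12)
  # adding a constant drift changes nothing after subtraction
  f2 <- vector_field2d(u + 7, v - 3, dx = 10)
  g2 <- subtract_drift(f2)
  expect_equal(g2$u, g$u, tolerance = 1e-12)
  expect_equal(g2$v, g$v, tolerance = 1e-12)
  # uniform field maps to zero
  g3 <- subtract_drift(vector_field2d(matrix(2, 4, 4), matrix(5, 4, 4), 1))
  expect_equal(max(abs(g3$u)), 0)
  expect_error(subtract_drift(vector_field2d(matrix(NA_real_, 2, 2),
                                             matrix(NA_real_, 2, 2), 1)),
               "entirely NA")
})

test_that("velocity_correlation FFT path equals the direct-sum oracle", {
  set.seed(11)
  for (k in 1:3) {
    u <- matrix(rnorm(15 * 12), 15, 12)
    v <- matrix(rnorm(15 * 12), 15, 12)
    if (k == 3) u[2, c(3, 7)] <- NA  # masked nodes
    f <- subtract_drift(vector_field2d(u, v, dx = 3))
    a <- velocity_correlation(f, max_r = 20, method = "fft")
    b <- velocity_correlation(f, max_r = 20, method = "direct")
    expect_equal(a$r, b$r)
    expect_equal(a$n_pairs, b$n_pairs)
    expect_equal(a$C_vv, b$C_vv, tolerance = 1e-10)
  }
})

test_that("velocity_correlation limits: C(0) = 1, white noise decorrelates", {
  set.seed(21)
  f <- subtract_drift(vector_field2d(matrix(rnorm(64^2), 64),
                                     matrix(rnorm(64^2), 64), dx = 1))
  cv <- velocity_correlation(f, max_r = 10)
  expect_equal(cv$C_vv[cv$r == 0], 1, tolerance = 1e-12)
  tail <- cv[cv$r > 0, ]
  # ~3 sd bound; node-sharing between pairs inflates the estimator
  # variance by about 2 over the independent-pair 1/n_pairs
  expect_true(all(abs(tail$C_vv) < 3 * sqrt(2) / sqrt(tail$n_pairs)))

  # perfectly correlated field: constant vector everywhere
  g <- vector_field2d(matrix(0.7, 16, 16), matrix(-0.2, 16, 16), dx = 1)
  cv <- velocity_correlation(g, max_r = 6)
  expect_equal(cv$C_vv, rep(1, nrow(cv)), tolerance = 1e-12)
})

test_that("correlation_length fits exactly and scales with r", {
  r <- 0:50
  fit <- correlation_length(r, exp(-r / 10))
  expect_equal(fit$C_L, 10, tolerance = 1e-6)
  expect_lt(fit$residual, 1e-6)
  # doubling r doubles the fitted length
  fit2 <- correlation_length(2 * r, exp(-r / 10))
  expect_equal(fit2$C_L, 20, tolerance = 1e-6)
  expect_error(correlation_length(r, rep(1, 51)), "does not decay")
})

test_that("classify_stationary applies the strict 10 um/h limit", {
  expect_equal(classify_stationary(c(9.99, 10, 0, 25)),
               c(TRUE, FALSE, TRUE, FALSE))
})

test_that("strain_energy computes the Butler integral in joules", {
  # uniform 100 Pa traction, 1 um aligned displacement over 100 x 100 um
  n <- 10; dx <- 10  # 10 x 10 nodes of a 100 x 100 um patch
  tr <- vector_field2d(matrix(100, n, n), matrix(0, n, n), dx,
                       kind = "traction")
  di <- vector_field2d(matrix(1, n, n), matrix(0, n, n), dx,
                       kind = "displacement")
  # 0.5 * 100 Pa * 1e-6 m * (1e-8 m^2) = 5e-13 J
  expect_equal(strain_energy(tr, di), 5e-13, tolerance = 1e-12)
  # half-factor flag
  expect_equal(strain_energy(tr, di, half = FALSE), 1e-12)
  # zero traction and orthogonal fields
  z <- vector_field2d(matrix(0, n, n), matrix(0, n, n), dx, "traction")
  expect_equal(strain_energy(z, di), 0)
  orth <- vector_field2d(matrix(0, n, n), matrix(1, n, n), dx,
                         kind = "displacement")
  expect_equal(strain_energy(tr, orth), 0)
  # bilinearity: scaling both fields by c scales U by c^2
  tr3 <- vector_field2d(3 * tr$u, 3 * tr$v, dx, "traction")
  di3 <- vector_field2d(3 * di$u, 3 * di$v, dx, "displacement")
  expect_equal(strain_energy(tr3, di3), 9 * strain_energy(tr, di))
  expect_error(strain_energy(tr, vector_field2d(matrix(1, 3, 3),
                                                matrix(0, 3, 3), dx,
                                                "displacement")),
               "do not match")
})

test_that("correlation pipeline is invariant to pre-existing drift", {
  f <- make_correlated_field(field_spec(grid_n = 64, dx = 2, lambda = 10,
                                        rms = 5, seed = 77))
  fd <- vector_field2d(f$u + 40, f$v - 15, f$dx)
  a <- velocity_correlation(subtract_drift(f), max_r = 40)
  b <- velocity_correlation(subtract_drift(fd), max_r = 40)
  expect_equal(a$C_vv, b$C_vv, tolerance = 1e-9)
})
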