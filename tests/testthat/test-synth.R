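test_that("generators are pure functions of their spec", {
  s <- monolayer_spec(n_cells = 40, seed = 5)
  m1 <- make_monolayer(s); m2 <- make_monolayer(s)
  expect_identical(m1$outlines, m2$outlines)
  p <- pcp_spec(n_cells = 30, seed = 5)
  expect_identical(make_pcp_points(p)$golgi, make_pcp_points(p)$golgi)
  f <- field_spec(grid_n = 32, dx = 2, lambda = 8, rms = 3, seed = 5)
  expect_identical(make_correlated_field(f)$u, make_correlated_field(f)$u)
  # different seeds decorrelate fields
  g1 <- make_correlated_field(field_spec(64, 2, 10, 5, seed = 1))
  g2 <- make_correlated_field(field_spec(64, 2, 10, 5, seed = 2))
  expect_lt(abs(cor(as.vector(g1$u), as.vector(g2$u))), 0.1)
})

test_that("monolayer generator hits the target order and aspect ratio", {
  for (S_star in c(0, 0.25, 0.5)) {
    sp <- monolayer_spec(n_cells = 500, target_order = S_star,
                         mean_aspect_ratio = 1.8, seed = 42)
    ml <- make_monolayer(sp)
    m <- monolayer_metrics(ml$outlines, reference = 0)
    ang <- m$orientation_deg
    se <- sd(cos(ang * pi / 180)^2) / sqrt(length(ang))
    expect_lt(abs(order_parameter(ang) - S_star), 3 * se + 1e-6)
    expect_equal(mean(m$aspect_ratio), 1.8, tolerance = 0.05)
    # fitted orientations equal the drawn ground-truth angles
    expect_equal(fold_angle(m$orientation_deg),
                 fold_angle(ml$true_angles), tolerance = 1e-6)
  }
  # degenerate fully ordered request
  ml <- make_monolayer(monolayer_spec(n_cells = 60, target_order = 2 / 3,
                                      seed = 1))
  m <- monolayer_metrics(ml$outlines, reference = 0)
  expect_equal(order_parameter(m$orientation_deg), 2 / 3,
               tolerance = 1e-6)
  # S* = 0 comes from concentrated-perpendicular angles, not uniform ones
  ml0 <- make_monolayer(monolayer_spec(n_cells = 400, target_order = 0,
                                       seed = 3))
  expect_gt(mean(fold_angle(ml0$true_angles)), 45)
  expect_error(monolayer_spec(target_order = 0.7), "0, 2/3")
})

test_that("isotropic-request monolayer measures mean angle near 45", {
  # target S = 1/6 corresponds to the 2D-uniform (isotropic) distribution
  ml <- make_monolayer(monolayer_spec(n_cells = 600, target_order = 1 / 6,
                                      seed = 8))
  m <- monolayer_metrics(ml$outlines, reference = 0)
  s <- attr(m, "summary")
  expect_equal(s$mean, 45, tolerance = 0.1)  # 3 se ~ 3.2 deg on n = 600
})

test_that("pcp generator recovers the polarization bias", {
  for (beta in c(-0.6, 0, 0.4)) {
    sp <- pcp_spec(n_cells = 600, polarization_bias = beta, seed = 19)
    pp <- make_pcp_points(sp)
    tab <- pcp_table(pp$nuclei, pp$golgi, flow_direction = 0)
    se <- sd(tab$pcp_index) / sqrt(nrow(tab))
    expect_lt(abs(mean(tab$pcp_index) - beta), 3 * se + 0.01)
  }
  # beta = -1 with zero noise: every index exactly -1 (upstream)
  pp <- make_pcp_points(pcp_spec(n_cells = 50, polarization_bias = -1,
                                 fragment_scatter = 0, seed = 2))
  tab <- pcp_table(pp$nuclei, pp$golgi, flow_direction = 0)
  expect_equal(tab$pcp_index, rep(-1, nrow(tab)), tolerance = 1e-9)
  # explicit kappa branch keeps the requested mean index
  sp <- pcp_spec(n_cells = 800, polarization_bias = 0.3,
                 angular_noise_kappa = 4, seed = 6)
  pp <- make_pcp_points(sp)
  tab <- pcp_table(pp$nuclei, pp$golgi, flow_direction = 0)
  expect_lt(abs(mean(tab$pcp_index) - 0.3), 0.06)
  expect_error(make_pcp_points(pcp_spec(polarization_bias = 0.9,
                                        angular_noise_kappa = 0.5)),
               "unreachable")
})

test_that("symmetric fragments recover the polarity point exactly", {
  np <- c(0, 0); pol <- c(4, 0)
  # mirrored pair: equal nucleus distances, equal weights, mean = pol
  w <- weighted_golgi_position(np, rbind(pol + c(0, 1.3), pol - c(0, 1.3)))
  expect_equal(w, pol, tolerance = 1e-12)
  # three fragments on one circle around the nucleus (equal weights)
  # arranged so their centroid is the polarity point
  a <- acos(0.7)  # (2 * 5 cos a + 5) / 3 = 4
  frags <- 5 * rbind(c(cos(a), sin(a)), c(cos(a), -sin(a)), c(1, 0))
  w <- weighted_golgi_position(np, frags)
  expect_equal(w, pol, tolerance = 1e-12)
})

test_that("correlated field generator matches its stated covariance", {
  sp <- field_spec(grid_n = 128, dx = 2, lambda = 20, rms = 12, seed = 31)
  f <- make_correlated_field(sp)
  # exact rms by construction
  expect_equal(sqrt(mean(f$u^2 + f$v^2)), 12, tolerance = 1e-9)
  cv <- velocity_correlation(subtract_drift(f), max_r = 60)
  c_at_lambda <- cv$C_vv[which.min(abs(cv$r - 20))]
  expect_lt(abs(c_at_lambda - exp(-1)), 0.1)
  # large lambda approaches a uniform field (correlation stays high)
  fs <- field_spec(grid_n = 64, dx = 2, lambda = 120, rms = 5, seed = 3)
  fl <- make_correlated_field(fs)
  cvl <- velocity_correlation(subtract_drift(fl), max_r = 16)
  expect_gt(min(cvl$C_vv), 0.6)
  expect_error(field_spec(grid_n = 64, dx = 2, lambda = 3), "resolved")
})

test_that("traction pairs carry their closed-form strain energy", {
  tp <- make_traction_pair(grid_n = 48, dx = 5, amplitude = 80, seed = 12)
  expect_equal(strain_energy(tp$traction, tp$displacement),
               tp$strain_energy_true, tolerance = 1e-10)
  # amplitude scaling: U scales quadratically
  tp2 <- make_traction_pair(grid_n = 48, dx = 5, amplitude = 160,
                            seed = 12)
  expect_equal(tp2$strain_energy_true, 4 * tp$strain_energy_true,
               tolerance = 1e-9)
  tp0 <- make_traction_pair(grid_n = 48, dx = 5, amplitude = 0, seed = 12)
  expect_equal(tp0$strain_energy_true, 0)
  expect_equal(strain_energy(tp0$traction, tp0$displacement), 0)
})
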