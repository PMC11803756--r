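test_that("K(0) = 1 and dG(0) = 0 for every bundled model", {
  sc <- softcore_spec(0, 50)
  for (m in all_builtin_models()) {
    expect_equal(k_lambda(m, schedule_point(0), sc, TH300), 1,
                 tolerance = 1e-6)
  }
  prof <- free_energy_profile(water_model(), linear_schedule(5), TH300)
  expect_equal(prof$delta_g_kcal_mol[1], 0, tolerance = 1e-6)
})

test_that("clash-free models reproduce the Gaussian closed forms", {
  th <- TH300
  g <- pure_gaussian_model(2.41, 3.46)
  sc <- wide_softcore()   # no saturation in the populated range
  k1 <- k_lambda(g, schedule_point(1), sc, th)
  expect_equal(k1, exp(-th$beta * 2.41 + th$beta^2 * 3.46^2 / 2),
               tolerance = 1e-5)
  prof <- free_energy_profile(g, linear_schedule(11, sc), th)
  expect_equal(attr(prof, "excess_dg"), 2.41 - th$beta * 3.46^2 / 2,
               tolerance = 1e-6)
  # tilted-density identity: mean shifts by -lambda beta sigma^2 at fixed width
  pt <- schedule_point(0.37)
  grid <- seq(-60, 40, length.out = 20001)
  d <- p_lambda_density(grid, g, pt, sc, th)
  mu <- trapz(grid, grid * d)
  s2 <- trapz(grid, (grid - mu)^2 * d)
  expect_equal(mu, 2.41 - 0.37 * th$beta * 3.46^2, tolerance = 1e-6)
  expect_equal(sqrt(s2), 3.46, tolerance = 1e-6)
})

test_that("quadrature is stable under refinement on the water model", {
  sc <- softcore_spec(0, 50)
  for (lam in c(0.25, 0.5, 1)) {
    ka <- k_lambda(water_model(), schedule_point(lam), sc, TH300)
    kb <- k_lambda(water_model(), schedule_point(lam), sc, TH300,
                   q = quadrature_spec(nodes = 8001))
    expect_lt(abs(kb / ka - 1), 1e-5)
  }
  # the refinement guard reports convergence rather than erroring here
  expect_silent(k_lambda(water_model(), schedule_point(0.5), sc, TH300,
                         rel_tol = 1e-4))
  expect_error(quadrature_spec(nodes = 50), "nodes")
})

test_that("intermediate densities are normalized and reduce to p0 at lambda = 0", {
  sc <- softcore_spec(0, 50)
  m <- water_model()
  u <- seq(-20, 30, by = 0.5)
  expect_equal(p_lambda_density(u, m, schedule_point(0), sc, TH300),
               p0_density(u, m), tolerance = 1e-6)
  # normalization at lambda = 0.5 on an independent (finer, wider) grid
  v <- seq(-46, 50 - 1e-7, length.out = 40001)
  d <- p_lambda_softcore_density(v, m, schedule_point(0.5), sc, TH300)
  expect_equal(trapz(v, d), 1, tolerance = 1e-4)
})

test_that("the soft-core change of variables conserves mass and keeps the spike integrable", {
  sc <- softcore_spec(0, 50)
  m <- water_model()
  pt <- schedule_point(0.3)
  k <- k_lambda(m, pt, sc, TH300)
  # below the cut the Jacobian is 1: densities agree
  u_neg <- seq(-20, -0.5, by = 0.5)
  expect_equal(p_lambda_softcore_density(u_neg, m, pt, sc, TH300, k = k),
               p_lambda_density(u_neg, m, pt, sc, TH300, k = k),
               tolerance = 1e-12)
  # mass over (-L, v] in u_sc space equals mass over (-L, inverse(v)] in u
  v <- seq(-40, 49.99, length.out = 60001)
  d_sc <- p_lambda_softcore_density(v, m, pt, sc, TH300, k = k)
  cum <- cumsum(pdtalch:::trapezoid_weights(v) * d_sc)
  v_at <- c(10, 30, 45)
  for (vv in v_at) {
    u_hi <- softcore_inverse(vv, sc)
    grid_u <- c(seq(-40, min(u_hi, 60), length.out = 20001),
                if (u_hi > 60) exp(seq(log(60), log(u_hi), length.out = 20001))[-1])
    d_u <- p_lambda_density(grid_u, m, pt, sc, TH300, k = k)
    expect_equal(cum[which.min(abs(v - vv))], trapz(grid_u, d_u),
                 tolerance = 1e-4)
  }
  # total mass (including the near-cap spike region) is finite and ~1
  expect_equal(cum[length(cum)], 1, tolerance = 1e-3)
  expect_error(p_lambda_softcore_density(50, m, pt, sc, TH300), "u_max")
})

test_that("free-energy profile is continuous in lambda on a refined grid", {
  # the profile's slope is the mean perturbation, 15-25 kcal/mol near
  # lambda = 0 for the water model, so continuity is checked by halving the
  # spacing and seeing the largest step halve with it
  sc <- softcore_spec(0, 50)
  prof1 <- free_energy_profile(water_model(), linear_schedule(101, sc),
                               TH300, q = quadrature_spec(nodes = 1001))
  prof2 <- free_energy_profile(water_model(), linear_schedule(201, sc),
                               TH300, q = quadrature_spec(nodes = 1001))
  j1 <- max(abs(diff(prof1$delta_g_kcal_mol)))
  j2 <- max(abs(diff(prof2$delta_g_kcal_mol)))
  expect_lt(j1, 0.3)
  expect_lt(j2 / j1, 0.7)
  expect_gt(j2 / j1, 0.3)
  expect_true(all(is.finite(prof1$K_lambda)) && all(prof1$K_lambda > 0))
})

test_that("coupled-state means: closed form, vanishing-fluctuation limit and quadrature", {
  th <- TH300
  cm <- coupled_state_mean(water_model(), th)
  expect_equal(cm$per_mode$u1bar, 2.41 - 3.46^2 / (0.0019872041 * 300),
               tolerance = 1e-12)
  expect_equal(cm$overall, -17.671, tolerance = 1e-3)
  tiny <- coupling_model(model_mode(1, gaussian_params(-4, 1e-4)))
  expect_equal(coupled_state_mean(tiny, th)$overall, -4, tolerance = 1e-6)
  cq <- coupled_state_mean(water_model(), th, method = "quadrature",
                           sc = softcore_spec(0, 50))
  expect_lt(abs(cq$mean_usc - cm$overall), 0.2)
})
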