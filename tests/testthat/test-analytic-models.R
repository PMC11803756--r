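test_that("gaussian background density has the right peak, symmetry and guards", {
  g <- water_gaussian()
  expect_equal(gaussian_density(2.41, g), 1 / (3.46 * sqrt(2 * pi)))
  expect_equal(gaussian_density(2.41, g), 0.1153, tolerance = 1e-3)
  d <- runif(20, 0, 15)
  expect_equal(gaussian_density(2.41 + d, g), gaussian_density(2.41 - d, g))
  expect_error(gaussian_density(NaN, g), "finite")
  expect_error(gaussian_params(0, -1), "sigma")
})

test_that("parameter constructors enforce their invariants", {
  expect_error(collision_params(-0.1), "b_no_collision")
  expect_error(collision_params(0.5, epsilon = 0), "epsilon")
  expect_error(collision_params(0.5, u_tilde = -1), "u_tilde")
  expect_error(collision_params(0.5, n_l = 0.5), "n_l")
  expect_error(model_mode(1.2, water_gaussian()), "weight")
  expect_error(coupling_model(list()), "non-empty")
  m <- model_mode(0.5, water_gaussian())
  expect_error(coupling_model(list(m, m, m)), "sum to 1")
  expect_silent(coupling_model(list(m, m)))
})

test_that("collisional density is supported on the positive axis and vanishes at the origin for n_l > 1", {
  cp <- water_collision()
  expect_identical(collision_density(c(-5, -0.01), cp), c(0, 0))
  expect_equal(collision_density(0, cp), 0)   # max-statistics factor vanishes
  expect_true(all(collision_density(c(0.1, 1, 10, 1e4), cp) > 0))
  # a single colliding group has a finite density at contact
  cp1 <- collision_params(0.5, 3.9, 3.9, 1)
  expect_gt(collision_density(0, cp1), 0)
})

test_that("collisional distribution function is the exact antiderivative of the density", {
  cp <- water_collision()
  expect_identical(collision_cdf(c(-1, 0), cp), c(0, 0))
  u <- c(0.3, 1, 2.7, 8, 40, 300, 5e3)
  fd <- (collision_cdf(u + 1e-5, cp) - collision_cdf(u - 1e-5, cp)) / 2e-5
  expect_equal(fd, collision_density(u, cp), tolerance = 1e-6)
  # monotone, with all mass recovered in the far tail
  expect_true(all(diff(collision_cdf(seq(0, 1e4, length.out = 200), cp)) >= 0))
  expect_equal(collision_cdf(1e30, cp), 1, tolerance = 1e-3)
  # interval mass agrees with adaptive quadrature of the density
  i1 <- stats::integrate(function(x) collision_density(x, cp), 2, 50,
                         rel.tol = 1e-10)$value
  expect_equal(i1, collision_cdf(50, cp) - collision_cdf(2, cp),
               tolerance = 1e-6)
})

test_that("collisional quantile function inverts the distribution function", {
  for (cp in list(water_collision(), collision_params(0.1, 1, 0, 6),
                  collision_params(0.9, 20, 200, 60))) {
    q <- c(1e-8, 1e-3, 0.25, 0.5, 0.9, 0.999)
    expect_equal(collision_cdf(collision_quantile(q, cp), cp), q,
                 tolerance = 1e-9)
  }
  cp <- water_collision()
  med <- collision_quantile(0.5, cp)
  expect_equal(stats::integrate(function(x) collision_density(x, cp), 0, med,
                                rel.tol = 1e-10)$value, 0.5, tolerance = 1e-6)
})

test_that("Gauss-Hermite convolution matches a dense-grid convolution oracle", {
  g <- water_gaussian()
  cp <- water_collision()
  u <- seq(-8, 40, by = 2)
  got <- convolved_collision_density(u, g, cp, nodes = 19)
  ref <- conv_oracle(u, g, cp)
  # 19 nodes resolve the bulk to high accuracy; in the low-density onset
  # shoulder the Heaviside kink limits Gauss-Hermite, so the check there is
  # absolute (the error stays below 1% of the peak density)
  sel <- ref > 0.75 * max(ref)
  expect_lt(max(abs(got[sel] / ref[sel] - 1)), 1e-3)
  expect_lt(max(abs(got - ref)), 1e-2 * max(ref))
  got199 <- convolved_collision_density(u, g, cp, nodes = 199)
  sel2 <- ref > 1e-6
  expect_lt(max(abs(got199[sel2] / ref[sel2] - 1)), 2e-2)
  # its antiderivative matches finite differences
  fd <- (convolved_collision_cdf(u + 1e-4, g, cp) -
           convolved_collision_cdf(u - 1e-4, g, cp)) / 2e-4
  expect_equal(fd, got, tolerance = 1e-5)
  expect_error(convolved_collision_density(0, g, cp, nodes = 3), "nodes")
})

test_that("p0 reduces to its pure components and is mixture-degenerate", {
  g <- water_gaussian()
  u <- seq(-10, 30, by = 0.5)
  m_b1 <- coupling_model(model_mode(1, g, collision_params(1, 3.9, 3.9, 2.5)))
  expect_equal(p0_density(u, m_b1), gaussian_density(u, g))
  cp <- collision_params(0, 3.9, 3.9, 2.5)
  m_b0 <- coupling_model(model_mode(1, g, cp))
  expect_equal(p0_density(u, m_b0), convolved_collision_density(u, g, cp))
  # two modes with equal parameters and weights 0.3/0.7 == a single mode
  cpw <- water_collision()
  one <- coupling_model(model_mode(1, g, cpw))
  two <- coupling_model(list(model_mode(0.3, g, cpw), model_mode(0.7, g, cpw)))
  expect_equal(p0_density(u, two), p0_density(u, one))
  expect_error(p0_density(0, structure(list(modes = list()),
                                       class = "coupling_model")), "modes")
})

test_that("every bundled table model is normalized", {
  for (m in all_builtin_models()) {
    # quadrature over the bulk matches the (analytic-in-the-tail) CDF ...
    r <- pdtalch:::model_u_range(m, TH300)
    grid <- seq(r[1], max(r[2], 500), length.out = 6001)
    mass <- trapz(grid, p0_density(grid, m))
    expect_equal(mass, p0_cdf(grid[length(grid)], m) - p0_cdf(grid[1], m),
                 tolerance = 1e-4)
    # ... and the CDF recovers all mass far out (the clash tail decays like
    # u^(-1/4), so the probe point must sit extremely deep)
    expect_equal(p0_cdf(1e40, m), 1, tolerance = 1e-6)
    expect_lt(abs(sum(mode_weights <- vapply(m$modes, `[[`, numeric(1),
                                             "weight")) - 1), 1e-9)
  }
})

test_that("mean and variance of a clash-free single mode are exact", {
  m <- pure_gaussian_model(-3.2, 2.7)
  grid <- seq(-3.2 - 12 * 2.7, -3.2 + 12 * 2.7, length.out = 8001)
  d <- p0_density(grid, m)
  mu <- trapz(grid, grid * d)
  v <- trapz(grid, (grid - mu)^2 * d)
  expect_equal(mu, -3.2, tolerance = 1e-8)
  expect_equal(v, 2.7^2, tolerance = 1e-7)
})

test_that("thermo derives beta from the fixed Boltzmann convention", {
  th <- thermo(300)
  expect_equal(th$beta, 1 / (0.0019872041 * 300))
  expect_error(thermo(-1))
  expect_equal(thermo(300, 0.0019872)$kT, 0.59616)
})
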