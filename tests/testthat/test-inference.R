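# single-state sample sets at lambda = 0 with uniform weights
flat_samples <- function(x, sc = softcore_spec(1e5, 2e5)) {
  sample_set(data.frame(state_index = 1, lambda = 0, lambda1 = 0, lambda2 = 0,
                        alpha = 1, u0 = 0, u_sc_kcal_mol = x), softcore = sc)
}

test_that("kernel density estimate is a normalized mixture of bumps", {
  s <- flat_samples(0.7)
  kde <- kernel_p0_estimate(s, weights = 1, bandwidth = 1,
                            grid = seq(-6, 8, length.out = 801))
  expect_equal(kde$density, stats::dnorm(kde$grid, 0.7, 1), tolerance = 1e-12)
  set.seed(5)
  s2 <- flat_samples(rnorm(500, -2, 3))
  kde2 <- kernel_p0_estimate(s2, weights = rep(1 / 500, 500),
                             grid = seq(-25, 21, length.out = 2001))
  expect_equal(trapz(kde2$grid, kde2$density), 1, tolerance = 1e-6)
  expect_error(kernel_p0_estimate(s2, rep(1 / 500, 500), bandwidth = 0),
               "bandwidth")
  # pointwise log-density error within kernel-bias bounds in the bulk
  big <- flat_samples(rnorm(20000, -2, 3))
  kb <- kernel_p0_estimate(big, rep(1 / 20000, 20000),
                           grid = seq(-8, 4, length.out = 241))
  smoothed <- stats::dnorm(kb$grid, -2, sqrt(3^2 + 1))   # truth x kernel
  expect_lt(max(abs(log(kb$density) - log(smoothed))), 0.15)
})

test_that("lambda-function is linear with slope -kT/sigma^2 for Gaussian data", {
  set.seed(6)
  x <- rnorm(20000, -2, 3)
  s <- flat_samples(x)
  w <- rep(1 / length(x), length(x))
  lf <- kernel_lambda_function(s, w, bandwidth = 1,
                               grid = seq(-8, 4, length.out = 121), th = TH300)
  # the kernel-smoothed density is Gaussian with variance sigma^2 + h^2
  fit <- stats::lm(lf$lambda0 ~ lf$grid)
  expect_equal(unname(stats::coef(fit)[2]), -TH300$kT / (3^2 + 1),
               tolerance = 0.05)
  zero_at <- -stats::coef(fit)[1] / stats::coef(fit)[2]
  expect_equal(unname(zero_at), -2, tolerance = 0.25)
  # translation equivariance: shifting samples shifts the curve horizontally
  s2 <- flat_samples(x + 5)
  lf2 <- kernel_lambda_function(s2, w, bandwidth = 1,
                                grid = seq(-8, 4, length.out = 121) + 5,
                                th = TH300)
  expect_equal(lf2$lambda0, lf$lambda0, tolerance = 1e-9)
})

test_that("lambda-function matches finite differences of the log kernel density", {
  set.seed(7)
  s <- flat_samples(rnorm(2000, 1, 2))
  w <- rep(1 / 2000, 2000)
  grid <- seq(-4, 6, length.out = 201)
  lf <- kernel_lambda_function(s, w, grid = grid, th = TH300)
  h <- 1e-6
  fd <- (log(kernel_p0_estimate(s, w, grid = grid + h)$density) -
           log(kernel_p0_estimate(s, w, grid = grid - h)$density)) / (2 * h)
  expect_equal(lf$lambda0, TH300$kT * fd, tolerance = 1e-6)
  # masking below the density floor yields NA, not an error
  lf2 <- kernel_lambda_function(s, w, grid = seq(-300, -250, length.out = 11),
                                th = TH300, floor = 1e-8)
  expect_true(all(is.na(lf2$lambda0)) || any(is.na(lf2$lambda0)))
})

test_that("single-state Gaussian likelihood reduces to the closed form", {
  set.seed(8)
  x <- rnorm(500, -1, 2)
  s <- flat_samples(x)          # no saturation, lambda = 0, Jacobian = 1
  m <- pure_gaussian_model(-1, 2)
  nll <- pdt_nll(m, s, TH300)
  expect_equal(nll, -sum(stats::dnorm(x, -1, 2, log = TRUE)), tolerance = 1e-6)
  # adding a duplicate sample adds exactly its per-sample term
  s2 <- flat_samples(c(x, x[1]))
  expect_equal(pdt_nll(m, s2, TH300) - nll,
               -stats::dnorm(x[1], -1, 2, log = TRUE), tolerance = 1e-6)
})

test_that("the generating model is a likelihood optimum among perturbations", {
  th <- TH300
  truth <- pure_gaussian_model(2.41, 3.46)
  sc <- softcore_spec()
  ds <- generate_dataset(truth, linear_schedule(7, sc), th,
                         n_per_state = 1500, seed = 12)
  c0 <- pdt_nll(truth, ds, th)
  set.seed(13)
  for (i in 1:8) {
    pert <- coupling_model(model_mode(
      1, gaussian_params(2.41 + rnorm(1, 0, 0.5),
                         3.46 * exp(rnorm(1, 0, 0.15)))))
    expect_gt(pdt_nll(pert, ds, th), c0)
  }
})

test_that("fitting never worsens the cost and refines a perturbed start", {
  th <- TH300
  truth <- pure_gaussian_model(2.41, 3.46)
  sc <- softcore_spec()
  ds <- generate_dataset(truth, linear_schedule(7, sc), th,
                         n_per_state = 800, seed = 14)
  # starting from the truth the descent contract holds
  f_truth <- pdt_fit(ds, init = truth, th = th,
                     cfg = fit_config(1, fit_collision = FALSE, max_iter = 60))
  expect_lte(f_truth$value, f_truth$init_value)
  # a biased start is pulled back toward the generating parameters
  start <- pure_gaussian_model(4.5, 2.6)
  f <- pdt_fit(ds, init = start, th = th,
               cfg = fit_config(1, fit_collision = FALSE, max_iter = 120))
  expect_lt(abs(f$model$modes[[1]]$gaussian$mean_u0 - 2.41), 0.3)
  expect_lt(abs(f$model$modes[[1]]$gaussian$sigma - 3.46), 0.2)
  expect_lt(f$value, pdt_nll(start, ds, th))
})

test_that("fit object methods expose the usual modelling interface", {
  th <- TH300
  truth <- pure_gaussian_model(-2, 2.5)
  sc <- softcore_spec()
  ds <- generate_dataset(truth, linear_schedule(5, sc), th,
                         n_per_state = 500, seed = 15)
  f <- pdt_fit(ds, init = truth, th = th,
               cfg = fit_config(1, fit_collision = FALSE, max_iter = 40))
  co <- coef(f)
  expect_named(co, c("w.1", "b.1", "u0bar.1", "sigma.1", "epsilon.1",
                     "u_tilde.1", "n_l.1"))
  ll <- logLik(f)
  expect_equal(as.numeric(ll), -f$value)
  expect_equal(attr(ll, "nobs"), nrow(ds))
  pr <- predict(f, u_sc = seq(-10, 5, by = 0.5), states = c(1, 5))
  expect_true(all(pr$density >= 0))
  expect_equal(unique(pr$lambda), c(0, 1))
  r <- residuals(f)
  expect_length(r, nrow(ds))
  expect_lt(abs(mean(r)), 0.1)       # near standard normal for a true model
  expect_lt(abs(sd(r) - 1), 0.1)
  sim <- simulate(f, seed = 99)
  expect_s3_class(sim, "sample_set")
  expect_equal(nrow(sim), 5 * 500)
  s <- summary(f)
  expect_s3_class(s, "summary.pdt_fit")
  expect_equal(nrow(s$states), 5)
  expect_output(print(f), "Analytical model fit")
})

test_that("diagnostic initialization recovers Gaussian parameters within 20%", {
  th <- TH300
  truth <- pure_gaussian_model(2.41, 3.46)
  sc <- softcore_spec()
  ds <- generate_dataset(truth, linear_schedule(11, sc), th,
                         n_per_state = 5000, seed = 16)
  uw <- uwham(ds, th)
  init <- initialize_from_diagnostics(ds, uw, mode_count = 1)
  expect_lt(abs(init$modes[[1]]$gaussian$mean_u0 / 2.41 - 1), 0.2)
  expect_lt(abs(init$modes[[1]]$gaussian$sigma / 3.46 - 1), 0.2)
  expect_silent(coupling_model(init$modes))   # passes all invariants
})

test_that("diagnostic initialization picks the dominant mode of bimodal data", {
  th <- TH300
  bim <- coupling_model(list(model_mode(0.75, gaussian_params(-10, 1.6)),
                             model_mode(0.25, gaussian_params(-3, 1.8))))
  sc <- softcore_spec()
  ds <- generate_dataset(bim, linear_schedule(7, sc), th,
                         n_per_state = 1500, seed = 17)
  uw <- uwham(ds, th)
  one <- initialize_from_diagnostics(ds, uw, mode_count = 1)
  expect_lt(abs(one$modes[[1]]$gaussian$mean_u0 + 10), 1.5)
  two <- initialize_from_diagnostics(ds, uw, mode_count = 2)
  expect_length(two$modes, 2)
  mus <- sort(vapply(two$modes, function(m) m$gaussian$mean_u0, numeric(1)))
  expect_lt(abs(mus[1] + 10), 1.5)
  expect_lt(abs(mus[2] + 3), 1.5)
  tiny <- flat_samples(rnorm(50))
  expect_error(initialize_from_diagnostics(tiny, rep(1 / 50, 50)),
               "too few")
})
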