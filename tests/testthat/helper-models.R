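# shared fixtures and small independent oracles

TH300 <- thermo(300)

# water-water coupling parameters (single mode)
water_model <- function() h2o_coupling_model()

water_collision <- function() collision_params(5.77e-3, 3.9, 3.9, 2.5)

water_gaussian <- function() gaussian_params(2.41, 3.46)

pure_gaussian_model <- function(mean_u0 = 2.41, sigma = 3.46)
  coupling_model(model_mode(1, gaussian_params(mean_u0, sigma)))

# host coupling of water (two modes) and a wide no-saturation soft-core
host_water_model <- function() builtin_model("temoa-h2o-coupling")

wide_softcore <- function() softcore_spec(1e5, 2e5)

# trapezoid integral on a grid
trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

# dense-grid direct convolution oracle for (N * F)(u): discretize F up to the
# largest collision energy the Gaussian can reach back from (its far tail
# cannot contribute to moderate u) and sum against the normal density
# (independent of the Gauss-Hermite path under test)
conv_oracle <- function(u, g, cp, du = 0.005) {
  cgrid <- seq(0, max(u) - g$mean_u0 + 9 * g$sigma, by = du)
  fvals <- collision_density(cgrid, cp)
  vapply(u, function(ui)
    sum(fvals * stats::dnorm(ui - cgrid, g$mean_u0, g$sigma)) * du,
    numeric(1))
}

all_builtin_models <- function() lapply(builtin_models(), builtin_model)
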