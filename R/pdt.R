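#' @title Potential-distribution propagation along the alchemical path
#'
#' @description
#' The decoupled-state density `p0(u)` determines every intermediate state:
#' `p_lambda(u) = exp(-beta W_lambda(u_sc(u))) p0(u) / K(lambda)` with the
#' excess binding constant `K(lambda) = E_0[exp(-beta W_lambda(u_sc(u)))]`,
#' and the excess free-energy profile `dG(lambda) = -kT log K(lambda)`.
#' All quadratures are carried out in the soft-core variable `u_sc`, whose
#' domain is bounded above by `u_max`; the heavy upper tail of the raw
#' perturbation energy is accounted for analytically through the model's
#' distribution function.
#'
#' @name pdt-engine
NULL

#' Quadrature settings for the PDT engine
#'
#' @param lower,upper Bounds of the `u_sc` integration grid (kcal/mol); by
#'   default derived from the model (12 background standard deviations below
#'   the lowest mode, further widened by the linear-response shift) and from
#'   the soft-core cap (`u_max` minus a relative offset of `1e-6`).
#' @param nodes Number of grid points for the composite trapezoid rule,
#'   >= 101 (default 4001).
#' @param method Quadrature flavour; the density grid always uses the
#'   trapezoid rule in `u_sc`, with per-mode Gauss-Hermite quadrature
#'   (`gh_nodes`) resolving the inner collisional convolution.
#' @param gh_nodes Gauss-Hermite node count for the convolution (default 19).
#' @return Object of class `"quadrature_spec"`.
#' @export
quadrature_spec <- function(lower = NULL, upper = NULL, nodes = 4001,
                            method = c("grid-trapezoid", "gauss-hermite-per-mode"),
                            gh_nodes = 19) {
  if (nodes < 101) stop("'nodes' must be >= 101")
  structure(list(lower = lower, upper = upper, nodes = as.integer(nodes),
                 method = match.arg(method), gh_nodes = as.integer(gh_nodes)),
            class = "quadrature_spec")
}

## Composite u_sc grid: dense, uniform nodes across the model's background
## support; log-spaced nodes across the (compressed) clash region up to just
## below the soft-core cap, where the raw-energy power-law tail lives.
usc_grid <- function(model, sc, th, q) {
  lo <- q$lower
  top <- q$upper
  if (is.null(lo)) lo <- model_u_range(model, th)[1]
  if (is.null(top)) top <- sc$u_max - 1e-6 * (sc$u_max - sc$u_cut)
  if (top >= sc$u_max) stop("quadrature upper bound must lie below u_max")
  if (lo >= top) stop("degenerate quadrature bounds")
  a_end <- min(softcore(model_u_range(model, th)[2], sc), top)
  if (a_end <= lo) a_end <- top
  if (a_end >= top - 1e-9 * (top - lo)) return(seq(lo, top, length.out = q$nodes))
  n_a <- max(51L, as.integer(ceiling(0.7 * q$nodes)))
  n_b <- max(51L, q$nodes - n_a)
  ga <- seq(lo, a_end, length.out = n_a)
  wb <- seq(0, log1p(top - a_end), length.out = n_b + 1L)
  gb <- a_end + expm1(wb[-1])
  c(ga, gb)
}

trapezoid_weights <- function(grid) {
  n <- length(grid)
  h <- diff(grid)
  w <- numeric(n)
  w[1] <- h[1] / 2
  w[n] <- h[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (h[-1] + h[-(n - 1)]) / 2
  w
}

## log p0 expressed in the soft-core variable (Jacobian included)
log_p0_softcore <- function(u_sc, model, sc, gh_nodes = 19) {
  u <- softcore_inverse(u_sc, sc)
  d <- p0_density(u, model, nodes = gh_nodes)
  log(d) - log(softcore_derivative(u, sc))
}

#' Excess binding constant at one alchemical state
#'
#' `K(lambda) = integral exp(-beta W_lambda(u_sc)) p0(u_sc) du_sc` over
#' `(-Inf, u_max)`, evaluated on the quadrature grid with an analytic
#' correction for the decoupled-state mass beyond the grid (where `W` is
#' effectively constant at its capped value).
#'
#' @param model A [coupling_model()].
#' @param pt A [schedule_point()].
#' @param sc A [softcore_spec()].
#' @param th A [thermo()] object (or temperature in K).
#' @param q A [quadrature_spec()].
#' @param rel_tol If non-`NULL`, the quadrature is repeated with twice the
#'   nodes and an error is raised when the relative change exceeds `rel_tol`.
#' @return The dimensionless `K(lambda) > 0`.
#' @export
k_lambda <- function(model, pt, sc, th = thermo(), q = quadrature_spec(),
                     rel_tol = NULL) {
  th <- as_thermo(th)
  k1 <- k_lambda_raw(model, pt, sc, th, q)
  if (!is.null(rel_tol)) {
    q2 <- q
    q2$nodes <- 2L * q$nodes - 1L
    k2 <- k_lambda_raw(model, pt, sc, th, q2)
    if (abs(k2 - k1) > rel_tol * abs(k2))
      stop(sprintf(paste0("quadrature did not converge for lambda = %g: ",
                          "K changed by %.3g relative between %d and %d nodes"),
                   pt$lam, abs(k2 - k1) / abs(k2), q$nodes, q2$nodes))
    k1 <- k2
  }
  k1
}

## The Gaussian (background) channel of each mode is integrated by the
## trapezoid rule in the raw-energy variable, where the integrand is smooth
## and decays at both ends. The collisional channel has a heavy power-law
## tail, so it is integrated with mass-exact cells instead: the analytic
## distribution function supplies each grid cell's probability exactly and
## exp(-beta W) is evaluated at the cell midpoint (exact at lambda = 0,
## where W vanishes). Both channels add analytic end corrections with W
## frozen at the edge value.
k_lambda_raw <- function(model, pt, sc, th, q) {
  v <- usc_grid(model, sc, th, q)
  u <- softcore_inverse(v, sc)
  lphi <- -th$beta * w_lambda(v, pt)              # log exp(-beta W) on nodes
  vmid <- (v[-1] + v[-length(v)]) / 2
  lphi_mid <- -th$beta * w_lambda(vmid, pt)
  wtr <- trapezoid_weights(v)
  jac <- softcore_derivative(u, sc)
  total <- 0
  for (mm in model$modes) {
    b <- mm$collision$b_no_collision
    g <- mm$gaussian
    ## Gaussian channel (trapezoid in u_sc with the Jacobian)
    lw <- lphi + stats::dnorm(u, g$mean_u0, g$sigma, log = TRUE) - log(jac)
    m <- max(lw)
    kn <- if (is.finite(m)) exp(m) * sum(wtr * exp(lw - m)) else 0
    kn <- kn +
      exp(lphi[length(v)]) * stats::pnorm(u[length(u)], g$mean_u0, g$sigma,
                                          lower.tail = FALSE) +
      exp(lphi[1]) * stats::pnorm(u[1], g$mean_u0, g$sigma)
    kc <- 0
    if (b < 1) {
      cdf <- convolved_collision_cdf(u, g, mm$collision, q$gh_nodes)
      cell <- pmax(diff(cdf), 0)
      lm <- lphi_mid + log(ifelse(cell > 0, cell, 1)) # masked below
      lm[cell <= 0] <- -Inf
      mx <- max(lm, lphi[length(v)] + log(max(1 - cdf[length(cdf)], 1e-300)),
                lphi[1] + log(max(cdf[1], 1e-300)))
      kc <- exp(mx) * (sum(exp(lm - mx)) +
                         exp(lphi[length(v)] - mx) * max(1 - cdf[length(cdf)], 0) +
                         exp(lphi[1] - mx) * cdf[1])
    }
    total <- total + mm$weight * (b * kn + (1 - b) * kc)
  }
  if (!is.finite(total) || total <= 0)
    stop("model density vanished on the whole quadrature grid")
  total
}

#' Density of the raw perturbation energy at an intermediate state
#'
#' @inheritParams k_lambda
#' @param u Raw perturbation energies (kcal/mol); vectorized.
#' @param k Optional precomputed `K(lambda)`.
#' @export
p_lambda_density <- function(u, model, pt, sc, th = thermo(),
                             q = quadrature_spec(), k = NULL) {
  th <- as_thermo(th)
  if (is.null(k)) k <- k_lambda(model, pt, sc, th, q)
  exp(-th$beta * w_lambda(softcore(u, sc), pt)) * p0_density(u, model, q$gh_nodes) / k
}

#' Density of the soft-core perturbation energy at an intermediate state
#'
#' The `u_sc`-space density `p_lambda(u_sc) = p_lambda(u) / u_sc'(u)` at
#' `u = u_sc^{-1}(u_sc)`; it develops an integrable spike as `u_sc`
#' approaches `u_max`, where the capped image of the heavy clash tail piles
#' up.
#'
#' @inheritParams p_lambda_density
#' @param u_sc Soft-core energies, each `< u_max`.
#' @export
p_lambda_softcore_density <- function(u_sc, model, pt, sc, th = thermo(),
                                      q = quadrature_spec(), k = NULL) {
  th <- as_thermo(th)
  if (any(u_sc >= sc$u_max)) stop("u_sc must be below u_max")
  if (is.null(k)) k <- k_lambda(model, pt, sc, th, q)
  exp(-th$beta * w_lambda(u_sc, pt) +
        log_p0_softcore(u_sc, model, sc, q$gh_nodes)) / k
}

#' Excess free-energy profile along a schedule
#'
#' `dG(lambda) = -kT log K(lambda)` at every schedule point; the value at the
#' final point is the excess free energy of the process.
#'
#' @param model A [coupling_model()].
#' @param schedule A [lambda_schedule()].
#' @param th A [thermo()] object.
#' @param q A [quadrature_spec()].
#' @return Object of class `"fe_profile"`: a data frame with columns
#'   `lambda`, `K_lambda`, `delta_g_kcal_mol` and attribute `excess_dg`.
#' @export
free_energy_profile <- function(model, schedule, th = thermo(),
                                q = quadrature_spec()) {
  stopifnot(inherits(schedule, "lambda_schedule"))
  th <- as_thermo(th)
  ks <- vapply(schedule$points, function(pt)
    k_lambda(model, pt, schedule$softcore, th, q), numeric(1))
  lam <- vapply(schedule$points, `[[`, numeric(1), "lam")
  dg <- -th$kT * log(ks)
  out <- data.frame(lambda = lam, K_lambda = ks, delta_g_kcal_mol = dg)
  structure(out, excess_dg = dg[length(dg)], thermo = th,
            class = c("fe_profile", "data.frame"))
}

#' @export
print.fe_profile <- function(x, digits = 4, ...) {
  cat("Excess free-energy profile (kcal/mol)\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  cat(sprintf("excess dG at the final state: %.4f kcal/mol\n",
              attr(x, "excess_dg")))
  invisible(x)
}

#' @export
plot.fe_profile <- function(x, ...) {
  graphics::plot(x$lambda, x$delta_g_kcal_mol, type = "b", pch = 19,
                 xlab = expression(lambda),
                 ylab = expression(Delta * G * " (kcal/mol)"), ...)
  invisible(x)
}

#' Mean interaction energy in the fully coupled state
#'
#' The linear-response closed form gives, per mode, `u1bar = u0bar -
#' beta sigma^2` (the collisional component is suppressed in the coupled
#' ensemble by the Boltzmann factor and neglected). The quadrature method
#' averages over the full model density at `lambda = 1` (linear alchemical
#' potential `W_1 = u_sc(u)`) and reports both the soft-core mean `<u_sc>`
#' (finite; the headline value) and the raw-energy mean truncated at raw
#' energies up to the cap `u_max` -- the clash tail's power-law decay makes
#' the untruncated raw mean infinite.
#'
#' @param model A [coupling_model()].
#' @param th A [thermo()] object.
#' @param method `"linear-response"` (default) or `"quadrature"`.
#' @param sc A [softcore_spec()], required for the quadrature method.
#' @param q A [quadrature_spec()].
#' @return For `"linear-response"`, a list with `per_mode` (data frame of
#'   mode, weight, `u1bar`) and `overall` (weight-averaged mean, kcal/mol).
#'   For `"quadrature"`, additionally `mean_u_truncated` and `mean_usc`.
#' @export
coupled_state_mean <- function(model, th = thermo(),
                               method = c("linear-response", "quadrature"),
                               sc = NULL, q = quadrature_spec()) {
  method <- match.arg(method)
  th <- as_thermo(th)
  mus <- vapply(model$modes, function(m) m$gaussian$mean_u0, numeric(1))
  sds <- vapply(model$modes, function(m) m$gaussian$sigma, numeric(1))
  w <- mode_weights(model)
  u1 <- mus - th$beta * sds^2
  per_mode <- data.frame(mode = seq_along(u1), weight = w, u1bar = u1)
  out <- list(per_mode = per_mode, overall = sum(w * u1), method = method)
  if (method == "quadrature") {
    if (is.null(sc)) stop("the quadrature method needs a softcore_spec")
    pt <- schedule_point(1)
    v <- usc_grid(model, sc, th, q)
    tw <- trapezoid_weights(v)
    lw <- -th$beta * w_lambda(v, pt) + log_p0_softcore(v, model, sc, q$gh_nodes)
    m <- max(lw)
    dens <- exp(lw - m)
    z <- sum(tw * dens)
    if (!is.finite(z) || z <= 0) stop("coupled-state quadrature diverged")
    u <- softcore_inverse(v, sc)
    sel <- u <= sc$u_max   # raw-energy average truncated at the cap scale
    out$mean_u_truncated <- sum(tw[sel] * dens[sel] * u[sel]) /
      sum(tw[sel] * dens[sel])
    out$mean_usc <- sum(tw * dens * v) / z
    out$overall <- out$mean_usc
  }
  out
}
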