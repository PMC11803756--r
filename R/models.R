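#' @title Analytical perturbation-energy density family
#'
#' @description
#' The probability density of the perturbation energy `u` (kcal/mol) of a
#' coupling process in the decoupled ensemble is modelled per mode as
#' `p0(u) = b * N(u) + (1 - b) * (N %*% F)(u)`, where `N` is a normal
#' background (linear-response) component, `F` is the max-statistics density
#' of the collisional (clash) energy, `%*%` denotes convolution, and `b` is
#' the probability that a decoupled configuration is free of collisions.
#' A full model is a weighted mixture of such modes, one per conformational
#' state. Alchemical-transfer densities share the same functional form.
#'
#' @name analytic-models
NULL

#' Gaussian background parameters
#'
#' @param mean_u0 Mean of the background interaction energy in the decoupled
#'   ensemble (kcal/mol).
#' @param sigma Standard deviation (kcal/mol), > 0.
#' @return Object of class `"gaussian_params"`.
#' @export
gaussian_params <- function(mean_u0, sigma) {
  stopifnot(is.numeric(mean_u0), length(mean_u0) == 1L, is.finite(mean_u0),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (sigma <= 0) stop("sigma must be > 0")
  structure(list(mean_u0 = mean_u0, sigma = sigma), class = "gaussian_params")
}

#' Collisional (max-statistics) parameters
#'
#' The collisional energy is the most repulsive atomic contact of `n_l`
#' statistically independent atom groups; its distribution follows max
#' statistics with an effective Lennard-Jones prefactor `epsilon` and a
#' minimum collision energy `u_tilde`.
#'
#' @param b_no_collision Probability that no collisions occur in the decoupled
#'   ensemble, in `[0, 1]`.
#' @param epsilon Effective Lennard-Jones energy prefactor (kcal/mol), > 0.
#' @param u_tilde Collision-energy onset (kcal/mol), >= 0.
#' @param n_l Effective number of independently colliding atom groups, >= 1
#'   (non-integer values allowed).
#' @return Object of class `"collision_params"`.
#' @export
collision_params <- function(b_no_collision, epsilon = 1, u_tilde = 1, n_l = 2.5) {
  stopifnot(is.numeric(b_no_collision), length(b_no_collision) == 1L,
            is.finite(b_no_collision))
  if (b_no_collision < 0 || b_no_collision > 1)
    stop("b_no_collision must lie in [0, 1]")
  if (!is.finite(epsilon) || epsilon <= 0) stop("epsilon must be > 0")
  if (!is.finite(u_tilde) || u_tilde < 0) stop("u_tilde must be >= 0")
  if (!is.finite(n_l) || n_l < 1) stop("n_l must be >= 1")
  structure(list(b_no_collision = b_no_collision, epsilon = epsilon,
                 u_tilde = u_tilde, n_l = n_l), class = "collision_params")
}

#' One mode of the analytical model
#'
#' @param weight Statistical weight of the mode in the decoupled ensemble.
#' @param gaussian A [gaussian_params()] object.
#' @param collision A [collision_params()] object, or `NULL` for a purely
#'   Gaussian (collision-free, `b = 1`) mode.
#' @return Object of class `"model_mode"`.
#' @export
model_mode <- function(weight, gaussian, collision = NULL) {
  stopifnot(is.numeric(weight), length(weight) == 1L, is.finite(weight))
  if (weight < 0 || weight > 1) stop("mode weight must lie in [0, 1]")
  stopifnot(inherits(gaussian, "gaussian_params"))
  if (is.null(collision)) collision <- collision_params(1)
  stopifnot(inherits(collision, "collision_params"))
  structure(list(weight = weight, gaussian = gaussian, collision = collision),
            class = "model_mode")
}

#' Multimodal analytical coupling / transfer model
#'
#' @param modes List of [model_mode()] objects; weights must sum to 1 within
#'   `1e-9` (set `normalize = TRUE` to rescale instead).
#' @param label Free-text label.
#' @param role One of `"host-coupling"`, `"solvent-coupling"`,
#'   `"transfer-binding"`, `"transfer-unbinding"` or `NA`.
#' @param normalize Rescale the weights to sum to exactly 1.
#' @return Object of class `"coupling_model"`.
#' @export
coupling_model <- function(modes, label = "", role = NA_character_,
                           normalize = FALSE) {
  if (inherits(modes, "model_mode")) modes <- list(modes)
  if (!is.list(modes) || length(modes) == 0L)
    stop("'modes' must be a non-empty list of model_mode objects")
  if (!all(vapply(modes, inherits, logical(1), "model_mode")))
    stop("every element of 'modes' must be a model_mode")
  w <- vapply(modes, function(m) m$weight, numeric(1))
  if (normalize) {
    if (sum(w) <= 0) stop("total mode weight must be positive")
    for (i in seq_along(modes)) modes[[i]]$weight <- w[i] / sum(w)
  } else if (abs(sum(w) - 1) > 1e-9) {
    stop(sprintf("mode weights must sum to 1 (got %.12g)", sum(w)))
  }
  if (!is.na(role) &&
      !role %in% c("host-coupling", "solvent-coupling",
                   "transfer-binding", "transfer-unbinding"))
    stop("unknown model role: ", role)
  structure(list(modes = modes, label = as.character(label), role = role),
            class = "coupling_model")
}

n_modes <- function(model) length(model$modes)

mode_weights <- function(model) vapply(model$modes, `[[`, numeric(1), "weight")

#' @export
print.coupling_model <- function(x, digits = 4, ...) {
  cat("Analytical perturbation-energy model")
  if (nzchar(x$label)) cat(": ", x$label, sep = "")
  if (!is.na(x$role)) cat(" [", x$role, "]", sep = "")
  cat("\n")
  print(as.data.frame(x), digits = digits)
  invisible(x)
}

#' @export
as.data.frame.coupling_model <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$modes), function(i) {
    m <- x$modes[[i]]
    data.frame(mode = i, w = m$weight, b = m$collision$b_no_collision,
               u0bar = m$gaussian$mean_u0, sigma = m$gaussian$sigma,
               epsilon = m$collision$epsilon, u_tilde = m$collision$u_tilde,
               n_l = m$collision$n_l)
  }))
}

## ---- Gauss-Hermite nodes (Golub-Welsch), cached ----

.gh_cache <- new.env(parent = emptyenv())

gauss_hermite <- function(n) {
  key <- as.character(n)
  if (!is.null(.gh_cache[[key]])) return(.gh_cache[[key]])
  stopifnot(n >= 1)
  if (n == 1L) {
    res <- list(nodes = 0, weights = sqrt(pi))
  } else {
    i <- seq_len(n - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- sqrt(i / 2)
    J[cbind(i + 1, i)] <- sqrt(i / 2)
    e <- eigen(J, symmetric = TRUE)
    idx <- order(e$values)
    res <- list(nodes = e$values[idx],
                weights = sqrt(pi) * e$vectors[1, idx]^2)
  }
  .gh_cache[[key]] <- res
  res
}

## ---- densities ----

#' Gaussian background density
#'
#' @param u Perturbation energy (kcal/mol); vectorized.
#' @param g A [gaussian_params()] object.
#' @return Probability density values, 1/(kcal/mol).
#' @export
gaussian_density <- function(u, g) {
  stopifnot(inherits(g, "gaussian_params"))
  if (any(!is.finite(u))) stop("'u' must be finite")
  stats::dnorm(u, mean = g$mean_u0, sd = g$sigma)
}

collision_xc <- function(c) sqrt(1 + c$u_tilde / c$epsilon)

#' Collisional energy density
#'
#' Max-statistics density of the most repulsive atomic contact. With
#' `x = sqrt(1 + (u_coll + u_tilde) / epsilon)` and
#' `xc = sqrt(1 + u_tilde / epsilon)`, the distribution function is
#' `G(u_coll) = (1 - sqrt((1 + xc) / (1 + x)))^n_l` on `u_coll >= 0` and the
#' density is its exact derivative,
#' `F = n_l (1 - sqrt((1+xc)/(1+x)))^(n_l - 1) sqrt(1 + xc) /
#'  (4 epsilon x (1 + x)^(3/2))`.
#' The tail is heavy (`1 - G ~ u^(-1/4)`): the distribution is normalized but
#' has no finite mean.
#'
#' @param u_coll Collisional energy (kcal/mol); vectorized.
#' @param c A [collision_params()] object.
#' @return Density values; 0 for `u_coll < 0`.
#' @export
collision_density <- function(u_coll, c) {
  stopifnot(inherits(c, "collision_params"))
  if (c$epsilon <= 0) stop("epsilon must be > 0")
  if (c$n_l < 1) stop("n_l must be >= 1")
  out <- numeric(length(u_coll))
  pos <- is.finite(u_coll) & u_coll >= 0
  if (any(pos)) {
    xc <- collision_xc(c)
    x <- sqrt(1 + (u_coll[pos] + c$u_tilde) / c$epsilon)
    r <- sqrt((1 + xc) / (1 + x))
    out[pos] <- c$n_l * (1 - r)^(c$n_l - 1) * sqrt(1 + xc) /
      (4 * c$epsilon * x * (1 + x)^1.5)
  }
  out
}

#' Collisional energy distribution function
#'
#' Analytic antiderivative of [collision_density()]; see that help page for
#' the parameterization.
#'
#' @inheritParams collision_density
#' @return `P(U_coll <= u_coll)`; vectorized.
#' @export
collision_cdf <- function(u_coll, c) {
  stopifnot(inherits(c, "collision_params"))
  out <- numeric(length(u_coll))
  pos <- is.finite(u_coll) & u_coll > 0
  if (any(pos)) {
    xc <- collision_xc(c)
    x <- sqrt(1 + (u_coll[pos] + c$u_tilde) / c$epsilon)
    r <- sqrt((1 + xc) / (1 + x))
    out[pos] <- (1 - r)^c$n_l
  }
  out
}

#' Collisional energy quantile function
#'
#' Exact inverse of [collision_cdf()], used for heavy-tail-exact quadrature
#' and sampling.
#'
#' @param q Probabilities in `[0, 1)`; vectorized.
#' @param c A [collision_params()] object.
#' @export
collision_quantile <- function(q, c) {
  stopifnot(inherits(c, "collision_params"))
  if (any(!is.finite(q) | q < 0 | q >= 1)) stop("'q' must lie in [0, 1)")
  xc <- collision_xc(c)
  r <- 1 - q^(1 / c$n_l)
  x <- (1 + xc) / r^2 - 1
  pmax(0, c$epsilon * (x^2 - 1) - c$u_tilde)
}

#' Convolution of the Gaussian background with the collisional density
#'
#' Evaluates `(N %*% F)(u)` by Gauss-Hermite quadrature over the Gaussian
#' factor (19 nodes by default).
#'
#' @param u Energies (kcal/mol); vectorized.
#' @param g A [gaussian_params()] object.
#' @param c A [collision_params()] object.
#' @param nodes Number of Gauss-Hermite nodes (>= 5).
#' @export
convolved_collision_density <- function(u, g, c, nodes = 19) {
  stopifnot(inherits(g, "gaussian_params"), inherits(c, "collision_params"))
  if (g$sigma <= 0) stop("sigma must be > 0")
  if (nodes < 5) stop("'nodes' must be >= 5")
  gh <- gauss_hermite(nodes)
  t <- g$mean_u0 + sqrt(2) * g$sigma * gh$nodes
  w <- gh$weights / sqrt(pi)
  drop(matrix(collision_density(rep(u, times = length(t)) -
                                  rep(t, each = length(u)), c),
              nrow = length(u)) %*% w)
}

convolved_collision_cdf <- function(u, g, c, nodes = 19) {
  gh <- gauss_hermite(nodes)
  t <- g$mean_u0 + sqrt(2) * g$sigma * gh$nodes
  w <- gh$weights / sqrt(pi)
  drop(matrix(collision_cdf(rep(u, times = length(t)) -
                              rep(t, each = length(u)), c),
              nrow = length(u)) %*% w)
}

#' Analytical density of the decoupled (lambda = 0) state
#'
#' Mixture over modes of `b N + (1 - b) (N %*% F)`.
#'
#' @param u Perturbation energies (kcal/mol); vectorized.
#' @param model A [coupling_model()].
#' @param nodes Gauss-Hermite node count for the convolution.
#' @export
p0_density <- function(u, model, nodes = 19) {
  stopifnot(inherits(model, "coupling_model"))
  if (length(model$modes) == 0L) stop("model has no modes")
  out <- numeric(length(u))
  for (m in model$modes) {
    b <- m$collision$b_no_collision
    d <- b * gaussian_density(u, m$gaussian)
    if (b < 1)
      d <- d + (1 - b) * convolved_collision_density(u, m$gaussian, m$collision, nodes)
    out <- out + m$weight * d
  }
  out
}

#' Distribution function of the decoupled-state density
#'
#' Analytic in the collisional factor; the Gaussian convolution is resolved
#' by Gauss-Hermite quadrature.
#'
#' @inheritParams p0_density
#' @export
p0_cdf <- function(u, model, nodes = 19) {
  stopifnot(inherits(model, "coupling_model"))
  out <- numeric(length(u))
  for (m in model$modes) {
    b <- m$collision$b_no_collision
    d <- b * stats::pnorm(u, m$gaussian$mean_u0, m$gaussian$sigma)
    if (b < 1)
      d <- d + (1 - b) * convolved_collision_cdf(u, m$gaussian, m$collision, nodes)
    out <- out + m$weight * d
  }
  out
}

## widest sensible u-range for quadrature over p0
model_u_range <- function(model, th = thermo()) {
  mus <- vapply(model$modes, function(m) m$gaussian$mean_u0, numeric(1))
  sds <- vapply(model$modes, function(m) m$gaussian$sigma, numeric(1))
  lo <- min(mus - 12 * sds, mus - as_thermo(th)$beta * sds^2 - 8 * sds)
  hi <- max(mus + 12 * sds)
  c(lo, hi)
}
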