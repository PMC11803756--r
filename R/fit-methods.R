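#' @export
print.pdt_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Analytical model fit: %d mode(s), %d samples in %d states\n",
              length(x$model$modes), x$n, length(x$states)))
  cat(sprintf("cost: %.6g (initial %.6g), converged: %s\n",
              x$value, x$init_value, x$converged))
  print(as.data.frame(x$model), digits = digits)
  invisible(x)
}

#' @export
summary.pdt_fit <- function(object, ...) {
  ks <- vapply(object$states, function(pt)
    k_lambda(object$model, pt, object$softcore, object$thermo),
    numeric(1))
  st <- data.frame(
    lambda = vapply(object$states, `[[`, numeric(1), "lam"),
    n = object$counts, K_lambda = ks,
    delta_g_kcal_mol = -object$thermo$kT * log(ks))
  out <- list(fit = object, states = st,
              parameters = as.data.frame(object$model))
  class(out) <- "summary.pdt_fit"
  out
}

#' @export
print.summary.pdt_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nPer-state normalization and free-energy profile:\n")
  print(x$states, digits = digits, row.names = FALSE)
  invisible(x)
}

#' @export
coef.pdt_fit <- function(object, ...) {
  df <- as.data.frame(object$model)
  out <- numeric(0)
  for (i in seq_len(nrow(df))) {
    v <- unlist(df[i, c("w", "b", "u0bar", "sigma", "epsilon", "u_tilde", "n_l")])
    names(v) <- paste0(names(v), ".", i)
    out <- c(out, v)
  }
  out
}

#' @export
logLik.pdt_fit <- function(object, ...) {
  per <- if (object$cfg$fit_collision) 6L else 2L
  df <- length(object$model$modes) * per + max(0L, length(object$model$modes) - 1L)
  structure(-object$value, df = df, nobs = object$n, class = "logLik")
}

#' Fitted state densities
#'
#' Evaluates the fitted model's soft-core perturbation-energy density at the
#' requested alchemical states.
#'
#' @param object A [pdt_fit()] result.
#' @param u_sc Energies at which to evaluate (default: 401 points across the
#'   sample range).
#' @param states Integer indices into the fitted states (default: all).
#' @param ... Unused.
#' @return Data frame with columns `state`, `lambda`, `u_sc`, `density`.
#' @export
predict.pdt_fit <- function(object, u_sc = NULL, states = NULL, ...) {
  if (is.null(u_sc)) {
    r <- range(object$samples$u_sc_kcal_mol)
    u_sc <- seq(r[1], r[2], length.out = 401L)
  }
  if (is.null(states)) states <- seq_along(object$states)
  out <- lapply(states, function(k) {
    pt <- object$states[[k]]
    data.frame(state = k, lambda = pt$lam, u_sc = u_sc,
               density = p_lambda_softcore_density(
                 u_sc, object$model, pt, object$softcore, object$thermo))
  })
  do.call(rbind, out)
}

#' Simulate replicate datasets from a fitted model
#'
#' @param object A [pdt_fit()] result.
#' @param nsim Number of replicate sample sets.
#' @param seed Master seed.
#' @param n_per_state Samples per state (default: the fitted per-state
#'   counts' median).
#' @param ... Unused.
#' @return A list of [sample_set()]s (a single one if `nsim = 1`).
#' @export
simulate.pdt_fit <- function(object, nsim = 1, seed = 1L,
                             n_per_state = NULL, ...) {
  if (is.null(n_per_state)) n_per_state <- as.integer(stats::median(object$counts))
  sched <- lambda_schedule(object$states, object$softcore, validate = FALSE)
  out <- lapply(seq_len(nsim), function(r)
    generate_dataset(object$model, sched, th = object$thermo,
                     n_per_state = n_per_state, seed = seed + (r - 1L)))
  if (nsim == 1) out[[1]] else out
}

#' Quantile residuals of a fitted model
#'
#' Each sample's model distribution-function value at its own state, mapped
#' through the standard-normal quantile function: standard-normal if the
#' model is exact.
#'
#' @param object A [pdt_fit()] result.
#' @param ... Unused.
#' @export
residuals.pdt_fit <- function(object, ...) {
  x <- object$samples
  scz <- object$softcore
  th <- object$thermo
  idx <- match(x$state_index, sort(unique(x$state_index)))
  res <- numeric(nrow(x))
  grid <- usc_grid(object$model, scz, th, quadrature_spec(nodes = 4001))
  for (k in seq_along(object$states)) {
    pt <- object$states[[k]]
    dens <- p_lambda_softcore_density(grid, object$model, pt, scz, th)
    cdf <- cumsum(trapezoid_weights(grid) * dens)
    cdf <- cdf / cdf[length(cdf)]
    sel <- idx == k
    p <- stats::approx(grid, cdf, xout = x$u_sc_kcal_mol[sel], rule = 2)$y
    res[sel] <- stats::qnorm(clamp(p, 1e-12, 1 - 1e-12))
  }
  res
}

#' @export
plot.pdt_fit <- function(x, states = NULL, breaks = 60, ...) {
  if (is.null(states))
    states <- unique(round(seq(1, length(x$states), length.out = 4)))
  op <- graphics::par(mfrow = c(length(states), 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  idx <- match(x$samples$state_index, sort(unique(x$samples$state_index)))
  for (k in states) {
    sel <- idx == k
    xs <- x$samples$u_sc_kcal_mol[sel]
    h <- graphics::hist(xs, breaks = breaks, plot = FALSE)
    pt <- x$states[[k]]
    grid <- seq(min(xs), max(xs), length.out = 301)
    dens <- p_lambda_softcore_density(grid, x$model, pt, x$softcore, x$thermo)
    graphics::plot(h, freq = FALSE, main = sprintf("lambda = %.3g", pt$lam),
                   xlab = expression(u[sc] * " (kcal/mol)"), ...)
    graphics::lines(grid, dens, col = "red3", lwd = 2)
  }
  invisible(x)
}
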