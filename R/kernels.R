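#' Weighted Gaussian kernel estimate of the decoupled-state density
#'
#' `p0(u_sc) = sum_i W0_i N(u_sc; u_sc_i, bandwidth)` with the per-sample
#' lambda = 0 weights from [uwham()]: the graphical diagnostic from which
#' the analytical model's parameters are read off.
#'
#' @param samples A [sample_set()].
#' @param weights A [uwham()] result (its `weights0` are used), or a numeric
#'   vector of normalized per-sample weights.
#' @param bandwidth Kernel standard deviation in kcal/mol (default 1).
#' @param grid Evaluation grid in `u_sc`; by default 512 points spanning the
#'   weighted sample range padded by 4 bandwidths.
#' @return Object of class `"pdt_kde"`: list with `grid`, `density`,
#'   `bandwidth`, `weights`.
#' @export
kernel_p0_estimate <- function(samples, weights, bandwidth = 1, grid = NULL) {
  x <- samples$u_sc_kcal_mol
  w <- if (inherits(weights, "uwham")) weights$weights0 else weights
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  if (length(w) != length(x)) stop("one weight per sample required")
  if (abs(sum(w) - 1) > 1e-6) stop("weights must be normalized")
  if (is.null(grid))
    grid <- seq(min(x) - 4 * bandwidth, max(x) + 4 * bandwidth,
                length.out = 512L)
  dens <- kde_eval(grid, x, w, bandwidth)$density
  structure(list(grid = grid, density = dens, bandwidth = bandwidth,
                 weights = w), class = "pdt_kde")
}

#' Weighted kernel estimate of the lambda-function
#'
#' The lambda-function `lambda0(u_sc) = kT d log p0(u_sc) / d u_sc` is the
#' slope diagnostic whose linear region reveals the Gaussian parameters of a
#' mode (`lambda0` crosses zero at `u0bar` with slope `-kT / sigma^2`). The
#' derivative uses the analytic derivative of the Gaussian kernel; values
#' where the density estimate falls below `floor` (relative to its maximum)
#' are masked to `NA` rather than reported.
#'
#' @inheritParams kernel_p0_estimate
#' @param th A [thermo()] object.
#' @param floor Relative density floor for masking.
#' @return Object of class `"pdt_lambda_fn"`: list with `grid`, `lambda0`,
#'   `density`, `bandwidth`.
#' @export
kernel_lambda_function <- function(samples, weights, bandwidth = 1,
                                   grid = NULL, th = thermo(), floor = 1e-8) {
  x <- samples$u_sc_kcal_mol
  w <- if (inherits(weights, "uwham")) weights$weights0 else weights
  if (bandwidth <= 0) stop("bandwidth must be > 0")
  th <- as_thermo(th)
  if (is.null(grid))
    grid <- seq(min(x) - 4 * bandwidth, max(x) + 4 * bandwidth,
                length.out = 512L)
  kv <- kde_eval(grid, x, w, bandwidth)
  lam <- th$kT * kv$ddensity / kv$density
  lam[kv$density < floor * max(kv$density)] <- NA_real_
  structure(list(grid = grid, lambda0 = lam, density = kv$density,
                 bandwidth = bandwidth), class = "pdt_lambda_fn")
}

## density and its derivative for a weighted Gaussian mixture kernel,
## evaluated in sample chunks to bound memory
kde_eval <- function(grid, x, w, h, chunk = 20000L) {
  ng <- length(grid)
  dens <- numeric(ng)
  dd <- numeric(ng)
  for (start in seq(1L, length(x), by = chunk)) {
    ix <- start:min(start + chunk - 1L, length(x))
    Z <- outer(grid, x[ix], "-") / h              # ng x chunk
    phi <- stats::dnorm(Z) / h
    dens <- dens + drop(phi %*% w[ix])
    dd <- dd + drop((-Z / h * phi) %*% w[ix])
  }
  list(density = dens, ddensity = dd)
}

#' @export
print.pdt_kde <- function(x, ...) {
  cat(sprintf("weighted kernel density: %d grid points on [%.3g, %.3g], bandwidth %g kcal/mol\n",
              length(x$grid), min(x$grid), max(x$grid), x$bandwidth))
  invisible(x)
}

#' @export
plot.pdt_kde <- function(x, log = FALSE, ...) {
  y <- if (log) log(x$density) else x$density
  graphics::plot(x$grid, y, type = "l",
                 xlab = expression(u[sc] * " (kcal/mol)"),
                 ylab = if (log) expression(log * " " * p[0]) else expression(p[0]),
                 ...)
  invisible(x)
}

#' @export
plot.pdt_lambda_fn <- function(x, ...) {
  graphics::plot(x$grid, x$lambda0, type = "l",
                 xlab = expression(u[sc] * " (kcal/mol)"),
                 ylab = expression(lambda[0](u[sc])), ...)
  invisible(x)
}
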