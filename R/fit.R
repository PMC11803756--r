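#' @title Maximum-likelihood fitting of the analytical model
#'
#' @description
#' The model parameters are estimated from multi-state soft-core
#' perturbation-energy samples by minimizing the pooled negative
#' log-likelihood `-sum_i log p_lambda_i(u_sc_i | theta)`, where the state
#' densities follow from the decoupled-state model by the
#' potential-distribution relation and the soft-core change of variables.
#'
#' @name model-fitting
NULL

#' Fit configuration
#'
#' @param mode_count Number of mixture modes to fit, >= 1.
#' @param fit_collision Optimize the collisional parameters
#'   (`b, epsilon, u_tilde, n_l`) as well; if `FALSE`, the model family is
#'   restricted to clash-free mixtures (`b = 1`, collisional block inert)
#'   and only the mode weights and Gaussian parameters are free.
#' @param max_iter Optimizer iteration cap.
#' @param rel_tol Relative cost-change convergence threshold.
#' @param n_starts Number of optimizer starts (start 1 is the supplied
#'   initial model; further starts jitter it, seeded).
#' @param seed Seed for multi-start jitter.
#' @param gh_nodes Gauss-Hermite nodes for the collisional convolution.
#' @param k_nodes Trapezoid nodes for the per-state normalization constants.
#' @return Object of class `"fit_config"`.
#' @export
fit_config <- function(mode_count = 1L, fit_collision = TRUE, max_iter = 300L,
                       rel_tol = 1e-9, n_starts = 1L, seed = 1L,
                       gh_nodes = 19L, k_nodes = 2001L) {
  if (mode_count < 1) stop("mode_count must be >= 1")
  structure(list(mode_count = as.integer(mode_count),
                 fit_collision = isTRUE(fit_collision),
                 max_iter = as.integer(max_iter), rel_tol = rel_tol,
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 gh_nodes = as.integer(gh_nodes),
                 k_nodes = as.integer(k_nodes)),
            class = "fit_config")
}

## ---- parameter transforms (unconstrained <-> model) ----

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

model_to_theta <- function(model, fit_collision) {
  m <- length(model$modes)
  th <- if (m > 1) {
    w <- mode_weights(model)
    log(w[-1] / w[1])
  } else numeric(0)
  for (mm in model$modes) {
    th <- c(th, mm$gaussian$mean_u0, log(mm$gaussian$sigma))
    if (fit_collision) {
      b <- clamp(mm$collision$b_no_collision, 1e-12, 1 - 1e-12)
      th <- c(th, stats::qlogis(b), log(mm$collision$epsilon),
              log(max(mm$collision$u_tilde, 1e-8)),
              log(max(mm$collision$n_l - 1, 1e-8)))
    }
  }
  th
}

theta_to_model <- function(theta, template, fit_collision) {
  m <- length(template$modes)
  pos <- 0L
  if (m > 1) {
    lw <- c(0, theta[seq_len(m - 1)])
    w <- exp(lw - max(lw)); w <- w / sum(w)
    pos <- m - 1L
  } else w <- 1
  per <- if (fit_collision) 6L else 2L
  modes <- vector("list", m)
  for (i in seq_len(m)) {
    p <- theta[pos + seq_len(per)]
    pos <- pos + per
    tm <- template$modes[[i]]
    ## sigma floored at 0.3 kcal/mol: guards the spike degeneracy of
    ## mixture likelihoods (sub-0.3 background widths are unphysical here)
    g <- gaussian_params(p[1], exp(clamp(p[2], log(0.3), 20)))
    cl <- if (fit_collision) {
      collision_params(stats::plogis(p[3]), exp(clamp(p[4], -20, 20)),
                       exp(clamp(p[5], -30, 20)), 1 + exp(clamp(p[6], -30, 10)))
    } else tm$collision
    modes[[i]] <- model_mode(w[i], g, cl)
  }
  coupling_model(modes, label = template$label, role = template$role,
                 normalize = TRUE)
}

## ---- likelihood ----

## static per-dataset context reused across objective evaluations
nll_context <- function(samples, th, cfg) {
  scz <- attr(samples, "softcore")
  pts <- sample_states(samples)
  idx <- match(samples$state_index, sort(unique(samples$state_index)))
  u <- softcore_inverse(samples$u_sc_kcal_mol, scz)
  const <- sum(vapply(seq_along(pts), function(k) {
    sel <- idx == k
    th$beta * sum(w_lambda(samples$u_sc_kcal_mol[sel], pts[[k]]))
  }, numeric(1))) + sum(log(softcore_derivative(u, scz)))
  list(softcore = scz, points = pts, counts = sample_counts(samples),
       u = u, const = const, th = th,
       q = quadrature_spec(nodes = cfg$k_nodes, gh_nodes = cfg$gh_nodes))
}

nll_core <- function(model, ctx) {
  d <- p0_density(ctx$u, model, nodes = ctx$q$gh_nodes)
  ks <- vapply(ctx$points, function(pt)
    k_lambda(model, pt, ctx$softcore, ctx$th, ctx$q), numeric(1))
  ctx$const + sum(ctx$counts * log(ks)) - sum(log(pmax(d, 1e-300)))
}

#' Negative log-likelihood of a model for a multi-state sample set
#'
#' `-sum_i log p_lambda_i(u_sc_i | model)` over all samples, with the state
#' densities `p_lambda(u_sc) = exp(-beta W_lambda(u_sc)) p0(u_sc) / K(lambda)`
#' and the soft-core Jacobian included. Samples falling in regions of
#' vanishing model density contribute a large finite penalty (the density is
#' floored at `1e-300`) rather than an infinite or undefined cost.
#'
#' @param model A [coupling_model()].
#' @param samples A [sample_set()].
#' @param th A [thermo()] object.
#' @param cfg A [fit_config()] (quadrature settings are taken from it).
#' @return The scalar cost (dimensionless).
#' @export
pdt_nll <- function(model, samples, th = thermo(), cfg = fit_config()) {
  stopifnot(inherits(samples, "sample_set"))
  nll_core(model, nll_context(samples, as_thermo(th), cfg))
}

#' Fit the analytical model to multi-state perturbation-energy samples
#'
#' Maximum-likelihood refinement of a [coupling_model()] against a
#' [sample_set()]. Mode weights are optimized through a simplex-preserving
#' softmax transform, positive parameters through log transforms and `b`
#' through a logit transform; optimization uses BFGS (numerical gradients)
#' with optional seeded multi-start. The returned cost never exceeds the
#' initial cost: if the optimizer fails to improve, the initial model is
#' returned with `converged = FALSE`.
#'
#' @param samples A [sample_set()].
#' @param init Initial [coupling_model()]; if `NULL`, derived from kernel
#'   diagnostics via [initialize_from_diagnostics()].
#' @param th A [thermo()] object.
#' @param cfg A [fit_config()].
#' @param weights Optional [uwham()] result, used only when `init` is
#'   `NULL` (and computed on demand otherwise).
#' @return Object of class `"pdt_fit"` with components `model`, `init_model`,
#'   `value`, `init_value`, `converged`, `evaluations`, `cfg`, `thermo`,
#'   `softcore`, `states`, `n`. Methods: `print`, `summary`, `coef`,
#'   `logLik`, `predict`, `simulate`, `residuals`, `plot`.
#' @export
pdt_fit <- function(samples, init = NULL, th = thermo(), cfg = fit_config(),
                    weights = NULL) {
  stopifnot(inherits(samples, "sample_set"))
  th <- as_thermo(th)
  if (is.null(init)) {
    if (is.null(weights)) weights <- uwham(samples, th)
    init <- initialize_from_diagnostics(samples, weights,
                                        mode_count = cfg$mode_count, th = th)
  }
  if (length(init$modes) != cfg$mode_count)
    cfg$mode_count <- length(init$modes)
  if (!cfg$fit_collision)
    init$modes <- lapply(init$modes, function(m) {
      m$collision <- collision_params(1)
      m
    })
  ctx <- nll_context(samples, th, cfg)
  f0 <- nll_core(init, ctx)
  obj <- function(theta) {
    md <- try(theta_to_model(theta, init, cfg$fit_collision), silent = TRUE)
    if (inherits(md, "try-error")) return(f0 + 1e6)
    val <- try(nll_core(md, ctx), silent = TRUE)
    if (inherits(val, "try-error") || !is.finite(val)) return(f0 + 1e6)
    val
  }
  theta0 <- model_to_theta(init, cfg$fit_collision)
  best <- list(value = f0, par = theta0, counts = c(0L, 0L), convergence = 1L)
  set.seed(cfg$seed)
  for (s in seq_len(cfg$n_starts)) {
    start <- if (s == 1) theta0 else theta0 + stats::rnorm(length(theta0), sd = 0.25)
    ## a simplex search is markedly more robust than gradient descent on
    ## mixture likelihoods; a quasi-Newton polish then tightens the optimum
    nm <- try(stats::optim(start, obj, method = "Nelder-Mead",
                           control = list(maxit = 10L * cfg$max_iter,
                                          reltol = cfg$rel_tol)),
              silent = TRUE)
    if (inherits(nm, "try-error")) next
    opt <- try(stats::optim(nm$par, obj, method = "BFGS",
                            control = list(maxit = cfg$max_iter,
                                           reltol = cfg$rel_tol)),
               silent = TRUE)
    if (inherits(opt, "try-error") || opt$value > nm$value) opt <- nm
    if (opt$value < best$value) best <- opt
  }
  model <- if (best$value < f0)
    theta_to_model(best$par, init, cfg$fit_collision) else init
  structure(list(model = model, init_model = init,
                 value = min(best$value, f0), init_value = f0,
                 converged = best$value < f0 &&
                   (is.null(best$convergence) || best$convergence == 0L),
                 evaluations = best$counts, cfg = cfg, thermo = th,
                 softcore = ctx$softcore, states = ctx$points,
                 counts = ctx$counts, n = nrow(samples),
                 samples = samples),
            class = "pdt_fit")
}

#' Initial model from kernel diagnostics
#'
#' Automates the graphical initialization: on the clash-free side of the
#' soft-core onset (`u_sc <= u_cut`, where collisional mass cannot lie), the
#' weighted kernel estimate of `log p0(u_sc)` is segmented at its local
#' minima, and each retained segment is fitted by a quadratic whose vertex
#' and curvature give `u0bar` and `sigma` (kernel bandwidth deconvolved).
#' Mode weights follow the segment masses; `b` is estimated from the mass
#' below the onset relative to the Gaussian share expected there
#' (`mass / Phi((u_cut - u0bar)/sigma)`); collisional parameters default to
#' `epsilon = 1`, `u_tilde = 1` kcal/mol and `n_l` from `size_hint`.
#'
#' @param samples A [sample_set()].
#' @param weights A [uwham()] result or normalized weight vector.
#' @param bandwidth Kernel bandwidth, kcal/mol.
#' @param mode_count Number of modes to return.
#' @param th A [thermo()] object.
#' @param size_hint Default `n_l` (scales with solute size).
#' @return A valid [coupling_model()].
#' @export
initialize_from_diagnostics <- function(samples, weights, bandwidth = 1,
                                        mode_count = 1L, th = thermo(),
                                        size_hint = 2.5) {
  stopifnot(inherits(samples, "sample_set"))
  if (nrow(samples) < 100) stop("too few samples to initialize from (< 100)")
  scz <- attr(samples, "softcore")
  w <- if (inherits(weights, "uwham")) weights$weights0 else weights
  x <- samples$u_sc_kcal_mol
  grid <- seq(min(x) - 4 * bandwidth, max(x) + 4 * bandwidth, length.out = 1024L)
  dens <- kde_eval(grid, x, w, bandwidth)$density
  step <- grid[2] - grid[1]
  ## stay 2 bandwidths clear of the onset: kernel mass leaking from the
  ## soft-core-compressed lobe just above it would bias the quadratic fit
  onset <- scz$u_cut - 2 * bandwidth
  keep <- grid <= onset + 1e-9
  if (sum(dens[keep]) * step < 1e-4) keep <- rep(TRUE, length(grid))
  g <- grid[keep]; d <- dens[keep]
  live <- d > 1e-3 * max(d)
  ## segment the live region at local minima of the density
  segs <- segment_peaks(g, d, live)
  segs <- segs[order(vapply(segs, function(s) -sum(d[s]) * step, numeric(1)))]
  if (length(segs) > mode_count) segs <- segs[seq_len(mode_count)]
  while (length(segs) < mode_count) segs <- c(segs, segs[1])
  masses <- vapply(segs, function(s) sum(d[s]) * step, numeric(1))
  mus <- sigs <- numeric(length(segs))
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    fit <- stats::lm(log(d[s]) ~ stats::poly(g[s], 2, raw = TRUE),
                     weights = d[s])
    c2 <- unname(stats::coef(fit)[3]); c1 <- unname(stats::coef(fit)[2])
    if (is.finite(c2) && c2 < 0) {
      sig2 <- -1 / (2 * c2)
      mus[i] <- -c1 / (2 * c2)
    } else {
      mus[i] <- sum(g[s] * d[s]) / sum(d[s])
      sig2 <- sum((g[s] - mus[i])^2 * d[s]) / sum(d[s])
    }
    sigs[i] <- sqrt(max(sig2 - bandwidth^2, (bandwidth / 2)^2))
  }
  ## each segment's visible mass is ~ w_i * b * Phi((onset - mu_i)/sigma_i);
  ## the implied full Gaussian masses give the weights and, summed, a common
  ## clash-free probability (exact for one mode, ~1 for clash-free data)
  implied <- masses / stats::pnorm((onset - mus) / sigs)
  implied[!is.finite(implied)] <- masses[!is.finite(implied)]
  b <- clamp(sum(implied), 1e-6, 1)
  modes <- lapply(seq_along(segs), function(i)
    model_mode(implied[i] / sum(implied), gaussian_params(mus[i], sigs[i]),
               collision_params(b, 1, 1, max(1.01, size_hint))))
  coupling_model(modes, label = "diagnostic initialization", normalize = TRUE)
}

segment_peaks <- function(g, d, live) {
  n <- length(d)
  is_peak <- which(live & c(FALSE, diff(d) > 0) & c(diff(d) < 0, FALSE))
  if (length(is_peak) == 0L) return(list(which(live)))
  if (length(is_peak) == 1L) return(list(which(live)))
  bounds <- integer(0)
  for (j in seq_len(length(is_peak) - 1)) {
    span <- is_peak[j]:is_peak[j + 1]
    bounds <- c(bounds, span[which.min(d[span])])
  }
  cuts <- c(0, bounds, n)
  lapply(seq_len(length(cuts) - 1), function(j) {
    s <- (cuts[j] + 1):cuts[j + 1]
    s[live[s]]
  })
}
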