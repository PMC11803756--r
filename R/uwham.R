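#' Unbinned weighted-histogram (multistate reweighting) analysis
#'
#' Solves the standard self-consistent multistate equations on the reduced
#' energies `beta * W_k(u_sc_i)` of every sample in every state: the
#' dimensionless state free energies `f_k` (anchored at `f_1 = 0`) satisfy
#' `exp(-f_k) = sum_i exp(-beta W_k(u_i)) / sum_l N_l exp(f_l - beta W_l(u_i))`.
#' The solution is obtained by minimizing the equivalent convex objective
#' with BFGS and polishing by direct iteration until `max |df| < 1e-8`.
#' Each sample also receives a normalized statistical weight at the
#' decoupled (lambda = 0) state -- where the alchemical perturbation
#' vanishes, whether or not that state was sampled -- the input for kernel
#' estimates of `p0`.
#'
#' @param samples A [sample_set()].
#' @param th A [thermo()] object.
#' @param tol Convergence threshold on `max |df|`.
#' @param max_iter Iteration cap for the polishing stage.
#' @param n_boot Number of bootstrap replicates (resampling within states,
#'   warm-started) for standard errors of the free energies; 0 disables.
#' @param seed Seed for the bootstrap resampling.
#' @param ess_floor Effective-sample-size floor at the target state below
#'   which a poor-overlap warning is recorded in the result.
#' @return Object of class `"uwham"`: list with `f` (dimensionless free
#'   energies), `delta_g` (`kT * f`, kcal/mol), `weights0` (per-sample
#'   weights at the first state, summing to 1), `ess0`, `se_delta_g`
#'   (if bootstrapped), `converged`, `iterations`, `warnings`.
#' @export
uwham <- function(samples, th = thermo(), tol = 1e-8, max_iter = 10000L,
                  n_boot = 0L, seed = 1L, ess_floor = 20) {
  stopifnot(inherits(samples, "sample_set"))
  th <- as_thermo(th)
  pts <- sample_states(samples)
  K <- length(pts)
  if (K < 2L) stop("need samples from at least 2 states")
  ## reduced energy matrix, n x K
  E <- vapply(pts, function(pt) th$beta * w_lambda(samples$u_sc_kcal_mol, pt),
              numeric(nrow(samples)))
  N <- sample_counts(samples)
  sol <- uwham_solve(E, N, tol = tol, max_iter = max_iter)
  w0 <- uwham_weights0(E, N, sol$f)
  ess0 <- 1 / sum(w0^2)
  warn <- character(0)
  if (ess0 < ess_floor)
    warn <- c(warn, sprintf(
      "poor overlap with the target state: effective sample size %.1f", ess0))
  se <- rep(NA_real_, K)
  if (n_boot > 0) {
    set.seed(seed)
    idx_by_state <- split(seq_len(nrow(samples)), samples$state_index)
    fb <- matrix(0, n_boot, K)
    for (b in seq_len(n_boot)) {
      take <- unlist(lapply(idx_by_state, function(ix)
        ix[sample.int(length(ix), length(ix), replace = TRUE)]))
      fb[b, ] <- uwham_solve(E[take, , drop = FALSE], N, f_init = sol$f,
                             tol = tol, max_iter = max_iter)$f
    }
    se <- apply(fb, 2, stats::sd) * th$kT
  }
  structure(list(f = sol$f, delta_g = th$kT * sol$f, weights0 = w0,
                 ess0 = ess0, se_delta_g = se, converged = sol$converged,
                 iterations = sol$iterations, warnings = warn,
                 thermo = th, n_states = K, n_samples = nrow(samples)),
            class = "uwham")
}

#' @export
print.uwham <- function(x, digits = 4, ...) {
  cat(sprintf("UWHAM: %d states, %d samples (converged: %s, %d iterations)\n",
              x$n_states, x$n_samples, x$converged, x$iterations))
  df <- data.frame(state = seq_along(x$f), f = x$f,
                   delta_g_kcal_mol = x$delta_g)
  if (any(is.finite(x$se_delta_g))) df$se <- x$se_delta_g
  print(df, digits = digits, row.names = FALSE)
  for (w in x$warnings) cat("warning: ", w, "\n", sep = "")
  invisible(x)
}

logsumexp_rows <- function(M) {
  m <- M[, 1]
  for (k in seq_len(ncol(M))[-1]) m <- pmax(m, M[, k])
  m + log(rowSums(exp(M - m)))
}

uwham_solve <- function(E, N, f_init = NULL, tol = 1e-8, max_iter = 10000L) {
  K <- ncol(E)
  logN <- log(N)
  f <- if (is.null(f_init)) numeric(K) else f_init
  obj <- function(f)
    sum(logsumexp_rows(sweep(-E, 2, f + logN, "+"))) - sum(N * f)
  ## optimize over f[2..K] with f[1] = 0 (a uniform shift of f is a null
  ## direction of the objective)
  fn <- function(fr) obj(c(0, fr))
  gr <- function(fr) {
    f <- c(0, fr)
    D <- sweep(-E, 2, f + logN, "+")
    m <- D[, 1]
    for (k in seq_len(K)[-1]) m <- pmax(m, D[, k])
    P <- exp(D - m)
    P <- P / rowSums(P)              # n x K responsibilities
    (colSums(P) - N)[-1]
  }
  if (K > 1) {
    opt <- stats::optim(f[-1], fn, gr, method = "BFGS",
                        control = list(maxit = 300, reltol = 1e-12))
    f <- c(0, opt$par)
  }
  ## self-consistent polishing to the stated tolerance
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    denom <- logsumexp_rows(sweep(-E, 2, f + logN, "+"))  # log sum_l N_l e^{f_l - E_il}
    fnew <- -vapply(seq_len(K), function(k) {
      m <- max(-E[, k] - denom)
      m + log(sum(exp(-E[, k] - denom - m)))
    }, numeric(1))
    fnew <- fnew - fnew[1]
    d <- max(abs(fnew - f))
    f <- fnew
    if (d < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  if (!converged && d > 1e-4)
    stop(sprintf("UWHAM iteration did not converge (max |df| = %.3g)", d))
  list(f = f, converged = converged, iterations = it)
}

## weights of each sample at the decoupled (lambda = 0) target state, where
## the alchemical perturbation vanishes identically -- valid whether or not
## that state was sampled
uwham_weights0 <- function(E, N, f) {
  denom <- logsumexp_rows(sweep(-E, 2, f + log(N), "+"))
  lw <- -denom
  m <- max(lw)
  w <- exp(lw - m)
  w / sum(w)
}
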