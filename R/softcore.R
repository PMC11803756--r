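#' Soft-core capping of the perturbation energy
#'
#' The soft-core transform is the identity below `u_cut` and smoothly caps
#' larger perturbation energies below `u_max`, leaving the alchemical end
#' states unaffected: with `y = (u - u_cut) / (u_max - u_cut)`,
#' `u_sc = (u_max - u_cut) * f_sc(y) + u_cut`, where
#' `f_sc(y) = (z^a - 1) / (z^a + 1)` and `z(y) = 1 + 2 y/a + 2 (y/a)^2`.
#' The transform is strictly increasing, once-differentiable at `u_cut`
#' (slope 1 there) and maps the real line onto `(-Inf, u_max)`.
#'
#' @param u_cut Energy above which capping starts (kcal/mol).
#' @param u_max Asymptotic cap (kcal/mol), > `u_cut`.
#' @param a_exponent Softness exponent `a` > 0 (default 1/16).
#' @return Object of class `"softcore_spec"`.
#' @examples
#' sc <- softcore_spec()             # coupling default: 0 / 50 kcal/mol
#' softcore(-5, sc)                  # identity branch
#' softcore_spec(100, 200)           # host-guest transfer convention
#' @export
softcore_spec <- function(u_cut = 0, u_max = 50, a_exponent = 0.0625) {
  stopifnot(is.numeric(u_cut), is.numeric(u_max), is.numeric(a_exponent),
            is.finite(u_cut), is.finite(u_max), is.finite(a_exponent))
  if (u_max <= u_cut) stop("u_max must exceed u_cut")
  if (a_exponent <= 0) stop("a_exponent must be > 0")
  structure(list(u_cut = u_cut, u_max = u_max, a_exponent = a_exponent),
            class = "softcore_spec")
}

#' @export
print.softcore_spec <- function(x, ...) {
  cat(sprintf("soft-core: identity below %g, cap %g kcal/mol, a = %g\n",
              x$u_cut, x$u_max, x$a_exponent))
  invisible(x)
}

#' Soft-core perturbation energy
#'
#' @param u Raw perturbation energies (kcal/mol); vectorized.
#' @param sc A [softcore_spec()].
#' @return `u_sc(u)` in kcal/mol.
#' @export
softcore <- function(u, sc) {
  stopifnot(inherits(sc, "softcore_spec"))
  out <- u
  hi <- is.finite(u) & u > sc$u_cut
  if (any(hi)) {
    span <- sc$u_max - sc$u_cut
    y <- (u[hi] - sc$u_cut) / span
    t <- y / sc$a_exponent
    za <- exp(sc$a_exponent * logz_softcore(t))
    out[hi] <- span * (1 - 2 / (za + 1)) + sc$u_cut
  }
  out
}

## log(1 + 2t + 2t^2) without overflow at extreme t
logz_softcore <- function(t) {
  ifelse(t > 1e8,
         log(2) + 2 * log(t) + log1p((1 + 2 * t) / (2 * t^2)),
         log1p(2 * t + 2 * t^2))
}

#' Derivative of the soft-core transform
#'
#' Equals 1 on the identity branch (`u <= u_cut`), is positive everywhere and
#' decays to 0 as `u` grows.
#'
#' @inheritParams softcore
#' @export
softcore_derivative <- function(u, sc) {
  stopifnot(inherits(sc, "softcore_spec"))
  out <- rep(1, length(u))
  hi <- is.finite(u) & u > sc$u_cut
  if (any(hi)) {
    a <- sc$a_exponent
    y <- (u[hi] - sc$u_cut) / (sc$u_max - sc$u_cut)
    t <- y / a
    logz <- logz_softcore(t)
    zp <- (2 + 4 * t) / a            # dz/dy
    ## f'(y) = 2 a z^(a-1) z' / (z^a + 1)^2, in logs for very large z
    log_fp <- log(2 * a) + (a - 1) * logz + log(zp) -
      2 * log1p(exp(a * logz))
    out[hi] <- exp(log_fp)
  }
  out
}

#' Inverse of the soft-core transform
#'
#' Analytic: `z = ((1 + f) / (1 - f))^(1/a)` and
#' `y = a (sqrt(2 z - 1) - 1) / 2` with `f = (u_sc - u_cut)/(u_max - u_cut)`.
#'
#' @param u_sc Soft-core energies, each `< u_max`.
#' @param sc A [softcore_spec()].
#' @return Raw energies `u` with `softcore(u, sc) == u_sc`.
#' @export
softcore_inverse <- function(u_sc, sc) {
  stopifnot(inherits(sc, "softcore_spec"))
  if (any(u_sc >= sc$u_max))
    stop("u_sc must be below u_max (the soft-core cap is never attained)")
  out <- u_sc
  hi <- is.finite(u_sc) & u_sc > sc$u_cut
  if (any(hi)) {
    a <- sc$a_exponent
    span <- sc$u_max - sc$u_cut
    f <- (u_sc[hi] - sc$u_cut) / span
    logz <- (log1p(f) - log1p(-f)) / a
    y <- ifelse(logz > 700,
                a * (sqrt(2) * exp(logz / 2) - 1) / 2,  # overflow-safe asymptote
                a * (sqrt(pmax(2 * exp(pmin(logz, 700)) - 1, 0)) - 1) / 2)
    out[hi] <- span * y + sc$u_cut
  }
  out
}
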