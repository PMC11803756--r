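#' Softplus alchemical perturbation function
#'
#' `W_lambda(u_sc) = ((lambda2 - lambda1)/alpha) * log(1 + exp(-alpha (u_sc - u0)))
#'  + lambda2 * u_sc`. It reduces to the linear form `lambda * u_sc` when
#' `lambda1 == lambda2 == lambda`, vanishes identically when
#' `lambda1 == lambda2 == 0`, and is evaluated through a numerically stable
#' softplus (`max(x, 0) + log1p(exp(-|x|))`).
#'
#' @param u_sc Soft-core perturbation energies (kcal/mol); vectorized.
#' @param pt A [schedule_point()].
#' @return `W` in kcal/mol.
#' @export
w_lambda <- function(u_sc, pt) {
  stopifnot(inherits(pt, "schedule_point"))
  x <- -pt$alpha * (u_sc - pt$u0_shift)
  softplus <- pmax(x, 0) + log1p(exp(-abs(x)))
  (pt$lam2 - pt$lam1) / pt$alpha * softplus + pt$lam2 * u_sc
}

#' One point of an alchemical schedule
#'
#' The four softplus parameters as functions of the progress variable
#' `lambda`. A linear point has `lambda1 == lambda2 == lambda` (the values of
#' `alpha` and `u0` are then irrelevant).
#'
#' @param lam Progress variable in `[0, 1]`.
#' @param lam1,lam2 Softplus mixing parameters.
#' @param alpha Softplus sharpness, 1/(kcal/mol), > 0.
#' @param u0_shift Softplus inflection energy (kcal/mol).
#' @return Object of class `"schedule_point"`.
#' @export
schedule_point <- function(lam, lam1 = lam, lam2 = lam, alpha = 1, u0_shift = 0) {
  stopifnot(is.numeric(lam), length(lam) == 1L, is.finite(lam))
  if (lam < 0 || lam > 1) stop("lambda must lie in [0, 1]")
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  stopifnot(is.finite(lam1), is.finite(lam2), is.finite(u0_shift))
  structure(list(lam = lam, lam1 = lam1, lam2 = lam2, alpha = alpha,
                 u0_shift = u0_shift), class = "schedule_point")
}

#' Alchemical schedule
#'
#' An ordered set of [schedule_point()]s (strictly increasing `lambda`) tied
#' to the [softcore_spec()] governing the run. On construction the endpoint
#' contract is verified numerically on a grid: `W` at `lambda = 0` must vanish
#' and `W` at `lambda = 1` must be the identity on `u_sc` (only checked if the
#' respective endpoints are part of the schedule).
#'
#' @param points List of [schedule_point()]s.
#' @param softcore A [softcore_spec()].
#' @param validate Check ordering and the endpoint contract.
#' @return Object of class `"lambda_schedule"`.
#' @export
lambda_schedule <- function(points, softcore = softcore_spec(), validate = TRUE) {
  if (inherits(points, "schedule_point")) points <- list(points)
  stopifnot(is.list(points), length(points) >= 1L,
            all(vapply(points, inherits, logical(1), "schedule_point")),
            inherits(softcore, "softcore_spec"))
  lams <- vapply(points, `[[`, numeric(1), "lam")
  if (validate) {
    if (any(diff(lams) <= 0)) stop("lambda must be strictly increasing")
    grid <- seq(softcore$u_cut - 50, softcore$u_max - 1e-3, length.out = 101)
    for (pt in points) {
      if (pt$lam == 0 && max(abs(w_lambda(grid, pt))) > 1e-8)
        stop("endpoint contract violated: W at lambda = 0 must vanish")
      if (pt$lam == 1 && max(abs(w_lambda(grid, pt) - grid)) > 1e-8)
        stop("endpoint contract violated: W at lambda = 1 must be the identity")
    }
  }
  structure(list(points = points, softcore = softcore),
            class = "lambda_schedule")
}

#' @export
print.lambda_schedule <- function(x, ...) {
  cat(sprintf("alchemical schedule: %d states\n", length(x$points)))
  print(as.data.frame(x))
  print(x$softcore)
  invisible(x)
}

#' @export
as.data.frame.lambda_schedule <- function(x, ...) {
  do.call(rbind, lapply(x$points, function(p)
    data.frame(lambda = p$lam, lambda1 = p$lam1, lambda2 = p$lam2,
               alpha = p$alpha, u0 = p$u0_shift)))
}

#' Evenly spaced linear schedule
#'
#' `n_states` points with `lambda1 = lambda2 = lambda` evenly spaced on
#' `[0, lam_end]` (`lam_end = 1/2` selects one alchemical-transfer leg).
#'
#' @param n_states Number of states, >= 2.
#' @param softcore A [softcore_spec()].
#' @param lam_end Final `lambda` (default 1).
#' @export
linear_schedule <- function(n_states, softcore = softcore_spec(), lam_end = 1) {
  if (!is.numeric(n_states) || n_states < 2) stop("n_states must be >= 2")
  lams <- seq(0, lam_end, length.out = as.integer(n_states))
  lambda_schedule(lapply(lams, schedule_point), softcore = softcore)
}

#' Read an alchemical schedule from a table
#'
#' Tabular text (TSV or CSV, auto-detected from the header line) with columns
#' `lambda, lambda1, lambda2, alpha, u0`.
#'
#' @param path File path.
#' @param softcore A [softcore_spec()] for the run.
#' @param validate Passed to [lambda_schedule()].
#' @export
read_schedule <- function(path, softcore = softcore_spec(), validate = TRUE) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  need <- c("lambda", "lambda1", "lambda2", "alpha", "u0")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("schedule file is missing columns: ", paste(miss, collapse = ", "))
  pts <- lapply(seq_len(nrow(df)), function(i)
    schedule_point(df$lambda[i], df$lambda1[i], df$lambda2[i],
                   df$alpha[i], df$u0[i]))
  lambda_schedule(pts, softcore = softcore, validate = validate)
}
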