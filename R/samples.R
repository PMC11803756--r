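#' Multi-state perturbation-energy sample set
#'
#' The unit of inference: soft-core perturbation energies tagged by the
#' alchemical state that produced them. Internally a data frame with columns
#' `state_index`, `lambda`, `lambda1`, `lambda2`, `alpha`, `u0`,
#' `u_sc_kcal_mol`; every state index maps to exactly one schedule point and
#' every energy lies below the governing soft-core cap.
#'
#' @param df Data frame with the columns above (`state_index` 1-based).
#' @param softcore The governing [softcore_spec()].
#' @param provenance Optional list recorded as an attribute (seed, model,
#'   grid resolution, ...).
#' @return Object of class `"sample_set"` (a data frame).
#' @export
sample_set <- function(df, softcore = softcore_spec(), provenance = NULL) {
  need <- c("state_index", "lambda", "lambda1", "lambda2", "alpha", "u0",
            "u_sc_kcal_mol")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample set is missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$u_sc_kcal_mol)))
    stop("non-finite perturbation energies in sample set")
  if (any(df$u_sc_kcal_mol >= softcore$u_max))
    stop("samples at or above the soft-core cap u_max")
  for (s in unique(df$state_index)) {
    rows <- df[df$state_index == s, c("lambda", "lambda1", "lambda2", "alpha", "u0")]
    if (nrow(unique(rows)) != 1L)
      stop("state_index ", s, " maps to more than one schedule point")
  }
  structure(as.data.frame(df), softcore = softcore, provenance = provenance,
            class = c("sample_set", "data.frame"))
}

#' @export
print.sample_set <- function(x, ...) {
  tab <- table(x$state_index)
  cat(sprintf("sample set: %d samples in %d states (n per state: %s)\n",
              nrow(x), length(tab),
              paste(utils::head(as.integer(tab), 12), collapse = ", ")))
  invisible(x)
}

## schedule points per state, ordered by state_index
sample_states <- function(samples) {
  idx <- sort(unique(samples$state_index))
  lapply(idx, function(s) {
    r <- samples[samples$state_index == s, ][1, ]
    schedule_point(r$lambda, r$lambda1, r$lambda2, r$alpha, r$u0)
  })
}

sample_counts <- function(samples) {
  idx <- sort(unique(samples$state_index))
  vapply(idx, function(s) sum(samples$state_index == s), numeric(1))
}

#' @export
as.data.frame.sample_set <- function(x, ...) {
  class(x) <- "data.frame"
  x
}
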