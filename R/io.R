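#' Read an analytical model from JSON
#'
#' Model files are JSON documents with a `label`, a `role` tag
#' (`host-coupling`, `solvent-coupling`, `transfer-binding`,
#' `transfer-unbinding`) and one record per mode carrying
#' `{weight, b, u0bar, sigma, epsilon, u_tilde, n_l}` (energies in
#' kcal/mol). Weights must sum to 1; sums off by at most `1e-3` (as printed,
#' rounded parameter tables are) are renormalized exactly, anything worse is
#' rejected with the offending sum.
#'
#' @param path Path to a JSON model file.
#' @return A [coupling_model()].
#' @export
read_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$modes) || length(doc$modes) == 0L)
    stop("model file has no 'modes' array: ", path)
  need <- c("weight", "b", "u0bar", "sigma", "epsilon", "u_tilde", "n_l")
  modes <- lapply(seq_along(doc$modes), function(i) {
    m <- doc$modes[[i]]
    miss <- setdiff(need, names(m))
    if (length(miss))
      stop(sprintf("mode %d is missing field(s): %s", i,
                   paste(miss, collapse = ", ")))
    for (f in need) if (!is.numeric(m[[f]]))
      stop(sprintf("mode %d field '%s' is not numeric", i, f))
    model_mode(m$weight, gaussian_params(m$u0bar, m$sigma),
               collision_params(m$b, m$epsilon, m$u_tilde, m$n_l))
  })
  wsum <- sum(vapply(modes, `[[`, numeric(1), "weight"))
  if (abs(wsum - 1) > 1e-3)
    stop(sprintf("mode weights must sum to 1; file '%s' sums to %.6g",
                 path, wsum))
  coupling_model(modes,
                 label = if (is.null(doc$label)) "" else doc$label,
                 role = if (is.null(doc$role)) NA_character_ else doc$role,
                 normalize = abs(wsum - 1) > 1e-12)
}

#' Write an analytical model to JSON
#'
#' Full-precision parameters; `read_model(write_model(m, f))` reproduces `m`
#' exactly.
#'
#' @param model A [coupling_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "coupling_model"))
  doc <- list(label = model$label, role = model$role,
              modes = lapply(model$modes, function(m)
                list(weight = m$weight, b = m$collision$b_no_collision,
                     u0bar = m$gaussian$mean_u0, sigma = m$gaussian$sigma,
                     epsilon = m$collision$epsilon,
                     u_tilde = m$collision$u_tilde, n_l = m$collision$n_l)))
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null"), path)
  invisible(path)
}

#' Bundled reference models
#'
#' Parameter sets for the water/TEMOA host-guest case studies shipped as
#' JSON under `inst/extdata/models`: coupling of water to water
#' (`h2o-coupling`), coupling of water and the five SAMPL8 guests to the
#' TEMOA host (`temoa-*-coupling`), the guests' hydration models
#' (`*-hydration`), and the published water transfer models (`h2o-transfer`,
#' `temoa-h2o-transfer-leg1/2`, which include small refits of the
#' collisional block relative to what the product rule yields).
#'
#' @param name Model name (without extension); `builtin_models()` lists
#'   what is available.
#' @return A [coupling_model()] (or a character vector of names).
#' @examples
#' builtin_models()
#' builtin_model("h2o-coupling")
#' @export
builtin_model <- function(name) {
  path <- system.file("extdata", "models", paste0(name, ".json"),
                      package = "pdtalch")
  if (!nzchar(path))
    stop("no bundled model named '", name, "'; see builtin_models()")
  read_model(path)
}

#' @rdname builtin_model
#' @export
builtin_models <- function() {
  dir <- system.file("extdata", "models", package = "pdtalch")
  sub("\\.json$", "", list.files(dir, pattern = "\\.json$"))
}

#' @rdname builtin_model
#' @export
h2o_coupling_model <- function() builtin_model("h2o-coupling")

#' Read multi-state perturbation-energy samples from TSV
#'
#' Expects a header with columns `state_index, lambda, lambda1, lambda2,
#' alpha, u0, u_sc_kcal_mol`; extra columns (e.g. replica-exchange
#' provenance) are ignored. Rows with energies at or above the soft-core cap
#' are dropped with a warning naming their lines; non-numeric cells are an
#' error with the offending line number. An optional equilibration discard
#' removes the leading fraction of each state's rows in file order.
#'
#' @param path TSV file path.
#' @param softcore The governing [softcore_spec()].
#' @param discard_fraction Fraction in `[0, 1)` of each state's initial rows
#'   to drop (default 0; molecular-simulation workflows typically use 1/3).
#' @return A [sample_set()].
#' @export
read_samples <- function(path, softcore = softcore_spec(),
                         discard_fraction = 0) {
  if (discard_fraction < 0 || discard_fraction >= 1)
    stop("discard_fraction must lie in [0, 1)")
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = NA, stringsAsFactors = FALSE)
  need <- c("state_index", "lambda", "lambda1", "lambda2", "alpha", "u0",
            "u_sc_kcal_mol")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("sample file is missing columns: ", paste(miss, collapse = ", "))
  for (col in need) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at line %d of %s",
                   col, bad[1] + 1L, path))
    if (anyNA(v))
      stop(sprintf("missing value in column '%s' at line %d of %s",
                   col, which(is.na(v))[1] + 1L, path))
    df[[col]] <- v
  }
  over <- which(df$u_sc_kcal_mol >= softcore$u_max)
  if (length(over)) {
    warning(sprintf(
      "dropped %d row(s) with u_sc >= u_max = %g kcal/mol (first at line %d)",
      length(over), softcore$u_max, over[1] + 1L))
    df <- df[-over, , drop = FALSE]
  }
  if (discard_fraction > 0) {
    keep <- unlist(lapply(split(seq_len(nrow(df)), df$state_index),
                          function(ix) {
                            drop_n <- floor(discard_fraction * length(ix))
                            ix[seq_along(ix) > drop_n]
                          }))
    df <- df[sort(keep), , drop = FALSE]
  }
  sample_set(df[need], softcore = softcore)
}

#' Write a sample set to TSV
#'
#' @param samples A [sample_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  stopifnot(inherits(samples, "sample_set"))
  utils::write.table(as.data.frame(samples), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a free-energy profile to TSV
#'
#' Columns `lambda`, `K_lambda`, `delta_g_kcal_mol`.
#'
#' @param profile A [free_energy_profile()] result.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "fe_profile"))
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
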