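#' Build an alchemical-transfer model from two coupling models
#'
#' The perturbation energy of transferring a ligand from the solvent to the
#' receptor site is the receptor-coupling energy minus the solvent
#' interaction energy in the solvated state, so its decoupled-state density
#' is the convolution of the receptor-coupling density with the mirrored
#' solvated-state density. Because the solvated state is clash-free, the
#' latter is Gaussian, and the convolution closes within the analytical
#' family: every pair of a receptor mode `i` and a solvent mode `j` yields a
#' transfer mode with
#' weight `w_ih * w_js`, mean `u0bar_h,i - u1bar_s,j` (with the coupled-state
#' mean `u1bar = u0bar - beta sigma^2` from linear response), standard
#' deviation `sqrt(sigma_h,i^2 + sigma_s,j^2)`, and collisional parameters
#' `(b, epsilon, u_tilde, n_l)` inherited from the receptor mode. For the
#' unbinding direction the two roles are exchanged.
#'
#' @param receptor Receptor-coupling [coupling_model()].
#' @param solvent Solvent-coupling (hydration) [coupling_model()].
#' @param direction `"binding"` (collisional parameters from the receptor
#'   model) or `"unbinding"` (from the solvent model).
#' @param th A [thermo()] object.
#' @param mean_method How the coupled-state mean of the decoupled role is
#'   obtained: the linear-response closed form (default, matches the
#'   printed transfer parameters) or full quadrature (needs `sc`).
#' @param sc,q Soft-core and quadrature settings for
#'   `mean_method = "quadrature"`.
#' @param label Label for the resulting model.
#' @return A [coupling_model()] with `m_h * m_s` modes.
#' @examples
#' w <- h2o_coupling_model()
#' tr <- build_transfer_model(w, w)   # water in water: one mode,
#' tr$modes[[1]]$gaussian             # mean 20.1, sigma 4.89
#' @export
build_transfer_model <- function(receptor, solvent,
                                 direction = c("binding", "unbinding"),
                                 th = thermo(),
                                 mean_method = c("linear-response", "quadrature"),
                                 sc = NULL, q = quadrature_spec(),
                                 label = NULL) {
  direction <- match.arg(direction)
  mean_method <- match.arg(mean_method)
  stopifnot(inherits(receptor, "coupling_model"),
            inherits(solvent, "coupling_model"))
  if (length(receptor$modes) == 0L || length(solvent$modes) == 0L)
    stop("both coupling models must have at least one mode")
  th <- as_thermo(th)
  ## "gain" role keeps its decoupled mean and collisional parameters;
  ## "loss" role enters through its coupled-state mean, mirrored
  if (direction == "binding") { gain <- receptor; loss <- solvent }
  else                        { gain <- solvent;  loss <- receptor }
  u1 <- if (mean_method == "linear-response") {
    coupled_state_mean(loss, th)$per_mode$u1bar
  } else {
    vapply(seq_along(loss$modes), function(j) {
      single <- coupling_model(list(loss$modes[[j]]), normalize = TRUE)
      coupled_state_mean(single, th, method = "quadrature", sc = sc, q = q)$overall
    }, numeric(1))
  }
  modes <- list()
  for (i in seq_along(gain$modes)) {
    gi <- gain$modes[[i]]
    for (j in seq_along(loss$modes)) {
      lj <- loss$modes[[j]]
      modes[[length(modes) + 1L]] <- model_mode(
        weight = gi$weight * lj$weight,
        gaussian = gaussian_params(gi$gaussian$mean_u0 - u1[j],
                                   sqrt(gi$gaussian$sigma^2 + lj$gaussian$sigma^2)),
        collision = gi$collision)
    }
  }
  if (is.null(label))
    label <- sprintf("%s transfer (%s)", direction,
                     paste(c(receptor$label, solvent$label), collapse = " / "))
  coupling_model(modes, label = label,
                 role = paste0("transfer-", direction))
}

#' Two-leg excess binding free energy
#'
#' The alchemical-transfer estimate combines the binding leg (solution to
#' site) and the unbinding leg: `dG_b = dG_plus - dG_minus`.
#'
#' @param dg_plus,dg_minus Leg free energies (kcal/mol).
#' @export
two_leg_free_energy <- function(dg_plus, dg_minus) {
  stopifnot(is.finite(dg_plus), is.finite(dg_minus))
  dg_plus - dg_minus
}

#' Ideal component of the standard binding free energy
#'
#' `-kT log(C0 * V_site)` for a spherical site of the given radius at the
#' 1 M standard concentration (one molecule per 1660.539 cubic Angstrom).
#'
#' @param site_radius Flat-bottom site radius in Angstrom, > 0.
#' @param th A [thermo()] object.
#' @return kcal/mol.
#' @examples
#' ideal_binding_term(4.5)  # 0.88 kcal/mol at 300 K
#' @export
ideal_binding_term <- function(site_radius, th = thermo()) {
  if (!is.numeric(site_radius) || site_radius <= 0)
    stop("site_radius must be > 0")
  th <- as_thermo(th)
  v_site <- 4 / 3 * pi * site_radius^3
  -th$kT * log(v_site / 1660.539)
}

#' Cavity-formation free energy from the clash-free probability
#'
#' `dG_cav = -kT log(b)`: the free-energy cost of opening a solvent cavity
#' of the size and shape of the solute, read off the `b` parameter of its
#' hydration model.
#'
#' @param b Probability of a collision-free configuration, in `(0, 1]`.
#' @param th A [thermo()] object.
#' @return kcal/mol (non-negative).
#' @export
cavity_free_energy <- function(b, th = thermo()) {
  if (!is.numeric(b) || any(b <= 0) || any(b > 1))
    stop("b must lie in (0, 1]")
  -as_thermo(th)$kT * log(b)
}

#' Standard binding free energy from its components
#'
#' @param excess_dg Excess (interaction) component, kcal/mol.
#' @param ideal_dg Ideal (site-volume / standard-state) component, kcal/mol.
#' @export
standard_binding_free_energy <- function(excess_dg, ideal_dg) {
  stopifnot(is.finite(excess_dg), is.finite(ideal_dg))
  excess_dg + ideal_dg
}
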