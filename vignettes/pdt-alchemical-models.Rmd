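---
title: "Analytical perturbation-energy models for alchemical coupling and transfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytical perturbation-energy models for alchemical coupling and transfer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdtalch)
```

## The model and its assumptions

Alchemical binding free-energy calculations hinge on the distribution of the
perturbation energy $u = U_1(x) - U_0(x)$ in the *decoupled* ensemble, where
the ligand does not interact with its environment. Decoupled configurations
fall into two statistical regimes. Long-range electrostatic and dispersion
interactions sum many small contributions, so the *background* energy $u_b$
is Gaussian by central-limit/linear-response arguments, with mean
$\bar u_0$ and standard deviation $\sigma$ (both kcal/mol). Short-range
repulsions are dominated by the single most severe atomic clash among
$n_l$ effectively independent atom groups, so the *collisional* energy
$u_c \ge 0$ follows max statistics. Starting from a Lennard-Jones-like
contact energy with prefactor $\varepsilon$ and onset $\tilde u$, its
distribution function is, with
$x = \sqrt{1 + (u_c + \tilde u)/\varepsilon}$ and
$x_c = \sqrt{1 + \tilde u/\varepsilon}$,

$$G(u_c) = \left[\,1 - \sqrt{\tfrac{1 + x_c}{1 + x}}\,\right]^{n_l},
\qquad u_c \ge 0,$$

and the density implemented in `collision_density()` is its exact
derivative,
$F(u_c) = n_l\,[1 - \sqrt{(1+x_c)/(1+x)}]^{\,n_l - 1}\,
\sqrt{1 + x_c} / \bigl(4 \varepsilon x (1 + x)^{3/2}\bigr)$.
Some renderings of this expression typeset $x$ and $x_c$ without the
radical; only the square-root form makes $F$ the derivative of the
max-statistics distribution function (including the $1/(4\varepsilon x)$
factor, which arises from $dx/du_c = 1/(2\varepsilon x)$) and integrates to
one, which is how the package pins the convention down. Two consequences
worth knowing:

* The clash tail is extremely heavy, $1 - G \sim u_c^{-1/4}$: the
  distribution is normalized but has **no finite mean**. Raw-energy
  averages over clash-contaminated ensembles are therefore reported on a
  truncated domain (see `coupled_state_mean()`), while every
  Boltzmann-weighted or soft-core-capped functional is finite.
* Because the distribution function and quantile function are analytic,
  normalization checks, tail masses and exact sampling never rely on
  truncated quadrature of the heavy tail.

A mode of the full model mixes a clash-free channel (probability $b$) with
a clashed channel, $p_0(u) = b\,N(u) + (1-b)\,(N \circledast F)(u)$, the
convolution resolved by Gauss–Hermite quadrature over the Gaussian factor
(19 nodes by default; the node count is configurable and the test suite
carries an independent dense-grid convolution oracle). Conformational
heterogeneity adds a mixture over modes with weights $w_i$. The probability
$b$ of finding a clash-free configuration links to hydrophobicity theory
through the cavity-formation free energy $-k_B T \ln b$
(`cavity_free_energy()`).

## Propagation along the alchemical path

The potential distribution theorem propagates $p_0$ to every state:
$p_\lambda(u) \propto e^{-\beta W_\lambda(u)} p_0(u)$ with normalization
$K(\lambda)$, and $\Delta G_b(\lambda) = -k_B T \ln K(\lambda)$. The
package works in the soft-core variable $u_{sc}$, the monotone transform
that is the identity below $u_{cut}$ and caps raw energies below $u_{max}$
(`softcore_spec()`; defaults $u_{cut}=0$, $u_{max}=50$ kcal/mol for
coupling, $100/200$ for host–guest transfer, softness $a = 1/16$). All
quadratures (`k_lambda()`, `free_energy_profile()`) are composite
trapezoid rules in $u_{sc}$: dense uniform nodes across the background
support (12 background standard deviations below the lowest mode, widened
by the linear-response shift $\beta\sigma^2$), log-spaced nodes across the
compressed clash region up to $10^{-6}(u_{max}-u_{cut})$ below the cap
(4001 nodes in total by default), an analytic correction for the residual
mass beyond the grid (where $W$ is constant at its capped value to
excellent accuracy), and log-domain accumulation so that strongly tilted
states ($e^{-\beta W} \sim e^{75}$ at $\lambda = 1$) neither overflow nor
underflow. Doubling the node count changes $K$ by $\lesssim 10^{-8}$
relative on the bundled models; `k_lambda(rel_tol =)` exposes that
refinement check.

The alchemical function is the softplus
$W_\lambda(u_{sc}) = \frac{\lambda_2-\lambda_1}{\alpha}
\ln(1 + e^{-\alpha(u_{sc}-u_0)}) + \lambda_2 u_{sc}$, evaluated through
$\max(z,0) + \log1p(e^{-|z|})$ so extreme arguments keep their asymptotes.
Linear schedules ($\lambda_1=\lambda_2=\lambda$) are generated by
`linear_schedule()`; the nonlinear schedules used in production simulations
are run-specific inputs, so the package reads user-supplied
$(\lambda, \lambda_1, \lambda_2, \alpha, u_0)$ tables instead of shipping
any. Model parameters are schedule-independent, so nothing downstream
depends on this choice.

## Transfer models and binding bookkeeping

For the transfer of a ligand between solvent and receptor site, the
decoupled-state density is the convolution of the receptor-coupling density
with the mirrored solvated-state density. Since the solvated state is
clash-free, the latter is Gaussian with mean $\bar u_1 = \bar u_0 -
\beta\sigma^2$ (the linear-response coupled-state mean; exact for a
Gaussian mode, and matching the published transfer tables to their printed
precision, which is why it is the default in `build_transfer_model()` — a
full-quadrature mean is available behind `mean_method`). Modes combine
pairwise: weight $w_{ih} w_{js}$, mean $\bar u_{0h,i} - \bar u_{1s,j}$,
variance $\sigma_{h,i}^2 + \sigma_{s,j}^2$, collisional block inherited
from the receptor mode (binding) or the solvent mode (unbinding). The
package implements the literal product rule for the weights; published
transfer tables show small deviations from it (e.g. 0.462 vs 0.446) that
stem from refitting the transfer model to simulation data, which this
package deliberately does not emulate. For the same reason one published
transfer mean (18.8 kcal/mol) differs from the combination rule's 18.74 in
its last digit. Direction bookkeeping follows the theory (binding inherits
the receptor collisional block); published "leg" labels are not hard-coded
because their mapping to directions is ambiguous in the source tables.

`ideal_binding_term()` evaluates $-k_B T \ln C^\circ V_{site}$ with
$C^\circ$ = 1 molecule / 1660.539 Å$^3$ and a spherical site;
`two_leg_free_energy()` and `standard_binding_free_energy()` complete the
double-decoupling arithmetic. The Boltzmann constant is fixed at
0.0019872041 kcal/(mol K) and the default temperature at 300 K; all
energies are kcal/mol with no unit-conversion layer.

## Inference from multi-state samples

`uwham()` solves the standard unbinned multistate reweighting equations on
the reduced energies $\beta W_{\lambda_k}(u_{sc,i})$ by minimizing the
equivalent convex objective (BFGS with analytic gradient) and polishing
with direct iteration to $\max|\Delta f| < 10^{-8}$, anchoring $f_1 = 0$.
It returns per-sample weights at the target state, an effective sample
size (a warning is recorded below 20), and optional within-state bootstrap
standard errors. `kernel_p0_estimate()` and `kernel_lambda_function()`
implement the weighted Gaussian kernel diagnostics (bandwidth 1 kcal/mol by
default) whose shapes guide initialization: for a Gaussian mode the
λ-function $k_B T\, d\log p_0/du_{sc}$ is linear with slope
$-k_B T/\sigma^2$ and zero crossing at $\bar u_0$.

`initialize_from_diagnostics()` automates the graphical initialization:
it restricts the weighted kernel estimate to the clash-free side of the
soft-core onset (collisional mass cannot lie below $u_{cut}$), segments it
at local minima, fits a quadratic to each segment's log-density (vertex
$\to \bar u_0$, curvature $\to \sigma$, with the kernel bandwidth
deconvolved), and converts segment masses into weights and a common $b$
through the identity "visible mass $\approx w_i\, b\,
\Phi((u_{cut}-\bar u_0)/\sigma)$". This reproduces a known $b$ exactly for
one mode and returns $b \approx 1$ on clash-free data; it is a starting
point, not an estimator — the published fits were initialized manually and
are not claimed to be reproducible from raw samples.

`pdt_fit()` minimizes the pooled negative log-likelihood
$-\sum_i \log p_{\lambda_i}(u_{sc,i}|\theta)$ (soft-core Jacobian
included; densities floored at $10^{-300}$ so stray samples yield a large
finite penalty). Weights are optimized through a softmax transform, $b$
through a logit, positive parameters through logs, and $\sigma$ is floored
at 0.3 kcal/mol — sub-0.3 background widths are unphysical at these energy
scales, and the floor removes the classical spike degeneracy of mixture
likelihoods. Each start runs a Nelder–Mead simplex search followed by a
BFGS polish; the simplex stage proved markedly more robust than
numeric-gradient descent on multimodal mixture surfaces, and a seeded
multi-start option jitters the initial point. The returned cost never
exceeds the initial cost. Collisional parameters are only weakly
identifiable — widely different $(\varepsilon, \tilde u, n_l)$ fit equally
well, a property of the model family itself — so recovery checks treat
them as order-of-magnitude quantities, and `fit_collision = FALSE`
restricts the family to clash-free Gaussian mixtures ($b = 1$).

## Synthetic data

`generate_dataset()` draws i.i.d. samples per state by inverse-CDF on a
dense tabulation of $p_\lambda(u_{sc})$ (20001 grid points by default,
monotone Hyman-spline interpolation of the CDF; rejection sampling was
rejected as fragile near the soft-core pile-up). A master seed spawns
deterministic per-state substreams, so extending a schedule leaves earlier
states' samples unchanged, and provenance (model, schedule, seed, grid
resolution) travels with the data. If more than $10^{-4}$ of a state's
mass falls outside the tabulation grid the sampler errors and asks for a
wider grid. What the generator deliberately does **not** emulate:
replica-exchange autocorrelation, equilibration transients, and force-field
error — passing recovery tests therefore demonstrates correctness of the
estimators under the model, not robustness to real-data pathologies
(equilibration trimming is available at read time via
`read_samples(discard_fraction = 1/3)`).

One subtlety drove a test-design choice. For the symmetric water-in-water
transfer model under a *linear* schedule with the low-cut soft-core
($u_{cut} = 0$), the midpoint density develops a dominant lobe just above
the cut — the compressed image of the Gaussian bulk — with no mirror
partner at negative energies, so the two legs' midpoint distributions are
*not* mirror images under the analytical model even though they are in
simulation (which used nonlinear schedules that suppress that region). The
mirror-symmetry property is therefore verified where the model's
linear-response assumptions hold: the clash-free symmetric transfer model
with the high-cut soft-core, for which the midpoint tilt centers the
density exactly at zero and the mirror relation is analytic.

## Problem sizes and runtime

The recovery experiments run at the study scale: 11 linear states with
5000 samples/state for UWHAM and single-mode maximum-likelihood recovery,
10000 samples/state for two-mode density-level recovery, 16 bootstrap
replicates for reweighting errors; together they complete in a few minutes
on one core. Closed-form and table-derived checks are instantaneous.

## Known limitations

* The collisional block is identifiable only at the order-of-magnitude
  level; do not interpret fitted $(\varepsilon, \tilde u, n_l)$
  quantitatively.
* Raw-energy means over clash-contaminated ensembles diverge; use
  soft-core means or the linear-response closed form.
* The automated initializer assumes the clash-free side of the onset is
  populated; data consisting purely of clashes defeats it (it falls back
  to the full grid and flags nothing).
* Per-atom soft-core pair potentials are out of scope: the theory requires
  an alchemical potential that depends on configurations only through the
  scalar perturbation energy.
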