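# Electroporation state per interface node: pore density N follows the
# asymptotic Smoluchowski-derived rate equation, a representative pore
# radius follows the pore-energy gradient flow, and together they close the
# membrane current law through the electroporation current density J_EP.

#' Pore density creation rate
#'
#' `dN/dt = alpha * exp((V/U_ep)^2) * (1 - N/N0 * exp(-q (V/U_ep)^2))`.
#' Smooth and symmetric in the sign of `V_m`; the exponent is guarded by
#' capping `|V_m|` (see `vm_cap` in the numerics block).
#'
#' @param V_m transmembrane voltage (V), vectorised.
#' @param N pore density (m^-2).
#' @param p electroporation parameter block (`$ep` of an `ep_params`).
#' @param vm_cap exponent guard (V).
#' @return dN/dt (m^-2 s^-1).
#' @export
pore_density_rate <- function(V_m, N, p, vm_cap = 2) {
  stopifnot(all(N >= 0))
  v <- pmin(abs(V_m), vm_cap)
  x2 <- (v / p$U_ep)^2
  p$alpha * exp(x2) * (1 - (N / p$N0) * exp(-p$q * x2))
}

# equilibrium pore density at constant voltage (closed-form fixed point)
pore_density_equilibrium <- function(V_m, p, vm_cap = 2) {
  v <- pmin(abs(V_m), vm_cap)
  p$N0 * exp(p$q * (v / p$U_ep)^2)
}

#' Pore energy
#'
#' Energy of a single hydrophilic pore of radius `r`:
#' electric (`-V^2 F_max (r - r_h log(r + r_h + r_t))`), steric repulsion
#' (`steric_coeff (r_star/r)^4`), line tension (`2 pi gamma r`) and surface
#' tension (`- pi delta_eff r^2`).  Its negative radial gradient times
#' `D/kT` is exactly [pore_radius_rate()]; the energy itself serves as a
#' diagnostic and as the test oracle for that consistency.
#'
#' @param r pore radius (m), vectorised; must be positive.
#' @param V_m transmembrane voltage (V).
#' @param delta_eff effective membrane tension (J m^-2), see
#'   [effective_tension()].
#' @param p electroporation parameter block.
#' @param steric include the steric term.
#' @return Energy (J).
#' @export
pore_energy <- function(r, V_m, delta_eff, p, steric = TRUE) {
  if (any(r <= 0)) stop("pore radius must be positive")
  W <- -V_m^2 * p$F_max * (r - p$r_h * log(r + p$r_h + p$r_t)) +
    2 * pi * p$gamma * r - pi * delta_eff * r^2
  if (steric) W <- W + p$steric_coeff * (p$r_star / r)^4
  W
}

#' Pore radius drift rate
#'
#' `dr/dt = (D/kT) [ V^2 F_max / (1 + r_h/(r + r_t)) + 4 steric_coeff
#' r_star^4 / r^5 - 2 pi gamma + 2 pi delta_eff r ]`, the advection velocity
#' of the asymptotic pore model; identical to `-(D/kT) dW/dr` of
#' [pore_energy()].
#'
#' @inheritParams pore_energy
#' @return dr/dt (m/s).
#' @export
pore_radius_rate <- function(r, V_m, delta_eff, p, steric = TRUE) {
  if (any(r <= 0)) stop("pore radius must be positive")
  f <- V_m^2 * p$F_max / (1 + p$r_h / (r + p$r_t)) -
    2 * pi * p$gamma + 2 * pi * delta_eff * r
  if (steric) f <- f + 4 * p$steric_coeff * p$r_star^4 / r^5
  (p$D_pore / (p$k_B * p$T)) * f
}

#' Effective membrane tension
#'
#' Tension of a membrane whose fraction `A_frac` is occupied by pores:
#' `2 sigma' - (2 sigma' - sigma0) / (1 - A_frac)^2`.  Equals `sigma0` for
#' an intact membrane and decreases monotonically as pores accumulate.
#'
#' @param A_frac fractional electroporated area, in `[0, 1)`.
#' @param p electroporation parameter block.
#' @return delta_eff (J m^-2).
#' @export
effective_tension <- function(A_frac, p) {
  if (any(A_frac < 0 | A_frac >= 1)) stop("A_frac must lie in [0, 1)")
  2 * p$sigma_prime - (2 * p$sigma_prime - p$sigma0) / (1 - A_frac)^2
}

#' Electroporation current density
#'
#' `J_EP = N * i_pore(V_m, r)` with the per-pore current through the series
#' of the pore-interior resistance `d / (sigma_p pi r^2)` and (for the
#' default `"access"` model) the access resistance `1 / (2 sigma_bulk r)`
#' of the adjacent electrolyte.  `model = "ohmic"` drops the access term.
#'
#' @param V_m transmembrane voltage (V).
#' @param N pore density (m^-2).
#' @param r pore radius (m).
#' @param p electroporation parameter block (`sigma_p` taken from it).
#' @param d membrane thickness (m).
#' @param sigma_bulk mean conductivity of the two adjacent bulk media (S/m).
#' @param model `"access"` or `"ohmic"`.
#' @return J_EP (A m^-2).
#' @export
ep_current_density <- function(V_m, N, r, p, d, sigma_bulk,
                               model = c("access", "ohmic")) {
  stopifnot(all(N >= 0), all(r >= 0))
  N * V_m * .pore_conductance_single(r, p, d, sigma_bulk, match.arg(model))
}

# radial derivative of pore_radius_rate at fixed delta_eff; used to damp the
# radius sub-step near stable stationary radii (semi-implicit update)
.pore_radius_rate_deriv <- function(r, V_m, delta_eff, p, steric = TRUE) {
  f <- V_m^2 * p$F_max * p$r_h / (r + p$r_t + p$r_h)^2 + 2 * pi * delta_eff
  if (steric) f <- f - 20 * p$steric_coeff * p$r_star^4 / r^6
  (p$D_pore / (p$k_B * p$T)) * f
}

# per-pore conductance (S); vectorised in r
.pore_conductance_single <- function(r, p, d, sigma_bulk, model) {
  R_int <- d / (p$sigma_p * pi * r^2)
  R_acc <- if (model == "access") 1 / (2 * sigma_bulk * r) else 0
  1 / (R_int + R_acc)
}

#' Areal electroporation conductance
#'
#' `g_ep = J_EP / V_m = N / (R_interior + R_access)`: the linear-in-voltage
#' conductance per membrane area contributed by the pores, used by the field
#' solver's interface coupling.
#'
#' @inheritParams ep_current_density
#' @return g_ep (S m^-2).
#' @export
ep_conductance <- function(N, r, p, d, sigma_bulk, model = c("access", "ohmic")) {
  N * .pore_conductance_single(r, p, d, sigma_bulk, match.arg(model))
}

#' Advance the pore state at frozen transmembrane voltage
#'
#' Operator-splitting stage (b): sub-stepped integration of pore density and
#' representative radius over `dt`.  The density equation is linear in `N`
#' at frozen voltage and is advanced by its exact exponential update; the
#' radius follows an explicit Euler sub-step of [pore_radius_rate()] with
#' the effective tension evaluated from the current fractional area.
#' Sub-steps are chosen adaptively so no state variable changes by more
#' than `num$substep_rel` per sub-step.  Newly created pores enter at
#' `r_star` and are merged into the representative radius by area-weighted
#' blending.
#'
#' @param state list with `N`, `r_pore`, `A_frac` (vectors over nodes).
#' @param V_m transmembrane voltage per node (V), frozen during `dt`.
#' @param dt field time step to cover (s).
#' @param p electroporation parameter block.
#' @param num numerics block (`substep_rel`, `vm_cap`, `r_floor_frac`,
#'   `afrac_cap`, `steric`).
#' @return Updated `state`, plus `vm_capped` flag.
#' @export
advance_pores <- function(state, V_m, dt, p, num = default_params()$numerics) {
  stopifnot(dt > 0)
  N <- state$N; r <- state$r_pore; A <- state$A_frac
  if (is.null(A)) A <- pmin(pi * r^2 * N, num$afrac_cap)
  vm_capped <- any(abs(V_m) > num$vm_cap)
  v <- pmin(abs(V_m), num$vm_cap)
  x2 <- (v / p$U_ep)^2
  a_rate <- p$alpha * exp(x2)                      # creation strength
  b_rate <- a_rate * exp(-p$q * x2) / p$N0         # relaxation rate (1/s)
  N_eq <- a_rate / b_rate
  r_floor <- num$r_floor_frac * p$r_star
  remaining <- dt
  iter <- 0
  while (remaining > 0) {
    iter <- iter + 1
    if (iter > 50000)
      stop("pore sub-step underflow: stiffness not resolved at a membrane node")
    delta_eff <- effective_tension(pmin(A, num$afrac_cap), p)
    drdt <- pore_radius_rate(r, v, delta_eff, p, steric = num$steric)
    dNdt <- a_rate * (1 - N / N_eq)
    relN <- abs(dNdt) / pmax(N, p$N0)        # |dN/dt|/N
    # net radius rate: drift plus the pull of newly created pores entering at
    # r_star (the two may balance; the sub-step is sized by the net change)
    merge_rate <- ifelse(dNdt > 0, dNdt * (p$r_star^2 - r^2) / (2 * r * pmax(N, p$N0)), 0)
    net <- drdt + merge_rate
    relr <- abs(net) / r
    relr[r <= r_floor & net < 0] <- 0        # pinned at the floor: no change
    # near a stable stationary radius the damped update limits itself to the
    # Newton correction |F/F'|; when that is already within the sub-step
    # budget the drift need not constrain h
    dF <- .pore_radius_rate_deriv(r, v, delta_eff, p, steric = num$steric)
    relr[dF < 0 & abs(drdt / dF) < num$substep_rel * r] <- 0
    h <- min(remaining, num$substep_rel / max(relN, relr, 1e-300))
    # exact exponential update of the linear density equation at frozen V
    # (expm1 keeps the increment accurate when b*h underflows double precision)
    N_new <- N - (N_eq - N) * expm1(-b_rate * h)
    dN <- N_new - N
    grow <- dN > 0 & N_new > 0
    # area-weighted merge of newly created pores entering at r_star
    r[grow] <- sqrt((N[grow] * r[grow]^2 + dN[grow] * p$r_star^2) / N_new[grow])
    # semi-implicit radius update: damped by the (stabilising) part of the
    # rate derivative so large sub-steps settle onto stationary radii
    # instead of limit-cycling around them; identical to explicit Euler to
    # first order in h
    dF <- .pore_radius_rate_deriv(r, v, delta_eff, p, steric = num$steric)
    r <- r + h * drdt / (1 - h * pmin(dF, 0))
    r <- pmax(r, r_floor)
    N <- pmax(N_new, 0)
    A <- pmin(pi * r^2 * N, num$afrac_cap)
    remaining <- remaining - h
  }
  list(N = N, r_pore = r, A_frac = A, vm_capped = vm_capped)
}
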