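# Derived quantities behind the headline results: field-strength area
# histograms, electroporated membrane area and permeabilized flux, the
# analytic tip-enhancement and Schwan transmembrane-voltage diagnostics.

#' Field-strength area histogram
#'
#' Bins the per-triangle field magnitude weighted by triangle area and
#' normalised by the total area of the selected region, i.e. the fraction
#' of the region's area experiencing each field-strength band.
#'
#' @param ctx an `ep_solver` context.
#' @param psi potential vector (one snapshot).
#' @param region `"domain"` (everything) or `"cell"` (cytoplasm +
#'   nucleoplasm), or a character vector of region tags.
#' @param n_bins number of bins.
#' @param log_bins logarithmic bin edges (from half the applied field to the
#'   snapshot maximum); otherwise linear from 0.
#' @param E_applied reference field for the log binning floor (V/m); taken
#'   from the registry of the assembled context by default.
#' @return A data.frame with `bin_lo`, `bin_hi` (V/m) and `fraction`;
#'   fractions sum to 1.
#' @export
field_area_histogram <- function(ctx, psi, region = "domain", n_bins = 30,
                                 log_bins = TRUE, E_applied = NULL) {
  tags <- if (identical(region, "domain")) unique(ctx$mesh$region)
          else if (identical(region, "cell")) c("cytoplasm", "nucleoplasm")
          else region
  sel <- ctx$mesh$region %in% tags
  if (!any(sel)) stop(sprintf("empty region selection: %s", paste(region, collapse = ",")))
  fm <- field_magnitude(ctx, psi)
  E <- fm$E[sel]
  w <- ctx$area[sel]
  if (is.null(E_applied)) E_applied <- ctx$params$pulse$E_applied
  Emax <- max(E)
  if (log_bins) {
    lo <- min(0.5 * E_applied, Emax / 2)
    edges <- exp(seq(log(lo), log(Emax), length.out = n_bins + 1))
    edges[1] <- 0                       # left-open catch-all for the quiet area
  } else {
    edges <- seq(0, Emax, length.out = n_bins + 1)
  }
  edges[length(edges)] <- Emax * (1 + 1e-12)
  bin <- findInterval(E, edges, rightmost.closed = TRUE, all.inside = TRUE)
  frac <- vapply(seq_len(n_bins), function(b) sum(w[bin == b]), numeric(1)) / sum(w)
  data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1], fraction = frac)
}

#' Electroporated membrane area series
#'
#' Discrete contour integral `S(t) = sum_edges pi r_pore^2 N edge_length`
#' over a membrane: the pore area per unit out-of-plane depth (reported in
#' m^2 per m; multiply by 1e6 for um^2/um).  In this planar model the
#' quantity is compared within-model only.
#'
#' @param sim an `ep_sim` result.
#' @param which `"outer"` or `"inner"` membrane.
#' @return A data.frame with `t` (s) and `S` (m^2/m).
#' @export
electroporated_area <- function(sim, which = c("outer", "inner")) {
  which <- match.arg(which)
  m <- sim$mem[[which]]
  if (is.null(m)) stop(sprintf("no '%s' membrane in this simulation", which))
  data.frame(t = sim$t, S = m$S)
}

#' Permeabilized flux
#'
#' Cumulative trapezoidal time integral of the electroporated area: a proxy
#' for the cumulative molecular transport through the membrane.
#'
#' @param S_series data.frame from [electroporated_area()] (columns `t`, `S`).
#' @return A data.frame with `t` and non-decreasing `flux` (m^2 s / m).
#' @export
permeabilized_flux <- function(S_series) {
  t <- S_series$t; S <- S_series$S
  n <- length(t)
  inc <- c(0, 0.5 * (S[-1] + S[-n]) * diff(t))
  data.frame(t = t, flux = cumsum(inc))
}

#' Tip field enhancement of a conductive rod
#'
#' Field-emission estimate `E_tip = beta * (L/D) * E0` for a conductor of
#' length `L` and diameter `D` in a background field `E0`: the lightning-rod
#' scaling in the aspect ratio.
#'
#' @param L,D rod length and diameter (m).
#' @param beta geometry constant (dimensionless).
#' @param E0 background field (V/m).
#' @return E_tip (V/m).
#' @export
tip_enhancement <- function(L, D, beta = 1, E0) {
  stopifnot(all(L > 0), all(D > 0), all(E0 > 0))
  beta * (L / D) * E0
}

#' Schwan steady-state transmembrane voltage
#'
#' `dPhi = factor * radius * E * cos(theta)`: the induced steady
#' transmembrane voltage of a cell of the given radius in a uniform field.
#' `factor = 1.5` is the spherical (3D) form; `factor = 2` is the consistent
#' value for the planar (2D cylinder cross-section) model solved here.
#'
#' @param radius cell radius (m).
#' @param E field strength (V/m).
#' @param theta polar angle from the field axis (rad).
#' @param factor geometry factor.
#' @return dPhi (V).
#' @export
schwan_tmv <- function(radius, E, theta, factor = 1.5) {
  stopifnot(all(radius >= 0), all(E >= 0))
  factor * radius * E * cos(theta)
}

#' Side-by-side summary of a simulation
#'
#' Scalar outputs used by the comparison tables: plateau max fields, peak
#' pore density, end-of-pulse electroporated area and final flux for both
#' membranes.
#'
#' @param sim an `ep_sim`.
#' @param t_plateau snapshot time for the field maxima (s).
#' @return A one-row data.frame.
#' @export
sim_summary <- function(sim, t_plateau = 150e-9) {
  k <- snapshot_at(sim, t_plateau)
  psi <- sim$snapshots$psi[, k]
  fm_dom <- field_magnitude(sim$ctx, psi)
  fm_cell <- if (sim$scene$has_cell) field_magnitude(sim$ctx, psi, "cell") else list(max = NA_real_)
  pulse <- sim$params$pulse
  t_off <- pulse$t_rise + pulse$t_width
  k_off <- which.min(abs(sim$t - t_off))
  out <- data.frame(
    t_snapshot = sim$snapshots$t[k],
    maxE_domain = fm_dom$max,
    maxE_cell = fm_cell$max
  )
  for (nm in names(sim$mem)) {
    m <- sim$mem[[nm]]
    fx <- permeabilized_flux(data.frame(t = sim$t, S = m$S))
    out[[paste0("maxN_", nm)]] <- max(m$N)
    out[[paste0("maxU_", nm)]] <- max(abs(m$u))
    out[[paste0("S_endpulse_", nm)]] <- m$S[k_off]
    out[[paste0("flux_end_", nm)]] <- fx$flux[nrow(fx)]
  }
  out
}
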