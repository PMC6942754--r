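# Convenience plots (base graphics for the mesh/field maps, ggplot2 when
# available for the tabular series).  Untested for pixel fidelity.

#' Plot a mesh (region-coloured triangles)
#'
#' @param x an `ep_mesh`.
#' @param window optional `c(x0, x1, y0, y1)` zoom window (m).
#' @param ... passed to [graphics::plot()].
#' @export
plot.ep_mesh <- function(x, window = NULL, ...) {
  P <- x$nodes * 1e6
  if (is.null(window)) window <- c(0, x$scene$side, 0, x$scene$side) * 1e6
  else window <- window * 1e6
  graphics::plot(NA, xlim = window[1:2], ylim = window[3:4], asp = 1,
                 xlab = "x (um)", ylab = "y (um)", ...)
  cols <- c(medium = "grey90", cytoplasm = "lightblue", nucleoplasm = "lightyellow")
  fill <- cols[x$region]
  fill[is.na(fill)] <- "grey40"     # CNTs
  for (k in seq_len(nrow(x$tri))) {
    v <- x$tri[k, ]
    graphics::polygon(P[v, 1], P[v, 2], col = fill[k], border = "grey60", lwd = 0.2)
  }
  invisible(x)
}

#' Field-magnitude map of a snapshot
#'
#' Colours each triangle by log10 of the field magnitude.
#'
#' @param sim an `ep_sim`.
#' @param t snapshot time (s).
#' @param window optional zoom window (m).
#' @export
plot_field <- function(sim, t = 150e-9, window = NULL) {
  k <- snapshot_at(sim, t)
  fm <- field_magnitude(sim$ctx, sim$snapshots$psi[, k])
  lv <- log10(pmax(fm$E, 1))
  sc <- (lv - min(lv)) / diff(range(lv))
  pal <- grDevices::hcl.colors(64, "viridis")
  P <- sim$mesh$nodes * 1e6
  if (is.null(window)) window <- c(0, sim$scene$side, 0, sim$scene$side) * 1e6
  else window <- window * 1e6
  graphics::plot(NA, xlim = window[1:2], ylim = window[3:4], asp = 1,
                 xlab = "x (um)", ylab = "y (um)",
                 main = sprintf("|E| at t = %g ns", sim$snapshots$t[k] * 1e9))
  for (i in seq_len(nrow(sim$mesh$tri))) {
    v <- sim$mesh$tri[i, ]
    graphics::polygon(P[v, 1], P[v, 2], col = pal[1 + floor(sc[i] * 63)], border = NA)
  }
  invisible(sim)
}

#' Membrane state profile around a contour
#'
#' Transmembrane voltage, pore density and pore radius against the polar
#' angle at a chosen time.  Uses ggplot2 when installed, base otherwise.
#'
#' @param sim an `ep_sim`.
#' @param which membrane name.
#' @param t time (s).
#' @return A ggplot object, or (base fallback) the plotted data.frame.
#' @export
plot_membrane <- function(sim, which = "outer", t = 300e-9) {
  k <- which.min(abs(sim$t - t))
  f <- sim$ctx$ifaces[[which]]
  m <- sim$mem[[which]]
  df <- data.frame(theta = f$theta, V_m = m$u[k, ], N = m$N[k, ],
                   r_pore = m$r[k, ] * 1e9)
  df <- df[order(df$theta), ]
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    long <- data.frame(theta = rep(df$theta, 3),
                       value = c(df$V_m, log10(df$N), df$r_pore),
                       what = rep(c("V_m (V)", "log10 N (m^-2)", "r_pore (nm)"),
                                  each = nrow(df)))
    ggplot2::ggplot(long, ggplot2::aes(.data$theta, .data$value)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~what, scales = "free_y", ncol = 1) +
      ggplot2::labs(x = "polar angle (rad)",
                    title = sprintf("%s membrane at t = %g ns", which, sim$t[k] * 1e9))
  } else {
    graphics::plot(df$theta, df$V_m, type = "l", xlab = "theta (rad)", ylab = "V_m (V)")
    invisible(df)
  }
}

#' Electroporated area and flux against time
#'
#' @param sim an `ep_sim`.
#' @return A ggplot object, or (base fallback) the plotted data.frame.
#' @export
plot_poration <- function(sim) {
  dfs <- lapply(names(sim$mem), function(nm) {
    S <- electroporated_area(sim, nm)
    cbind(membrane = nm, S, flux = permeabilized_flux(S)$flux)
  })
  df <- do.call(rbind, dfs)
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    long <- rbind(data.frame(t = df$t, membrane = df$membrane,
                             value = df$S * 1e6, what = "S (um^2/um)"),
                  data.frame(t = df$t, membrane = df$membrane,
                             value = df$flux * 1e15, what = "flux (um^2 fs / um)"))
    ggplot2::ggplot(long, ggplot2::aes(.data$t * 1e9, .data$value,
                                       colour = .data$membrane)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~what, scales = "free_y", ncol = 1) +
      ggplot2::labs(x = "t (ns)", y = NULL)
  } else {
    graphics::matplot(df$t * 1e9, cbind(df$S), type = "l",
                      xlab = "t (ns)", ylab = "S (m^2/m)")
    invisible(df)
  }
}
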