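# Quasi-static field solver.  Bulk regions obey the conduction-displacement
# equation  -div(sigma grad psi) - div(eps0 epsr d/dt grad psi) = 0,
# discretised with P1 triangles and backward-Euler in time.  Each membrane
# is a zero-thickness interface: its contour DOFs are duplicated and the
# normal current between the two traces is the distributed-impedance law
#   J = (sigma_mem0/d) u + (eps0 eps_mem/d) du/dt + J_EP(u; N, r),
# with u = psi_inner - psi_outer the transmembrane voltage relative to rest
# (the resting offset enters the conduction term as (V_m - U_rest) = u).

EPS0 <- 8.854187817e-12

# ---- assembly ---------------------------------------------------------------

#' Assemble the finite-element operators for a mesh
#'
#' Builds the conduction and permittivity stiffness matrices on the
#' duplicated-DOF space, the electrode Dirichlet sets, and the membrane
#' interface coupling structure.
#'
#' @param mesh an `ep_mesh`.
#' @param params an `ep_params` registry; every region tag present in the
#'   mesh must have dielectric properties.
#' @return An `ep_solver` context.
#' @export
assemble <- function(mesh, params) {
  stopifnot(inherits(mesh, "ep_mesh"))
  P <- mesh$nodes; T <- mesh$tri; Td <- mesh$tri_dof
  n_dof <- mesh$n_dof
  reg <- mesh$region
  dl <- params$dielectrics
  sig_of <- function(tags) {
    out <- numeric(length(tags))
    for (tg in unique(tags)) {
      key <- if (grepl("^cnt_", tg)) "cnt" else tg
      if (is.null(dl[[key]])) stop(sprintf("no dielectric properties for region '%s'", tg))
      out[tags == tg] <- dl[[key]]$sigma
    }
    out
  }
  eps_of <- function(tags) {
    out <- numeric(length(tags))
    for (tg in unique(tags)) {
      key <- if (grepl("^cnt_", tg)) "cnt" else tg
      out[tags == tg] <- dl[[key]]$eps_r
    }
    out
  }
  x1 <- P[T[, 1], 1]; y1 <- P[T[, 1], 2]
  x2 <- P[T[, 2], 1]; y2 <- P[T[, 2], 2]
  x3 <- P[T[, 3], 1]; y3 <- P[T[, 3], 2]
  A2 <- (x2 - x1) * (y3 - y1) - (y2 - y1) * (x3 - x1)   # 2*area, positive (CCW)
  b <- cbind(y2 - y3, y3 - y1, y1 - y2) / A2            # d(phi_i)/dx
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1) / A2           # d(phi_i)/dy
  area <- A2 / 2
  # element stiffness K_ij = coef * area * (b_i b_j + c_i c_j)
  ii <- jj <- vector("list", 9); vs <- vector("list", 9); ve <- vector("list", 9)
  sig <- sig_of(reg); epsr <- eps_of(reg) * EPS0
  k <- 0
  for (a in 1:3) for (bq in 1:3) {
    k <- k + 1
    ii[[k]] <- Td[, a]; jj[[k]] <- Td[, bq]
    g <- area * (b[, a] * b[, bq] + cc[, a] * cc[, bq])
    vs[[k]] <- sig * g
    ve[[k]] <- epsr * g
  }
  I <- unlist(ii); J <- unlist(jj)
  K_sig <- Matrix::sparseMatrix(i = I, j = J, x = unlist(vs), dims = c(n_dof, n_dof))
  K_eps <- Matrix::sparseMatrix(i = I, j = J, x = unlist(ve), dims = c(n_dof, n_dof))

  g <- params$geometry
  ifaces <- list()
  for (nm in names(mesh$interfaces)) {
    mi <- mesh$interfaces[[nm]]
    if (nm == "outer") {
      dmem <- g$d_mem
      mem <- dl$membrane
      sig_access <- (dl$medium$sigma + dl$cytoplasm$sigma) / 2
      ep <- params$ep
    } else {
      dmem <- g$d_ne
      mem <- dl$nuclear_envelope
      sig_access <- (dl$cytoplasm$sigma + dl$nucleoplasm$sigma) / 2
      ep <- params$ep_ne
    }
    ifaces[[nm]] <- list(
      name = nm, idx_in = mi$dup, idx_out = mi$nodes, w = mi$w,
      theta = mi$theta, edge_len = mi$edge_len, next_node = mi$next_node,
      d = dmem, g_m = mem$sigma / dmem, C_m = EPS0 * mem$eps_r / dmem,
      sigma_access = sig_access, ep = ep, radius = mi$radius
    )
  }
  # fixed coupling pattern: (in,in) (out,out) (in,out) (out,in) per node
  ci <- cj <- integer(0)
  for (f in ifaces) {
    ci <- c(ci, f$idx_in, f$idx_out, f$idx_in, f$idx_out)
    cj <- c(cj, f$idx_in, f$idx_out, f$idx_out, f$idx_in)
  }
  dir_left <- mesh$boundary$left
  dir_right <- mesh$boundary$right
  dir_all <- c(dir_left, dir_right)
  free <- setdiff(seq_len(n_dof), dir_all)
  structure(list(
    mesh = mesh, params = params, n_dof = n_dof,
    K_sig = K_sig, K_eps = K_eps, b = b, c = cc, area = area,
    ifaces = ifaces, coup_i = ci, coup_j = cj,
    dir_left = dir_left, dir_right = dir_right, free = free
  ), class = "ep_solver")
}

# coupling matrix for per-node total areal conductance g_tot (list by iface)
.coupling_matrix <- function(ctx, g_tot) {
  vals <- numeric(0)
  for (nm in names(ctx$ifaces)) {
    f <- ctx$ifaces[[nm]]
    wg <- f$w * g_tot[[nm]]
    vals <- c(vals, wg, wg, -wg, -wg)
  }
  if (!length(vals))
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(ctx$n_dof, ctx$n_dof)))
  Matrix::sparseMatrix(i = ctx$coup_i, j = ctx$coup_j, x = vals,
                       dims = c(ctx$n_dof, ctx$n_dof))
}

# ---- static (conduction-only) solve ----------------------------------------

#' Solve the steady conduction problem
#'
#' Solves `-div(sigma grad psi) = 0` with the electrodes at fixed potential
#' (or an arbitrary Dirichlet map), ignoring displacement currents.  With
#' membranes present their conduction term `sigma_mem0/d` (plus any supplied
#' electroporation conductance) couples the duplicated traces.
#'
#' @param ctx an `ep_solver` context.
#' @param V_drive potential of the left (driven) electrode in volts; the
#'   right electrode is grounded.
#' @param dirichlet optional list `(idx, values)` overriding the electrode
#'   boundary conditions entirely.
#' @param g_ep optional list of per-node areal electroporation conductances
#'   by interface name.
#' @return Potential vector psi over all DOFs.
#' @export
solve_static <- function(ctx, V_drive = NULL, dirichlet = NULL, g_ep = NULL) {
  stopifnot(inherits(ctx, "ep_solver"))
  g_tot <- lapply(ctx$ifaces, function(f) {
    g <- rep(f$g_m, length(f$idx_in))
    if (!is.null(g_ep[[f$name]])) g <- g + g_ep[[f$name]]
    g
  })
  A <- ctx$K_sig + .coupling_matrix(ctx, g_tot)
  if (is.null(dirichlet)) {
    idx <- c(ctx$dir_left, ctx$dir_right)
    vals <- c(rep(V_drive, length(ctx$dir_left)), rep(0, length(ctx$dir_right)))
  } else {
    idx <- dirichlet$idx; vals <- dirichlet$values
  }
  free <- setdiff(seq_len(ctx$n_dof), idx)
  psi <- numeric(ctx$n_dof)
  psi[idx] <- vals
  rhs <- -A[free, idx, drop = FALSE] %*% vals
  psi[free] <- as.numeric(Matrix::solve(A[free, free], rhs))
  psi
}

# ---- field evaluation -------------------------------------------------------

#' Per-triangle electric field magnitude
#'
#' @param ctx an `ep_solver` context.
#' @param psi potential vector over DOFs.
#' @param regions optional character vector of region tags (or the shorthand
#'   `"cell"` = cytoplasm + nucleoplasm); default all triangles.
#' @return List with `E` (per-triangle |grad psi|, V/m, NA outside the
#'   filter), `max` and `which_max` (triangle index).
#' @export
field_magnitude <- function(ctx, psi, regions = NULL) {
  Td <- ctx$mesh$tri_dof
  Ex <- -(ctx$b[, 1] * psi[Td[, 1]] + ctx$b[, 2] * psi[Td[, 2]] + ctx$b[, 3] * psi[Td[, 3]])
  Ey <- -(ctx$c[, 1] * psi[Td[, 1]] + ctx$c[, 2] * psi[Td[, 2]] + ctx$c[, 3] * psi[Td[, 3]])
  E <- sqrt(Ex^2 + Ey^2)
  if (!is.null(regions)) {
    if (identical(regions, "cell")) regions <- c("cytoplasm", "nucleoplasm")
    E[!(ctx$mesh$region %in% regions)] <- NA_real_
  }
  wm <- which.max(E)
  list(E = E, max = E[wm], which_max = wm)
}

#' Transmembrane voltage from a potential vector
#'
#' `u = psi(inner trace) - psi(outer trace)` at matched interface nodes,
#' relative to rest (the resting offset is carried by the membrane current
#' law, not by this bookkeeping).
#'
#' @param ctx an `ep_solver` context.
#' @param psi potential vector.
#' @param which interface name (`"outer"` or `"inner"`).
#' @return Numeric vector of u (V) ordered along the contour.
#' @export
transmembrane_voltage <- function(ctx, psi, which = "outer") {
  f <- ctx$ifaces[[which]]
  if (is.null(f)) stop(sprintf("no interface '%s' in this mesh", which))
  psi[f$idx_in] - psi[f$idx_out]
}

# ---- time stepping ----------------------------------------------------------

.new_state <- function(ctx) {
  st <- list(t = 0, psi = numeric(ctx$n_dof), mem = list())
  for (nm in names(ctx$ifaces)) {
    f <- ctx$ifaces[[nm]]
    n <- length(f$idx_in)
    ep <- f$ep
    st$mem[[nm]] <- list(
      u = numeric(n),
      N = rep(ep$N0, n),
      r = rep(ep$r_star, n),
      A_frac = pmin(pi * ep$r_star^2 * ep$N0, 0.99) * rep(1, n)
    )
  }
  st
}

# one implicit step of the coupled bulk + membrane-charging system at frozen
# pore state; returns state with updated psi, u and solver cache
step_field <- function(ctx, state, dt, V_drive, cache = NULL,
                       ep_enabled = TRUE) {
  num <- ctx$params$numerics
  g_tot <- list(); rhs_if <- list()
  for (nm in names(ctx$ifaces)) {
    f <- ctx$ifaces[[nm]]
    m <- state$mem[[nm]]
    g_ep <- if (ep_enabled) ep_conductance(m$N, m$r, f$ep, f$d, f$sigma_access,
                                           model = num$pore_current_model) else 0
    g_tot[[nm]] <- f$g_m + f$C_m / dt + g_ep
    rhs_if[[nm]] <- f$w * (f$C_m / dt) * m$u
  }
  A <- ctx$K_sig + ctx$K_eps / dt + .coupling_matrix(ctx, g_tot)
  rhs <- as.numeric((ctx$K_eps / dt) %*% state$psi)
  for (nm in names(ctx$ifaces)) {
    f <- ctx$ifaces[[nm]]
    rhs[f$idx_in] <- rhs[f$idx_in] + rhs_if[[nm]]
    rhs[f$idx_out] <- rhs[f$idx_out] - rhs_if[[nm]]
  }
  idx <- c(ctx$dir_left, ctx$dir_right)
  vals <- c(rep(V_drive, length(ctx$dir_left)), rep(0, length(ctx$dir_right)))
  free <- ctx$free
  Aff <- A[free, free]
  b_f <- rhs[free] - as.numeric(A[free, idx, drop = FALSE] %*% vals)
  if (is.null(cache) || !isTRUE(all.equal(cache$dt, dt))) {
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(Aff), LDL = FALSE, perm = TRUE)
  } else {
    ch <- tryCatch(Matrix::update(cache$ch, Matrix::forceSymmetric(Aff)),
                   error = function(e) Matrix::Cholesky(Matrix::forceSymmetric(Aff),
                                                        LDL = FALSE, perm = TRUE))
  }
  psi <- numeric(ctx$n_dof)
  psi[idx] <- vals
  psi[free] <- as.numeric(Matrix::solve(ch, b_f))
  # electrode reaction currents (per unit out-of-plane depth): conduction +
  # displacement current collected at the Dirichlet rows
  res <- as.numeric(A %*% psi) - rhs
  I_left <- sum(res[ctx$dir_left]); I_right <- sum(res[ctx$dir_right])
  state$psi <- psi
  state$t <- state$t + dt
  for (nm in names(ctx$ifaces))
    state$mem[[nm]]$u <- psi[ctx$ifaces[[nm]]$idx_in] - psi[ctx$ifaces[[nm]]$idx_out]
  state$I_left <- I_left
  state$I_right <- I_right
  state$cache <- list(dt = dt, ch = ch)
  state
}

#' Advance the coupled field + membrane system by one implicit step
#'
#' One backward-Euler step of the bulk conduction-displacement equation
#' coupled to the membrane charging law, at frozen pore state
#' (operator-splitting stage a).  Unconditionally stable in `dt`.
#'
#' @param ctx an `ep_solver` context.
#' @param state solver state (from [run_simulation()] internals or a fresh
#'   rest state); `NULL` starts from rest.
#' @param dt time step (s).
#' @param V_drive driven-electrode potential (V) at the end of the step.
#' @return Updated state (potential `psi`, per-membrane `u`, electrode
#'   currents `I_left`/`I_right`).
#' @export
step <- function(ctx, state = NULL, dt, V_drive = 0) {
  stopifnot(dt > 0)
  if (is.null(state)) state <- .new_state(ctx)
  step_field(ctx, state, dt, V_drive, cache = state$cache)
}

# time grid honouring the fine/coarse schedule
.time_grid <- function(pulse, num, t_stop = pulse$t_end) {
  t3 <- pulse$t_rise + pulse$t_width           # pulse end
  t2 <- t3 - pulse$t_fall                      # fall start
  fine1 <- c(0, pulse$t_rise + 6e-9)           # rise + bulk relaxation
  fine2 <- c(t2 - 1e-9, min(t3 + 6e-9, t_stop))
  ts <- 0
  t <- 0
  while (t < t_stop - 1e-15) {
    dt <- if ((t >= fine1[1] && t < fine1[2]) || (t >= fine2[1] && t < fine2[2]))
      num$dt_fine else num$dt_coarse
    t <- min(t + dt, t_stop)
    ts <- c(ts, t)
  }
  ts
}

#' Run the full coupled electroporation simulation
#'
#' Orchestrates the operator-split time integration from `t = 0` to
#' `t_end`: each step solves the implicit field + membrane-charging system
#' at frozen pore state, then advances pore density and radius at frozen
#' transmembrane voltage ([advance_pores()]).  Records full membrane time
#' series every step and potential snapshots at the configured cadence.
#'
#' @param params an `ep_params` registry.
#' @param scene an `ep_scene`; defaults to the CNT-free centred-cell scene.
#' @param mesh an `ep_mesh`; built from `scene` and the registry mesh sizes
#'   when omitted.
#' @param ep enable electroporation (`FALSE` gives the passive membrane).
#' @param t_stop simulate only to this time (s); defaults to `t_end`.
#' @param progress print stage progress.
#' @return An `ep_sim` object: `t` (time grid), per-membrane series
#'   (`u`, `N`, `r_pore`, `g_ep` as time-by-node matrices, electroporated
#'   area `S`), potential `snapshots`, electrode current series, and the
#'   inputs.
#' @export
run_simulation <- function(params, scene = NULL, mesh = NULL, ep = TRUE,
                           t_stop = NULL, progress = FALSE) {
  if (is.null(scene)) scene <- build_scene(params)
  if (is.null(mesh)) {
    ms <- params$mesh
    mesh <- build_mesh(scene, h_far = ms$h_far, h_membrane = ms$h_membrane,
                       h_tip = ms$h_tip, grade = ms$grade,
                       min_angle = ms$min_angle)
  }
  ctx <- assemble(mesh, params)
  num <- params$numerics
  if (is.null(t_stop)) t_stop <- params$pulse$t_end
  ts <- .time_grid(params$pulse, num, t_stop)
  nt <- length(ts)
  nms <- names(ctx$ifaces)
  mem_series <- lapply(ctx$ifaces, function(f) {
    n <- length(f$idx_in)
    list(u = matrix(0, nt, n), N = matrix(0, nt, n), r = matrix(0, nt, n),
         g_ep = matrix(0, nt, n), S = numeric(nt))
  })
  state <- .new_state(ctx)
  for (nm in nms) {
    m <- state$mem[[nm]]
    mem_series[[nm]]$N[1, ] <- m$N
    mem_series[[nm]]$r[1, ] <- m$r
    mem_series[[nm]]$S[1] <- sum(pi * m$r^2 * m$N * ctx$ifaces[[nm]]$w)
  }
  snap_t <- numeric(0); snaps <- list()
  I_series <- matrix(0, nt, 2, dimnames = list(NULL, c("left", "right")))
  side <- scene$side
  vm_warned <- FALSE
  next_snap <- 0
  for (k in 2:nt) {
    dt <- ts[k] - ts[k - 1]
    V_drive <- pulse_value(params$pulse, ts[k]) * side
    state <- step_field(ctx, state, dt, V_drive, cache = state$cache,
                        ep_enabled = ep)
    if (ep) for (nm in nms) {
      f <- ctx$ifaces[[nm]]
      m <- state$mem[[nm]]
      adv <- advance_pores(
        list(N = m$N, r_pore = m$r, A_frac = m$A_frac),
        V_m = m$u, dt = dt, p = f$ep, num = num)
      state$mem[[nm]]$N <- adv$N
      state$mem[[nm]]$r <- adv$r_pore
      state$mem[[nm]]$A_frac <- adv$A_frac
      if (adv$vm_capped && !vm_warned) {
        warning("transmembrane voltage exceeded the exponent guard; capped in the pore-rate evaluation")
        vm_warned <- TRUE
      }
    }
    for (nm in nms) {
      f <- ctx$ifaces[[nm]]
      m <- state$mem[[nm]]
      mem_series[[nm]]$u[k, ] <- m$u
      mem_series[[nm]]$N[k, ] <- m$N
      mem_series[[nm]]$r[k, ] <- m$r
      mem_series[[nm]]$g_ep[k, ] <- if (ep)
        ep_conductance(m$N, m$r, f$ep, f$d, f$sigma_access,
                       model = num$pore_current_model) else 0
      mem_series[[nm]]$S[k] <- sum(pi * m$r^2 * m$N * f$w)
    }
    I_series[k, ] <- c(state$I_left, state$I_right)
    if (ts[k] >= next_snap - 1e-15 || k == nt) {
      snap_t <- c(snap_t, ts[k])
      snaps[[length(snaps) + 1]] <- state$psi
      next_snap <- next_snap + num$snapshot_every
      if (progress) message(sprintf("t = %.1f ns", ts[k] * 1e9))
    }
  }
  structure(list(
    t = ts, mem = mem_series,
    snapshots = list(t = snap_t, psi = do.call(cbind, snaps)),
    I_electrode = I_series,
    params = params, scene = scene, mesh = mesh, ctx = ctx,
    ep = ep
  ), class = "ep_sim")
}

#' @export
print.ep_sim <- function(x, ...) {
  cat(sprintf("<ep_sim> %d steps to %g ns, %d snapshots, electroporation %s\n",
              length(x$t) - 1, max(x$t) * 1e9, length(x$snapshots$t),
              if (x$ep) "on" else "off"))
  for (nm in names(x$mem)) {
    m <- x$mem[[nm]]
    cat(sprintf("  %s membrane: max |u| %.3f V, max N %.3g m^-2, final S %.3g um^2/um\n",
                nm, max(abs(m$u)), max(m$N), m$S[length(m$S)] * 1e6))
  }
  invisible(x)
}

#' Snapshot index closest to a requested time
#'
#' @param sim an `ep_sim`.
#' @param t requested time (s).
#' @return Index into `sim$snapshots`.
#' @export
snapshot_at <- function(sim, t) which.min(abs(sim$snapshots$t - t))
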