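test_that("homogeneous parallel-plate scene gives the uniform field exactly", {
  p <- default_params()
  sc <- build_scene(p, cell = FALSE)
  ctx <- assemble(build_mesh(sc), p)
  V <- 120
  psi <- solve_static(ctx, V_drive = V)
  E0 <- V / sc$side
  fm <- field_magnitude(ctx, psi)
  expect_lt(max(abs(fm$E - E0)) / E0, 1e-6)
  expect_equal(fm$max, E0, tolerance = 1e-9)
})

test_that("two-conductivity concentric disk matches the closed-form solution", {
  p <- params_from_list(list(sigma_np = 0.3, eps_np = 154.4))  # merge nucleus into the disk
  sc <- build_scene(p, seed = 0L)
  m <- suppressWarnings(build_mesh(sc, h_far = 5e-6, interfaces = FALSE))
  ctx <- assemble(m, p)
  s1 <- 0.3; s2 <- 1; a <- sc$r_c; k <- (s2 - s1) / (s2 + s1)
  E0 <- 6e5; cen <- sc$center
  exact <- function(x, y) {
    dx <- x - cen[1]; r2 <- dx^2 + (y - cen[2])^2
    ifelse(sqrt(r2) < a, -2 * s2 / (s1 + s2) * E0 * dx,
           -E0 * dx * (1 + k * a^2 / r2))
  }
  bidx <- sort(unique(unlist(m$boundary)))
  psi <- solve_static(ctx, dirichlet = list(
    idx = bidx, values = exact(m$nodes[bidx, 1], m$nodes[bidx, 2])))
  err <- psi - exact(m$nodes[, 1], m$nodes[, 2])
  rel_l2 <- sqrt(mean(err^2)) / sqrt(mean(exact(m$nodes[, 1], m$nodes[, 2])^2))
  expect_lt(rel_l2, 1e-3)
  expect_lt(max(abs(err)) / (E0 * a), 1e-2)
})

test_that("a CNT region is near-equipotential under the applied field", {
  p <- default_params()
  cap <- capsule(center = c(118e-6, 106e-6), angle = 0.4, L = 1.5e-6, D = 50e-9)
  sc <- build_scene(p, list(cap), seed = 1L)
  m <- suppressWarnings(build_mesh(sc))
  ctx <- assemble(m, p)
  psi <- solve_static(ctx, V_drive = 120)
  cnt_dofs <- unique(as.vector(m$tri_dof[m$region == "cnt_1", ]))
  expect_lt(diff(range(psi[cnt_dofs])) / 120, 1e-3)
  # the max field sits at a capsule cap ("tip"), not at the cell
  fm <- field_magnitude(ctx, psi)
  cen <- colMeans(m$nodes[m$tri[fm$which_max, ], ])
  spn <- porefield:::capsule_spine(cap)
  d_tip <- min(sqrt(rowSums(sweep(spn, 2, cen)^2)))
  expect_lt(d_tip, cap$L / 4)
  expect_gt(fm$max, 2 * 6e5)
})

test_that("rest is stationary: zero drive leaves potential, density and areas at rest", {
  p <- params_from_list(list(E_applied = 0))
  sc <- build_scene(p, seed = 0L)
  sim <- run_simulation(p, sc, fx_cell_mesh(), t_stop = 50e-9)
  expect_lt(max(abs(sim$snapshots$psi)), 1e-12)
  expect_lt(max(abs(sim$mem$outer$u)), 1e-12)
  expect_equal(max(abs(sim$mem$outer$N - p$ep$N0)), 0)
  expect_lt(max(sim$mem$outer$S), 1e-10)     # areas ~ 0 (r relaxes to its rest radius)
  expect_lt(max(sim$mem$inner$S), 1e-10)
})

test_that("passive membrane charges to the 2D Schwan steady state with the analytic time constant", {
  sim <- fx_schwan_sim()
  f <- sim$ctx$ifaces$outer
  E0 <- 6e5; rc <- sim$scene$r_c
  u_end <- sim$mem$outer$u[length(sim$t), ]
  pred <- 2 * rc * E0 * cos(f$theta)
  expect_lt(max(abs(u_end - pred)) / (2 * rc * E0), 0.02)
  # equator node is at zero TMV
  i_eq <- which.min(abs(f$theta - pi / 2))
  expect_lt(abs(u_end[i_eq]) / max(abs(u_end)), 0.01)
  # mirror antisymmetry u(theta) = -u(pi - theta), by exact node pairing
  wrap <- function(a) atan2(sin(a), cos(a))
  j <- vapply(f$theta, function(th)
    which.min(abs(wrap(f$theta - (pi - th)))), integer(1))
  expect_lt(max(abs(u_end + u_end[j])) / max(abs(u_end)), 0.01)
  # exponential approach with tau = r_c C_m (1/sigma_c + 1/sigma_m)
  i0 <- which.min(abs(f$theta))
  ts <- sim$t; us <- sim$mem$outer$u[, i0]
  sel <- ts > 50e-9 & ts < 2000e-9
  fit <- stats::lm(log(1 - us[sel] / pred[i0]) ~ ts[sel])
  tau_fit <- -1 / stats::coef(fit)[[2]]
  d <- sim$params$dielectrics
  Cm <- 8.854187817e-12 * d$membrane$eps_r / sim$params$geometry$d_mem
  tau_ana <- rc * Cm * (1 / d$cytoplasm$sigma + 1 / d$medium$sigma)
  expect_lt(abs(tau_fit - tau_ana) / tau_ana, 0.05)
})

test_that("backward-Euler stepping is first-order accurate and stable for large dt", {
  p <- default_params()
  ctx <- assemble(fx_cell_mesh(), p)
  run_dt <- function(dt, t_total = 40e-9) {
    st <- NULL
    for (k in seq_len(ceiling(t_total / dt))) st <- step(ctx, st, dt, V_drive = 120)
    st
  }
  i0 <- which.min(abs(ctx$ifaces$outer$theta))
  u2 <- run_dt(2e-9)$mem$outer$u[i0]
  u1 <- run_dt(1e-9)$mem$outer$u[i0]
  u05 <- run_dt(0.5e-9)$mem$outer$u[i0]
  ratio <- (u2 - u1) / (u1 - u05)
  expect_gt(ratio, 1.5); expect_lt(ratio, 2.6)
  # unconditional stability: psi stays bounded by the drive for any dt
  for (dt in c(0.1e-9, 1e-9, 10e-9)) {
    st <- run_dt(dt, t_total = 50 * dt)
    expect_true(all(is.finite(st$psi)))
    expect_lte(max(abs(st$psi)), 120 * (1 + 1e-9))
  }
})

test_that("discrete current is conserved between the electrodes at every step", {
  sim <- fx_baseline_sim()
  I <- sim$I_electrode[-1, ]
  imbalance <- abs(I[, 1] + I[, 2]) / pmax(abs(I[, 1]), abs(I[, 2]))
  expect_lt(max(imbalance), 0.005)
})

test_that("simulation reruns are bit-identical and TMV stays physically clamped", {
  sim <- fx_baseline_sim()
  p <- sim$params
  sim2 <- run_simulation(p, build_scene(p, seed = 0L), fx_cell_mesh())
  expect_identical(sim$mem$outer$u, sim2$mem$outer$u)
  expect_identical(sim$snapshots$psi, sim2$snapshots$psi)
  # pore conductance clamps the TMV well below the exponent guard
  expect_lt(max(abs(sim$mem$outer$u)), 2)
  expect_lt(max(abs(sim$mem$inner$u)), 2)
})
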