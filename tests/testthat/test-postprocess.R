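test_that("field-strength histograms conserve area mass", {
  sim <- fx_baseline_sim()
  k <- snapshot_at(sim, 150e-9)
  psi <- sim$snapshots$psi[, k]
  for (region in c("domain", "cell")) {
    h <- field_area_histogram(sim$ctx, psi, region)
    expect_equal(sum(h$fraction), 1, tolerance = 1e-9)
    expect_true(all(h$fraction >= 0))
  }
  expect_error(field_area_histogram(sim$ctx, psi, "no_such_region"), "empty region")
})

test_that("homogeneous scene puts all histogram mass in the applied-field bin", {
  p <- default_params()
  sc <- build_scene(p, cell = FALSE)
  ctx <- assemble(build_mesh(sc), p)
  psi <- solve_static(ctx, V_drive = 120)
  h <- field_area_histogram(ctx, psi, "domain", n_bins = 20)
  E0 <- 120 / sc$side
  hit <- which(h$fraction > 0)
  expect_length(hit, 1)
  expect_lte(h$bin_lo[hit], E0)
  expect_gte(h$bin_hi[hit], E0 * (1 - 1e-9))
})

test_that("electroporated area reduces to the closed-form contour integral", {
  m <- fx_cell_mesh()
  f <- assemble(m, default_params())$ifaces$outer
  N <- 3e14; r <- 2e-9
  S_discrete <- sum(pi * r^2 * N * f$w)
  S_closed <- pi * r^2 * N * 2 * pi * m$scene$r_c
  expect_equal(S_discrete, S_closed, tolerance = 1e-3)
})

test_that("electroporated area rises during the pulse and recovers afterwards", {
  sim <- fx_baseline_sim()
  for (nm in c("outer", "inner")) {
    S <- electroporated_area(sim, nm)
    t_on <- sim$params$pulse$t_rise + sim$params$pulse$t_width
    k_off <- which.min(abs(S$t - t_on))
    expect_gt(S$S[k_off], 100 * S$S[1])          # grows by orders of magnitude
    expect_lt(S$S[nrow(S)], S$S[k_off])          # resealing after pulse removal
    expect_true(all(S$S >= 0))
  }
})

test_that("permeabilized flux is the cumulative integral and is monotone", {
  # closed forms on synthetic series
  t <- seq(0, 1e-7, length.out = 101)
  expect_equal(permeabilized_flux(data.frame(t = t, S = 0 * t))$flux, rep(0, 101))
  fx_const <- permeabilized_flux(data.frame(t = t, S = rep(2e-6, 101)))
  expect_equal(fx_const$flux[101], 2e-6 * 1e-7, tolerance = 1e-12)
  # simulated series: non-decreasing everywhere
  sim <- fx_baseline_sim()
  fl <- permeabilized_flux(electroporated_area(sim, "outer"))
  expect_true(all(diff(fl$flux) >= 0))
})

test_that("tip enhancement scales linearly in aspect ratio and the solver reproduces the trend", {
  expect_identical(tip_enhancement(1e-6, 1e-6, 1, 1e4), 1e4)
  expect_equal(tip_enhancement(2e-6, 1e-8, 1, 1e4) / tip_enhancement(1e-6, 1e-8, 1, 1e4), 2)
  # FEM sweep: max tip field grows monotonically with L/D at fixed D
  p <- params_from_list(list(side = "12 um", h_far = "1.2 um", r_c = "2 um", r_n = "1 um"))
  D <- 20e-9
  maxE <- vapply(c(10, 30, 100), function(ar) {
    cap <- capsule(center = c(6e-6, 6e-6), angle = 0, L = ar * D, D = D)
    sc <- build_scene(p, list(cap), seed = 1L, cell = FALSE)
    m <- suppressWarnings(build_mesh(sc, h_far = 1.2e-6))
    ctx <- assemble(m, p)
    psi <- solve_static(ctx, V_drive = 1e4 * 12e-6)   # 10 kV/m background
    field_magnitude(ctx, psi)$max
  }, numeric(1))
  expect_true(all(diff(maxE) > 0))
})

test_that("Schwan diagnostic evaluates the textbook values and the solver's 2D factor", {
  expect_equal(schwan_tmv(10e-6, 6e5, pi / 2, 1.5), 0, tolerance = 1e-15)
  expect_equal(schwan_tmv(10e-6, 6e5, 0, 1.5), 9)
  expect_equal(schwan_tmv(10e-6, 6e5, 0, 2), 12)
  # the passive planar solve realises the factor-2 cosine profile
  sim <- fx_schwan_sim()
  f <- sim$ctx$ifaces$outer
  u_end <- sim$mem$outer$u[length(sim$t), ]
  fit <- stats::lm(u_end ~ cos(f$theta) - 1)
  factor <- stats::coef(fit)[[1]] / (sim$scene$r_c * 6e5)
  expect_equal(factor, 2, tolerance = 0.02)
})

test_that("matched scenes: adding CNTs never decreases the poration measures", {
  base <- fx_baseline_sim()
  cnt <- fx_cnt_sim()
  sb <- sim_summary(base); sc <- sim_summary(cnt)
  expect_gte(sc$maxE_domain, sb$maxE_domain)
  expect_gte(sc$maxN_outer, sb$maxN_outer)
  expect_gte(sc$S_endpulse_outer, sb$S_endpulse_outer)
  expect_gte(sc$flux_end_outer, sb$flux_end_outer)
})
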