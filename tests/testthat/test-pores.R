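p_ep <- default_params()$ep
num <- default_params()$numerics

test_that("pore creation rate has the stated fixed points and limits", {
  expect_identical(pore_density_rate(0, p_ep$N0, p_ep), 0)
  expect_identical(pore_density_rate(0, 0, p_ep), p_ep$alpha)   # = 1e9 m^-2 s^-1
  # symmetric in the sign of the voltage
  expect_identical(pore_density_rate(0.4, 2e9, p_ep), pore_density_rate(-0.4, 2e9, p_ep))
})

test_that("integrated density reaches the closed-form equilibrium N0 exp(q (V/U)^2)", {
  for (V in c(0, 0.1, 0.17, 0.3)) {
    st <- list(N = p_ep$N0, r_pore = p_ep$r_star, A_frac = 0)
    # equilibration time scale is 1/b with b = alpha exp((1-q)(V/U)^2)/N0
    b <- p_ep$alpha * exp((1 - p_ep$q) * (V / p_ep$U_ep)^2) / p_ep$N0
    out <- advance_pores(st, V, dt = 30 / b, p = p_ep, num = num)
    expect_equal(out$N, p_ep$N0 * exp(p_ep$q * (V / p_ep$U_ep)^2), tolerance = 1e-3)
  }
})

test_that("radius rate is the negative energy gradient times D/kT", {
  D_kT <- p_ep$D_pore / (p_ep$k_B * p_ep$T)
  for (V in c(0, 0.5, 1)) for (delta in c(p_ep$sigma0, 1e-3, -1e-3)) {
    r <- seq(0.7e-9, 20e-9, length.out = 41)
    h <- 1e-6 * r
    dWdr <- (pore_energy(r + h, V, delta, p_ep) - pore_energy(r - h, V, delta, p_ep)) / (2 * h)
    got <- pore_radius_rate(r, V, delta, p_ep)
    expect_equal(got, -D_kT * dWdr, tolerance = 1e-3)
  }
})

test_that("pore energy and radius rate have the expected asymptotics and signs", {
  # large pores at zero voltage: quadratic decrease from the surface tension
  r_big <- c(1e-7, 2e-7, 4e-7)
  W <- pore_energy(r_big, 0, p_ep$sigma0, p_ep)
  quad <- -pi * p_ep$sigma0 * r_big^2 + 2 * pi * p_ep$gamma * r_big
  expect_equal(W, quad, tolerance = 1e-3)
  # energy strictly decreases with |V| at fixed r
  expect_true(all(pore_energy(2e-9, 0.5, p_ep$sigma0, p_ep) <
                  pore_energy(2e-9, 0, p_ep$sigma0, p_ep)))
  # high TMV expands pores at r_star; line tension shrinks large pores at rest
  expect_gt(pore_radius_rate(p_ep$r_star, 1, p_ep$sigma0, p_ep), 0)
  expect_lt(pore_radius_rate(10 * p_ep$r_star, 0, p_ep$sigma0, p_ep), 0)
  # stationary radius: rate vanishes where a brute-force 1D minimiser puts
  # the energy minimum
  opt <- stats::optimize(function(r) pore_energy(r, 0, p_ep$sigma0, p_ep),
                         interval = c(0.8e-9, 10e-9), tol = 1e-14)
  expect_lt(abs(pore_radius_rate(opt$minimum, 0, p_ep$sigma0, p_ep)),
            1e-3 * abs(pore_radius_rate(p_ep$r_star, 0, p_ep$sigma0, p_ep)))
  expect_error(pore_radius_rate(-1e-9, 0, p_ep$sigma0, p_ep))
  expect_error(pore_energy(0, 0, p_ep$sigma0, p_ep))
})

test_that("effective tension closure matches its closed-form values and root", {
  expect_equal(effective_tension(0, p_ep), p_ep$sigma0)   # = 1e-6 J/m^2
  # zero-tension area fraction by an independent bisection oracle
  root <- stats::uniroot(function(A) effective_tension(A, p_ep),
                         interval = c(0, 0.9), tol = 1e-12)$root
  closed <- 1 - sqrt((2 * p_ep$sigma_prime - p_ep$sigma0) / (2 * p_ep$sigma_prime))
  expect_equal(root, closed, tolerance = 1e-8)
  # monotone decreasing on [0, 0.5]
  A <- seq(0, 0.5, length.out = 50)
  expect_true(all(diff(effective_tension(A, p_ep)) < 0))
  expect_error(effective_tension(1, p_ep))
})

test_that("electroporation current density follows the series-resistance closure", {
  d <- 5e-9; sig_b <- (1 + 0.3) / 2
  expect_identical(ep_current_density(0, p_ep$N0, p_ep$r_star, p_ep, d, sig_b), 0)
  # hand-computed series resistance at the stated operating point
  r <- p_ep$r_star; V <- 0.5
  R_int <- d / (0.22 * pi * r^2)
  R_acc <- 1 / (2 * sig_b * r)
  expect_equal(ep_current_density(V, p_ep$N0, r, p_ep, d, sig_b),
               p_ep$N0 * V / (R_int + R_acc), tolerance = 1e-12)
  # ohmic model drops the access term
  expect_equal(ep_current_density(V, p_ep$N0, r, p_ep, d, sig_b, model = "ohmic"),
               p_ep$N0 * V / R_int, tolerance = 1e-12)
  # strictly increasing in N, r and |V|
  expect_gt(ep_current_density(V, 2e9, r, p_ep, d, sig_b),
            ep_current_density(V, 1e9, r, p_ep, d, sig_b))
  expect_gt(ep_current_density(V, p_ep$N0, 2 * r, p_ep, d, sig_b),
            ep_current_density(V, p_ep$N0, r, p_ep, d, sig_b))
  expect_gt(abs(ep_current_density(-0.8, p_ep$N0, r, p_ep, d, sig_b)),
            abs(ep_current_density(-0.4, p_ep$N0, r, p_ep, d, sig_b)))
})

test_that("pore advance matches a tiny-step reference and preserves floors", {
  st <- list(N = p_ep$N0, r_pore = p_ep$r_star, A_frac = 0)
  coarse <- advance_pores(st, 1, dt = 100e-9, p = p_ep, num = num)
  fine_num <- num; fine_num$substep_rel <- 0.002
  fine <- advance_pores(st, 1, dt = 100e-9, p = p_ep, num = fine_num)
  expect_equal(coarse$N, fine$N, tolerance = 5e-3)
  expect_equal(coarse$r_pore, fine$r_pore, tolerance = 5e-3)
  # non-negativity / floors under assorted dt schedules and voltages
  set.seed(11)
  st <- list(N = rep(p_ep$N0, 20), r_pore = rep(p_ep$r_star, 20),
             A_frac = rep(0, 20))
  for (k in 1:30) {
    V <- runif(20, -1.2, 1.2)
    dt <- 10^runif(1, -10, -8.5)
    st <- advance_pores(st, V, dt, p = p_ep, num = num)
    expect_true(all(st$N >= 0))
    expect_true(all(st$r_pore >= num$r_floor_frac * p_ep$r_star))
    expect_true(all(st$A_frac >= 0 & st$A_frac < 1))
  }
  # pulse removed: the radius decays back toward its resting stationary value
  grown <- advance_pores(list(N = 1e15, r_pore = 5e-9, A_frac = 0.05),
                         0, dt = 2e-6, p = p_ep, num = num)
  expect_lt(grown$r_pore, 5e-9)
})
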