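test_that("registry defaults reproduce the published geometry and dielectric table", {
  p <- default_params()
  g <- p$geometry
  expect_identical(g$r_c, 10e-6)
  expect_identical(g$r_n, 5e-6)
  expect_identical(g$d_mem, 5e-9)
  expect_identical(g$d_ne, 40e-9)
  expect_identical(g$side, 200e-6)
  d <- p$dielectrics
  expect_identical(d$medium$sigma, 1)
  expect_identical(d$cytoplasm$sigma, 0.3)
  expect_identical(d$nucleoplasm$sigma, 1.35)
  expect_identical(d$membrane$sigma, 3e-7)
  expect_identical(d$nuclear_envelope$sigma, 6e-3)
  expect_identical(d$pore$sigma, 0.22)
  expect_identical(d$cnt$sigma, 1e8)
  expect_identical(d$medium$eps_r, 80)
  expect_identical(d$cytoplasm$eps_r, 154.4)
  expect_identical(d$nucleoplasm$eps_r, 52)
  expect_identical(d$membrane$eps_r, 8.57)
  expect_identical(d$nuclear_envelope$eps_r, 28)
  expect_identical(d$cnt$eps_r, 1e4)
})

test_that("registry defaults reproduce the published electroporation constants", {
  ep <- default_params()$ep
  expect_identical(ep$alpha, 1e9)
  expect_identical(ep$U_ep, 0.170)
  expect_identical(ep$N0, 1.5e9)
  expect_identical(ep$q, 2.46)
  expect_identical(ep$r_star, 0.8e-9)
  expect_identical(ep$r_h, 0.97e-9)
  expect_identical(ep$F_max, 0.7e-9)
  expect_identical(ep$gamma, 1.8e-11)
  expect_identical(ep$sigma_prime, 2e-2)
  expect_identical(ep$sigma0, 1e-6)
  expect_identical(ep$D_pore, 5e-14)
  expect_identical(ep$k_B, 1.38e-23)
  expect_identical(ep$T, 295)
  expect_identical(ep$U_rest, -0.080)
  expect_gt(ep$r_star, ep$r_t)
  # documented-but-unused rows are retained
  expect_identical(default_params()$unused$relative_pore_density, 0.15)
  expect_identical(default_params()$unused$energy_barrier_Omega0, 2.65)
  # every deviation from the printed table is in the corrections ledger
  led <- corrections_ledger()
  expect_true(all(c("r_t", "lambda", "D", "F", "R", "q", "t_fall") %in% led$symbol))
})

test_that("trapezoidal pulse has the stated shape and area", {
  p <- default_params()$pulse
  expect_identical(pulse_value(p, -1e-9), 0)
  expect_identical(pulse_value(p, 0), 0)
  expect_equal(pulse_value(p, 1e-9), 3e5)       # mid rise
  expect_equal(pulse_value(p, 150e-9), 6e5)     # plateau
  expect_equal(pulse_value(p, 301e-9), 3e5)     # mid fall
  expect_identical(pulse_value(p, 350e-9), 0)
  # area against a numerical quadrature oracle
  quad <- stats::integrate(function(t) pulse_value(p, t), 0, p$t_end,
                           subdivisions = 2000, rel.tol = 1e-10)$value
  closed <- p$E_applied * (p$t_width + p$t_rise - (p$t_rise + p$t_fall) / 2)
  expect_equal(quad, closed, tolerance = 1e-6)
})

test_that("config round-trips, accepts units, rejects bad keys and values", {
  p <- default_params()
  f <- withr::local_tempfile(fileext = ".yaml")
  save_params(p, f)
  expect_equal(load_params(f), p)
  # partial override with unit strings leaves everything else at defaults
  f2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("E_applied: 3 kV/cm", "t_width: 100 ns"), f2)
  q <- load_params(f2)
  expect_equal(q$pulse$E_applied, 3e5)
  expect_equal(q$pulse$t_width, 100e-9)
  q$pulse$E_applied <- p$pulse$E_applied
  q$pulse$t_width <- p$pulse$t_width
  expect_equal(q, p)
  # invariant violations name the field
  f3 <- withr::local_tempfile(fileext = ".yaml")
  writeLines("sigma_m: -1", f3)
  expect_error(load_params(f3), "sigma_m")
  expect_error(params_from_list(list(nonsense_key = 1)), "nonsense_key")
  expect_error(params_from_list(list(eps_m = 0.5)), "eps_m")
  expect_error(load_params("does/not/exist.yaml"), "not found")
})
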