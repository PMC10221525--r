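test_that("rest state with no forcing stays at rest", {
  m <- rasterize_geometry(build_linear_channel(W = 50, L = 200), 5)
  st <- initialize_state(m, fluid_pair_params(sigma = 0))
  res <- advance_momentum(st, inflow_spec(u_d = 0, ratio = 0, u_c = 0),
                          n_steps = 20, dt = 1e-6)
  expect_equal(max(abs(res$state$u)), 0)
  expect_equal(max(abs(res$state$v)), 0)
  expect_equal(max(abs(res$state$p)), 0)
})

test_that("steady inflow develops the plane-Poiseuille parabola", {
  g <- build_linear_channel(W = 50, L = 500)
  m <- rasterize_geometry(g, 2.5)                    # 20 cells across
  st <- initialize_state(m, fluid_pair_params(sigma = 0))
  infl <- inflow_spec(u_d = 0, ratio = 0, u_c = 0.005)
  res <- advance_momentum(st, infl, n_steps = 1500)
  mid <- res$state$u[101, ]                          # x = 250 um
  yc <- (seq_len(m$ny) - 0.5) * 2.5
  uex <- 1.5 * 0.005 * (1 - (2 * (yc - 25) / 50)^2)
  expect_lt(sqrt(sum((mid - uex)^2) / sum(uex^2)), 0.02)
  expect_equal(max(mid), 1.5 * 0.005, tolerance = 0.02)
  # post-projection incompressibility
  umax <- max(abs(res$state$u), abs(res$state$v))
  expect_lt(res$divmax, 1e-8 * umax / 2.5e-6)
  # inlet volumetric flux matches the prescribed mean velocity
  fl <- boundary_fluxes(res$state)
  expect_equal(fl$inlet, 0.005 * 50e-6, tolerance = 1e-10)
  expect_equal(fl$outlet, fl$inlet, tolerance = 0.01)
})

test_that("surface tension force is zero without an interface and balanced on a disc", {
  m <- box_mask(48, 48, 5)
  p <- fluid_pair_params()
  st <- initialize_state(m, p)
  f0 <- surface_tension_force(st)
  expect_equal(max(abs(f0$Fx)), 0)
  expect_equal(max(abs(f0$Fy)), 0)

  st$phi <- disc_phi(m, 120, 120, 60, eps_um = 5)
  f <- surface_tension_force(st)
  h <- 5e-6
  # closed interface: the net force integrates to ~0 by symmetry
  net_x <- sum(f$Fx) * h^2
  mag <- sum(abs(f$Fx)) * h^2
  expect_lt(abs(net_x) / mag, 0.02)
  expect_lt(abs(sum(f$Fy)) / sum(abs(f$Fy)), 0.02)
  # curvature near the interface is ~ -1/R (2D, phi rising inward)
  kap <- f$kappa[abs(st$phi - 0.5) < 0.2]
  expect_equal(mean(abs(kap)), 1 / 60e-6, tolerance = 0.2)
})

test_that("a static droplet supports the Young-Laplace pressure jump", {
  # 20 cells per radius; interface kept in equilibrium by the full coupled
  # solver; pressure jump within 15% of sigma/R (2D)
  m <- box_mask(64, 64, 2.5)
  p <- fluid_pair_params()
  st <- initialize_state(m, p)
  st$phi <- disc_phi(m, 80, 80, 50, eps_um = 2.5)
  infl <- inflow_spec(u_d = 0, ratio = 0, u_c = 0)
  run <- run_simulation(st, infl, t_end = 0.002, record_every = 500)
  s <- run$state
  dp <- mean(s$p[28:37, 28:37]) - mean(s$p[1:6, 1:6])
  expect_equal(dp, 5e-3 / 50e-6, tolerance = 0.15)
  # spurious currents stay small compared to the capillary velocity scale
  expect_lt(max(abs(s$u), abs(s$v)), 0.05 * 5e-3 / 1.12e-2)
  # dispersed area is conserved
  ser <- run$series
  expect_lt(abs(ser$dispersed_area[nrow(ser)] / ser$dispersed_area[1] - 1),
            0.02)
})

test_that("identical configurations reproduce bit-identical series", {
  g <- build_t_junction()
  m <- rasterize_geometry(g, 5)
  run1 <- {
    st <- prefill_dispersed(initialize_state(m, fluid_pair_params()),
                            droplamp:::prefill_rect(g))
    run_simulation(st, inflow_spec(ratio = 5), t_end = 2e-4,
                   record_every = 20)
  }
  run2 <- {
    st <- prefill_dispersed(initialize_state(m, fluid_pair_params()),
                            droplamp:::prefill_rect(g))
    run_simulation(st, inflow_spec(ratio = 5), t_end = 2e-4,
                   record_every = 20)
  }
  expect_identical(run1$series, run2$series)
  expect_identical(run1$state$phi, run2$state$phi)
  expect_identical(run1$state$u, run2$state$u)
})

test_that("t_end at or before the current time returns the state unchanged", {
  m <- rasterize_geometry(build_t_junction(), 5)
  st <- initialize_state(m, fluid_pair_params())
  run <- run_simulation(st, inflow_spec(ratio = 5), t_end = 0)
  expect_identical(run$steps, 0L)
  expect_identical(run$state$phi, st$phi)
})
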