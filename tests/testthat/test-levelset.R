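test_that("reinitialization holds its own equilibrium profile stationary", {
  # relax a tanh front under reinitialization alone (u = 0); once settled,
  # one further step must not move it
  m <- strip_mask(32, 32, 5)
  p <- fluid_pair_params(sigma = 0, gamma = 0.01, eps = 5e-6)
  st <- initialize_state(m, p)
  cc <- droplamp:::mask_cell_centers(m)
  st$phi <- matrix(rep(1 / (1 + exp((cc$x - 80) / 5)), m$ny), m$nx, m$ny)
  infl <- inflow_spec(u_d = 0, ratio = 0, u_c = 0)
  res <- transport_levelset(st, infl, dt = 1e-4, n_steps = 2000,
                            periodic_x = TRUE)
  settled <- res$state$phi
  res2 <- transport_levelset(res$state, infl, dt = 1e-4, n_steps = 1L,
                             periodic_x = TRUE)
  expect_lt(max(abs(res2$state$phi - settled)), 1e-6)
})

test_that("uniform advection translates the front and conserves mass", {
  m <- strip_mask(64, 16, 5)
  p <- fluid_pair_params(sigma = 0, gamma = 0.005, eps = 5e-6)
  st <- initialize_state(m, p)
  cc <- droplamp:::mask_cell_centers(m)
  # periodic double front (band of dispersed phase)
  band <- 1 / (1 + exp((abs(cc$x - 160) - 60) / 5))
  st$phi <- matrix(rep(band, m$ny), m$nx, m$ny)
  u0 <- 0.005
  st$u[] <- u0
  infl <- inflow_spec(u_d = 0, ratio = 0, u_c = 0)
  mass0 <- sum(st$phi)
  # advect for exactly 16 cells of travel: 16*5e-6/u0 seconds
  dt <- 2e-4
  nsteps <- as.integer(round(16 * 5e-6 / u0 / dt))
  res <- transport_levelset(st, infl, dt = dt, n_steps = nsteps,
                            periodic_x = TRUE)
  phi1 <- res$state$phi
  expect_equal(sum(phi1), mass0, tolerance = 1e-12)   # exact conservation
  shifted <- st$phi[c((m$nx - 15):m$nx, 1:(m$nx - 16)), ]
  expect_lt(max(abs(phi1 - shifted)), 0.06)
})

test_that("with stabilization off the scheme reduces to pure advection", {
  # compare against an independent semi-Lagrangian advection oracle
  m <- strip_mask(32, 32, 5)
  p <- fluid_pair_params(sigma = 0, gamma = 0, eps = 1e-12)
  st <- initialize_state(m, p)
  cc <- droplamp:::mask_cell_centers(m)
  blob <- outer(exp(-((cc$x - 80) / 25)^2), exp(-((cc$y - 80) / 25)^2))
  st$phi <- blob
  u0 <- 0.005
  st$u[] <- u0
  infl <- inflow_spec(u_d = 0, ratio = 0, u_c = 0)
  dt <- 1e-4; nsteps <- 50L
  res <- transport_levelset(st, infl, dt = dt, n_steps = nsteps,
                            periodic_x = TRUE)
  # semi-Lagrangian oracle: sample the initial field at x - u t (periodic),
  # linear interpolation
  shift <- u0 * dt * nsteps / (m$cell_size * 1e-6)   # in cells
  xg <- seq_len(m$nx)
  xs <- ((xg - 1 - shift) %% m$nx)
  i0 <- floor(xs); w <- xs - i0
  ia <- (i0 %% m$nx) + 1; ib <- ((i0 + 1) %% m$nx) + 1
  oracle <- (1 - w) * blob[ia, ] + w * blob[ib, ]
  expect_lt(max(abs(res$state$phi - oracle)), 0.05)
  expect_equal(sum(res$state$phi), sum(blob), tolerance = 1e-12)
})

test_that("transport rejects time steps violating the advective CFL", {
  m <- strip_mask(16, 16, 5)
  st <- initialize_state(m, fluid_pair_params(sigma = 0))
  st$u[] <- 0.1
  expect_error(transport_levelset(st, inflow_spec(u_d = 0, ratio = 0),
                                  dt = 1, n_steps = 1),
               "CFL")
})

test_that("dispersed inflow through the tagged inlet fills the channel", {
  g <- build_linear_channel(W = 50, L = 300)
  g$inlets[[1]]$role <- "dispersed"
  m <- rasterize_geometry(g, 5)
  p <- fluid_pair_params(sigma = 0)
  st <- initialize_state(m, p)
  st$u[] <- 0.005                     # plug flow, frozen
  infl <- inflow_spec(u_d = 0.005, ratio = 1)
  res <- transport_levelset(st, infl, dt = 2e-4, n_steps = 100L)
  phi <- res$state$phi
  # the front has advanced about u*t = 100 um into the channel (the
  # parabolic inlet profile fills the near-wall corners more slowly)
  expect_gt(mean(phi[1:10, ]), 0.75)
  expect_gt(mean(phi[1:10, 4:7]), 0.95)
  expect_lt(mean(phi[50:60, ]), 0.05)
})
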