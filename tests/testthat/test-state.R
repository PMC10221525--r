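test_that("initial state is continuous phase at rest", {
  m <- rasterize_geometry(build_t_junction(), 5)
  p <- fluid_pair_params()
  st <- initialize_state(m, p)
  expect_equal(sum(st$phi), 0)                       # no dispersed phase
  expect_equal(max(abs(st$u)), 0)
  expect_equal(max(abs(st$v)), 0)
  expect_equal(max(abs(st$p)), 0)
  expect_true(all(st$rho == p$rho_c))
  expect_true(all(st$mu == p$mu_c))
  expect_identical(st$t, 0)
  expect_identical(dim(st$p), c(m$nx, m$ny))         # one unknown per cell
})

test_that("property interpolation blends linearly between the phases", {
  p <- fluid_pair_params()                           # oil / water defaults
  expect_equal(interpolate_properties(0, p)$rho, 1.164e3)
  expect_equal(interpolate_properties(1, p)$rho, 1e3)
  expect_equal(interpolate_properties(0.5, p)$rho, 1.082e3)
  expect_equal(interpolate_properties(0, p)$mu, 1.12e-2)
  expect_equal(interpolate_properties(1, p)$mu, 1.01e-2)
  expect_error(interpolate_properties(1.5, p), "phi")
  expect_error(interpolate_properties(-0.2, p), "phi")
})

test_that("parameter constructors validate physical ranges", {
  expect_error(fluid_pair_params(rho_c = -1), "positive")
  expect_error(fluid_pair_params(sigma = -1), "sigma")
  expect_error(fluid_pair_params(theta = 4), "theta")
  expect_error(inflow_spec(u_d = -1), "non-negative")
  i <- inflow_spec(u_d = 0.005, ratio = 6)
  expect_equal(i$u_c, 0.03)
  expect_equal(i$ratio, 6)
})

test_that("dispersed prefill marks exactly the requested rectangle", {
  g <- build_t_junction()
  m <- rasterize_geometry(g, 5)
  st <- initialize_state(m, fluid_pair_params())
  st2 <- prefill_dispersed(st, c(200, 100, 250, 200))
  area <- sum(st2$phi) * m$cell_size^2
  # the rectangle clipped to the fluid domain (dispersed arm is 50 wide)
  expect_gt(area, 0)
  expect_true(all(st2$phi %in% c(0, 1)))
  expect_true(all(st2$rho[st2$phi == 1] == 1e3))
})
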