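test_that("effective diameter inverts the sphere volume", {
  v100 <- 4 / 3 * pi * 50^3            # sphere with d = 100 um
  expect_equal(effective_diameter(v100), 100, tolerance = 1e-12)
  expect_equal(effective_diameter(4.18879e6), 200, tolerance = 1e-4)
  # round trip across three decades
  for (d in c(1, 10, 137.5, 1000)) {
    v <- pi * d^3 / 6
    expect_equal(effective_diameter(v), d, tolerance = 1e-12)
  }
  expect_error(effective_diameter(0), "positive")
  expect_error(effective_diameter(-5), "positive")
})

test_that("droplet detection matches closed forms and the labelling oracle", {
  m <- box_mask(80, 80, 5)             # 400 um box
  # no dispersed phase: empty table
  expect_identical(nrow(detect_droplets(matrix(0, 80, 80), m)), 0L)

  # sharp disc radius 50 um, depth 50 um: V = pi 50^2 * 50, d_eff ~ 90.9
  phi <- disc_sharp(m, 200, 200, 50)
  d <- detect_droplets(phi, m, depth = 50)
  expect_identical(nrow(d), 1L)
  expect_equal(d$volume, pi * 50^2 * 50, tolerance = 0.03)
  expect_equal(d$d_eff, 90.86, tolerance = 0.02)
  expect_equal(d$x, 200, tolerance = 1)
  expect_equal(d$y, 200, tolerance = 1)

  # two separated discs: two records, agreeing with the brute-force
  # 8-connected labelling oracle
  phi2 <- pmax(disc_sharp(m, 120, 120, 40), disc_sharp(m, 290, 280, 30))
  d2 <- detect_droplets(phi2, m)
  expect_identical(nrow(d2), 2L)
  oracle <- label_oracle(phi2 > 0.5)
  expect_identical(max(oracle), 2L)

  # labelling agreement on random fields
  set.seed(42)
  mk <- box_mask(40, 40, 5)
  for (rep in 1:10) {
    bin <- matrix(stats::runif(40 * 40) < 0.35, 40, 40) & mk$fluid
    lab <- matrix(droplamp:::label_components_cpp(as.integer(mk$fluid),
                                                  40L, 40L,
                                                  as.numeric(bin), 0.5),
                  40, 40)
    oracle <- label_oracle(bin)
    expect_identical(max(lab), max(oracle))
    # same partition: labels may be permuted but co-membership must agree
    ok <- tapply(oracle[bin], lab[bin], function(v) length(unique(v)) == 1)
    expect_true(all(ok))
  }
})

test_that("generation frequency summarises detachment times", {
  rec <- data.frame(detach_time = c(0.01, 0.02, 0.03))
  fr <- generation_frequency(rec, window = c(0, 1))
  expect_equal(fr$frequency, 100)
  expect_equal(fr$period_cv, 0)

  set.seed(1)
  tt <- cumsum(0.002 + stats::runif(20, -5e-4, 5e-4))
  fr2 <- generation_frequency(data.frame(detach_time = tt), window = range(tt))
  expect_equal(fr2$frequency, (length(tt) - 1) / diff(range(tt)))
  expect_equal(fr2$frequency, 1 / mean(diff(tt)), tolerance = 1e-10)
  expect_gt(fr2$period_cv, 0)

  expect_error(generation_frequency(data.frame(detach_time = 0.01)),
               "insufficient")
})

test_that("pressure probes recover the plane-Poiseuille pressure drop", {
  g <- build_linear_channel(W = 50, L = 500)
  m <- rasterize_geometry(g, 2.5)
  mu <- 1.12e-2; ub <- 0.005
  st <- solve_steady_stokes(m, ub, mu = mu)
  # uniform field: zero difference
  st0 <- st; st0$p[] <- 42
  pr <- probe_pair(c(100, 25), c(400, 25))
  expect_equal(probe_pressure_difference(st0, pr), 0)
  # dP = 12 mu ubar L / W^2 over L = 300 um
  dp <- probe_pressure_difference(st, pr)
  expect_equal(dp, 12 * mu * ub * 300e-6 / (50e-6)^2, tolerance = 0.02)
  expect_error(probe_pressure_difference(st, probe_pair(c(-10, 25), c(1, 1))),
               "probe")
})

test_that("velocity profiles are no-slip, symmetric and flux-consistent", {
  g <- build_linear_channel(W = 50, L = 500)
  m <- rasterize_geometry(g, 2.5)
  st <- solve_steady_stokes(m, 0.005, mu = 1.12e-2)
  prof <- sample_velocity_profile(st, c(250, 0), c(250, 50), n = 51)
  expect_lt(prof$speed[1], 0.15 * max(prof$speed))     # small at the walls
  expect_lt(prof$speed[51], 0.15 * max(prof$speed))
  expect_equal(prof$speed, rev(prof$speed), tolerance = 1e-8)
  expect_lte(abs(which.max(prof$speed) - 26), 1)       # peak at the centre
  # trapezoid integral of the profile ~ inlet flux (2D, per unit depth)
  q <- sum(diff(prof$y * 1e-6) * (head(prof$speed, -1) + tail(prof$speed, -1)) / 2)
  expect_equal(q, 0.005 * 50e-6, tolerance = 0.01)
  expect_error(sample_velocity_profile(st, c(-100, -100), c(-90, -90)),
               "probe")
})

test_that("zero flow gives all-zero profiles", {
  g <- build_linear_channel(W = 50, L = 200)
  m <- rasterize_geometry(g, 5)
  st <- initialize_state(m, fluid_pair_params())
  prof <- sample_velocity_profile(st, c(100, 0), c(100, 50))
  expect_true(all(prof$speed == 0))
})
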