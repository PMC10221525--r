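test_that("neutral wetting reduces to a homogeneous Neumann condition", {
  m <- rasterize_geometry(build_t_junction(), 5)
  st <- initialize_state(m, fluid_pair_params())
  cc <- droplamp:::mask_cell_centers(m)
  st$phi <- outer(1 / (1 + exp((cc$x - 150) / 10)), rep(1, m$ny))
  st$phi[!m$fluid] <- 0
  out <- apply_contact_angle(st, theta = pi / 2)
  # fluid cells untouched
  expect_identical(out$phi[m$fluid], st$phi[m$fluid])
  # ghost equals the mean of adjacent fluid values (cos(pi/2) = 0)
  solid_adj <- which(!m$fluid & droplamp:::dilate8(m$fluid), arr.ind = TRUE)
  r <- solid_adj[1, ]
  nb <- c()
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    ii <- r[1] + d[1]; jj <- r[2] + d[2]
    if (ii >= 1 && ii <= m$nx && jj >= 1 && jj <= m$ny && m$fluid[ii, jj])
      nb <- c(nb, st$phi[ii, jj])
  }
  expect_equal(out$phi[r[1], r[2]], mean(nb), tolerance = 1e-12)
})

test_that("the condition is local: no effect far from the interface", {
  m <- rasterize_geometry(build_t_junction(), 5)
  st <- initialize_state(m, fluid_pair_params())   # phi identically 0
  out <- apply_contact_angle(st, theta = 3 * pi / 4)
  expect_equal(max(abs(out$phi)), 0)
  expect_error(apply_contact_angle(st, theta = 0), "theta")
})

test_that("a wall droplet relaxes toward the prescribed oblique angle", {
  # water disc seeded on the floor of a closed oil-filled box with
  # theta = 3pi/4; after capillary relaxation the circle fitted to the
  # phi = 0.5 contour meets the wall obliquely, near 135 degrees
  m <- box_mask(66, 66, 5)
  st <- initialize_state(m, fluid_pair_params(eps = 2.5e-6))
  st$phi <- disc_phi(m, 165, 5, 80, eps_um = 5)
  st$phi[!m$fluid] <- 0
  run <- run_simulation(st, inflow_spec(u_d = 0, ratio = 0, u_c = 0),
                        t_end = 0.06, record_every = 5000)
  ph <- run$state$phi
  cc <- droplamp:::mask_cell_centers(m)
  pts <- NULL
  for (j in 3:(m$ny - 1)) {
    row <- ph[, j]
    idx <- which(diff(row > 0.5) != 0)
    for (i in idx) {
      x <- cc$x[i] + (0.5 - row[i]) / (row[i + 1] - row[i]) * m$cell_size
      pts <- rbind(pts, c(x, cc$y[j]))
    }
  }
  sel <- pts[, 2] > 60                       # fit away from the contact line
  A <- cbind(2 * pts[sel, 1], 2 * pts[sel, 2], 1)
  b <- pts[sel, 1]^2 + pts[sel, 2]^2
  sol <- qr.solve(A, b)
  yc <- sol[2]; R <- sqrt(sol[3] + sol[1]^2 + yc^2)
  theta <- 180 - acos(min(1, max(-1, (yc - m$cell_size) / R))) * 180 / pi
  # clearly de-wetting (angle well above neutral), approaching 135 within
  # the first-order accuracy of the wall extrapolation
  expect_gt(theta, 115)
  expect_lt(theta, 150)
})
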