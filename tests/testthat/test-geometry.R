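test_that("flow-focusing junction has the right ports, symmetry and area", {
  g <- build_flow_focusing(Wc = 50, Wd = 50)
  roles <- vapply(g$inlets, `[[`, "", "role")
  expect_identical(sum(roles == "continuous"), 2L)
  expect_identical(sum(roles == "dispersed"), 1L)
  expect_length(g$outlets, 1)

  # rectangle decomposition is overlap-free, so the union area is the sum
  # (checked pairwise), and the aligned raster reproduces it exactly
  rects <- g$polygons
  overlap <- 0
  for (a in seq_along(rects)) for (b in seq_along(rects)) {
    if (a >= b) next
    ra <- rects[[a]]; rb <- rects[[b]]
    ox <- max(0, min(max(ra[, 1]), max(rb[, 1])) -
                max(min(ra[, 1]), min(rb[, 1])))
    oy <- max(0, min(max(ra[, 2]), max(rb[, 2])) -
                max(min(ra[, 2]), min(rb[, 2])))
    overlap <- overlap + ox * oy
  }
  expect_equal(overlap, 0)
  area_sum <- sum(vapply(rects, droplamp:::polygon_area, numeric(1)))
  m <- rasterize_geometry(g, 5)
  expect_equal(mask_area(m), area_sum)

  # mirror symmetry about the dispersed-channel axis (grid-aligned)
  expect_identical(m$fluid, m$fluid[, rev(seq_len(m$ny))])

  expect_error(build_flow_focusing(Wc = -5), "positive")
})

test_that("T-junction step constricts the mouth to Wd - h", {
  g0 <- build_t_junction(h = 0)
  expect_identical(g0$name, "t_junction")
  roles <- vapply(g0$inlets, `[[`, "", "role")
  expect_identical(sort(roles), c("continuous", "dispersed"))

  # h = 35 um on a 50 um channel leaves a 15 um mouth
  g35 <- build_t_junction(h = 35)
  m35 <- rasterize_geometry(g35, 2.5)
  j_mouth <- as.integer(50 / 2.5) + 1L   # first row above the main channel
  expect_identical(sum(m35$fluid[, j_mouth]), as.integer(15 / 2.5))

  # geometry is continuous at h -> 0: a vanishing step changes nothing
  # beyond one cell
  m0 <- rasterize_geometry(g0, 2.5)
  meps <- rasterize_geometry(build_t_junction(h = 1e-9), 2.5)
  expect_lte(sum(m0$fluid != meps$fluid), m0$nx)

  expect_error(build_t_junction(h = 50), "h")
})

test_that("linear and serpentine channels are well formed", {
  gl <- build_linear_channel(W = 50, L = 1000)
  expect_equal(droplamp:::polygon_area(gl$polygons[[1]]), 50 * 1000)

  gs <- build_serpentine_channel(W = 50, n_turns = 4, pitch = 150)
  expect_equal(gs$params$W, gl$params$W)   # equal widths by design
  # non-self-intersecting path, brute-force segment-pair oracle
  expect_false(polyline_self_intersects(gs$params$centerline))
  # longer centreline than the straight channel over the same bbox width
  cl <- gs$params$centerline
  len <- sum(sqrt(rowSums(diff(cl)^2)))
  expect_gt(len, max(cl[, 1]) - min(cl[, 1]))
  expect_error(build_serpentine_channel(W = 50, pitch = 40), "overlap")
})

test_that("spiral centreline length matches Archimedean quadrature", {
  g <- build_spiral_channel(W = 100, n_loops = 3, pitch = 250, r0 = 200)
  cl <- g$params$centerline
  len <- sum(sqrt(rowSums(diff(cl)^2)))
  b <- 250 / (2 * pi)
  arc <- stats::integrate(function(t) sqrt(b^2 + (200 + b * t)^2),
                          0, 2 * pi * 3, rel.tol = 1e-10)$value
  expect_equal(len, arc, tolerance = 1e-3)
  expect_false(polyline_self_intersects(cl))
  expect_equal(g$params$W, 100)
  expect_error(build_spiral_channel(W = 100, pitch = 50), "overlap")
})

test_that("splitting manifold bifurcates symmetrically", {
  g <- build_splitting_manifold(W = 100, n_outlets = 4)
  expect_length(g$outlets, 4)
  widths <- vapply(g$outlets, function(s) abs(diff(s[, 1])), numeric(1))
  expect_true(all(widths == 100))          # congruent outlet segments
  # evenly spaced outlets
  centers <- sort(vapply(g$outlets, function(s) mean(s[, 1]), numeric(1)))
  expect_equal(diff(centers), rep(400, 3))
  m <- rasterize_geometry(g, 10)
  expect_identical(m$fluid, m$fluid[rev(seq_len(m$nx)), ])  # mirror-exact
  expect_error(build_splitting_manifold(n_outlets = 3), "power of 2")
})

test_that("rasterization is exact on aligned channels and convergent", {
  m <- rasterize_geometry(build_linear_channel(W = 50, L = 200), 2.5)
  expect_identical(sum(m$fluid[1, ]), as.integer(50 / 2.5))  # 20 cells across

  # every fluid cell reaches the outlet
  expect_identical(droplamp:::cells_reaching_outlet(m), m$fluid)

  # spiral raster area converges to the polygon area, first order
  g <- build_spiral_channel()
  atrue <- droplamp:::polygon_area(g$polygons[[1]])
  errs <- vapply(c(10, 5), function(h)
    abs(mask_area(rasterize_geometry(g, h)) - atrue) / atrue, numeric(1))
  expect_lt(errs[2], errs[1])
  expect_lt(errs[2], 0.05)

  expect_error(rasterize_geometry(build_linear_channel(W = 50, L = 200), 10),
               "cell_size")
})
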