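test_that("junction probe placement sits in each feed channel", {
  gff <- build_flow_focusing()
  pff <- junction_probes(gff)
  m <- rasterize_geometry(gff, 5)
  expect_length(droplamp:::probe_cell_index(m, pff), 2)

  gtj <- build_t_junction(h = 10)
  ptj <- junction_probes(gtj)
  mt <- rasterize_geometry(gtj, 5)
  expect_length(droplamp:::probe_cell_index(mt, ptj), 2)
})

test_that("a single-ratio sweep yields a single well-formed row", {
  # very short horizon: structure of the table, not droplet statistics
  tab <- sweep_flow_ratio("t_junction", ratios = 5, cell_size = 5,
                          t_end = 2e-3)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$structure, "t_junction")
  expect_identical(tab$ratio, 5)
  expect_true(is.finite(tab$dP_mean))
  # too short for three detachments: flagged, never fabricated
  expect_true(tab$flagged)
  expect_true(is.na(tab$d_eff_mean))
  expect_error(sweep_flow_ratio("t_junction", ratios = 12), "ratios")
})

test_that("cross-sections are perpendicular to the centreline", {
  g <- build_serpentine_channel()
  cl <- g$params$centerline
  cs <- droplamp:::cross_section_at(cl, 0.5, 50)
  v <- cs$to - cs$from
  expect_equal(sqrt(sum(v^2)), 50, tolerance = 1e-9)
  # midpoint back on the centreline
  expect_equal((cs$from + cs$to) / 2, cs$at, tolerance = 1e-9)
})

test_that("step-height zero reproduces the plain T-junction geometry", {
  m0 <- rasterize_geometry(build_t_junction(h = 0), 5)
  ms <- rasterize_geometry(build_t_junction(h = 1e-12), 5)
  expect_identical(m0$fluid, ms$fluid)
})
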