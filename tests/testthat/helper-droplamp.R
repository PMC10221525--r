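# shared fixtures built in code

# closed rectangular box mask (all walls, no inlet/outlet) for static
# interface benchmarks; a one-cell solid border carries the wall ghost
# values used by the contact-angle condition
box_mask <- function(nx, ny, cell_size, depth = 50) {
  fl <- matrix(FALSE, nx, ny)
  fl[2:(nx - 1), 2:(ny - 1)] <- TRUE
  xt <- matrix(0L, nx + 1, ny)
  xt[c(2, nx), 2:(ny - 1)] <- 1L
  yt <- matrix(0L, nx, ny + 1)
  yt[2:(nx - 1), c(2, ny)] <- 1L
  structure(list(cell_size = cell_size, origin = c(0, 0), nx = nx, ny = ny,
                 fluid = fl, xtag = xt, ytag = yt,
                 depth = depth, geometry_name = "box",
                 inlet_roles = character(0)),
            class = "domain_mask")
}

# periodic strip mask: all-fluid, walls top/bottom at the domain edge,
# open x ends (the solver's periodic test mode wraps them)
strip_mask <- function(nx, ny, cell_size, depth = 50) {
  structure(list(cell_size = cell_size, origin = c(0, 0), nx = nx, ny = ny,
                 fluid = matrix(TRUE, nx, ny),
                 xtag = matrix(0L, nx + 1, ny),
                 ytag = matrix(0L, nx, ny + 1),
                 depth = depth, geometry_name = "strip",
                 inlet_roles = character(0)),
            class = "domain_mask")
}

# smooth disc level-set profile, tanh of signed distance (um units)
disc_phi <- function(mask, cx, cy, radius, eps_um = mask$cell_size) {
  cc <- mask_cell_centers(mask)
  d <- sqrt(outer(cc$x, rep(1, mask$ny)) * 0 +
              outer((cc$x - cx)^2, (cc$y - cy)^2, "+"))
  1 / (1 + exp((d - radius) / eps_um))
}

# sharp disc indicator
disc_sharp <- function(mask, cx, cy, radius) {
  cc <- mask_cell_centers(mask)
  d2 <- outer((cc$x - cx)^2, (cc$y - cy)^2, "+")
  (d2 < radius^2) * 1
}

# brute-force 8-connected labelling oracle (pure R, queue-based)
label_oracle <- function(bin) {
  nx <- nrow(bin); ny <- ncol(bin)
  lab <- matrix(0L, nx, ny)
  nxt <- 0L
  for (j0 in seq_len(ny)) for (i0 in seq_len(nx)) {
    if (!bin[i0, j0] || lab[i0, j0]) next
    nxt <- nxt + 1L
    queue <- list(c(i0, j0))
    lab[i0, j0] <- nxt
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- q[1] + di; jj <- q[2] + dj
        if (ii >= 1 && ii <= nx && jj >= 1 && jj <= ny &&
            bin[ii, jj] && !lab[ii, jj]) {
          lab[ii, jj] <- nxt
          queue[[length(queue) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# brute-force segment-pair intersection test for a polyline (excluding
# consecutive segments)
polyline_self_intersects <- function(pts) {
  segint <- function(p1, p2, p3, p4) {
    d1 <- (p4[1] - p3[1]) * (p1[2] - p3[2]) - (p4[2] - p3[2]) * (p1[1] - p3[1])
    d2 <- (p4[1] - p3[1]) * (p2[2] - p3[2]) - (p4[2] - p3[2]) * (p2[1] - p3[1])
    d3 <- (p2[1] - p1[1]) * (p3[2] - p1[2]) - (p2[2] - p1[2]) * (p3[1] - p1[1])
    d4 <- (p2[1] - p1[1]) * (p4[2] - p1[2]) - (p2[2] - p1[2]) * (p4[1] - p1[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  n <- nrow(pts) - 1
  for (a in seq_len(n - 2)) for (b in seq(a + 2, n)) {
    if (segint(pts[a, ], pts[a + 1, ], pts[b, ], pts[b + 1, ])) return(TRUE)
  }
  FALSE
}

# default two-phase fluid pair used across solver tests
test_params <- function(...) fluid_pair_params(...)
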