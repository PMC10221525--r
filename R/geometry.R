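## Channel layouts are unions of simple polygons in the chip plane.
## Units: micrometres throughout; origin at the lower-left of the bounding box.

rect_poly <- function(x0, y0, x1, y1) {
  stopifnot(x1 > x0, y1 > y0)
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

polygon_area <- function(p) {
  # shoelace, absolute value
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

segment <- function(x0, y0, x1, y1) cbind(x = c(x0, x1), y = c(y0, y1))

new_channel_geometry <- function(name, polygons, inlets, outlets, depth = 50,
                                 params = list()) {
  stopifnot(length(polygons) >= 1, length(outlets) >= 1)
  structure(list(name = name, polygons = polygons, inlets = inlets,
                 outlets = outlets, depth = depth, params = params),
            class = "channel_geometry")
}

#' @export
print.channel_geometry <- function(x, ...) {
  bb <- geometry_bbox(x)
  roles <- vapply(x$inlets, `[[`, "", "role")
  cat(sprintf("<channel_geometry> %s\n", x$name))
  cat(sprintf("  %d polygon(s), bbox %.0f x %.0f um, depth %.0f um\n",
              length(x$polygons), bb[3] - bb[1], bb[4] - bb[2], x$depth))
  cat(sprintf("  inlets: %s; outlets: %d\n",
              if (length(roles)) paste(roles, collapse = ", ") else "none",
              length(x$outlets)))
  invisible(x)
}

#' Bounding box of a channel geometry
#' @param g a `channel_geometry`.
#' @return numeric `c(xmin, ymin, xmax, ymax)` in micrometres.
#' @export
geometry_bbox <- function(g) {
  xy <- do.call(rbind, g$polygons)
  c(min(xy[, 1]), min(xy[, 2]), max(xy[, 1]), max(xy[, 2]))
}

.check_dims <- function(...) {
  v <- c(...)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("invalid geometry: all dimensions must be positive and finite")
}

#' Flow-focusing (cross) droplet-generation junction
#'
#' A central dispersed-phase (aqueous) channel is pinched by two opposing
#' continuous-phase (oil) streams at a cross junction; droplets detach into
#' the downstream outlet channel.
#'
#' @param Wc continuous-phase channel width, um (default 50).
#' @param Wd dispersed-phase channel width, um (default 50).
#' @param downstream_width outlet channel width, um (default `Wc`).
#' @param arm_length inlet arm length, um (default `4 * Wc`, long enough for
#'   developed inflow).
#' @param downstream_length outlet channel length, um (default `6 * Wc`).
#' @param depth out-of-plane channel depth, um (default 50, the mould layer
#'   thickness).
#' @return a `channel_geometry` with one dispersed inlet, two continuous
#'   inlets, and one outlet.
#' @export
build_flow_focusing <- function(Wc = 50, Wd = 50, downstream_width = Wc,
                                arm_length = 4 * Wc,
                                downstream_length = 6 * Wc, depth = 50) {
  .check_dims(Wc, Wd, downstream_width, arm_length, downstream_length, depth)
  arm <- arm_length
  yc <- arm + Wd / 2                      # dispersed-channel axis
  xj <- arm                               # junction left edge
  polys <- list(
    dispersed  = rect_poly(0, yc - Wd / 2, xj + Wc, yc + Wd / 2),
    arm_top    = rect_poly(xj, yc + Wd / 2, xj + Wc, yc + Wd / 2 + arm),
    arm_bottom = rect_poly(xj, yc - Wd / 2 - arm, xj + Wc, yc - Wd / 2),
    outlet     = rect_poly(xj + Wc, yc - downstream_width / 2,
                           xj + Wc + downstream_length,
                           yc + downstream_width / 2)
  )
  inlets <- list(
    list(segment = segment(0, yc - Wd / 2, 0, yc + Wd / 2),
         role = "dispersed"),
    list(segment = segment(xj, yc + Wd / 2 + arm, xj + Wc, yc + Wd / 2 + arm),
         role = "continuous"),
    list(segment = segment(xj, yc - Wd / 2 - arm, xj + Wc, yc - Wd / 2 - arm),
         role = "continuous")
  )
  outlets <- list(segment(xj + Wc + downstream_length, yc - downstream_width / 2,
                          xj + Wc + downstream_length, yc + downstream_width / 2))
  new_channel_geometry("flow_focusing", polys, inlets, outlets, depth,
                       params = list(Wc = Wc, Wd = Wd, arm_length = arm,
                                     downstream_width = downstream_width,
                                     downstream_length = downstream_length,
                                     junction_x = xj + Wc / 2, axis_y = yc))
}

#' T-junction droplet-generation structure
#'
#' A dispersed-phase side channel meets a straight continuous-phase main
#' channel at a right angle. An optional one-sided step of height `h`
#' constricts the dispersed channel at its mouth to width `Wd - h`
#' (`h = 0` gives the plain T-junction).
#'
#' @param Wc main (continuous) channel width, um.
#' @param Wd dispersed channel width, um.
#' @param h step height, um; `0 <= h < Wd`.
#' @param arm_length dispersed arm length and continuous development length,
#'   um (default `4 * Wc`).
#' @param downstream_length main-channel length past the junction, um
#'   (default `6 * Wc`).
#' @param depth out-of-plane depth, um.
#' @return a `channel_geometry` with one continuous inlet, one dispersed
#'   inlet, one outlet.
#' @export
build_t_junction <- function(Wc = 50, Wd = 50, h = 0, arm_length = 4 * Wc,
                             downstream_length = 6 * Wc, depth = 50) {
  .check_dims(Wc, Wd, arm_length, downstream_length, depth)
  if (h < 0 || h >= Wd)
    stop("invalid geometry: step height `h` must satisfy 0 <= h < Wd")
  arm <- arm_length
  xd <- arm                               # dispersed-channel left edge
  step_len <- Wd                          # axial extent of the constriction
  polys <- list(
    main = rect_poly(0, 0, xd + Wd + downstream_length, Wc)
  )
  if (h > 0) {
    # full-width approach, then a one-sided constriction at the mouth
    # (step on the upstream side, so the mouth is Wd - h wide)
    polys$approach <- rect_poly(xd, Wc + step_len, xd + Wd, Wc + arm)
    polys$mouth <- rect_poly(xd + h, Wc, xd + Wd, Wc + step_len + 1e-9)
  } else {
    polys$approach <- rect_poly(xd, Wc, xd + Wd, Wc + arm)
  }
  inlets <- list(
    list(segment = segment(0, 0, 0, Wc), role = "continuous"),
    list(segment = segment(xd, Wc + arm, xd + Wd, Wc + arm),
         role = "dispersed")
  )
  outlets <- list(segment(xd + Wd + downstream_length, 0,
                          xd + Wd + downstream_length, Wc))
  new_channel_geometry(if (h > 0) "t_junction_step" else "t_junction",
                       polys, inlets, outlets, depth,
                       params = list(Wc = Wc, Wd = Wd, h = h, arm_length = arm,
                                     downstream_length = downstream_length,
                                     junction_x = xd + Wd / 2, axis_y = Wc / 2))
}

#' Straight (linear) channel
#' @param W channel width, um (default 50).
#' @param L channel length, um.
#' @param depth out-of-plane depth, um.
#' @return a `channel_geometry`, inlet left, outlet right.
#' @export
build_linear_channel <- function(W = 50, L = 1000, depth = 50) {
  .check_dims(W, L, depth)
  g <- new_channel_geometry(
    "linear",
    list(rect_poly(0, 0, L, W)),
    list(list(segment = segment(0, 0, 0, W), role = "continuous")),
    list(segment(L, 0, L, W)),
    depth, params = list(W = W, L = L))
  g$params$centerline <- cbind(x = c(0, L), y = c(W / 2, W / 2))
  g
}

#' Serpentine buffering channel
#'
#' Boustrophedon channel: parallel limbs joined by 180-degree turns, used to
#' buffer unstable inflow before the droplet junction.
#'
#' @param W channel width, um (default 50).
#' @param n_turns number of 180-degree turns (>= 1; default 4).
#' @param pitch centreline spacing of adjacent limbs, um; must be `>= W`.
#' @param limb_length straight limb length, um (default 400).
#' @param depth out-of-plane depth, um.
#' @return a `channel_geometry`; `params$centerline` holds the channel
#'   centreline polyline.
#' @export
build_serpentine_channel <- function(W = 50, n_turns = 4, pitch = 150,
                                     limb_length = 400, depth = 50) {
  .check_dims(W, pitch, limb_length, depth)
  if (n_turns < 1) stop("invalid geometry: n_turns must be >= 1")
  if (pitch < W)
    stop("invalid geometry: pitch < W makes adjacent serpentine limbs overlap")
  L <- limb_length
  y0 <- W / 2
  polys <- list()
  cl <- NULL
  for (i in 0:n_turns) {
    yi <- y0 + i * pitch
    polys[[paste0("limb", i)]] <- rect_poly(0, yi - W / 2, L, yi + W / 2)
    pts <- cbind(x = c(0, L), y = c(yi, yi))
    if (i %% 2 == 1) pts <- pts[2:1, , drop = FALSE]
    cl <- rbind(cl, pts)
    if (i < n_turns) {
      right_end <- (i %% 2 == 0)
      xr <- if (right_end) c(L - W, L) else c(0, W)
      polys[[paste0("turn", i)]] <- rect_poly(xr[1], yi - W / 2,
                                              xr[2], yi + pitch + W / 2)
    }
  }
  last_right <- (n_turns %% 2 == 0)
  out_x <- if (last_right) L else 0
  ylast <- y0 + n_turns * pitch
  g <- new_channel_geometry(
    "serpentine", polys,
    list(list(segment = segment(0, 0, 0, W), role = "continuous")),
    list(segment(out_x, ylast - W / 2, out_x, ylast + W / 2)),
    depth,
    params = list(W = W, n_turns = n_turns, pitch = pitch,
                  limb_length = L, centerline = cl))
  g
}

#' Archimedean spiral collection channel
#'
#' Spiral channel (r = r0 + pitch * angle / 2pi) used to stabilise droplets
#' on their way to the collection chamber.
#'
#' @param W channel width, um (default 100).
#' @param n_loops number of full turns (default 3).
#' @param pitch radial spacing of adjacent loops, um; must be `>= W`.
#' @param r0 inner start radius of the centreline, um (default `2 * W`).
#' @param depth out-of-plane depth, um.
#' @param points_per_loop polygon sampling density (default 120).
#' @return a `channel_geometry`; inlet at the outer end, outlet at the inner
#'   end; `params$centerline` holds the sampled centreline.
#' @export
build_spiral_channel <- function(W = 100, n_loops = 3, pitch = 250,
                                 r0 = 2 * W, depth = 50,
                                 points_per_loop = 120) {
  .check_dims(W, pitch, r0, depth)
  if (n_loops < 1) stop("invalid geometry: n_loops must be >= 1")
  if (pitch < W)
    stop("invalid geometry: pitch < W makes adjacent spiral loops overlap")
  if (r0 <= W / 2) stop("invalid geometry: r0 must exceed W/2")
  b <- pitch / (2 * pi)
  t <- seq(0, 2 * pi * n_loops, length.out = points_per_loop * n_loops + 1)
  r <- r0 + b * t
  R <- max(r) + W / 2
  cx <- R; cy <- R                        # shift so bbox starts at origin
  outer <- cbind(x = cx + (r + W / 2) * cos(t), y = cy + (r + W / 2) * sin(t))
  inner <- cbind(x = cx + (r - W / 2) * cos(t), y = cy + (r - W / 2) * sin(t))
  poly <- rbind(outer, inner[rev(seq_len(nrow(inner))), ])
  cl <- cbind(x = cx + r * cos(t), y = cy + r * sin(t))
  r_out <- r0 + b * 2 * pi * n_loops
  g <- new_channel_geometry(
    "spiral", list(poly),
    list(list(segment = segment(cx + r_out - W / 2, cy,
                                cx + r_out + W / 2, cy),
              role = "continuous")),
    list(segment(cx + r0 - W / 2, cy, cx + r0 + W / 2, cy)),
    depth,
    params = list(W = W, n_loops = n_loops, pitch = pitch, r0 = r0,
                  centerline = cl[rev(seq_len(nrow(cl))), ]))
  g
}

#' Symmetric splitting manifold (bifurcation cascade)
#'
#' H-tree style manifold that splits one inlet stream into `n_outlets`
#' geometrically equivalent outlets so droplets spread evenly into the
#' collection chamber.
#'
#' @param W channel width, um (default 100).
#' @param n_outlets number of outlets; must be a power of 2 (default 4).
#' @param outlet_spacing centre-to-centre spacing of adjacent outlets, um
#'   (default `4 * W`).
#' @param stem_length vertical branch length per level, um (default `4 * W`).
#' @param depth out-of-plane depth, um.
#' @return a `channel_geometry`, inlet at the top, outlets along the bottom.
#' @export
build_splitting_manifold <- function(W = 100, n_outlets = 4,
                                     outlet_spacing = 4 * W,
                                     stem_length = 4 * W, depth = 50) {
  .check_dims(W, outlet_spacing, stem_length, depth)
  levels <- log2(n_outlets)
  if (n_outlets < 2 || levels != round(levels))
    stop("invalid geometry: n_outlets must be a power of 2 (>= 2)")
  levels <- as.integer(round(levels))
  span0 <- outlet_spacing * (n_outlets - 1)
  height <- (levels + 1) * stem_length + levels * W
  xc0 <- span0 / 2 + W / 2
  polys <- list()
  outlets <- list()
  k <- 0
  recurse <- function(xc, ytop, span, lev) {
    k <<- k + 1
    y1 <- ytop - stem_length
    polys[[paste0("stem", k)]] <<- rect_poly(xc - W / 2, y1, xc + W / 2, ytop)
    if (lev == 0) {
      # leaf: extend stem to the floor and terminate in an outlet
      if (y1 > 0)
        polys[[paste0("leaf", k)]] <<- rect_poly(xc - W / 2, 0, xc + W / 2, y1)
      outlets[[length(outlets) + 1]] <<- segment(xc - W / 2, 0, xc + W / 2, 0)
    } else {
      d <- span / 4
      polys[[paste0("bar", k)]] <<- rect_poly(xc - d - W / 2, y1 - W,
                                              xc + d + W / 2, y1)
      recurse(xc - d, y1 - W, span / 2, lev - 1)
      recurse(xc + d, y1 - W, span / 2, lev - 1)
    }
  }
  # span/4 at the root gives offset s*2^(levels-2), halving per level, which
  # lands the 2^levels leaves on an evenly spaced comb with spacing s
  recurse(xc0, height, outlet_spacing * n_outlets, levels)
  # outlets come out of the recursion left-to-right already
  new_channel_geometry(
    "splitting", polys,
    list(list(segment = segment(xc0 - W / 2, height, xc0 + W / 2, height),
              role = "continuous")),
    outlets, depth,
    params = list(W = W, n_outlets = n_outlets,
                  outlet_spacing = outlet_spacing,
                  stem_length = stem_length, height = height))
}
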