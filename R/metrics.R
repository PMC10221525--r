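## Droplet identification and the derived design metrics.

#' Effective droplet diameter from its volume
#'
#' Diameter of the sphere whose volume equals the droplet volume:
#' `d_eff = 2 * (3 V / (4 pi))^(1/3)`.
#'
#' @param volume droplet volume(s), um^3; must be positive.
#' @return effective diameter(s), um.
#' @export
effective_diameter <- function(volume) {
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("volume must be positive")
  2 * (3 * volume / (4 * pi))^(1 / 3)
}

#' Detect detached droplets in a level-set field
#'
#' Droplets are 8-connected components of the region `phi > 0.5` that are
#' not attached to a dispersed-phase inlet. The area uses cell counting
#' with a sub-cell correction: each component cell contributes its `phi`
#' fraction, as does the one-cell skirt around the component (shared skirt
#' cells are split between adjacent components). Planar areas are converted
#' to volumes with the out-of-plane channel depth before applying the
#' spherical effective-diameter formula.
#'
#' @param phi level-set field (nx x ny matrix) or a `flow_state`.
#' @param mask a `domain_mask` (taken from the state when `phi` is one).
#' @param depth out-of-plane depth, um; defaults to the mask depth.
#' @return data frame with columns `id`, `area` (um^2), `volume` (um^3),
#'   `d_eff` (um), `x`, `y` (centroid, um). Empty when no droplets.
#' @export
detect_droplets <- function(phi, mask = NULL, depth = NULL) {
  if (inherits(phi, "flow_state")) {
    mask <- phi$mask
    phi <- phi$phi
  }
  stopifnot(inherits(mask, "domain_mask"))
  if (is.null(depth)) depth <- mask$depth
  nx <- mask$nx; ny <- mask$ny
  lab <- matrix(label_components_cpp(as.integer(mask$fluid), nx, ny,
                                     as.numeric(phi), 0.5), nx, ny)
  nlab <- max(lab)
  empty <- data.frame(id = integer(), area = numeric(), volume = numeric(),
                      d_eff = numeric(), x = numeric(), y = numeric())
  if (nlab == 0) return(empty)
  attached <- attached_labels(lab, mask)
  h <- mask$cell_size
  cc <- mask_cell_centers(mask)
  rows <- list()
  # skirt attribution: for each unlabelled cell, find adjacent labels
  for (L in setdiff(seq_len(nlab), attached)) {
    sel <- lab == L
    area <- sum(phi[sel]) * h^2
    # one-cell 8-neighbourhood skirt
    skirt <- dilate8(sel) & !sel & mask$fluid & phi > 1e-6 & lab == 0
    if (any(skirt)) {
      idx <- which(skirt, arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1]; j <- idx[r, 2]
        nb <- lab[max(1, i - 1):min(nx, i + 1), max(1, j - 1):min(ny, j + 1)]
        nbl <- unique(nb[nb > 0])
        area <- area + phi[i, j] * h^2 / length(nbl)
      }
    }
    if (area <= 0) next
    w <- phi[sel]
    ij <- which(sel, arr.ind = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      id = L, area = area, volume = area * depth,
      d_eff = effective_diameter(area * depth),
      x = sum(cc$x[ij[, 1]] * w) / sum(w),
      y = sum(cc$y[ij[, 2]] * w) / sum(w))
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$id <- seq_len(nrow(out))
  out
}

dilate8 <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  out <- m
  sh <- function(a, di, dj) {
    r <- matrix(FALSE, nx, ny)
    xi <- seq_len(nx) - di; yi <- seq_len(ny) - dj
    ok_x <- xi >= 1 & xi <= nx; ok_y <- yi >= 1 & yi <= ny
    r[ok_x, ok_y] <- a[xi[ok_x], yi[ok_y]]
    r
  }
  for (di in -1:1) for (dj in -1:1)
    if (di || dj) out <- out | sh(m, di, dj)
  out
}

# labels of components touching a dispersed inlet face
attached_labels <- function(lab, mask) {
  nx <- mask$nx; ny <- mask$ny
  att <- integer(0)
  xi <- which(mask$xtag == FACE_INLET_D, arr.ind = TRUE)
  if (nrow(xi)) for (r in seq_len(nrow(xi))) {
    i <- xi[r, 1]; j <- xi[r, 2]
    if (i <= nx && lab[i, j] > 0) att <- c(att, lab[i, j])
    if (i > 1 && lab[i - 1, j] > 0) att <- c(att, lab[i - 1, j])
  }
  yi <- which(mask$ytag == FACE_INLET_D, arr.ind = TRUE)
  if (nrow(yi)) for (r in seq_len(nrow(yi))) {
    i <- yi[r, 1]; j <- yi[r, 2]
    if (j <= ny && lab[i, j] > 0) att <- c(att, lab[i, j])
    if (j > 1 && lab[i, j - 1] > 0) att <- c(att, lab[i, j - 1])
  }
  unique(att)
}

#' Track droplets through a recorded component series
#'
#' Matches the free (detached) connected components recorded during
#' [run_simulation()] across frames by nearest-centroid association and
#' returns one record per droplet: detachment time (first frame on which
#' the free component appears), area at detachment, volume, effective
#' diameter and detachment centroid.
#'
#' @param components the `components` table from [run_simulation()].
#' @param mask the `domain_mask` of the run.
#' @param depth out-of-plane depth, um (default: mask depth).
#' @param max_move maximum centroid displacement (in cells) between frames
#'   for two observations to be the same droplet (default 8).
#' @param min_area_cells ignore components smaller than this many cells
#'   (default 4; sub-grid fragments).
#' @return data frame with `id`, `detach_time` (s), `area` (um^2),
#'   `volume` (um^3), `d_eff` (um), `x`, `y` (um), sorted by `detach_time`.
#' @export
track_droplets <- function(components, mask, depth = NULL, max_move = 8,
                           min_area_cells = 4) {
  if (is.null(depth)) depth <- mask$depth
  h <- mask$cell_size
  empty <- data.frame(id = integer(), detach_time = numeric(),
                      area = numeric(), volume = numeric(),
                      d_eff = numeric(), x = numeric(), y = numeric(),
                      last_seen = numeric())
  if (is.null(components) || !nrow(components)) return(empty)
  free <- components[components$attached == 0 &
                       components$area_cells >= min_area_cells, , drop = FALSE]
  if (!nrow(free)) return(empty)
  times <- sort(unique(free$t))
  active <- data.frame(id = integer(), cx = numeric(), cy = numeric(),
                       last = numeric())
  records <- list()
  seen <- numeric(0)      # last frame each droplet id was observed
  next_id <- 1L
  for (tt in times) {
    fr <- free[free$t == tt, , drop = FALSE]
    assigned <- rep(FALSE, nrow(fr))
    if (nrow(active)) {
      keep <- logical(nrow(active))
      for (a in seq_len(nrow(active))) {
        if (!nrow(fr)) break
        d2 <- (fr$cx_cell - active$cx[a])^2 + (fr$cy_cell - active$cy[a])^2
        cand <- which(!assigned & d2 <= max_move^2)
        if (length(cand)) {
          b <- cand[which.min(d2[cand])]
          assigned[b] <- TRUE
          active$cx[a] <- fr$cx_cell[b]
          active$cy[a] <- fr$cy_cell[b]
          active$last[a] <- tt
          seen[active$id[a]] <- tt
          keep[a] <- TRUE
        }
      }
      active <- active[keep, , drop = FALSE]
    }
    for (b in which(!assigned)) {
      area <- fr$area_cells[b] * h^2
      records[[next_id]] <- data.frame(
        id = next_id, detach_time = tt, area = area,
        volume = area * depth, d_eff = effective_diameter(area * depth),
        x = mask$origin[1] + fr$cx_cell[b] * h,
        y = mask$origin[2] + fr$cy_cell[b] * h)
      active <- rbind(active, data.frame(id = next_id, cx = fr$cx_cell[b],
                                         cy = fr$cy_cell[b], last = tt))
      seen[next_id] <- tt
      next_id <- next_id + 1L
    }
  }
  out <- do.call(rbind, records)
  out$last_seen <- seen[out$id]
  out[order(out$detach_time), , drop = FALSE]
}

#' Droplet generation frequency and monodispersity
#'
#' Frequency over a steady window: `(count - 1) / (last - first)` detachment
#' time, plus the coefficient of variation of the inter-detachment periods
#' as a monodispersity measure. By default the first 40% of the run is
#' discarded as start-up transient.
#'
#' @param records droplet record table ([track_droplets()] output).
#' @param window length-2 time window (s); default the last 60% of the
#'   recorded detachment-time span.
#' @return list with `frequency` (Hz), `period_cv`, `n`, `window`.
#' @export
generation_frequency <- function(records, window = NULL) {
  tt <- sort(records$detach_time)
  if (is.null(window)) {
    t0 <- if (length(tt)) tt[1] + 0.4 * (tt[length(tt)] - tt[1]) else 0
    window <- c(t0, if (length(tt)) tt[length(tt)] else 0)
  }
  tt <- tt[tt >= window[1] & tt <= window[2]]
  if (length(tt) < 3)
    stop("insufficient events: need >= 3 droplet detachments in the window")
  periods <- diff(tt)
  list(frequency = (length(tt) - 1) / (tt[length(tt)] - tt[1]),
       period_cv = stats::sd(periods) / mean(periods),
       n = length(tt), window = window)
}

#' Pressure probe pair for the two-phase pressure difference
#'
#' Standard placement is one channel-width upstream of the junction mouth
#' in each feed channel.
#'
#' @param probe_c `(x, y)` um in the continuous-phase feed channel.
#' @param probe_d `(x, y)` um in the dispersed-phase feed channel.
#' @return an object of class `probe_pair`.
#' @export
probe_pair <- function(probe_c, probe_d) {
  stopifnot(length(probe_c) == 2, length(probe_d) == 2)
  structure(list(probe_c = as.numeric(probe_c),
                 probe_d = as.numeric(probe_d)), class = "probe_pair")
}

# nearest-cell indices (0-based, for the compiled recorder); errors if the
# probe is not in fluid
probe_cell_index <- function(mask, probes) {
  one <- function(pxy) {
    i <- as.integer(floor((pxy[1] - mask$origin[1]) / mask$cell_size)) + 1L
    j <- as.integer(floor((pxy[2] - mask$origin[2]) / mask$cell_size)) + 1L
    if (i < 1 || i > mask$nx || j < 1 || j > mask$ny || !mask$fluid[i, j])
      stop("probe error: probe point outside the fluid domain")
    (i - 1L) + (j - 1L) * mask$nx
  }
  c(one(probes$probe_c), one(probes$probe_d))
}

# bilinear interpolation of a cell-centred field at (x, y) um
interp_cell_field <- function(field, mask, x, y) {
  h <- mask$cell_size
  gx <- (x - mask$origin[1]) / h + 0.5
  gy <- (y - mask$origin[2]) / h + 0.5
  i0 <- pmin(pmax(floor(gx), 1), mask$nx - 1)
  j0 <- pmin(pmax(floor(gy), 1), mask$ny - 1)
  fx <- pmin(pmax(gx - i0, 0), 1)
  fy <- pmin(pmax(gy - j0, 0), 1)
  f00 <- field[cbind(i0, j0)]; f10 <- field[cbind(i0 + 1, j0)]
  f01 <- field[cbind(i0, j0 + 1)]; f11 <- field[cbind(i0 + 1, j0 + 1)]
  f00 * (1 - fx) * (1 - fy) + f10 * fx * (1 - fy) +
    f01 * (1 - fx) * fy + f11 * fx * fy
}

#' Two-phase pressure difference at a probe pair
#'
#' `P_c - P_d`: pressure in the continuous feed channel minus pressure in
#' the dispersed feed channel, by bilinear interpolation of the cell-centred
#' pressure field.
#'
#' @param state a `flow_state`.
#' @param probes a [probe_pair()].
#' @return pressure difference, Pa.
#' @export
probe_pressure_difference <- function(state, probes) {
  stopifnot(inherits(probes, "probe_pair"))
  probe_cell_index(state$mask, probes)  # validates probes are in fluid
  pc <- interp_cell_field(state$p, state$mask,
                          probes$probe_c[1], probes$probe_c[2])
  pd <- interp_cell_field(state$p, state$mask,
                          probes$probe_d[1], probes$probe_d[2])
  pc - pd
}

# cell-centred speed field from the staggered velocities
cell_speed <- function(state) {
  nx <- state$mask$nx; ny <- state$mask$ny
  uc <- 0.5 * (state$u[1:nx, , drop = FALSE] +
                 state$u[2:(nx + 1), , drop = FALSE])
  vc <- 0.5 * (state$v[, 1:ny, drop = FALSE] +
                 state$v[, 2:(ny + 1), drop = FALSE])
  sp <- sqrt(uc^2 + vc^2)
  sp[!state$mask$fluid] <- 0
  sp
}

#' Sample the speed profile along a cross-section line
#'
#' @param state a `flow_state`.
#' @param from,to line endpoints `(x, y)` in um.
#' @param n number of sample points (default 50).
#' @return data frame with `s` (arc position, um), `x`, `y`, `speed` (m/s).
#' @export
sample_velocity_profile <- function(state, from, to, n = 50) {
  stopifnot(length(from) == 2, length(to) == 2)
  tseq <- seq(0, 1, length.out = n)
  x <- from[1] + tseq * (to[1] - from[1])
  y <- from[2] + tseq * (to[2] - from[2])
  # require the line to cross the fluid domain
  h <- state$mask$cell_size
  i <- floor((x - state$mask$origin[1]) / h) + 1
  j <- floor((y - state$mask$origin[2]) / h) + 1
  inside <- i >= 1 & i <= state$mask$nx & j >= 1 & j <= state$mask$ny
  if (!any(inside) ||
      !any(state$mask$fluid[cbind(i[inside], j[inside])]))
    stop("probe error: line does not cross the fluid domain")
  sp <- cell_speed(state)
  data.frame(s = tseq * sqrt(sum((to - from)^2)), x = x, y = y,
             speed = interp_cell_field(sp, state$mask, x, y))
}

#' Sample speed along a stored centreline
#'
#' @param state a `flow_state` on a geometry whose `params$centerline`
#'   polyline was recorded (linear, serpentine and spiral structures).
#' @param centerline n x 2 matrix of um coordinates; defaults to the one in
#'   the mask's source geometry parameters if supplied explicitly.
#' @param trim fraction of the arc length to drop at each end (default 0.1,
#'   away from inlet/outlet effects).
#' @return data frame with `s` (um), `speed` (m/s).
#' @export
sample_centerline <- function(state, centerline, trim = 0.1) {
  stopifnot(is.matrix(centerline), ncol(centerline) == 2)
  # densify the polyline to ~one sample per grid cell
  pts <- resample_polyline(centerline, state$mask$cell_size)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  keep <- s >= trim * max(s) & s <= (1 - trim) * max(s)
  sp <- cell_speed(state)
  data.frame(s = s[keep],
             speed = interp_cell_field(sp, state$mask,
                                       pts[keep, 1], pts[keep, 2]))
}

# linear resampling of a polyline at spacing ds (um)
resample_polyline <- function(pts, ds) {
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  stot <- max(s)
  sq <- seq(0, stot, by = ds)
  k <- findInterval(sq, s, all.inside = TRUE)
  w <- (sq - s[k]) / pmax(s[k + 1] - s[k], 1e-12)
  cbind(pts[k, 1] + w * (pts[k + 1, 1] - pts[k, 1]),
        pts[k, 2] + w * (pts[k + 1, 2] - pts[k, 2]))
}
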