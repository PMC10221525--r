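## Scripted design-sweep experiments: droplet generation vs. flow ratio,
## junction comparison, step-height optimization, buffer-channel and
## collection-path studies. All campaigns are deterministic.

#' Standard probe pair for a junction geometry
#'
#' One channel width upstream of the junction mouth in each feed channel.
#'
#' @param g a junction `channel_geometry` (flow-focusing or T-junction).
#' @return a [probe_pair()].
#' @export
junction_probes <- function(g) {
  p <- g$params
  if (g$name == "flow_focusing") {
    probe_pair(
      probe_c = c(p$junction_x, p$axis_y + p$Wd / 2 + p$Wc),
      probe_d = c(p$arm_length - p$Wd, p$axis_y))
  } else {
    probe_pair(
      probe_c = c(p$arm_length - p$Wc, p$axis_y),
      probe_d = c(p$arm_length + p$Wd / 2, p$Wc + p$Wd))
  }
}

# dispersed-channel prefill rectangle (up to just upstream of the junction)
prefill_rect <- function(g) {
  p <- g$params
  if (g$name == "flow_focusing")
    c(0, p$axis_y - p$Wd / 2, p$arm_length - p$Wd / 2, p$axis_y + p$Wd / 2)
  else
    c(p$arm_length, p$Wc + p$Wd, p$arm_length + p$Wd, p$Wc + p$arm_length)
}

# run one droplet-generation case and summarise it
run_droplet_case <- function(g, inflow, cell_size, t_end, params,
                             record_every = 100L, p_tol = 1e-10,
                             prefill = TRUE) {
  mask <- rasterize_geometry(g, cell_size)
  st <- initialize_state(mask, params)
  if (prefill) st <- prefill_dispersed(st, prefill_rect(g))
  probes <- junction_probes(g)
  run <- run_simulation(st, inflow, t_end, record_every = record_every,
                        probes = probes, p_tol = p_tol)
  rec <- track_droplets(run$components, mask)
  run$records <- rec
  run$mask <- mask
  run
}

# steady-window droplet summary for one case
summarise_case <- function(run, structure, ratio, h = 0) {
  rec <- run$records
  if (is.null(rec)) rec <- track_droplets(run$components, run$mask)
  ser <- run$series
  steady <- ser$t >= 0.4 * max(ser$t)
  dp_mean <- mean(ser$p_probe_c[steady] - ser$p_probe_d[steady], na.rm = TRUE)
  row <- data.frame(structure = structure, ratio = ratio, h = h,
                    n_droplets = nrow(rec), d_eff_mean = NA_real_,
                    d_eff_cv = NA_real_, frequency = NA_real_,
                    period_cv = NA_real_, dP_mean = dp_mean,
                    flagged = FALSE)
  if (nrow(rec) >= 3) {
    # with very few events the transient-trimmed window can be empty;
    # fall back to the full record
    fr <- tryCatch(generation_frequency(rec),
                   error = function(e)
                     generation_frequency(rec, window = range(rec$detach_time)))
    win <- rec$detach_time >= fr$window[1]
    # volume-weighted mean diameter: robust against satellite fragments
    row$d_eff_mean <- sum(rec$volume[win] * rec$d_eff[win]) /
      sum(rec$volume[win])
    row$d_eff_cv <- stats::sd(rec$d_eff[win]) / mean(rec$d_eff[win])
    row$frequency <- fr$frequency
    row$period_cv <- fr$period_cv
  } else {
    row$flagged <- TRUE                 # no stable droplet generation
  }
  row
}

#' Sweep the flow-rate ratio for a droplet-generation structure
#'
#' Runs the two-phase solver for each flow-rate ratio `u_c/u_d` (with
#' `u_d = 0.005` m/s) and summarises droplet effective diameter, generation
#' frequency and the two-phase probe pressure difference.
#'
#' @param structure `"flow_focusing"` or `"t_junction"`.
#' @param ratios integer flow-rate ratios, each in 1..10.
#' @param cell_size grid spacing, um (default 5).
#' @param t_end simulated time per ratio, s (default 0.1).
#' @param u_d dispersed-phase mean velocity, m/s (default 0.005).
#' @param params fluid parameters.
#' @param keep_runs return the raw runs as an attribute (default FALSE).
#' @return data frame of per-ratio summary rows; ratios with fewer than 3
#'   detachments are flagged (`flagged = TRUE`), never fabricated.
#' @export
sweep_flow_ratio <- function(structure = c("flow_focusing", "t_junction"),
                             ratios = c(2, 5, 8), cell_size = 5,
                             t_end = 0.1, u_d = 0.005,
                             params = fluid_pair_params(),
                             keep_runs = FALSE) {
  structure <- match.arg(structure)
  stopifnot(all(ratios >= 1), all(ratios <= 10))
  g <- if (structure == "flow_focusing") build_flow_focusing()
       else build_t_junction()
  runs <- list()
  rows <- lapply(ratios, function(r) {
    infl <- inflow_spec(u_d = u_d, ratio = r)
    run <- run_droplet_case(g, infl, cell_size, t_end, params)
    if (keep_runs) runs[[as.character(r)]] <<- run
    summarise_case(run, structure, r)
  })
  out <- do.call(rbind, rows)
  if (keep_runs) attr(out, "runs") <- runs
  out
}

#' Compare the flow-focusing and T-junction structures at one flow ratio
#'
#' @param ratio flow-rate ratio `u_c/u_d` (default 5).
#' @inheritParams sweep_flow_ratio
#' @return list with `table` (one summary row per structure), `dp_series`
#'   (per-structure probe pressure-difference time series) and `orderings`
#'   (logical flags: whether the flow-focusing structure shows the larger
#'   pressure difference, diameter and frequency).
#' @export
compare_junction_structures <- function(ratio = 5, cell_size = 5,
                                        t_end = 0.1, u_d = 0.005,
                                        params = fluid_pair_params()) {
  infl <- inflow_spec(u_d = u_d, ratio = ratio)
  out <- list(dp_series = list())
  rows <- lapply(c("flow_focusing", "t_junction"), function(s) {
    g <- if (s == "flow_focusing") build_flow_focusing() else build_t_junction()
    run <- run_droplet_case(g, infl, cell_size, t_end, params)
    out$dp_series[[s]] <<- data.frame(
      t = run$series$t, dP = run$series$p_probe_c - run$series$p_probe_d)
    summarise_case(run, s, ratio)
  })
  tab <- do.call(rbind, rows)
  ff <- tab[tab$structure == "flow_focusing", ]
  tj <- tab[tab$structure == "t_junction", ]
  out$table <- tab
  out$orderings <- c(
    dp_ff_greater = isTRUE(ff$dP_mean > tj$dP_mean),
    d_eff_tj_smaller = isTRUE(tj$d_eff_mean < ff$d_eff_mean),
    freq_tj_smaller = isTRUE(tj$frequency < ff$frequency))
  out
}

#' Sweep the T-junction step height
#'
#' Constricting the dispersed-channel mouth to width `Wd - h` sharpens the
#' local shear; droplet diameter is expected to fall and generation
#' frequency and the two-phase pressure difference to rise with `h`.
#'
#' @param h_list step heights, um (each `0 <= h < Wd`).
#' @inheritParams compare_junction_structures
#' @return data frame of summary rows keyed by `h`.
#' @export
sweep_step_height <- function(h_list = c(5, 10, 40), ratio = 5,
                              cell_size = 5, t_end = 0.1, u_d = 0.005,
                              params = fluid_pair_params()) {
  infl <- inflow_spec(u_d = u_d, ratio = ratio)
  rows <- lapply(h_list, function(h) {
    g <- build_t_junction(h = h)
    run <- run_droplet_case(g, infl, cell_size, t_end, params)
    summarise_case(run, "t_junction_step", ratio, h = h)
  })
  do.call(rbind, rows)
}

# cross-section line of length W perpendicular to the centreline at arc
# fraction f
cross_section_at <- function(centerline, f, W) {
  seg <- sqrt(rowSums(diff(centerline)^2))
  s <- c(0, cumsum(seg))
  target <- f * max(s)
  k <- findInterval(target, s, all.inside = TRUE)
  w <- (target - s[k]) / (s[k + 1] - s[k])
  pt <- centerline[k, ] + w * (centerline[k + 1, ] - centerline[k, ])
  dirv <- centerline[k + 1, ] - centerline[k, ]
  dirv <- dirv / sqrt(sum(dirv^2))
  nrm <- c(-dirv[2], dirv[1])
  list(from = pt - nrm * W / 2, to = pt + nrm * W / 2, at = pt)
}

#' Compare linear and serpentine buffer channels (steady single phase)
#'
#' Solves the steady Stokes flow through a linear and a serpentine channel
#' of equal width at the same inlet mean velocity and zero outlet pressure,
#' and reports six equally spaced cross-section speed profiles, the
#' outlet-centre speed and the inlet pressure of each.
#'
#' @param u_mean inlet mean velocity, m/s (default 0.005).
#' @param cell_size grid spacing, um (default 5).
#' @param W channel width, um (default 50).
#' @param mu viscosity, Pa s.
#' @return list with `profiles` (per-structure list of 6 profile data
#'   frames), `summary` (data frame: structure, inlet_pressure,
#'   outlet_center_speed) and `states`.
#' @export
compare_linear_serpentine <- function(u_mean = 0.005, cell_size = 5, W = 50,
                                      mu = 1.01e-2) {
  gl <- build_linear_channel(W = W, L = 1000)
  gs <- build_serpentine_channel(W = W)
  out <- list(profiles = list(), states = list())
  summary <- NULL
  for (g in list(gl, gs)) {
    mask <- rasterize_geometry(g, cell_size)
    st <- solve_steady_stokes(mask, u_mean, mu = mu)
    cl <- g$params$centerline
    profs <- lapply(seq_len(6) / 7, function(f) {
      cs <- cross_section_at(cl, f, W)
      sample_velocity_profile(st, cs$from, cs$to, n = 41)
    })
    # inlet pressure: mean over cells adjacent to inlet faces
    pin <- inlet_pressure(st)
    ocs <- sample_centerline(st, cl, trim = 0)
    outlet_speed <- ocs$speed[nrow(ocs)]
    # centre-of-structure speed: mean along the centreline (ends trimmed).
    # In the serpentine's turns the velocity maximum shifts off the
    # centreline, so this is the metric on which the serpentine's "centre
    # velocity" is genuinely lower; at equal flux and width the developed
    # outlet-centre speeds of the two structures coincide.
    ccs <- sample_centerline(st, cl, trim = 0.1)
    out$profiles[[g$name]] <- profs
    out$states[[g$name]] <- st
    summary <- rbind(summary, data.frame(structure = g$name,
                                         inlet_pressure = pin,
                                         outlet_center_speed = outlet_speed,
                                         center_speed_mean = mean(ccs$speed)))
  }
  out$summary <- summary
  out
}

# mean pressure over fluid cells adjacent to inlet faces
inlet_pressure <- function(state) {
  mask <- state$mask
  ps <- c()
  xi <- which(mask$xtag == FACE_INLET_C | mask$xtag == FACE_INLET_D,
              arr.ind = TRUE)
  if (nrow(xi)) for (r in seq_len(nrow(xi))) {
    i <- xi[r, 1]; j <- xi[r, 2]
    ii <- if (i <= mask$nx && mask$fluid[i, j]) i else i - 1
    ps <- c(ps, state$p[ii, j])
  }
  yi <- which(mask$ytag == FACE_INLET_C | mask$ytag == FACE_INLET_D,
              arr.ind = TRUE)
  if (nrow(yi)) for (r in seq_len(nrow(yi))) {
    i <- yi[r, 1]; j <- yi[r, 2]
    jj <- if (j <= mask$ny && mask$fluid[i, j]) j else j - 1
    ps <- c(ps, state$p[i, jj])
  }
  mean(ps)
}

#' Evaluate the droplet collection path (splitting manifold and spiral)
#'
#' Steady single-phase solves: per-outlet mean speed and relative spread of
#' the splitting manifold, and the centreline speed coefficient of
#' variation of the spiral (ends trimmed).
#'
#' @param u_mean inlet mean velocity, m/s (default 0.005).
#' @param cell_size grid spacing, um (default 10; the collection channels
#'   are 100 um wide).
#' @param n_outlets manifold outlets (power of 2, default 4).
#' @param mu viscosity, Pa s.
#' @return list with `outlet_table` (per-outlet mean speed, m/s),
#'   `outlet_spread` (max relative deviation from the mean),
#'   `spiral_speed_cv`, and the two steady `states`.
#' @export
evaluate_collection_path <- function(u_mean = 0.005, cell_size = 10,
                                     n_outlets = 4, mu = 1.01e-2) {
  gm <- build_splitting_manifold(n_outlets = n_outlets)
  mask_m <- rasterize_geometry(gm, cell_size)
  st_m <- solve_steady_stokes(mask_m, u_mean, mu = mu)
  # per-outlet mean |v| over each outlet segment's faces
  h <- cell_size
  outlet_speed <- vapply(gm$outlets, function(seg) {
    j <- as.integer(round((seg[1, 2] - mask_m$origin[2]) / h)) + 1L
    xlo <- min(seg[, 1]); xhi <- max(seg[, 1])
    cc <- mask_cell_centers(mask_m)
    ii <- which(cc$x > xlo & cc$x < xhi)
    ii <- ii[mask_m$ytag[ii, j] == FACE_OUTLET]
    mean(abs(st_m$v[ii, j]))
  }, numeric(1))
  spread <- (max(outlet_speed) - min(outlet_speed)) / mean(outlet_speed)

  gs <- build_spiral_channel()
  mask_s <- rasterize_geometry(gs, cell_size)
  st_s <- solve_steady_stokes(mask_s, u_mean, mu = mu)
  cs <- sample_centerline(st_s, gs$params$centerline, trim = 0.1)
  cv <- stats::sd(cs$speed) / mean(cs$speed)

  list(outlet_table = data.frame(outlet = seq_along(outlet_speed),
                                 mean_speed = outlet_speed),
       outlet_spread = spread, spiral_speed_cv = cv,
       states = list(splitting = st_m, spiral = st_s))
}

#' Dispersed-phase mass balance of a droplet run
#'
#' Checks that the dispersed volume fed through the inlet equals the change
#' of in-channel dispersed volume plus the volume carried out by detached
#' droplets that left the domain.
#'
#' @param run a [run_simulation()] result.
#' @param mask the run's `domain_mask`.
#' @return list with `inflow`, `delta_inchannel`, `exited` (planar areas,
#'   um^2), `outflow` (integrated outlet dispersed flux, um^2),
#'   `relative_error` (inflow vs. in-channel change plus tracked detached
#'   droplets that left) and `relative_error_flux` (inflow vs. in-channel
#'   change plus the dispersed volume metered through the outlet).
#' @export
mass_balance <- function(run, mask) {
  ser <- run$series
  # trapezoidal integrals (m^2/s over s -> m^2 -> um^2)
  tt <- ser$t
  trap <- function(v) sum(diff(tt) * (head(v, -1) + tail(v, -1)) / 2) * 1e12
  inflow <- trap(ser$influx_d)
  outflow <- if ("outflux_d" %in% names(ser)) trap(ser$outflux_d) else NA_real_
  delta <- (ser$dispersed_area[nrow(ser)] - ser$dispersed_area[1]) * 1e12
  rec <- track_droplets(run$components, mask)
  exited <- 0
  if (nrow(rec) && "last_seen" %in% names(rec)) {
    gone <- rec$last_seen < max(tt) - 2 * diff(range(tt)) / nrow(ser)
    exited <- sum(rec$area[gone])
  }
  err <- abs(inflow - delta - exited) / max(inflow, 1e-12)
  err_flux <- abs(inflow - delta - outflow) / max(inflow, 1e-12)
  list(inflow = inflow, delta_inchannel = delta, exited = exited,
       outflow = outflow, relative_error = err,
       relative_error_flux = err_flux)
}
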