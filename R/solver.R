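## Time integration drivers around the compiled stepper.

run_cpp <- function(state, inflow, t_end, dt = -1, max_steps = .Machine$integer.max,
                    record_every = 100L, probe_cells = c(-1L, -1L),
                    do_momentum = TRUE, do_levelset = TRUE,
                    periodic_x = FALSE, cfl_adv = 0.25, p_tol = 1e-10) {
  mask <- state$mask
  run_twophase_cpp(
    fluid = as.integer(mask$fluid), xtag = as.integer(mask$xtag),
    ytag = as.integer(mask$ytag), nx = mask$nx, ny = mask$ny,
    h_m = mask$cell_size * 1e-6,
    pars = cpp_params(state$params, mask, inflow, p_tol),
    u0 = as.numeric(state$u), v0 = as.numeric(state$v),
    p0 = as.numeric(state$p), phi0 = as.numeric(state$phi),
    t0 = state$t, t_end = t_end, dt_fixed = dt,
    max_steps = as.integer(min(max_steps, .Machine$integer.max)),
    record_every = as.integer(record_every),
    probe_cells = as.integer(probe_cells),
    do_momentum = do_momentum, do_levelset = do_levelset,
    periodic_x = periodic_x, cfl_adv = cfl_adv)
}

as_state <- function(res, state) {
  mask <- state$mask
  nx <- mask$nx; ny <- mask$ny
  out <- state
  out$t <- res$t
  out$u <- matrix(res$u, nx + 1, ny)
  out$v <- matrix(res$v, nx, ny + 1)
  out$p <- matrix(res$p, nx, ny)
  out$phi <- matrix(res$phi, nx, ny)
  pr <- interpolate_properties(pmin(1, pmax(0, out$phi)), state$params)
  out$rho <- pr$rho
  out$mu <- pr$mu
  out
}

#' Run a two-phase droplet-generation simulation
#'
#' Advances the coupled incompressible Navier-Stokes / conservative
#' level-set system from `state` to time `t_end`. The time step is
#' CFL-adaptive and honours the explicit surface-tension stability bound
#' `dt <= 0.9 * sqrt(mean(rho) h^3 / (2 pi sigma))`. The run is
#' deterministic: no randomness is involved.
#'
#' @param state a [initialize_state()] flow state (possibly pre-filled with
#'   dispersed phase, see [prefill_dispersed()]).
#' @param inflow an [inflow_spec()].
#' @param t_end end time, s.
#' @param record_every record the diagnostic series and droplet components
#'   every this many steps (default 100).
#' @param probes optional `probe_pair` (see [probe_pair()]); their pressures
#'   enter the recorded series.
#' @param dt fixed time step, s; the default `-1` selects it adaptively.
#' @param max_steps hard cap on step count.
#' @param p_tol relative tolerance of the pressure Poisson solve
#'   (default 1e-10).
#' @param cfl_adv advective CFL number (default 0.25).
#' @return list with `state` (final `flow_state`), `series` (data frame:
#'   `t`, `dispersed_area` (m^2), `u_max`, `div_max`, probe pressures,
#'   `influx_d` (m^2/s)), `components` (per-record droplet component table
#'   in cell units), `steps`, `dt_last`.
#' @export
run_simulation <- function(state, inflow, t_end, record_every = 100L,
                           probes = NULL, dt = -1,
                           max_steps = .Machine$integer.max,
                           p_tol = 1e-10, cfl_adv = 0.25) {
  stopifnot(inherits(state, "flow_state"), inherits(inflow, "inflow_spec"))
  if (t_end <= state$t)
    return(list(state = state,
                series = data.frame(t = state$t,
                                    dispersed_area = sum(state$phi[state$mask$fluid]) *
                                      (state$mask$cell_size * 1e-6)^2,
                                    u_max = max(abs(state$u), abs(state$v)),
                                    div_max = 0, p_probe_c = NA_real_,
                                    p_probe_d = NA_real_, influx_d = 0,
                                    outflux_d = 0),
                components = NULL, steps = 0L, dt_last = dt))
  pc <- c(-1L, -1L)
  if (!is.null(probes)) pc <- probe_cell_index(state$mask, probes)
  res <- run_cpp(state, inflow, t_end, dt = dt, max_steps = max_steps,
                 record_every = record_every, probe_cells = pc,
                 p_tol = p_tol, cfl_adv = cfl_adv)
  if (isTRUE(res$nan_abort))
    stop(sprintf(paste0("numerical failure: non-finite fields at t = %.4g s ",
                        "(step %d, dt = %.3g); try a smaller CFL number or ",
                        "finer grid"), res$t, res$steps, res$dt_last))
  list(state = as_state(res, state), series = res$series,
       components = as.data.frame(res$components), steps = res$steps,
       dt_last = res$dt_last, divmax = res$divmax)
}

#' Advance only the momentum/pressure system by one (or a few) steps
#'
#' Single-phase / frozen-interface projection stepping: upwind advection,
#' implicit viscosity, surface-tension force from the current `phi`,
#' pressure projection. Used for steady-state relaxation and solver
#' verification; the level-set field is not transported.
#'
#' @inheritParams run_simulation
#' @param n_steps number of steps to take.
#' @return as [run_simulation()].
#' @export
advance_momentum <- function(state, inflow, dt = -1, n_steps = 1L,
                             p_tol = 1e-10, cfl_adv = 0.25) {
  res <- run_cpp(state, inflow, t_end = Inf, dt = dt, max_steps = n_steps,
                 record_every = max(1L, n_steps), do_levelset = FALSE,
                 p_tol = p_tol, cfl_adv = cfl_adv)
  list(state = as_state(res, state), series = res$series,
       divmax = res$divmax, steps = res$steps, dt_last = res$dt_last)
}

#' Transport the level-set field with a frozen velocity field
#'
#' Conservative level-set step: upwind advection in flux form plus the
#' reinitialization flux `gamma * (eps * grad(phi) - phi (1 - phi) nhat)`.
#'
#' @inheritParams run_simulation
#' @param n_steps number of steps.
#' @param periodic_x treat the x direction as periodic (used in transport
#'   verification on strips).
#' @return as [run_simulation()].
#' @export
transport_levelset <- function(state, inflow, dt, n_steps = 1L,
                               periodic_x = FALSE) {
  stopifnot(dt > 0)
  umax <- max(abs(state$u), abs(state$v), inflow$u_c, inflow$u_d)
  if (umax * dt > state$mask$cell_size * 1e-6)
    stop("time-step error: advective CFL violated in transport_levelset")
  res <- run_cpp(state, inflow, t_end = Inf, dt = dt, max_steps = n_steps,
                 record_every = max(1L, n_steps), do_momentum = FALSE,
                 periodic_x = periodic_x)
  list(state = as_state(res, state), series = res$series,
       components = as.data.frame(res$components), steps = res$steps)
}

#' Continuum-surface-force surface tension field
#'
#' Computes the balanced-force CSF field `F = sigma * kappa * grad(phi)` on
#' the staggered faces, with curvature `kappa = -div(grad(phi)/|grad(phi)|)`
#' at cell centres. Zero away from the interface.
#'
#' @param state a `flow_state` (its `phi`, mask and params are used).
#' @param sigma surface tension, N/m; defaults to the state's parameter.
#' @return list with `Fx` ((nx+1) x ny), `Fy` (nx x (ny+1)) in N/m^3 and
#'   `kappa` (nx x ny, 1/m).
#' @export
surface_tension_force <- function(state, sigma = state$params$sigma) {
  mask <- state$mask
  res <- csf_force_cpp(as.integer(mask$fluid), as.integer(mask$xtag),
                       as.integer(mask$ytag), mask$nx, mask$ny,
                       mask$cell_size * 1e-6, as.numeric(state$phi),
                       sigma, state$params$theta)
  list(Fx = matrix(res$Fx, mask$nx + 1, mask$ny),
       Fy = matrix(res$Fy, mask$nx, mask$ny + 1),
       kappa = matrix(res$kappa, mask$nx, mask$ny))
}

#' Apply the wall contact-angle condition to the level-set field
#'
#' Fills solid cells bordering the fluid with ghost values extrapolated so
#' that the interface meets the wall at the prescribed angle `theta`
#' (measured through the dispersed phase; `theta = pi/2` reduces to a
#' homogeneous Neumann condition). Fluid-cell values are untouched.
#'
#' @param state a `flow_state`.
#' @param theta contact angle, rad; defaults to the state's parameter.
#' @return the state with ghost `phi` values filled in solid border cells.
#' @export
apply_contact_angle <- function(state, theta = state$params$theta) {
  stopifnot(theta > 0, theta < pi)
  mask <- state$mask
  ph <- contact_ghosts_cpp(as.integer(mask$fluid), as.integer(mask$xtag),
                           as.integer(mask$ytag), mask$nx, mask$ny,
                           mask$cell_size * 1e-6, as.numeric(state$phi),
                           theta)
  state$phi <- matrix(ph, mask$nx, mask$ny)
  state
}

#' Pre-fill a region with dispersed phase
#'
#' Sets `phi = 1` in fluid cells whose centres fall inside the axis-aligned
#' rectangle `c(x0, y0, x1, y1)` (um). Typically used to pre-fill the
#' dispersed feed channel up to the junction so droplet production starts
#' without the long inlet-transit transient.
#'
#' @param state a `flow_state`.
#' @param rect numeric `c(x0, y0, x1, y1)`, um.
#' @return the modified state.
#' @export
prefill_dispersed <- function(state, rect) {
  stopifnot(length(rect) == 4)
  cc <- mask_cell_centers(state$mask)
  ix <- cc$x >= rect[1] & cc$x <= rect[3]
  iy <- cc$y >= rect[2] & cc$y <= rect[4]
  sel <- outer(ix, iy, "&") & state$mask$fluid
  state$phi[sel] <- 1
  pr <- interpolate_properties(state$phi, state$params)
  state$rho <- pr$rho; state$mu <- pr$mu
  state
}
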