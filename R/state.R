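#' Initial flow state on a rasterized domain
#'
#' The channel starts filled with continuous-phase fluid (`phi = 0`
#' everywhere), at rest (`u = v = 0`) and with zero gauge pressure.
#'
#' @param mask a `domain_mask` from [rasterize_geometry()].
#' @param params a [fluid_pair_params()] object.
#' @return an object of class `flow_state`: `t` (s), `u` ((nx+1) x ny, m/s),
#'   `v` (nx x (ny+1), m/s), `p` (nx x ny, Pa), `phi` (nx x ny, 0 =
#'   continuous phase, 1 = dispersed), derived `rho`/`mu` cell fields, and
#'   the `mask` and `params` used.
#' @export
initialize_state <- function(mask, params) {
  stopifnot(inherits(mask, "domain_mask"), inherits(params, "fluid_pair_params"))
  nx <- mask$nx; ny <- mask$ny
  phi <- matrix(0, nx, ny)
  pr <- interpolate_properties(phi, params)
  structure(list(t = 0,
                 u = matrix(0, nx + 1, ny),
                 v = matrix(0, nx, ny + 1),
                 p = matrix(0, nx, ny),
                 phi = phi, rho = pr$rho, mu = pr$mu,
                 mask = mask, params = params),
            class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  disp <- sum(x$phi[x$mask$fluid]) * x$mask$cell_size^2
  cat(sprintf("<flow_state> t = %.6g s on %s (%d x %d cells)\n",
              x$t, x$mask$geometry_name, x$mask$nx, x$mask$ny))
  cat(sprintf("  max |u| = %.4g m/s, dispersed area = %.4g um^2\n",
              max(abs(x$u), abs(x$v)), disp))
  invisible(x)
}

#' Interpolate fluid properties from the level-set field
#'
#' Linear blend between the continuous (`phi = 0`) and dispersed (`phi = 1`)
#' phase: `rho = rho_c + (rho_d - rho_c) * phi`, and likewise for `mu`, so
#' each pure phase recovers its own density and viscosity.
#'
#' @param phi level-set field (any numeric array), values in `[0, 1]`.
#' @param params a [fluid_pair_params()].
#' @param tol tolerance for out-of-range `phi` (default 1e-6).
#' @return list with `rho` and `mu`, same shape as `phi`.
#' @export
interpolate_properties <- function(phi, params, tol = 1e-6) {
  if (any(phi < -tol | phi > 1 + tol, na.rm = TRUE))
    stop("invalid state: phi outside [0, 1]")
  phi <- pmin(1, pmax(0, phi))
  list(rho = params$rho_c + (params$rho_d - params$rho_c) * phi,
       mu = params$mu_c + (params$mu_d - params$mu_c) * phi)
}

# resolve auto gamma / eps against a mask + inflow
resolve_ls_params <- function(params, mask, inflow) {
  # gamma = NULL: auto mode, the stepper tracks the running max |velocity|
  gamma <- params$gamma
  if (is.null(gamma)) gamma <- -1
  # half a cell, the conventional conservative level-set interface
  # thickness on a uniform mesh
  eps <- params$eps
  if (is.null(eps)) eps <- mask$cell_size * 1e-6 / 2
  list(gamma = gamma, eps = eps)
}

# parameter list handed to the compiled stepper
cpp_params <- function(params, mask, inflow, p_tol = 1e-10) {
  ls <- resolve_ls_params(params, mask, inflow)
  list(rho_c = params$rho_c, rho_d = params$rho_d,
       mu_c = params$mu_c, mu_d = params$mu_d,
       sigma = params$sigma, theta = params$theta,
       gamma = ls$gamma, eps = ls$eps,
       u_c = inflow$u_c, u_d = inflow$u_d, p_tol = p_tol)
}
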