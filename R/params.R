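#' Fluid-pair parameters for the two-phase solver
#'
#' Defaults are the study's simulation fluids: fluorinated oil
#' (HFE-7500 class) as the continuous phase and the aqueous reaction mix
#' (water) as the dispersed phase.
#'
#' @param rho_c continuous-phase density, kg/m^3 (default 1.164e3, oil).
#' @param rho_d dispersed-phase density, kg/m^3 (default 1e3, water).
#' @param mu_c continuous-phase dynamic viscosity, Pa s (default 1.12e-2).
#' @param mu_d dispersed-phase dynamic viscosity, Pa s (default 1.01e-2).
#' @param sigma surface tension coefficient, N/m (default 5e-3).
#' @param theta wall contact angle, rad, measured through the dispersed
#'   phase (default `3*pi/4`: oil-wetting walls, as needed for water-in-oil
#'   droplets in PDMS).
#' @param gamma level-set reinitialization velocity, m/s; `NULL` (default)
#'   means "use the maximum inlet mean velocity", set at run time.
#' @param eps level-set interface half-thickness, m; `NULL` (default) means
#'   "one grid cell", set at run time.
#' @return an object of class `fluid_pair_params`.
#' @export
fluid_pair_params <- function(rho_c = 1.164e3, rho_d = 1e3,
                              mu_c = 1.12e-2, mu_d = 1.01e-2,
                              sigma = 5e-3, theta = 3 * pi / 4,
                              gamma = NULL, eps = NULL) {
  if (rho_c <= 0 || rho_d <= 0) stop("densities must be positive")
  if (mu_c <= 0 || mu_d <= 0) stop("viscosities must be positive")
  if (sigma < 0) stop("sigma must be non-negative")
  if (theta <= 0 || theta >= pi) stop("theta must lie in (0, pi)")
  if (!is.null(eps) && eps <= 0) stop("eps must be positive")
  structure(list(rho_c = rho_c, rho_d = rho_d, mu_c = mu_c, mu_d = mu_d,
                 sigma = sigma, theta = theta, gamma = gamma, eps = eps),
            class = "fluid_pair_params")
}

#' @export
print.fluid_pair_params <- function(x, ...) {
  cat("<fluid_pair_params>\n")
  cat(sprintf("  rho_c = %g kg/m^3, rho_d = %g kg/m^3\n", x$rho_c, x$rho_d))
  cat(sprintf("  mu_c  = %g Pa s,   mu_d  = %g Pa s\n", x$mu_c, x$mu_d))
  cat(sprintf("  sigma = %g N/m, theta = %g rad\n", x$sigma, x$theta))
  cat(sprintf("  gamma = %s, eps = %s\n",
              if (is.null(x$gamma)) "auto (max inlet velocity)" else x$gamma,
              if (is.null(x$eps)) "auto (1 cell)" else x$eps))
  invisible(x)
}

#' Inlet flow specification
#'
#' @param u_d dispersed-phase mean inlet velocity, m/s (default 0.005).
#' @param ratio flow-rate ratio `u_c / u_d` (used when `u_c` missing).
#' @param u_c continuous-phase mean inlet velocity, m/s; default
#'   `ratio * u_d`.
#' @return an object of class `inflow_spec` with `u_c`, `u_d`, `ratio`.
#' @export
inflow_spec <- function(u_d = 0.005, ratio = 1, u_c = ratio * u_d) {
  if (u_d < 0 || u_c < 0) stop("inlet velocities must be non-negative")
  structure(list(u_c = u_c, u_d = u_d,
                 ratio = if (u_d > 0) u_c / u_d else NA_real_),
            class = "inflow_spec")
}

#' @export
print.inflow_spec <- function(x, ...) {
  cat(sprintf("<inflow_spec> u_c = %g m/s, u_d = %g m/s (ratio %.3g)\n",
              x$u_c, x$u_d, x$ratio))
  invisible(x)
}
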