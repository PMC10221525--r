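## Configuration files (YAML), results tables (CSV with a units row) and
## field snapshots (legacy VTK rectilinear grid, ASCII).

config_defaults <- function() {
  list(
    geometry = list(type = "flow_focusing", Wc = 50, Wd = 50, h = 0,
                    depth = 50),
    fluids = list(rho_c = 1.164e3, rho_d = 1e3, mu_c = 1.12e-2,
                  mu_d = 1.01e-2, sigma = 5e-3, theta = 3 * pi / 4,
                  gamma = NULL, eps = NULL),
    inflow = list(u_d = 0.005, ratio = 5),
    grid = list(cell_size = 5, p_tol = 1e-10, cfl = 0.25),
    output = list(dir = "runs", snapshot_interval = 0),
    assay = list(v_droplet = 5e-4, n_droplets = 2e4,
                 concentrations = c(10, 1e2, 1e3, 2e3, 1e4), seed = 1)
  )
}

#' Load (and validate) a run configuration
#'
#' YAML file with optional blocks `geometry`, `fluids`, `inflow`, `grid`,
#' `output`, `assay`; missing keys take the study defaults (oil/water
#' fluid pair, 50 um channels, `u_d` = 0.005 m/s). Unknown keys are
#' rejected, as are non-physical values.
#'
#' @param path YAML file path; missing/empty file gives the all-defaults
#'   configuration.
#' @return a validated `run_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config error: file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  bad <- setdiff(names(user), names(cfg))
  if (length(bad))
    stop("config error: unknown block(s): ", paste(bad, collapse = ", "))
  for (blk in names(user)) {
    badk <- setdiff(names(user[[blk]]), names(cfg[[blk]]))
    if (length(badk))
      stop("config error: unknown key(s) in `", blk, "`: ",
           paste(badk, collapse = ", "))
    cfg[[blk]][names(user[[blk]])] <- user[[blk]]
  }
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  f <- cfg$fluids
  for (k in c("rho_c", "rho_d", "mu_c", "mu_d"))
    if (f[[k]] <= 0) stop("config error: `fluids.", k, "` must be positive")
  if (f$sigma < 0) stop("config error: `fluids.sigma` must be >= 0")
  if (f$theta <= 0 || f$theta >= pi)
    stop("config error: `fluids.theta` must lie in (0, pi)")
  if (cfg$grid$cell_size <= 0)
    stop("config error: `grid.cell_size` must be positive")
  if (cfg$inflow$u_d < 0 || cfg$inflow$ratio < 0)
    stop("config error: inflow velocities must be non-negative")
  g <- cfg$geometry
  if (!g$type %in% c("flow_focusing", "t_junction", "linear", "serpentine",
                     "spiral", "splitting"))
    stop("config error: unknown `geometry.type`: ", g$type)
  invisible(cfg)
}

#' Save a run configuration
#' @param cfg a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Build the geometry named in a configuration
#' @param cfg a `run_config`.
#' @return a `channel_geometry`.
#' @export
config_geometry <- function(cfg) {
  g <- cfg$geometry
  switch(g$type,
    flow_focusing = build_flow_focusing(Wc = g$Wc, Wd = g$Wd,
                                        depth = g$depth),
    t_junction = build_t_junction(Wc = g$Wc, Wd = g$Wd, h = g$h,
                                  depth = g$depth),
    linear = build_linear_channel(W = g$Wc, depth = g$depth),
    serpentine = build_serpentine_channel(W = g$Wc, depth = g$depth),
    spiral = build_spiral_channel(depth = g$depth),
    splitting = build_splitting_manifold(depth = g$depth))
}

#' Write a results table as CSV with a units header row
#'
#' First line: column names; second line: a `# units:` comment naming the
#' unit of each column; then the data.
#'
#' @param rows a data frame.
#' @param path output path.
#' @param units optional character vector of units (one per column).
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path, units = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(rows), collapse = ","), con)
  if (!is.null(units)) {
    stopifnot(length(units) == ncol(rows))
    writeLines(paste0("# units: ", paste(units, collapse = ",")), con)
  }
  if (nrow(rows))
    utils::write.table(rows, con, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#' @param path CSV path.
#' @return data frame (the units row, if present, is attached as
#'   `attr(, "units")`).
#' @export
read_results_table <- function(path) {
  lines <- readLines(path)
  units <- NULL
  if (length(lines) >= 2 && startsWith(lines[2], "# units:")) {
    units <- strsplit(sub("^# units: ", "", lines[2]), ",")[[1]]
    lines <- lines[-2]
  }
  out <- utils::read.csv(text = paste(lines, collapse = "\n"))
  attr(out, "units") <- units
  out
}

#' Write a flow-state snapshot as a VTK rectilinear grid file
#'
#' Legacy ASCII VTK: cell-centred `phi`, `p`, `speed` and the fluid mask as
#' point data on the cell-centre lattice, readable by standard viewers.
#'
#' @param state a `flow_state`.
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_field_snapshot <- function(state, path) {
  mask <- state$mask
  cc <- mask_cell_centers(mask)
  nx <- mask$nx; ny <- mask$ny
  sp <- cell_speed(state)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  num <- function(v) paste(format(v, digits = 9, trim = TRUE),
                           collapse = " ")
  wl("# vtk DataFile Version 3.0")
  wl("droplamp snapshot t=%.9g s (lengths um, velocity m/s, pressure Pa)",
     state$t)
  wl("ASCII")
  wl("DATASET RECTILINEAR_GRID")
  wl("DIMENSIONS %d %d 1", nx, ny)
  wl("X_COORDINATES %d float", nx); writeLines(num(cc$x), con)
  wl("Y_COORDINATES %d float", ny); writeLines(num(cc$y), con)
  wl("Z_COORDINATES 1 float"); writeLines("0", con)
  wl("POINT_DATA %d", nx * ny)
  scalar <- function(name, m) {
    wl("SCALARS %s float 1", name)
    wl("LOOKUP_TABLE default")
    writeLines(num(as.numeric(m)), con)   # column-major = x fastest
  }
  scalar("phi", state$phi)
  scalar("pressure", state$p)
  scalar("speed", sp)
  scalar("fluid", state$mask$fluid * 1)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration, seeds, package version and timing needed to
#' re-run an experiment identically.
#'
#' @param dir run directory (created if needed).
#' @param cfg the `run_config` used.
#' @param seeds named list/vector of seeds (may be empty for the
#'   deterministic solver campaigns).
#' @param extra optional named list appended verbatim.
#' @return manifest path, invisibly.
#' @export
write_manifest <- function(dir, cfg, seeds = list(), extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- list(package = "droplamp",
              version = as.character(utils::packageVersion("droplamp")),
              date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seeds = seeds, config = unclass(cfg))
  man <- c(man, extra)
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(man, path)
  invisible(path)
}
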