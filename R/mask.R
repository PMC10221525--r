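## Rasterization of channel geometries onto a uniform grid.
## Scalar fields live at cell centres; velocities at cell faces (staggered).
## Face tag codes shared with the compiled solver:
##   0 = not a boundary face, 1 = wall, 2 = continuous inlet,
##   3 = dispersed inlet, 4 = outlet.

FACE_NONE <- 0L; FACE_WALL <- 1L; FACE_INLET_C <- 2L
FACE_INLET_D <- 3L; FACE_OUTLET <- 4L

# even-odd point-in-polygon, vectorized over points
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Rasterize a channel geometry onto a uniform staggered grid
#'
#' Produces the boolean fluid mask and tagged boundary faces the solver
#' consumes. Cells are fluid when their centre falls inside the (union of)
#' geometry polygons; boundary faces inherit `wall`, `inlet_c` / `inlet_d`,
#' or `outlet` tags from the geometry's inlet/outlet segments.
#'
#' @param g a `channel_geometry`.
#' @param cell_size grid spacing, um; must not exceed 1/8 of the narrowest
#'   channel width so profiles are resolved.
#' @return an object of class `domain_mask`: list with `cell_size`, `origin`,
#'   `nx`, `ny`, `fluid` (nx x ny logical matrix), `xtag` ((nx+1) x ny
#'   integer), `ytag` (nx x (ny+1) integer), `depth`, `geometry_name`,
#'   and `inlet_roles` (role per inlet tag).
#' @export
rasterize_geometry <- function(g, cell_size) {
  stopifnot(inherits(g, "channel_geometry"), cell_size > 0)
  widths <- unlist(g$params[names(g$params) %in% c("Wc", "Wd", "W",
                                                   "downstream_width")])
  if (length(widths) && cell_size > min(widths) / 8 + 1e-9)
    stop("cell_size must be <= min(channel width)/8 to resolve the channels")
  bb <- geometry_bbox(g)
  h <- cell_size
  x0 <- floor(bb[1] / h) * h
  y0 <- floor(bb[2] / h) * h
  nx <- as.integer(ceiling((bb[3] - x0) / h - 1e-9))
  ny <- as.integer(ceiling((bb[4] - y0) / h - 1e-9))
  xc <- x0 + (seq_len(nx) - 0.5) * h
  yc <- y0 + (seq_len(ny) - 0.5) * h
  px <- rep(xc, times = ny)
  py <- rep(yc, each = nx)
  fluid <- rep(FALSE, nx * ny)
  for (poly in g$polygons)
    fluid <- fluid | points_in_polygon(px, py, poly)
  fluid <- matrix(fluid, nx, ny)
  if (!any(fluid)) stop("rasterization error: no fluid cells")

  # boundary faces: exactly one adjacent cell is fluid
  fl <- fluid
  padx <- rbind(FALSE, fl); padX <- rbind(fl, FALSE)
  xbound <- xor(padx, padX)                       # (nx+1) x ny
  pady <- cbind(FALSE, fl); padY <- cbind(fl, FALSE)
  ybound <- xor(pady, padY)                       # nx x (ny+1)

  xtag <- matrix(FACE_NONE, nx + 1, ny); xtag[xbound] <- FACE_WALL
  ytag <- matrix(FACE_NONE, nx, ny + 1); ytag[ybound] <- FACE_WALL

  tag_faces <- function(seg, code) {
    vertical <- abs(seg[1, 1] - seg[2, 1]) < 1e-9
    if (vertical) {
      i <- as.integer(round((seg[1, 1] - x0) / h)) + 1L
      i <- max(1L, min(nx + 1L, i))
      ylo <- min(seg[, 2]); yhi <- max(seg[, 2])
      jj <- which(yc > ylo - h / 2 + 1e-9 & yc < yhi + h / 2 - 1e-9)
      jj <- jj[xbound[i, jj]]
      if (!length(jj)) stop("rasterization error: inlet/outlet segment ",
                            "maps to no boundary faces")
      xtag[i, jj] <<- code
    } else {
      j <- as.integer(round((seg[1, 2] - y0) / h)) + 1L
      j <- max(1L, min(ny + 1L, j))
      xlo <- min(seg[, 1]); xhi <- max(seg[, 1])
      ii <- which(xc > xlo - h / 2 + 1e-9 & xc < xhi + h / 2 - 1e-9)
      ii <- ii[ybound[ii, j]]
      if (!length(ii)) stop("rasterization error: inlet/outlet segment ",
                            "maps to no boundary faces")
      ytag[ii, j] <<- code
    }
  }
  inlet_roles <- character(0)
  for (k in seq_along(g$inlets)) {
    role <- g$inlets[[k]]$role
    code <- if (role == "dispersed") FACE_INLET_D else FACE_INLET_C
    tag_faces(g$inlets[[k]]$segment, code)
    inlet_roles <- c(inlet_roles, role)
  }
  for (seg in g$outlets) tag_faces(seg, FACE_OUTLET)

  m <- structure(list(cell_size = h, origin = c(x0, y0), nx = nx, ny = ny,
                      fluid = fluid, xtag = xtag, ytag = ytag,
                      depth = g$depth, geometry_name = g$name,
                      inlet_roles = inlet_roles),
                 class = "domain_mask")
  reach <- cells_reaching_outlet(m)
  if (!all(fluid == reach))
    stop("rasterization error: fluid region disconnected from the outlet ",
         "at this cell size")
  m
}

#' @export
print.domain_mask <- function(x, ...) {
  cat(sprintf("<domain_mask> %s: %d x %d cells @ %.3g um, %d fluid cells\n",
              x$geometry_name, x$nx, x$ny, x$cell_size, sum(x$fluid)))
  invisible(x)
}

# flood fill (iterative dilation) from outlet faces through 4-connectivity
cells_reaching_outlet <- function(mask) {
  fl <- mask$fluid
  nx <- mask$nx; ny <- mask$ny
  seed <- matrix(FALSE, nx, ny)
  ox <- which(mask$xtag == FACE_OUTLET, arr.ind = TRUE)
  if (nrow(ox)) for (r in seq_len(nrow(ox))) {
    i <- ox[r, 1]; j <- ox[r, 2]
    if (i <= nx && fl[i, j]) seed[i, j] <- TRUE
    if (i > 1 && fl[i - 1, j]) seed[i - 1, j] <- TRUE
  }
  oy <- which(mask$ytag == FACE_OUTLET, arr.ind = TRUE)
  if (nrow(oy)) for (r in seq_len(nrow(oy))) {
    i <- oy[r, 1]; j <- oy[r, 2]
    if (j <= ny && fl[i, j]) seed[i, j] <- TRUE
    if (j > 1 && fl[i, j - 1]) seed[i, j - 1] <- TRUE
  }
  repeat {
    grown <- seed
    grown[-1, ] <- grown[-1, ] | seed[-nx, ]
    grown[-nx, ] <- grown[-nx, ] | seed[-1, ]
    grown[, -1] <- grown[, -1] | seed[, -ny]
    grown[, -ny] <- grown[, -ny] | seed[, -1]
    grown <- grown & fl
    if (identical(grown, seed)) break
    seed <- grown
  }
  seed
}

#' Rasterized fluid area
#' @param mask a `domain_mask`.
#' @return fluid area in um^2 (cell count times cell area).
#' @export
mask_area <- function(mask) sum(mask$fluid) * mask$cell_size^2

# cell-centre coordinates (vectors)
mask_cell_centers <- function(mask) {
  list(x = mask$origin[1] + (seq_len(mask$nx) - 0.5) * mask$cell_size,
       y = mask$origin[2] + (seq_len(mask$ny) - 0.5) * mask$cell_size)
}
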