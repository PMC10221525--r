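## Direct steady single-phase solver (Stokes regime).
##
## At the study's channel scales Re = rho*u*W/mu ~ 1e-2, so the steady
## velocity/pressure fields of the buffer and collection structures are the
## solution of the Stokes system: -mu lap(u) + grad(p) = 0, div(u) = 0,
## with parabolic inlet Dirichlet velocity, no-slip walls and p = 0 at the
## outlet. Assembled sparse and solved directly (Matrix LU).

# face classification mirroring the compiled solver:
# 0 inactive, 1 interior, 2 Dirichlet (wall/inlet), 3 outlet
classify_faces_r <- function(mask, u_c, u_d = u_c) {
  nx <- mask$nx; ny <- mask$ny
  fl <- mask$fluid
  padL <- rbind(FALSE, fl); padR <- rbind(fl, FALSE)    # (nx+1) x ny
  ukind <- matrix(0L, nx + 1, ny)
  ukind[padL & padR] <- 1L
  bnd <- xor(padL, padR)
  ukind[bnd] <- 2L
  ukind[bnd & mask$xtag == FACE_OUTLET] <- 3L
  padB <- cbind(FALSE, fl); padT <- cbind(fl, FALSE)
  vkind <- matrix(0L, nx, ny + 1)
  vkind[padB & padT] <- 1L
  bndv <- xor(padB, padT)
  vkind[bndv] <- 2L
  vkind[bndv & mask$ytag == FACE_OUTLET] <- 3L

  ubc <- matrix(0, nx + 1, ny)
  vbc <- matrix(0, nx, ny + 1)
  assign_profile <- function(idx, mean_v, sgn) {
    # idx: ordered positions along the run
    n <- length(idx)
    s <- ((seq_len(n) - 0.5) / n) * 2 - 1
    raw <- 1 - s^2
    sgn * mean_v * raw * n / sum(raw)
  }
  for (i in seq_len(nx + 1)) {
    tags <- mask$xtag[i, ]
    for (tg in c(FACE_INLET_C, FACE_INLET_D)) {
      jj <- which(tags == tg & ukind[i, ] == 2L)
      if (!length(jj)) next
      runs <- split(jj, cumsum(c(1, diff(jj) != 1)))
      for (r in runs) {
        right_fluid <- i <= nx && fl[i, r[1]]
        ubc[i, r] <- assign_profile(r, if (tg == FACE_INLET_C) u_c else u_d,
                                    if (right_fluid) 1 else -1)
      }
    }
  }
  for (j in seq_len(ny + 1)) {
    tags <- mask$ytag[, j]
    for (tg in c(FACE_INLET_C, FACE_INLET_D)) {
      ii <- which(tags == tg & vkind[, j] == 2L)
      if (!length(ii)) next
      runs <- split(ii, cumsum(c(1, diff(ii) != 1)))
      for (r in runs) {
        top_fluid <- j <= ny && fl[r[1], j]
        vbc[r, j] <- assign_profile(r, if (tg == FACE_INLET_C) u_c else u_d,
                                    if (top_fluid) 1 else -1)
      }
    }
  }
  list(ukind = ukind, vkind = vkind, ubc = ubc, vbc = vbc)
}

#' Steady single-phase flow through a channel structure
#'
#' Solves the steady Stokes system on a rasterized geometry with a
#' parabolic inlet profile of the given mean velocity, no-slip walls and
#' zero outlet reference pressure, by direct sparse solve.
#'
#' @param mask a `domain_mask`.
#' @param u_mean inlet mean velocity, m/s (applied to every inlet).
#' @param mu dynamic viscosity, Pa s (default the aqueous-phase 1.01e-2).
#' @param params optional [fluid_pair_params()] stored on the returned state.
#' @return a `flow_state` at `t = Inf` holding the steady `u`, `v`, `p`.
#' @export
solve_steady_stokes <- function(mask, u_mean, mu = 1.01e-2,
                                params = fluid_pair_params()) {
  stopifnot(inherits(mask, "domain_mask"), u_mean >= 0, mu > 0)
  nx <- mask$nx; ny <- mask$ny
  h <- mask$cell_size * 1e-6
  fc <- classify_faces_r(mask, u_mean, u_mean)

  # unknown numbering
  uidx <- matrix(0L, nx + 1, ny)
  sel_u <- fc$ukind == 1L | fc$ukind == 3L
  uidx[sel_u] <- seq_len(sum(sel_u))
  nu <- sum(sel_u)
  vidx <- matrix(0L, nx, ny + 1)
  sel_v <- fc$vkind == 1L | fc$vkind == 3L
  vidx[sel_v] <- seq_len(sum(sel_v))
  nv <- sum(sel_v)
  pidx <- matrix(0L, nx, ny)
  pidx[mask$fluid] <- seq_len(sum(mask$fluid))
  np <- sum(mask$fluid)
  off_v <- nu; off_p <- nu + nv
  n <- nu + nv + np

  cap <- 12L * n
  ti <- integer(cap); tj <- integer(cap); tv <- numeric(cap)
  nt <- 0L
  rhs <- numeric(n)
  push <- function(r, c, val) {
    nt <<- nt + 1L
    if (nt > length(ti)) {
      ti <<- c(ti, integer(cap)); tj <<- c(tj, integer(cap))
      tv <<- c(tv, numeric(cap))
    }
    ti[nt] <<- r; tj[nt] <<- c; tv[nt] <<- val
  }
  h2 <- h * h

  ## x-momentum rows
  for (j in seq_len(ny)) for (i in seq_len(nx + 1)) {
    if (!sel_u[i, j]) next
    row <- uidx[i, j]
    if (fc$ukind[i, j] == 3L) {
      # outlet: zero normal gradient of u, p = 0 at the face
      left_fluid <- i > 1 && mask$fluid[i - 1, j]
      diagc <- 3 * mu / h2
      push(row, row, diagc)
      # tangential neighbours
      for (jj in c(j - 1, j + 1)) {
        if (jj >= 1 && jj <= ny && sel_u[i, jj])
          push(row, uidx[i, jj], -mu / h2)
        else if (jj >= 1 && jj <= ny && fc$ukind[i, jj] == 2L)
          rhs[row] <- rhs[row] + mu / h2 * fc$ubc[i, jj]
        else push(row, row, mu / h2)  # wall ghost: +2mu/h2 total
      }
      # one interior normal neighbour
      ii <- if (left_fluid) i - 1 else i + 1
      if (sel_u[ii, j]) push(row, uidx[ii, j], -mu / h2)
      # pressure: dp/dn with p = 0 at the face
      pc <- if (left_fluid) pidx[i - 1, j] else pidx[i, j]
      sgn <- if (left_fluid) 1 else -1
      push(row, off_p + pc, -sgn * 2 / h)
      next
    }
    push(row, row, 4 * mu / h2)
    nbs <- list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
    for (nb in nbs) {
      ii <- nb[1]; jj <- nb[2]
      inb <- ii >= 1 && ii <= nx + 1 && jj >= 1 && jj <= ny
      k <- if (inb) fc$ukind[ii, jj] else 0L
      if (k == 1L || k == 3L) push(row, uidx[ii, jj], -mu / h2)
      else if (k == 2L) rhs[row] <- rhs[row] + mu / h2 * fc$ubc[ii, jj]
      else push(row, row, mu / h2)      # wall ghost u = -u
    }
    push(row, off_p + pidx[i, j], 1 / h)
    push(row, off_p + pidx[i - 1, j], -1 / h)
  }

  ## y-momentum rows
  for (j in seq_len(ny + 1)) for (i in seq_len(nx)) {
    if (!sel_v[i, j]) next
    row <- off_v + vidx[i, j]
    if (fc$vkind[i, j] == 3L) {
      bottom_fluid <- j > 1 && mask$fluid[i, j - 1]
      push(row, row, 3 * mu / h2)
      for (ii in c(i - 1, i + 1)) {
        if (ii >= 1 && ii <= nx && sel_v[ii, j])
          push(row, off_v + vidx[ii, j], -mu / h2)
        else if (ii >= 1 && ii <= nx && fc$vkind[ii, j] == 2L)
          rhs[row] <- rhs[row] + mu / h2 * fc$vbc[ii, j]
        else push(row, row, mu / h2)
      }
      jj <- if (bottom_fluid) j - 1 else j + 1
      if (sel_v[i, jj]) push(row, off_v + vidx[i, jj], -mu / h2)
      pc <- if (bottom_fluid) pidx[i, j - 1] else pidx[i, j]
      sgn <- if (bottom_fluid) 1 else -1
      push(row, off_p + pc, -sgn * 2 / h)
      next
    }
    push(row, row, 4 * mu / h2)
    nbs <- list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))
    for (nb in nbs) {
      ii <- nb[1]; jj <- nb[2]
      inb <- ii >= 1 && ii <= nx && jj >= 1 && jj <= ny + 1
      k <- if (inb) fc$vkind[ii, jj] else 0L
      if (k == 1L || k == 3L) push(row, off_v + vidx[ii, jj], -mu / h2)
      else if (k == 2L) rhs[row] <- rhs[row] + mu / h2 * fc$vbc[ii, jj]
      else push(row, row, mu / h2)
    }
    push(row, off_p + pidx[i, j], 1 / h)
    push(row, off_p + pidx[i, j - 1], -1 / h)
  }

  ## continuity rows
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    if (!mask$fluid[i, j]) next
    row <- off_p + pidx[i, j]
    addu <- function(ii, jj, sgn) {
      k <- fc$ukind[ii, jj]
      if (k == 1L || k == 3L) push(row, uidx[ii, jj], sgn / h)
      else if (k == 2L) rhs[row] <<- rhs[row] - sgn / h * fc$ubc[ii, jj]
    }
    addv <- function(ii, jj, sgn) {
      k <- fc$vkind[ii, jj]
      if (k == 1L || k == 3L) push(row, off_v + vidx[ii, jj], sgn / h)
      else if (k == 2L) rhs[row] <<- rhs[row] - sgn / h * fc$vbc[ii, jj]
    }
    addu(i + 1, j, 1); addu(i, j, -1)
    addv(i, j + 1, 1); addv(i, j, -1)
  }

  A <- Matrix::sparseMatrix(i = ti[seq_len(nt)], j = tj[seq_len(nt)],
                            x = tv[seq_len(nt)], dims = c(n, n))
  sol <- Matrix::solve(A, rhs)
  sol <- as.numeric(sol)

  u <- matrix(0, nx + 1, ny); u[sel_u] <- sol[uidx[sel_u]]
  u[fc$ukind == 2L] <- fc$ubc[fc$ukind == 2L]
  v <- matrix(0, nx, ny + 1); v[sel_v] <- sol[off_v + vidx[sel_v]]
  v[fc$vkind == 2L] <- fc$vbc[fc$vkind == 2L]
  p <- matrix(0, nx, ny); p[mask$fluid] <- sol[off_p + pidx[mask$fluid]]

  phi <- matrix(0, nx, ny)
  pr <- interpolate_properties(phi, params)
  structure(list(t = Inf, u = u, v = v, p = p, phi = phi,
                 rho = pr$rho, mu = pr$mu, mask = mask, params = params),
            class = "flow_state")
}

#' Net volumetric flux through inlet and outlet boundaries
#'
#' @param state a `flow_state`.
#' @return list with `inlet` and `outlet` 2D fluxes (m^2/s; multiply by the
#'   channel depth for a volumetric rate).
#' @export
boundary_fluxes <- function(state) {
  mask <- state$mask
  h <- mask$cell_size * 1e-6
  inlet <- 0; outlet <- 0
  xin <- mask$xtag == FACE_INLET_C | mask$xtag == FACE_INLET_D
  inlet <- inlet + sum(abs(state$u[xin])) * h
  yin <- mask$ytag == FACE_INLET_C | mask$ytag == FACE_INLET_D
  inlet <- inlet + sum(abs(state$v[yin])) * h
  outlet <- outlet + sum(abs(state$u[mask$xtag == FACE_OUTLET])) * h +
    sum(abs(state$v[mask$ytag == FACE_OUTLET])) * h
  list(inlet = inlet, outlet = outlet)
}
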