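#' Channel geometry and activator patch
#'
#' Cell-centred uniform grid on a rectangular channel; `x` runs downstream
#' in `[0, length_x]`, `y` across the channel in `[0, height_y]`. The
#' TF-bearing activator occupies `[activator_start,
#' activator_start + activator_length]` on the `y = 0` wall.
#'
#' @param length_x Channel length, um (default 6000).
#' @param height_y Channel height, um (default 1000).
#' @param activator_start Upstream edge of the activator patch, um.
#' @param activator_length Activator length, um (default 1000).
#' @param dx Grid spacing, um (must divide all extents).
#' @return An object of class `domain_spec`.
#' @export
domain_spec <- function(length_x = 6000, height_y = 1000,
                        activator_start = 1000, activator_length = 1000,
                        dx = 25) {
  div <- function(a) abs(a / dx - round(a / dx)) < 1e-9
  if (!all(vapply(c(length_x, height_y, activator_start, activator_length),
                  div, logical(1))))
    stop("dx must divide length_x, height_y and the activator interval",
         call. = FALSE)
  if (activator_start < 0 ||
      activator_start + activator_length > length_x)
    stop("activator interval must lie within [0, length_x]", call. = FALSE)
  d <- list(length_x = length_x, height_y = height_y,
            activator_start = activator_start,
            activator_length = activator_length, dx = dx,
            nx = as.integer(round(length_x / dx)),
            ny = as.integer(round(height_y / dx)))
  class(d) <- "domain_spec"
  d
}

# 1-based x-cell indices of the activator row (j = 0 wall row)
activator_cells <- function(domain) {
  i0 <- as.integer(round(domain$activator_start / domain$dx))
  n  <- as.integer(round(domain$activator_length / domain$dx))
  if (n == 0L) integer(0) else (i0 + 1L):(i0 + n)
}

#' Pressure drive for a target clean-channel wall shear rate
#'
#' For plane Poiseuille flow in a channel of height `h`, the wall shear
#' rate and mean velocity are linked by `u_mean = gamma_w * h / 6`; the
#' constant pressure gradient producing that profile (viscosity `mu`) is
#' `G = 2 * mu * gamma_w / h`. The drive is then held fixed as the clot
#' grows (constant-pressure perfusion).
#'
#' @param gamma_w Target clean-channel wall shear rate, 1/s.
#' @param domain A [domain_spec()].
#' @param mu Dynamic viscosity (arbitrary consistent units; cancels for
#'   the clean channel).
#' @return A `flow_drive` object with elements `grad` (pressure gradient),
#'   `pressure_drop` (over the channel length), `u_mean` (clean-channel
#'   mean velocity, um/s) and `gamma_w`.
#' @export
shear_to_drive <- function(gamma_w, domain, mu = 1) {
  if (!is.finite(gamma_w) || gamma_w < 0)
    stop("gamma_w must be >= 0", call. = FALSE)
  h <- domain$height_y
  G <- 2 * mu * gamma_w / h
  structure(list(grad = G, pressure_drop = G * domain$length_x,
                 u_mean = gamma_w * h / 6, gamma_w = gamma_w, mu = mu),
            class = "flow_drive")
}

#' Steady flow around the current clot
#'
#' Solves the steady incompressible Stokes equations on a MAC staggered
#' grid with no-slip walls, a fixed pressure drop between inlet and outlet,
#' and Brinkman-type velocity penalization inside zero-permeability (gel)
#' cells. The creeping-flow limit is appropriate at these scales
#' (Re << 1); the solve is deterministic for fixed inputs.
#'
#' @param domain A [domain_spec()].
#' @param permeability Integer/logical vector or matrix over cells (length
#'   `nx * ny`, x-fastest): 1 = open, 0 = gel. `NULL` means all open.
#' @param drive A `flow_drive` from [shear_to_drive()].
#' @param penal_factor Dimensionless penalization strength (the drag
#'   coefficient in gel cells is `penal_factor * mu / dx^2`).
#' @return A `flow_state` with face velocities `u` (`(nx+1) x ny`) and `v`
#'   (`nx x (ny+1)`), cell pressures `p`, the drive, and an `occluded`
#'   flag set when the channel carries essentially no flux.
#' @export
solve_flow <- function(domain, permeability = NULL, drive,
                       penal_factor = 1e6) {
  nx <- domain$nx; ny <- domain$ny; dx <- domain$dx
  mu <- drive$mu %||% 1
  gel <- if (is.null(permeability)) integer(nx * ny) else {
    g <- as.integer(!(as.vector(permeability) > 0))
    stopifnot(length(g) == nx * ny)
    g
  }
  if (drive$grad == 0) {
    return(structure(list(
      u = matrix(0, nx + 1L, ny), v = matrix(0, nx, ny + 1L),
      p = matrix(0, nx, ny), drive = drive, occluded = FALSE,
      domain = domain), class = "flow_state"))
  }
  Nu <- (nx + 1L) * ny; Nv <- nx * (ny + 1L); Np <- nx * ny
  iu <- function(i, j) i + (nx + 1L) * j + 1L           # i 0..nx, j 0..ny-1
  iv <- function(i, j) Nu + i + nx * j + 1L             # i 0..nx-1, j 0..ny
  ip <- function(i, j) Nu + Nv + i + nx * j + 1L
  gl <- function(i, j) gel[i + nx * j + 1L]             # cell gel lookup
  kap <- penal_factor * mu / dx^2
  p_in <- drive$grad * (nx + 1L) * dx; p_out <- 0

  ti <- integer(0); tj <- integer(0); tv <- numeric(0)
  b <- numeric(Nu + Nv + Np)
  add <- function(rows, cols, vals) {
    ti <<- c(ti, rows); tj <<- c(tj, cols); tv <<- c(tv, vals)
  }
  c1 <- mu / dx^2
  # --- u momentum ---
  for (j in 0:(ny - 1L)) {
    i <- 0:nx
    row <- iu(i, j)
    cl <- ifelse(i > 0, i - 1L, 0L)      # left cell (clamped at inlet)
    cr <- ifelse(i < nx, i, nx - 1L)     # right cell (clamped at outlet)
    blocked <- (gl(cl, j) == 1L) | (gl(cr, j) == 1L)
    cen <- numeric(nx + 1L)
    # d2/dx2
    cen <- cen - ifelse(i == 0L | i == nx, 1, 2) * c1
    has_w <- i > 0L;  add(row[has_w], iu(i[has_w] - 1L, j), rep(c1, sum(has_w)))
    has_e <- i < nx;  add(row[has_e], iu(i[has_e] + 1L, j), rep(c1, sum(has_e)))
    # d2/dy2 with no-slip ghost at walls
    cen <- cen - ifelse(j == 0L | j == ny - 1L, 3, 2) * c1
    if (j > 0L)      add(row, iu(i, j - 1L), rep(c1, nx + 1L))
    if (j < ny - 1L) add(row, iu(i, j + 1L), rep(c1, nx + 1L))
    cen <- cen - ifelse(blocked, kap, 0)
    add(row, row, cen)
    # pressure gradient
    hasE <- i < nx
    add(row[hasE], ip(i[hasE], j), rep(-1 / dx, sum(hasE)))
    hasW <- i > 0L
    add(row[hasW], ip(i[hasW] - 1L, j), rep(1 / dx, sum(hasW)))
    b[iu(0L, j)] <- -p_in / dx
    b[iu(nx, j)] <- p_out / dx
  }
  # --- v momentum ---
  for (j in 0:ny) {
    i <- 0:(nx - 1L)
    row <- iv(i, j)
    if (j == 0L || j == ny) {            # wall faces: v = 0
      add(row, row, rep(1, nx))
      next
    }
    blocked <- (gl(i, j - 1L) == 1L) | (gl(i, j) == 1L)
    cen <- numeric(nx)
    cen <- cen - ifelse(i == 0L | i == nx - 1L, 1, 2) * c1
    has_w <- i > 0L;       add(row[has_w], iv(i[has_w] - 1L, j), rep(c1, sum(has_w)))
    has_e <- i < nx - 1L;  add(row[has_e], iv(i[has_e] + 1L, j), rep(c1, sum(has_e)))
    cen <- cen - 2 * c1
    add(row, iv(i, j - 1L), rep(c1, nx))
    add(row, iv(i, j + 1L), rep(c1, nx))
    cen <- cen - ifelse(blocked, kap, 0)
    add(row, row, cen)
    add(row, ip(i, j), rep(-1 / dx, nx))
    add(row, ip(i, j - 1L), rep(1 / dx, nx))
  }
  # --- continuity ---
  for (j in 0:(ny - 1L)) {
    i <- 0:(nx - 1L)
    row <- ip(i, j)
    add(row, iu(i + 1L, j), rep(1 / dx, nx))
    add(row, iu(i, j), rep(-1 / dx, nx))
    add(row, iv(i, j + 1L), rep(1 / dx, nx))
    add(row, iv(i, j), rep(-1 / dx, nx))
  }
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tv,
                            dims = c(Nu + Nv + Np, Nu + Nv + Np))
  x <- as.numeric(Matrix::solve(A, b))
  u <- matrix(x[seq_len(Nu)], nx + 1L, ny)
  v <- matrix(x[Nu + seq_len(Nv)], nx, ny + 1L)
  p <- matrix(x[Nu + Nv + seq_len(Np)], nx, ny)
  q_in <- sum(u[1L, ]) * dx             # inflow flux per unit depth
  q_clean <- drive$u_mean * domain$height_y
  occluded <- is.finite(q_clean) && q_clean > 0 && abs(q_in) < 1e-6 * q_clean
  structure(list(u = u, v = v, p = p, drive = drive,
                 occluded = occluded, domain = domain),
            class = "flow_state")
}

#' A no-flow state
#' @param domain A [domain_spec()].
#' @return A `flow_state` with zero velocity everywhere.
#' @export
zero_flow <- function(domain) {
  solve_flow(domain, NULL, shear_to_drive(0, domain))
}

#' Volumetric flux through each x-cross-section
#' @param flow A `flow_state`.
#' @return Numeric vector (length `nx + 1`) of fluxes per unit depth,
#'   um^2/s.
#' @export
section_flux <- function(flow) {
  rowSums(flow$u) * flow$domain$dx
}

#' Wall shear rate measured from a flow state
#'
#' One-sided velocity gradient at the `y = 0` wall (quadratic
#' extrapolation through the two wall-nearest `u` rows, exact for a
#' parabolic profile), averaged over the clean region upstream of the
#' activator.
#'
#' @param flow A `flow_state`.
#' @param domain A [domain_spec()] (defaults to the one in `flow`).
#' @return Wall shear rate, 1/s.
#' @export
measure_wall_shear <- function(flow, domain = flow$domain) {
  dx <- domain$dx
  i_max <- max(1L, as.integer(floor(domain$activator_start / dx)))
  faces <- seq_len(i_max)                 # u-face columns upstream
  u0 <- flow$u[faces, 1L]
  if (domain$ny < 2L) return(mean(u0) / (dx / 2))
  u1 <- flow$u[faces, 2L]
  mean((9 * u0 - u1) / (3 * dx))
}
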