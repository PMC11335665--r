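#' Solver configuration
#'
#' Settings for the steady incompressible solver. The discretization is a
#' staggered (MAC) finite-volume scheme; the coupled velocity-pressure
#' system is solved by sparse direct factorization; the nonlinear
#' convective terms are handled by damped Newton iteration (default) or
#' lagged Picard iteration, and `scheme = "stokes_direct"` drops them
#' entirely (creeping flow, one linear solve). Convection can be pure
#' first-order upwind or upwind with a deferred central correction
#' (second-order at convergence).
#'
#' @param scheme `"coupled_newton"` (default: damped Newton with line
#'   search, started from the creeping-flow solution),
#'   `"coupled_picard"` (lagged convection with under-relaxation) or
#'   `"stokes_direct"` (drop convection, one linear solve).
#' @param convection `"upwind"` or `"central_deferred"`.
#' @param tolerance Relative change in velocity between Picard iterates at
#'   which the iteration is declared converged.
#' @param max_iterations Maximum number of Picard iterations (each one is a
#'   full implicit solve).
#' @param under_relaxation Velocity under-relaxation factor in (0, 1].
#' @param pseudo_time_step Pseudo-time step in s used as inertial damping
#'   by the non-convergence fallback (`"auto"` = two cell transit times
#'   `2 dx / U`).
#' @return An object of class `solver_config`.
#' @examples
#' solver_config(tolerance = 1e-8)
#' @export
solver_config <- function(scheme = c("coupled_newton", "coupled_picard",
                                     "stokes_direct"),
                          convection = c("upwind", "central_deferred"),
                          tolerance = 1e-6,
                          max_iterations = 100,
                          under_relaxation = 0.7,
                          pseudo_time_step = "auto") {
  scheme <- match.arg(scheme)
  convection <- match.arg(convection)
  check_positive(tolerance = tolerance, max_iterations = max_iterations)
  if (under_relaxation <= 0 || under_relaxation > 1) {
    abort("`under_relaxation` must lie in (0, 1].",
          class = "eddyrisk_domain_error")
  }
  structure(
    list(scheme = scheme, convection = convection, tolerance = tolerance,
         max_iterations = max_iterations,
         under_relaxation = under_relaxation,
         pseudo_time_step = pseudo_time_step),
    class = "solver_config"
  )
}

#' Boundary conditions for a solver run
#'
#' Uniform normal velocity on the inlet opening, fixed gauge pressure with
#' zero-gradient velocity on the outlet opening, no-slip everywhere else.
#' `lid_velocity` imposes a tangential velocity on the top wall (used by
#' closed-cavity verification cases).
#'
#' @param inlet_velocity Mean inlet velocity in m/s (>= 0).
#' @param outlet_gauge_pressure Outlet gauge pressure in Pa (default 0).
#' @param fluid A [fluid_properties()] object.
#' @param lid_velocity Tangential velocity of the top wall in m/s.
#' @return An object of class `boundary_conditions`.
#' @examples
#' boundary_conditions(5.8946e-4)
#' @export
boundary_conditions <- function(inlet_velocity,
                                outlet_gauge_pressure = 0,
                                fluid = fluid_properties(),
                                lid_velocity = 0) {
  if (!is.numeric(inlet_velocity) || inlet_velocity < 0) {
    abort("`inlet_velocity` must be non-negative.",
          class = "eddyrisk_domain_error")
  }
  structure(
    list(inlet_velocity = inlet_velocity,
         outlet_gauge_pressure = outlet_gauge_pressure,
         fluid = fluid, lid_velocity = lid_velocity),
    class = "boundary_conditions"
  )
}

# Neighbour type codes used by the assembly
NB_UNK <- 1L   # unknown degree of freedom
NB_DIR <- 2L   # known face value (Dirichlet)
NB_MIR <- 3L   # mirror ghost across a no-slip wall (value 2*wall - self)
NB_ZG  <- 4L   # zero-gradient ghost (outflow)

# Classify the neighbours of unknown faces in one direction.
# fm: face index matrix (0 = known), fv: known face values, ii/jj: unknown
# face positions, ti/tj: neighbour positions (may exceed matrix extent).
classify_dir <- function(fm, fv, ii, jj, ti, tj, mirror_mask, wall_vel,
                         zg_mask = rep(FALSE, length(ii))) {
  n <- length(ii)
  type <- integer(n); nbid <- integer(n); nblin <- integer(n)
  val <- numeric(n); w <- numeric(n)
  quad <- logical(n); nb2id <- integer(n); nb2val <- numeric(n)
  inr <- ti >= 1 & ti <= nrow(fm) & tj >= 1 & tj <= ncol(fm)
  type[zg_mask] <- NB_ZG
  mm <- mirror_mask & !zg_mask
  type[mm] <- NB_MIR
  w[mm] <- wall_vel[mm]
  # second interior point (opposite the ghost) for the quadratic no-slip
  # ghost; fall back to the linear mirror when it does not exist
  if (any(mm)) {
    oi <- ii[mm] - (ti[mm] - ii[mm])
    oj <- jj[mm] - (tj[mm] - jj[mm])
    oin <- oi >= 1 & oi <= nrow(fm) & oj >= 1 & oj <= ncol(fm)
    olin <- (pmax(oj, 1L) - 1L) * nrow(fm) + pmax(oi, 1L)
    oid <- ifelse(oin, fm[olin], 0L)
    quad[mm] <- oin
    nb2id[mm] <- ifelse(oin, oid, 0L)
    nb2val[mm] <- ifelse(oin & oid == 0L, fv[olin], 0)
  }
  rest <- !zg_mask & !mm
  stopifnot(all(inr[rest]))
  lin <- (tj[rest] - 1L) * nrow(fm) + ti[rest]
  id <- fm[lin]
  type[rest] <- ifelse(id > 0L, NB_UNK, NB_DIR)
  nbid[rest] <- id
  nblin[rest] <- lin
  val[rest] <- ifelse(id > 0L, 0, fv[lin])
  list(type = type, nbid = nbid, nblin = nblin, val = val, wall = w,
       quad = quad, nb2id = nb2id, nb2val = nb2val)
}

# Precompute unknown numbering, neighbour topology and the fixed part
# (diffusion + pressure gradient + continuity) of the coupled system.
solver_structure <- function(grid, bc) {
  nx <- grid$nx; ny <- grid$ny; dx <- grid$dx; dy <- grid$dy
  fluid <- grid$fluid
  mu <- bc$fluid$dynamic_viscosity
  uin <- bc$inlet_velocity

  # unknown numbering -------------------------------------------------------
  iu <- matrix(0L, nx + 1, ny)
  for (i in 2:nx) {
    iu[i, ] <- ifelse(fluid[i - 1, ] & fluid[i, ], 1L, 0L)
  }
  if (length(grid$outlet_rows)) {
    iu[nx + 1, grid$outlet_rows] <- ifelse(fluid[nx, grid$outlet_rows], 1L, 0L)
  }
  nU <- sum(iu > 0); iu[iu > 0] <- seq_len(nU)

  ub <- matrix(0, nx + 1, ny)
  if (length(grid$inlet_rows)) {
    ub[1, grid$inlet_rows] <- ifelse(fluid[1, grid$inlet_rows], uin, 0)
  }

  iv <- matrix(0L, nx, ny + 1)
  for (j in 2:ny) {
    iv[, j] <- ifelse(fluid[, j - 1] & fluid[, j], 1L, 0L)
  }
  nV <- sum(iv > 0); iv[iv > 0] <- nU + seq_len(nV)
  vb <- matrix(0, nx, ny + 1)

  ip <- matrix(0L, nx, ny)
  nP <- sum(fluid); ip[fluid] <- nU + nV + seq_len(nP)
  ndof <- nU + nV + nP

  solid_at <- function(ci, cj) {
    # TRUE where the cell is outside the domain or solid
    out <- ci < 1 | ci > nx | cj < 1 | cj > ny
    res <- rep(TRUE, length(ci))
    lin <- (pmax(cj, 1L) - 1L) * nx + pmax(ci, 1L)
    res[!out] <- !fluid[lin[!out]]
    res
  }

  # u-face neighbour topology ----------------------------------------------
  ku <- which(iu > 0)
  u_ii <- ((ku - 1L) %% (nx + 1L)) + 1L
  u_jj <- ((ku - 1L) %/% (nx + 1L)) + 1L
  u_row <- iu[ku]
  u_lin <- ku
  is_outlet_face <- u_ii == nx + 1L

  uW <- classify_dir(iu, ub, u_ii, u_jj, u_ii - 1L, u_jj,
                     mirror_mask = rep(FALSE, nU), wall_vel = numeric(nU))
  uE <- classify_dir(iu, ub, u_ii, u_jj, u_ii + 1L, u_jj,
                     mirror_mask = rep(FALSE, nU), wall_vel = numeric(nU),
                     zg_mask = is_outlet_face)
  # north: wall if at domain top or all cells above solid
  above_solid <- solid_at(u_ii - 1L, u_jj + 1L) & solid_at(u_ii, u_jj + 1L)
  n_mirror <- u_jj == ny | above_solid
  n_wall <- ifelse(u_jj == ny, bc$lid_velocity, 0)
  uN <- classify_dir(iu, ub, u_ii, u_jj, u_ii, u_jj + 1L,
                     mirror_mask = n_mirror, wall_vel = n_wall)
  below_solid <- solid_at(u_ii - 1L, u_jj - 1L) & solid_at(u_ii, u_jj - 1L)
  s_mirror <- u_jj == 1L | below_solid
  uS <- classify_dir(iu, ub, u_ii, u_jj, u_ii, u_jj - 1L,
                     mirror_mask = s_mirror, wall_vel = numeric(nU))

  # v-face neighbour topology ----------------------------------------------
  kv <- which(iv > 0)
  v_ii <- ((kv - 1L) %% nx) + 1L
  v_jj <- ((kv - 1L) %/% nx) + 1L
  v_row <- iv[kv]
  v_lin <- kv

  vS <- classify_dir(iv, vb, v_ii, v_jj, v_ii, v_jj - 1L,
                     mirror_mask = rep(FALSE, nV), wall_vel = numeric(nV))
  vN <- classify_dir(iv, vb, v_ii, v_jj, v_ii, v_jj + 1L,
                     mirror_mask = rep(FALSE, nV), wall_vel = numeric(nV))
  west_solid <- solid_at(v_ii - 1L, v_jj - 1L) & solid_at(v_ii - 1L, v_jj)
  w_mirror <- v_ii == 1L | west_solid
  vW <- classify_dir(iv, vb, v_ii, v_jj, v_ii - 1L, v_jj,
                     mirror_mask = w_mirror, wall_vel = numeric(nV))
  outlet_mask <- logical(ny + 1)
  if (length(grid$outlet_rows) > 1) {
    # v-face row j is open to the outlet when cell rows j-1 and j both are
    both <- intersect(grid$outlet_rows + 1L, grid$outlet_rows)
    outlet_mask[both] <- TRUE
  }
  east_solid <- solid_at(v_ii + 1L, v_jj - 1L) & solid_at(v_ii + 1L, v_jj)
  e_zg <- v_ii == nx & outlet_mask[v_jj]
  e_mirror <- (v_ii == nx & !e_zg) | east_solid
  vE <- classify_dir(iv, vb, v_ii, v_jj, v_ii + 1L, v_jj,
                     mirror_mask = e_mirror, wall_vel = numeric(nV),
                     zg_mask = e_zg)

  # fixed triplets: diffusion ----------------------------------------------
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  rhs_fix <- numeric(ndof)
  add_diffusion <- function(rows, nb, coef) {
    # contribution -mu * (u_nb - u)/h^2 per direction; mirror ghosts use
    # the quadratic no-slip fit g = (8 w + u_2 - 6 u)/3 through the wall
    # point and the two nearest interior points (second-order), falling
    # back to the linear mirror g = 2 w - u where u_2 does not exist
    mir_q <- nb$type == NB_MIR & nb$quad
    mir_l <- nb$type == NB_MIR & !nb$quad
    dxv <- numeric(length(rows))
    dxv[nb$type == NB_UNK] <- coef
    dxv[nb$type == NB_DIR] <- coef
    dxv[mir_l] <- 2 * coef
    dxv[mir_q] <- 3 * coef
    trip_i <<- c(trip_i, rows); trip_j <<- c(trip_j, rows)
    trip_x <<- c(trip_x, dxv)
    unk <- nb$type == NB_UNK
    trip_i <<- c(trip_i, rows[unk]); trip_j <<- c(trip_j, nb$nbid[unk])
    trip_x <<- c(trip_x, rep(-coef, sum(unk)))
    dir <- nb$type == NB_DIR
    rhs_fix[rows[dir]] <<- rhs_fix[rows[dir]] + coef * nb$val[dir]
    rhs_fix[rows[mir_l]] <<- rhs_fix[rows[mir_l]] +
      2 * coef * nb$wall[mir_l]
    rhs_fix[rows[mir_q]] <<- rhs_fix[rows[mir_q]] +
      (8 / 3) * coef * nb$wall[mir_q]
    q_unk <- mir_q & nb$nb2id > 0L
    trip_i <<- c(trip_i, rows[q_unk]); trip_j <<- c(trip_j, nb$nb2id[q_unk])
    trip_x <<- c(trip_x, rep(-coef / 3, sum(q_unk)))
    q_dir <- mir_q & nb$nb2id == 0L
    rhs_fix[rows[q_dir]] <<- rhs_fix[rows[q_dir]] +
      (coef / 3) * nb$nb2val[q_dir]
  }
  add_diffusion(u_row, uW, mu / dx^2)
  add_diffusion(u_row, uE, mu / dx^2)
  add_diffusion(u_row, uS, mu / dy^2)
  add_diffusion(u_row, uN, mu / dy^2)
  add_diffusion(v_row, vW, mu / dx^2)
  add_diffusion(v_row, vE, mu / dx^2)
  add_diffusion(v_row, vS, mu / dy^2)
  add_diffusion(v_row, vN, mu / dy^2)

  # pressure gradient in momentum rows --------------------------------------
  interior_u <- !is_outlet_face
  pw <- ip[cbind(u_ii[interior_u] - 1L, u_jj[interior_u])]
  pe <- ip[cbind(pmin(u_ii[interior_u], nx), u_jj[interior_u])]
  stopifnot(all(pw > 0), all(pe > 0))
  trip_i <- c(trip_i, u_row[interior_u], u_row[interior_u])
  trip_j <- c(trip_j, pe, pw)
  trip_x <- c(trip_x, rep(1 / dx, sum(interior_u)),
              rep(-1 / dx, sum(interior_u)))
  if (any(is_outlet_face)) {
    po <- ip[cbind(rep(nx, sum(is_outlet_face)), u_jj[is_outlet_face])]
    trip_i <- c(trip_i, u_row[is_outlet_face])
    trip_j <- c(trip_j, po)
    trip_x <- c(trip_x, rep(-2 / dx, sum(is_outlet_face)))
    rhs_fix[u_row[is_outlet_face]] <-
      rhs_fix[u_row[is_outlet_face]] - 2 * bc$outlet_gauge_pressure / dx
  }
  ps <- ip[cbind(v_ii, v_jj - 1L)]
  pn <- ip[cbind(v_ii, pmin(v_jj, ny))]
  stopifnot(all(ps > 0), all(pn > 0))
  trip_i <- c(trip_i, v_row, v_row)
  trip_j <- c(trip_j, pn, ps)
  trip_x <- c(trip_x, rep(1 / dy, nV), rep(-1 / dy, nV))

  # continuity rows ----------------------------------------------------------
  kp <- which(fluid)
  c_ii <- ((kp - 1L) %% nx) + 1L
  c_jj <- ((kp - 1L) %/% nx) + 1L
  c_row <- ip[kp]
  add_cont <- function(fm, fv, ti, tj, coef) {
    lin <- (tj - 1L) * nrow(fm) + ti
    id <- fm[lin]
    unk <- id > 0L
    trip_i <<- c(trip_i, c_row[unk]); trip_j <<- c(trip_j, id[unk])
    trip_x <<- c(trip_x, rep(coef, sum(unk)))
    rhs_fix[c_row[!unk]] <<- rhs_fix[c_row[!unk]] - coef * fv[lin[!unk]]
  }
  add_cont(iu, ub, c_ii + 1L, c_jj, 1 / dx)
  add_cont(iu, ub, c_ii, c_jj, -1 / dx)
  add_cont(iv, vb, c_ii, c_jj + 1L, 1 / dy)
  add_cont(iv, vb, c_ii, c_jj, -1 / dy)

  pinned <- FALSE
  if (length(grid$outlet_rows) == 0 || sum(iu[nx + 1, ] > 0) == 0) {
    # closed domain: continuity rows are dependent; pin one pressure dof
    pin_row <- c_row[1]
    drop <- trip_i == pin_row
    trip_i <- trip_i[!drop]; trip_j <- trip_j[!drop]; trip_x <- trip_x[!drop]
    rhs_fix[pin_row] <- 0
    trip_i <- c(trip_i, pin_row); trip_j <- c(trip_j, pin_row)
    trip_x <- c(trip_x, 1)
    pinned <- TRUE
  }

  list(
    nx = nx, ny = ny, dx = dx, dy = dy, ndof = ndof,
    nU = nU, nV = nV, nP = nP,
    iu = iu, iv = iv, ip = ip, ub = ub, vb = vb,
    u_row = u_row, u_ii = u_ii, u_jj = u_jj, u_lin = u_lin,
    v_row = v_row, v_ii = v_ii, v_jj = v_jj, v_lin = v_lin,
    uW = uW, uE = uE, uS = uS, uN = uN,
    vW = vW, vE = vE, vS = vS, vN = vN,
    trip_fix = list(i = trip_i, j = trip_j, x = trip_x),
    rhs_fix = rhs_fix, pinned = pinned, pin_row = if (pinned) c_row[1] else NA
  )
}

# neighbour values of a face field at the previous iterate, ghosts resolved
nb_values <- function(nb, field_full, self_old) {
  out <- numeric(length(nb$type))
  k <- nb$type == NB_UNK | nb$type == NB_DIR
  out[k] <- field_full[nb$nblin[k]]
  m <- nb$type == NB_MIR
  out[m] <- 2 * nb$wall[m] - self_old[m]
  z <- nb$type == NB_ZG
  out[z] <- self_old[z]
  out
}

# upwind convection triplets + rhs for one momentum family
conv_terms <- function(rows, adv, h, rho, nb_up_pos, nb_up_neg) {
  # rho*|a|/h * (u - u_up); upwind neighbour switches with sign(adv)
  n <- length(rows)
  c0 <- rho * abs(adv) / h
  pick <- function(field) ifelse(adv >= 0, nb_up_pos[[field]],
                                 nb_up_neg[[field]])
  type <- pick("type"); nbid <- pick("nbid")
  val <- pick("val"); wall <- pick("wall")
  ti <- rows; tj <- rows
  tx <- ifelse(type == NB_MIR, 2 * c0, ifelse(type == NB_ZG, 0, c0))
  unk <- type == NB_UNK & c0 > 0
  rhs <- numeric(0); rhs_rows <- integer(0)
  dir <- type == NB_DIR
  mir <- type == NB_MIR
  list(
    ti = c(ti, rows[unk]),
    tj = c(tj, nbid[unk]),
    tx = c(tx, -c0[unk]),
    rhs_rows = c(rows[dir], rows[mir]),
    rhs_vals = c(c0[dir] * val[dir], 2 * c0[mir] * wall[mir])
  )
}

# explicit convection value at the old iterate (for deferred correction
# and residual reporting); scheme: "upwind" or "central"
conv_explicit <- function(st, u_full, v_full, rho, scheme) {
  u_self <- u_full[st$u_lin]
  v_self <- v_full[st$v_lin]
  ua_u <- u_self
  va_u <- v_at_u(st, v_full)
  ua_v <- u_at_v(st, u_full)
  va_v <- v_self
  uWv <- nb_values(st$uW, u_full, u_self); uEv <- nb_values(st$uE, u_full, u_self)
  uSv <- nb_values(st$uS, u_full, u_self); uNv <- nb_values(st$uN, u_full, u_self)
  vWv <- nb_values(st$vW, v_full, v_self); vEv <- nb_values(st$vE, v_full, v_self)
  vSv <- nb_values(st$vS, v_full, v_self); vNv <- nb_values(st$vN, v_full, v_self)
  if (scheme == "upwind") {
    cu <- rho * (ifelse(ua_u >= 0, ua_u * (u_self - uWv),
                        ua_u * (uEv - u_self)) / st$dx +
                 ifelse(va_u >= 0, va_u * (u_self - uSv),
                        va_u * (uNv - u_self)) / st$dy)
    cv <- rho * (ifelse(ua_v >= 0, ua_v * (v_self - vWv),
                        ua_v * (vEv - v_self)) / st$dx +
                 ifelse(va_v >= 0, va_v * (v_self - vSv),
                        va_v * (vNv - v_self)) / st$dy)
  } else {
    cu <- rho * (ua_u * (uEv - uWv) / (2 * st$dx) +
                 va_u * (uNv - uSv) / (2 * st$dy))
    cv <- rho * (ua_v * (vEv - vWv) / (2 * st$dx) +
                 va_v * (vNv - vSv) / (2 * st$dy))
  }
  list(u = cu, v = cv)
}

# advecting v at u faces / u at v faces (averages of available neighbours)
v_at_u <- function(st, v_full) {
  nx <- st$nx
  ciL <- pmax(st$u_ii - 1L, 1L)
  ciR <- pmin(st$u_ii, nx)
  0.25 * (v_full[cbind(ciL, st$u_jj)] + v_full[cbind(ciL, st$u_jj + 1L)] +
          v_full[cbind(ciR, st$u_jj)] + v_full[cbind(ciR, st$u_jj + 1L)])
}
u_at_v <- function(st, u_full) {
  0.25 * (u_full[cbind(st$v_ii, st$v_jj - 1L)] +
          u_full[cbind(st$v_ii + 1L, st$v_jj - 1L)] +
          u_full[cbind(st$v_ii, st$v_jj)] +
          u_full[cbind(st$v_ii + 1L, st$v_jj)])
}

# assemble the coupled system at a given state; A x = rhs with lagged
# (Picard) upwind convection, optional deferred central correction and
# optional pseudo-time inertial damping
assemble_system <- function(st, bc, cfg, u_full, v_full, with_conv,
                            dt = Inf) {
  rho <- bc$fluid$density
  ti <- st$trip_fix$i; tj <- st$trip_fix$j; tx <- st$trip_fix$x
  rhs <- st$rhs_fix
  if (with_conv) {
    add <- function(ct) {
      ti <<- c(ti, ct$ti); tj <<- c(tj, ct$tj); tx <<- c(tx, ct$tx)
      rhs[ct$rhs_rows] <<- rhs[ct$rhs_rows] + ct$rhs_vals
    }
    add(conv_terms(st$u_row, u_full[st$u_lin], st$dx, rho, st$uW, st$uE))
    add(conv_terms(st$u_row, v_at_u(st, v_full), st$dy, rho, st$uS, st$uN))
    add(conv_terms(st$v_row, u_at_v(st, u_full), st$dx, rho, st$vW, st$vE))
    add(conv_terms(st$v_row, v_full[st$v_lin], st$dy, rho, st$vS, st$vN))
    if (cfg$convection == "central_deferred") {
      up <- conv_explicit(st, u_full, v_full, rho, "upwind")
      ce <- conv_explicit(st, u_full, v_full, rho, "central")
      rhs[st$u_row] <- rhs[st$u_row] + (up$u - ce$u)
      rhs[st$v_row] <- rhs[st$v_row] + (up$v - ce$v)
    }
  }
  if (is.finite(dt)) {
    ti <- c(ti, st$u_row, st$v_row)
    tj <- c(tj, st$u_row, st$v_row)
    tx <- c(tx, rep(rho / dt, st$nU + st$nV))
    rhs[st$u_row] <- rhs[st$u_row] + rho / dt * u_full[st$u_lin]
    rhs[st$v_row] <- rhs[st$v_row] + rho / dt * v_full[st$v_lin]
  }
  list(A = Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                                dims = c(st$ndof, st$ndof)),
       rhs = rhs)
}

state_vector <- function(st, u_full, v_full, p_vec) {
  x <- numeric(st$ndof)
  x[st$u_row] <- u_full[st$u_lin]
  x[st$v_row] <- v_full[st$v_lin]
  x[st$nU + st$nV + seq_len(st$nP)] <- p_vec
  x
}

fields_from_x <- function(st, x) {
  u <- st$ub; u[st$u_lin] <- x[st$u_row]
  v <- st$vb; v[st$v_lin] <- x[st$v_row]
  list(u = u, v = v, p = x[st$nU + st$nV + seq_len(st$nP)])
}

# solve one lagged-convection step and return new full fields
picard_step <- function(st, bc, cfg, u_full, v_full, p_vec, with_conv,
                        dt = Inf) {
  sys <- assemble_system(st, bc, cfg, u_full, v_full, with_conv, dt)
  x <- as.numeric(Matrix::solve(sys$A, sys$rhs))
  fields_from_x(st, x)
}

# advector-derivative triplets that turn the lagged matrix into the full
# Newton Jacobian of the (upwind) momentum residual
newton_extra <- function(st, bc, u_full, v_full) {
  rho <- bc$fluid$density
  u_self <- u_full[st$u_lin]
  v_self <- v_full[st$v_lin]
  uWv <- nb_values(st$uW, u_full, u_self)
  uEv <- nb_values(st$uE, u_full, u_self)
  uSv <- nb_values(st$uS, u_full, u_self)
  uNv <- nb_values(st$uN, u_full, u_self)
  vWv <- nb_values(st$vW, v_full, v_self)
  vEv <- nb_values(st$vE, v_full, v_self)
  vSv <- nb_values(st$vS, v_full, v_self)
  vNv <- nb_values(st$vN, v_full, v_self)
  va_u <- v_at_u(st, v_full)
  ua_v <- u_at_v(st, u_full)
  # d(conv)/d(advector): (phi - phi_W)/h when advecting downstream,
  # (phi_E - phi)/h when advecting upstream (upwind switch)
  du_x <- ifelse(u_self >= 0, u_self - uWv, uEv - u_self) / st$dx
  du_y <- ifelse(va_u >= 0, u_self - uSv, uNv - u_self) / st$dy
  dv_x <- ifelse(ua_v >= 0, v_self - vWv, vEv - v_self) / st$dx
  dv_y <- ifelse(v_self >= 0, v_self - vSv, vNv - v_self) / st$dy
  ti <- c(st$u_row, st$v_row)
  tj <- c(st$u_row, st$v_row)
  tx <- rho * c(du_x, dv_y)
  # u-momentum couples to the 4 v faces averaged into its advector
  nx <- st$nx
  ciL <- pmax(st$u_ii - 1L, 1L)
  ciR <- pmin(st$u_ii, nx)
  for (idx in list(cbind(ciL, st$u_jj), cbind(ciL, st$u_jj + 1L),
                   cbind(ciR, st$u_jj), cbind(ciR, st$u_jj + 1L))) {
    id <- st$iv[idx]
    k <- id > 0L
    ti <- c(ti, st$u_row[k]); tj <- c(tj, id[k])
    tx <- c(tx, 0.25 * rho * du_y[k])
  }
  for (idx in list(cbind(st$v_ii, st$v_jj - 1L),
                   cbind(st$v_ii + 1L, st$v_jj - 1L),
                   cbind(st$v_ii, st$v_jj),
                   cbind(st$v_ii + 1L, st$v_jj))) {
    id <- st$iu[idx]
    k <- id > 0L
    ti <- c(ti, st$v_row[k]); tj <- c(tj, id[k])
    tx <- c(tx, 0.25 * rho * dv_x[k])
  }
  Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(st$ndof, st$ndof))
}

#' Solve steady incompressible flow on a flagged grid
#'
#' Solves the steady laminar Navier-Stokes equations on the staggered grid
#' with a uniform-velocity inlet, fixed-gauge-pressure outlet and no-slip
#' walls and baffles. The momentum and continuity equations are solved
#' fully coupled by a sparse direct method. The default strategy starts
#' from the creeping-flow solution and applies damped Newton iteration
#' (analytic Jacobian including the advector derivatives, line search on
#' the residual norm). If Newton stalls -- which can happen when the
#' steady state is only weakly attracting, e.g. an oscillatory inlet jet
#' -- the solver falls back to pseudo-time-damped iteration and returns
#' the average of the trailing iterates, reporting `converged = FALSE`
#' and `time_averaged = TRUE`.
#'
#' @param grid A validated, connected [rasterize_layout()] grid.
#' @param bc A [boundary_conditions()] object.
#' @param cfg A [solver_config()] object.
#' @return An object of class `flow_field`: staggered velocity matrices
#'   `u` ((nx+1) x ny) and `v` (nx x (ny+1)), cell pressures `p`
#'   (nx x ny, NA in solids), the `grid`, `bc` and a `report` list
#'   (`iterations`, `converged`, `rel_change`, `momentum_residual`,
#'   `continuity_residual`, `mass_imbalance`, `time_averaged`).
#' @examples
#' g <- rasterize_layout(standard_layout("A"), nx = 48, ny = 16)
#' f <- solve_stokes(g, boundary_conditions(1e-4))
#' glance(f)
#' @export
solve_steady_flow <- function(grid, bc, cfg = solver_config()) {
  stopifnot(inherits(grid, "flagged_grid"),
            inherits(bc, "boundary_conditions"))
  if (length(grid$inlet_rows) && length(grid$outlet_rows)) {
    rep_geo <- validate_geometry(grid)
    if (rep_geo$reachable_fraction < 1) {
      abort("Fluid domain contains isolated pockets; refine the geometry.",
            class = "eddyrisk_geometry_error")
    }
  }
  st <- solver_structure(grid, bc)
  uref <- max(abs(bc$inlet_velocity), abs(bc$lid_velocity))
  if (uref == 0) {
    return(new_flow_field(grid, bc, cfg, st$ub * 0, st$vb * 0,
                          rep(0, st$nP), st,
                          list(iterations = 0L, converged = TRUE,
                               rel_change = 0, time_averaged = FALSE)))
  }
  # creeping-flow solve: the final answer for stokes_direct, the initial
  # Newton iterate otherwise
  sol <- picard_step(st, bc, cfg, st$ub, st$vb, NULL, with_conv = FALSE)
  if (cfg$scheme == "stokes_direct") {
    return(new_flow_field(grid, bc, cfg, sol$u, sol$v, sol$p, st,
                          list(iterations = 1L, converged = TRUE,
                               rel_change = 0, time_averaged = FALSE)))
  }
  if (cfg$scheme == "coupled_picard") {
    out <- iterate_picard(st, bc, cfg, sol, uref,
                          n_iter = cfg$max_iterations, dt = Inf,
                          average = FALSE)
    return(new_flow_field(grid, bc, cfg, out$u, out$v, out$p, st,
                          out$report))
  }
  n_newton <- ceiling(0.4 * cfg$max_iterations)
  out <- iterate_newton(st, bc, cfg, sol, uref, n_iter = n_newton)
  if (!out$report$converged) {
    # no steady attractor found (oscillatory flow): damped pseudo-time
    # march, returning the average over the trailing iterates
    n_damped <- max(cfg$max_iterations - out$report$iterations, 10L)
    out2 <- iterate_ptc_average(st, bc, cfg,
                                list(u = out$u, v = out$v, p = out$p),
                                uref, n_iter = n_damped)
    out2$report$iterations <- out$report$iterations +
      out2$report$iterations
    out <- out2
  }
  new_flow_field(grid, bc, cfg, out$u, out$v, out$p, st, out$report)
}

# residual of the steady coupled system at a state vector
ns_residual <- function(st, bc, cfg, x) {
  f <- fields_from_x(st, x)
  sys <- assemble_system(st, bc, cfg, f$u, f$v, with_conv = TRUE)
  r <- as.numeric(sys$A %*% x - sys$rhs)
  list(fields = f, sys = sys, r = r, rnorm = sqrt(sum(r^2)))
}

# Damped Newton iteration on the coupled steady residual, with
# pseudo-transient continuation (PTC) engaged when a plain Newton step
# cannot reduce the residual. Two cost-saving structural choices:
# the factorized Jacobian is reused for several "chord" steps (only the
# residual is re-assembled; sparse refactorization happens when
# convergence per step slows or a step is rejected), and PTC accepts
# steps non-monotonically, growing the pseudo-time step with the
# residual reduction achieved per factorization cycle
# (switched-evolution relaxation). Convergence is only declared on a
# full undamped Newton step, with a freshly assembled Jacobian, that
# changes the velocities by less than the tolerance.
iterate_newton <- function(st, bc, cfg, sol, uref, n_iter) {
  x <- state_vector(st, sol$u, sol$v, sol$p)
  cur <- ns_residual(st, bc, cfg, x)
  dt0 <- if (is.numeric(cfg$pseudo_time_step)) {
    cfg$pseudo_time_step
  } else {
    2 * st$dx / uref
  }
  rho <- bc$fluid$density
  vel <- seq_len(st$nU + st$nV)
  damp_diag <- function(dt) {
    Matrix::sparseMatrix(i = vel, j = vel, x = rep(rho / dt, length(vel)),
                         dims = c(st$ndof, st$ndof))
  }
  newton_mode <- TRUE
  dt <- dt0
  ptc_cycles <- 0L
  rel <- Inf
  converged <- FALSE
  it <- 0L
  refactor <- TRUE
  fresh <- FALSE
  chord <- 0L
  rnorm_ref <- cur$rnorm
  J <- NULL
  rejected_fresh_newton <- FALSE
  while (it < n_iter) {
    if (refactor) {
      f <- cur$fields
      J <- cur$sys$A + newton_extra(st, bc, f$u, f$v)
      if (!newton_mode) J <- J + damp_diag(dt)
      fresh <- TRUE
      chord <- 0L
      rnorm_ref <- cur$rnorm
      refactor <- FALSE
    }
    it <- it + 1L
    chord <- chord + 1L
    dxv <- as.numeric(Matrix::solve(J, -cur$r))
    if (newton_mode) {
      lambda <- 1
      accepted <- FALSE
      for (ls in seq_len(if (fresh) 4L else 2L)) {
        trial <- ns_residual(st, bc, cfg, x + lambda * dxv)
        if (trial$rnorm <= (1 - 1e-4 * lambda) * cur$rnorm ||
            trial$rnorm < 1e-300) {
          accepted <- TRUE
          break
        }
        lambda <- lambda / 2
      }
      if (accepted) {
        rel <- lambda * max(abs(dxv[vel])) / uref
        prev <- cur$rnorm
        x <- x + lambda * dxv
        cur <- trial
        rejected_fresh_newton <- FALSE
        if (rel < cfg$tolerance && lambda == 1) {
          if (fresh && chord == 1L) {
            converged <- TRUE
            break
          }
          refactor <- TRUE # confirm with a fresh Jacobian
        } else if (lambda < 1 || chord >= 8L ||
                   trial$rnorm > 0.6 * prev) {
          refactor <- TRUE
        }
        fresh <- FALSE
      } else if (!fresh) {
        refactor <- TRUE # stale Jacobian may be to blame: retry fresh
        fresh <- FALSE
      } else if (!rejected_fresh_newton) {
        # a fresh full Newton step failed: damp in pseudo-time
        rejected_fresh_newton <- TRUE
        newton_mode <- FALSE
        refactor <- TRUE
      } else {
        newton_mode <- FALSE
        dt <- dt / 2
        refactor <- TRUE
      }
    } else {
      trial <- ns_residual(st, bc, cfg, x + dxv)
      if (trial$rnorm > 5 * cur$rnorm) {
        if (fresh) dt <- min(dt, 1e4 * dt0) / 4
        refactor <- TRUE
        next
      }
      rel <- max(abs(dxv[vel])) / uref
      x <- x + dxv
      cur <- trial
      fresh <- FALSE
      if (chord >= 8L) {
        # grow the pseudo-time step with the progress of this cycle
        dt <- dt * min(8, max(rnorm_ref / max(cur$rnorm, 1e-300), 0.3))
        ptc_cycles <- ptc_cycles + 1L
        if (ptc_cycles %% 3L == 0L || dt > 1e6 * dt0) {
          newton_mode <- TRUE # periodic full-Newton attempt
          rejected_fresh_newton <- FALSE
        }
        refactor <- TRUE
      }
    }
  }
  f <- fields_from_x(st, x)
  list(u = f$u, v = f$v, p = f$p,
       report = list(iterations = it, converged = converged,
                     rel_change = rel, time_averaged = FALSE))
}

# Linearly implicit pseudo-time march with a frozen, periodically
# refreshed Jacobian, used when no steady attractor exists (oscillatory
# flow). Returns the average of the trailing two-thirds of the iterates.
iterate_ptc_average <- function(st, bc, cfg, sol, uref, n_iter) {
  x <- state_vector(st, sol$u, sol$v, sol$p)
  cur <- ns_residual(st, bc, cfg, x)
  rho <- bc$fluid$density
  vel <- seq_len(st$nU + st$nV)
  dt <- 6 * st$dx / uref
  keep_from <- ceiling(n_iter / 3)
  acc <- 0 * x
  n_acc <- 0L
  J <- NULL
  rel <- Inf
  converged <- FALSE
  for (it in seq_len(n_iter)) {
    if (it %% 10L == 1L || is.null(J)) {
      f <- cur$fields
      J <- cur$sys$A + newton_extra(st, bc, f$u, f$v) +
        Matrix::sparseMatrix(i = vel, j = vel,
                             x = rep(rho / dt, length(vel)),
                             dims = c(st$ndof, st$ndof))
    }
    dxv <- as.numeric(Matrix::solve(J, -cur$r))
    trial <- ns_residual(st, bc, cfg, x + dxv)
    if (trial$rnorm > 10 * cur$rnorm) {
      dt <- dt / 2
      J <- NULL
      next
    }
    rel <- max(abs(dxv[vel])) / uref
    x <- x + dxv
    cur <- trial
    if (it >= keep_from) {
      acc <- acc + x
      n_acc <- n_acc + 1L
    }
    if (rel < cfg$tolerance) {
      converged <- TRUE
      break
    }
  }
  averaged <- !converged && n_acc > 0L
  if (averaged) x <- acc / n_acc
  if (!converged) {
    warn(sprintf(
      "solver did not reach tolerance %.1e (last relative change %.2e)%s",
      cfg$tolerance, rel,
      if (averaged) "; returning pseudo-time average" else ""))
  }
  f <- fields_from_x(st, x)
  list(u = f$u, v = f$v, p = f$p,
       report = list(iterations = it, converged = converged,
                     rel_change = rel, time_averaged = averaged))
}

# (optionally damped) lagged-convection iteration; with average = TRUE the
# returned field is the mean of the trailing half of the iterates
iterate_picard <- function(st, bc, cfg, sol, uref, n_iter, dt = Inf,
                           average = FALSE) {
  u <- sol$u; v <- sol$v; p <- sol$p
  alpha <- cfg$under_relaxation
  acc_u <- 0 * u; acc_v <- 0 * v; acc_p <- 0 * p; n_acc <- 0L
  keep_from <- if (average) ceiling(n_iter / 3) else n_iter + 1L
  rel <- Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(n_iter)) {
    sol_i <- picard_step(st, bc, cfg, u, v, p, with_conv = TRUE, dt = dt)
    rel <- max(abs(sol_i$u - u), abs(sol_i$v - v)) / uref
    u <- u + alpha * (sol_i$u - u)
    v <- v + alpha * (sol_i$v - v)
    p <- sol_i$p
    if (it >= keep_from) {
      acc_u <- acc_u + u; acc_v <- acc_v + v; acc_p <- acc_p + p
      n_acc <- n_acc + 1L
    }
    if (rel < cfg$tolerance) {
      converged <- TRUE
      break
    }
  }
  if (average && !converged && n_acc > 0L) {
    u <- acc_u / n_acc; v <- acc_v / n_acc; p <- acc_p / n_acc
  }
  if (!converged) {
    warn(sprintf(
      "solver did not reach tolerance %.1e in %d iterations (last %.2e)%s",
      cfg$tolerance, it, rel,
      if (average && n_acc > 0L) "; returning pseudo-time average" else ""))
  }
  list(u = u, v = v, p = p,
       report = list(iterations = it, converged = converged,
                     rel_change = rel,
                     time_averaged = average && !converged && n_acc > 0L))
}

#' Solve creeping (Stokes) flow
#'
#' Drops the convective terms and solves the linear creeping-flow system in
#' a single sparse direct solve. Appropriate for the lowest feed rates
#' (inlet Re well below 1), and exactly linear in the inlet velocity.
#'
#' @inheritParams solve_steady_flow
#' @return A `flow_field` (see [solve_steady_flow()]).
#' @export
solve_stokes <- function(grid, bc, cfg = solver_config()) {
  cfg$scheme <- "stokes_direct"
  solve_steady_flow(grid, bc, cfg)
}

new_flow_field <- function(grid, bc, cfg, u, v, p_vec, st, conv_info) {
  p <- matrix(NA_real_, grid$nx, grid$ny)
  p[grid$fluid] <- p_vec
  flux_in <- if (length(grid$inlet_rows)) {
    sum(u[1, grid$inlet_rows]) * grid$dy
  } else 0
  flux_out <- if (length(grid$outlet_rows)) {
    sum(u[grid$nx + 1, grid$outlet_rows]) * grid$dy
  } else 0
  mass_imb <- if (flux_in > 0) abs(flux_out - flux_in) / flux_in else 0
  div <- (u[2:(grid$nx + 1), ] - u[1:grid$nx, ]) / grid$dx +
    (v[, 2:(grid$ny + 1)] - v[, 1:grid$ny]) / grid$dy
  div[!grid$fluid] <- 0
  uref <- max(abs(u), abs(v), 1e-300)
  cont_res <- max(abs(div)) * min(grid$dx, grid$dy) / uref
  mom_res <- NA_real_
  if (st$nU + st$nV > 0 && uref > 1e-300) {
    with_conv <- cfg$scheme != "stokes_direct"
    sys <- assemble_system(st, bc, cfg, u, v, with_conv = with_conv)
    x <- state_vector(st, u, v, p_vec)
    r <- as.numeric(sys$A %*% x - sys$rhs)
    mom_scale <- max(abs(sys$rhs), bc$fluid$dynamic_viscosity * uref /
                       min(grid$dx, grid$dy)^2)
    mom_res <- max(abs(r[seq_len(st$nU + st$nV)])) / mom_scale
  }
  structure(
    list(u = u, v = v, p = p, grid = grid, bc = bc, cfg = cfg,
         report = c(conv_info,
                    list(momentum_residual = mom_res,
                         continuity_residual = cont_res,
                         mass_imbalance = mass_imb))),
    class = "flow_field"
  )
}

#' @export
print.flow_field <- function(x, ...) {
  r <- x$report
  cat(sprintf("<flow_field> %s, %d x %d cells\n",
              x$grid$layout$condition, x$grid$nx, x$grid$ny))
  cat(sprintf("  %s after %d iteration(s); rel change %.2e; mass imbalance %.2e\n",
              if (r$converged) "converged" else "NOT converged",
              r$iterations, r$rel_change, r$mass_imbalance))
  invisible(x)
}

#' @method tidy flow_field
#' @export
tidy.flow_field <- function(x, ...) {
  nx <- x$grid$nx; ny <- x$grid$ny
  uc <- 0.5 * (x$u[1:nx, ] + x$u[2:(nx + 1), ])
  vc <- 0.5 * (x$v[, 1:ny] + x$v[, 2:(ny + 1)])
  df <- tidyr::expand_grid(i = seq_len(nx), j = seq_len(ny))
  idx <- cbind(df$i, df$j)
  xc <- (df$i - 0.5) * x$grid$dx
  yc <- (df$j - 0.5) * x$grid$dy
  flag <- ifelse(x$grid$fluid[idx], "fluid", "solid")
  pv <- x$p[idx]
  tibble(
    x = xc, y = yc,
    u = uc[idx], v = vc[idx], p = pv,
    speed = sqrt(uc[idx]^2 + vc[idx]^2),
    flag = flag
  )
}

#' @method glance flow_field
#' @export
glance.flow_field <- function(x, ...) {
  r <- x$report
  tibble(
    iterations = r$iterations, converged = r$converged,
    rel_change = r$rel_change, momentum_residual = r$momentum_residual,
    continuity_residual = r$continuity_residual,
    mass_imbalance = r$mass_imbalance
  )
}

#' @method autoplot flow_field
#' @export
autoplot.flow_field <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x * 1e3, y = .data$y * 1e3)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$speed * 1e3)) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = "speed (mm/s)") +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = object$grid$layout$condition)
}
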