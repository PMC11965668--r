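# Laminar incompressible Navier-Stokes solver on tagged voxel meshes.
#
# Explicit two-stage (Heun) momentum integration with conservative QUICK
# advection and theta-corrected wall diffusion (see src/mac_kernels.cpp),
# followed by a pressure projection: the Poisson operator over fluid cells
# is assembled once per mesh/boundary topology, Cholesky-factorized with
# Matrix, and reused at every sub-step and across sweep cases. The sub-step
# size is CFL-limited and adapted to the current velocity extrema; the
# clinical 0.01 s reporting step is the boundary-condition/output cadence,
# not a stability limit. Pressures are handled kinematically (q = p/rho);
# only pressure differences affect the velocity field of this rigid-wall
# model, so gauge and absolute outlet values give identical flows.

#' Newtonian blood properties
#'
#' Of the clinical record only the Reynolds number (~445) is fixed; density
#' 1050 kg/m^3 and dynamic viscosity 4.0 mPa s are the conventional blood
#' values consistent with it (giving Re ~454 from the measured PRA mean
#' velocity and diameter).
#'
#' @param density kg/m^3.
#' @param viscosity dynamic viscosity in Pa s.
#' @return a `fluid_properties` object.
#' @export
fluid_properties <- function(density = 1050, viscosity = 4.0e-3) {
  if (density <= 0 || viscosity <= 0) stop("fluid properties must be positive")
  structure(list(density = density, viscosity = viscosity,
                 nu = viscosity / density),
            class = "fluid_properties")
}

#' Reynolds number rho v d / mu
#'
#' @param fluid a [fluid_properties()] object.
#' @param v characteristic velocity in m/s.
#' @param d characteristic diameter in m.
#' @return dimensionless Reynolds number.
#' @examples
#' reynolds(fluid_properties(), 0.577, 3.0e-3) # ~454
#' @export
reynolds <- function(fluid = fluid_properties(), v, d) {
  stopifnot(inherits(fluid, "fluid_properties"), v >= 0, d > 0)
  fluid$density * v * d / fluid$viscosity
}

as_value_fn <- function(x) {
  if (inherits(x, "avf_waveform")) {
    spec <- attr(x, "spec")
    function(t) eval_waveform_impl(spec, t)
  } else if (is.function(x)) {
    x
  } else {
    force(x)
    function(t) x
  }
}

#' Boundary conditions for the AVF model
#'
#' PRA inlet: prescribed axial velocity (waveform or constant), uniform
#' ("flat", the clinical protocol default) or parabolic profile. DRA end: prescribed axial
#' velocity whose direction flag selects anterograde (outflow toward the
#' hand) or retrograde (inflow feeding the anastomosis). CV outlet: uniform
#' pressure (default the measured 1064 Pa). Walls are no-slip.
#'
#' @param pra_inlet,dra_end `avf_waveform`, constant velocity in m/s, or a
#'   function of time (non-negative speeds; direction comes from the flag).
#' @param dra_direction `"anterograde"` or `"retrograde"`.
#' @param cv_pressure outlet pressure in Pa.
#' @param profile inlet velocity profile, `"flat"` or `"parabolic"`.
#' @return an `avf_bc` object.
#' @export
avf_boundary_spec <- function(pra_inlet, dra_end,
                              dra_direction = c("anterograde", "retrograde"),
                              cv_pressure = 1064,
                              profile = c("flat", "parabolic")) {
  dra_direction <- match.arg(dra_direction)
  profile <- match.arg(profile)
  pra <- as_value_fn(pra_inlet)
  dra0 <- as_value_fn(dra_end)
  # DRA port lies at the +x end: anterograde outflow has +x velocity there,
  # retrograde inflow -x
  dsign <- if (dra_direction == "anterograde") +1 else -1
  structure(list(
    ports = list(
      PRA_INLET = list(kind = "velocity", value = pra, profile = profile),
      DRA_END = list(kind = "velocity",
                     value = function(t) dsign * dra0(t), profile = profile),
      CV_OUTLET = list(kind = "pressure", value = as_value_fn(cv_pressure))),
    dra_direction = dra_direction, body_force = NULL,
    period = if (inherits(pra_inlet, "avf_waveform"))
      waveform_spec(pra_inlet)$period else NA_real_),
    class = "avf_bc")
}

#' Boundary conditions for the straight-tube benchmarks
#'
#' Either a velocity inlet with a pressure outlet (Poiseuille), or pressure
#' at both ends with an oscillatory axial body force (Womersley).
#'
#' @param inlet waveform/constant/function for the inlet axial velocity, or
#'   `NULL` for a pressure inlet.
#' @param inlet_pressure,outlet_pressure pressures in Pa.
#' @param profile `"flat"` or `"parabolic"` inlet profile.
#' @param body_force function of time giving a uniform axial body force per
#'   unit mass (m/s^2), or `NULL`.
#' @param period signal period in s (for transient runs).
#' @return an `avf_bc` object.
#' @export
tube_boundary_spec <- function(inlet = NULL, inlet_pressure = NULL,
                               outlet_pressure = 0,
                               profile = c("parabolic", "flat"),
                               body_force = NULL, period = NA_real_) {
  profile <- match.arg(profile)
  inport <- if (!is.null(inlet)) {
    list(kind = "velocity", value = as_value_fn(inlet), profile = profile)
  } else {
    list(kind = "pressure", value = as_value_fn(
      if (is.null(inlet_pressure)) 0 else inlet_pressure))
  }
  if (is.na(period) && inherits(inlet, "avf_waveform")) {
    period <- waveform_spec(inlet)$period
  }
  structure(list(
    ports = list(INLET = inport,
                 OUTLET = list(kind = "pressure",
                               value = as_value_fn(outlet_pressure))),
    body_force = body_force, period = period),
    class = "avf_bc")
}

# --- solver state -----------------------------------------------------------

solver_setup <- function(mesh, bc, fluid) {
  stopifnot(inherits(mesh, "avf_mesh"), inherits(bc, "avf_bc"),
            inherits(fluid, "fluid_properties"))
  pt <- mesh$ports
  miss <- setdiff(pt$name, names(bc$ports))
  if (length(miss)) stop("no boundary condition for port(s): ",
                         paste(miss, collapse = ", "))
  specs <- bc$ports[pt$name]
  kind <- ifelse(vapply(specs, `[[`, "", "kind") == "pressure", 1L, 0L)
  if (!any(kind == 1L)) stop("at least one pressure port is required")
  dims <- mesh$dims
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  nfl <- mesh$n_elements
  h <- mesh$h

  E <- new.env(parent = emptyenv())
  E$mesh <- mesh; E$bc <- bc; E$fluid <- fluid
  E$kind <- kind
  E$dir <- as.integer(pt$dir)
  E$valfn <- lapply(specs, `[[`, "value")
  E$rho <- fluid$density
  E$nu <- fluid$nu
  E$h <- h
  E$dims <- as.integer(dims)
  E$code <- mesh$cellcode
  E$cid <- mesh$cellid
  nu_len <- (nx + 1) * ny * nz
  nv_len <- nx * (ny + 1) * nz
  nw_len <- nx * ny * (nz + 1)
  for (nm in c("u", "u1", "k1u", "k2u")) assign(nm, numeric(nu_len), envir = E)
  for (nm in c("v", "v1", "k1v", "k2v")) assign(nm, numeric(nv_len), envir = E)
  for (nm in c("w", "w1", "k1w", "k2w")) assign(nm, numeric(nw_len), envir = E)
  E$phiu <- as.numeric(mesh$phi_u)
  E$phiv <- as.numeric(mesh$phi_v)
  E$phiw <- as.numeric(mesh$phi_w)
  E$div <- numeric(nfl)
  E$q <- numeric(nfl)

  # inlet-profile weights on u faces of ghost cells
  wu <- rep(1, nu_len)
  for (p in seq_len(nrow(pt))) {
    if (kind[p] != 0L || specs[[p]]$profile != "parabolic") next
    gc <- which(mesh$cellcode == pt$code[p])
    if (!length(gc)) next
    idx <- arrayInd(gc, dims)
    yc <- mesh$x0[2] + (idx[, 2] - 0.5) * h
    zc <- mesh$x0[3] + (idx[, 3] - 0.5) * h
    ctr <- mesh$solid$ports[[p]]$center
    r2 <- (yc - ctr[2])^2 + (zc - ctr[3])^2
    wgt <- pmax(0, 2 * (1 - r2 / pt$radius[p]^2))
    ilo <- idx[, 1] + (nx + 1) * ((idx[, 2] - 1) + ny * (idx[, 3] - 1))
    wu[ilo] <- wgt
    wu[ilo + 1] <- wgt
  }
  E$wu <- wu

  # Poisson operator over fluid cells (-Laplacian, h^2-scaled)
  fl <- mesh$cellcode == 0L
  deg <- numeric(nfl)
  ii <- integer(0); jj <- integer(0)
  pcell <- integer(0); pport <- integer(0)
  for (ax in 1:3) for (sd in c(-1L, 1L)) {
    nbc <- shift_arr(mesh$cellcode, ax, sd, 1L)
    nbi <- shift_arr(mesh$cellid, ax, sd, 0L)
    sel <- which(fl & nbc == 0L)
    ii <- c(ii, mesh$cellid[sel]); jj <- c(jj, nbi[sel])
    deg <- deg + tabulate(mesh$cellid[sel], nfl)
    selp <- which(fl & nbc >= 2L)
    if (length(selp)) {
      pk <- kind[nbc[selp] - 1L]
      selp <- selp[pk == 1L]
      if (length(selp)) {
        ids <- mesh$cellid[selp]
        deg[ids] <- deg[ids] + 2
        pcell <- c(pcell, ids)
        pport <- c(pport, nbc[selp] - 1L)
      }
    }
  }
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(nfl)),
                            j = c(jj, seq_len(nfl)),
                            x = c(rep(-1, length(ii)), deg),
                            dims = c(nfl, nfl))
  E$chol <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  E$pcell <- pcell
  E$pport <- pport

  # port plane faces for flux accounting
  f <- mesh$facets
  E$port_faces <- lapply(seq_len(nrow(pt)), function(p) {
    sel <- which(f$tag == pt$name[p])
    idx <- arrayInd(f$cell[sel], dims)
    iface <- ifelse(f$side[sel] > 0, idx[, 1] + 1L, idx[, 1])
    list(idx = iface + (nx + 1) * ((idx[, 2] - 1) + ny * (idx[, 3] - 1)),
         side = f$side[sel])
  })
  names(E$port_faces) <- pt$name

  # face classification for the momentum kernel: "fast" faces have the
  # whole QUICK + Laplacian stencil valid (branch-free path); the rest are
  # handled with checked wall/theta logic
  E$fast <- vector("list", 3)
  E$slow <- vector("list", 3)
  for (a in 1:3) {
    fd <- dims; fd[a] <- fd[a] + 1L
    put <- function(offset) {
      out <- array(1L, fd)
      sel <- lapply(fd, seq_len)
      sel[[a]] <- seq_len(dims[a]) + offset
      out[sel[[1]], sel[[2]], sel[[3]]] <- mesh$cellcode
      out
    }
    cl <- put(1L)   # cell behind the face (f - e_a)
    cr <- put(0L)   # cell ahead (f)
    uok <- cl == 0L | cr == 0L | cl >= 2L | cr >= 2L
    dof <- cl == 0L & cr == 0L
    reg <- dof
    for (ax in 1:3) for (sh in c(-2L, -1L, 1L, 2L)) {
      reg <- reg & shift_n(uok, ax, sh, FALSE)
    }
    E$fast[[a]] <- as.integer(which(reg) - 1L)
    E$slow[[a]] <- as.integer(which(dof & !reg) - 1L)
  }

  # face indices for cell-centred velocity reconstruction
  idx <- arrayInd(which(fl), dims)
  E$iu_lo <- idx[, 1] + (nx + 1) * ((idx[, 2] - 1) + ny * (idx[, 3] - 1))
  E$iu_hi <- E$iu_lo + 1L
  E$iv_lo <- idx[, 1] + nx * ((idx[, 2] - 1) + (ny + 1) * (idx[, 3] - 1))
  E$iv_hi <- E$iv_lo + nx
  E$iw_lo <- idx[, 1] + nx * ((idx[, 2] - 1) + ny * (idx[, 3] - 1))
  E$iw_hi <- E$iw_lo + nx * ny
  E$t <- 0
  E
}

# plug-flow initial condition for AVF steady runs: fill each branch with
# its expected bulk velocity so the pseudo-time march only has to develop
# profiles and the junction flow, not fill 10-diameter extensions
warm_start_plug <- function(E) {
  mesh <- E$mesh
  solid <- mesh$solid
  if (!identical(solid$kind, "avf")) return(invisible(FALSE))
  g <- solid$geom
  pt <- mesh$ports
  pv <- port_values(E, 0)
  v_pra <- pv[pt$name == "PRA_INLET"]
  v_dra <- pv[pt$name == "DRA_END"]
  q_cv <- v_pra * pt$area_mesh[pt$name == "PRA_INLET"] -
    v_dra * pt$area_mesh[pt$name == "DRA_END"]
  v_cv <- q_cv / pt$area_mesh[pt$name == "CV_OUTLET"]
  dims <- mesh$dims; h <- mesh$h; x0 <- mesh$x0
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  margin <- 0.25 * h

  fill_u <- function() {
    xf <- x0[1] + (0:(nx)) * h
    yc <- x0[2] + (seq_len(ny) - 0.5) * h
    zc <- x0[3] + (seq_len(nz) - 0.5) * h
    co <- expand.grid(x = xf, y = yc, z = zc, KEEP.OUT.ATTRS = FALSE)
    val <- numeric(nrow(co))
    art <- artery_lateral(g, co$x, co$y, co$z) < -margin
    val[art & co$x < g$taper_x0] <- v_pra
    val[art & co$x > g$taper_x1] <- v_dra
    vein_par <- !art &
      dist_segment(co$x, co$y, co$z, g$p2, g$p3) < g$rv - margin
    val[vein_par] <- -v_cv
    vein_45 <- !art & !vein_par &
      dist_segment(co$x, co$y, co$z, g$p0, g$p1) < g$rv - margin
    val[vein_45] <- g$u1[1] * v_cv
    val
  }
  fill_v <- function() {
    xc <- x0[1] + (seq_len(nx) - 0.5) * h
    yf <- x0[2] + (0:ny) * h
    zc <- x0[3] + (seq_len(nz) - 0.5) * h
    co <- expand.grid(x = xc, y = yf, z = zc, KEEP.OUT.ATTRS = FALSE)
    val <- numeric(nrow(co))
    vein_45 <- artery_lateral(g, co$x, co$y, co$z) >= 0 &
      dist_segment(co$x, co$y, co$z, g$p0, g$p1) < g$rv - margin
    val[vein_45] <- g$u1[2] * v_cv
    val
  }
  E$u[] <- fill_u()
  E$v[] <- fill_v()
  # zero anything that is not an interior velocity DOF
  mask_u <- logical(length(E$u)); mask_u[E$fast[[1]] + 1L] <- TRUE
  mask_u[E$slow[[1]] + 1L] <- TRUE
  E$u[!mask_u] <- 0
  mask_v <- logical(length(E$v)); mask_v[E$fast[[2]] + 1L] <- TRUE
  mask_v[E$slow[[2]] + 1L] <- TRUE
  E$v[!mask_v] <- 0
  invisible(TRUE)
}

port_values <- function(E, t) {
  vapply(seq_along(E$valfn), function(p) {
    val <- E$valfn[[p]](t)
    if (E$kind[p] == 1L) val / E$rho else val   # kinematic pressure
  }, 0)
}

body_force_at <- function(E, t) {
  if (is.null(E$bc$body_force)) 0 else E$bc$body_force(t)
}

apply_bc_now <- function(E, u, v, w, t) {
  pv <- port_values(E, t)
  .mac_apply_bc(u, v, w, E$code, E$dims, E$kind, E$dir,
                ifelse(E$kind == 0L, pv, 0), E$wu)
  invisible(pv)
}

stable_dt <- function(E, cfl = 0.40) {
  umax <- max(.mac_maxabs(E$u), .mac_maxabs(E$v), .mac_maxabs(E$w), 1e-3)
  if (!is.finite(umax)) {
    stop("momentum integration diverged (non-finite velocities); ",
         "reduce the CFL number or refine the mesh")
  }
  dt_adv <- cfl * E$h / umax
  dt_visc <- 0.8 * 0.1 * E$h^2 / (6 * E$nu)  # worst-case theta = 0.1
  min(dt_adv, dt_visc)
}

advance <- function(E, t, dt) {
  apply_bc_now(E, E$u, E$v, E$w, t)
  .mac_rhs(E$u, E$v, E$w, E$code, E$dims, E$phiu, E$phiv, E$phiw,
           E$nu, E$h, body_force_at(E, t), E$k1u, E$k1v, E$k1w,
           E$fast, E$slow)
  .mac_copy_axpy(E$u1, E$u, E$k1u, dt)
  .mac_copy_axpy(E$v1, E$v, E$k1v, dt)
  .mac_copy_axpy(E$w1, E$w, E$k1w, dt)
  t1 <- t + dt
  apply_bc_now(E, E$u1, E$v1, E$w1, t1)
  .mac_rhs(E$u1, E$v1, E$w1, E$code, E$dims, E$phiu, E$phiv, E$phiw,
           E$nu, E$h, body_force_at(E, t1), E$k2u, E$k2v, E$k2w,
           E$fast, E$slow)
  .mac_axpy(E$u, E$k1u, dt / 2); .mac_axpy(E$u, E$k2u, dt / 2)
  .mac_axpy(E$v, E$k1v, dt / 2); .mac_axpy(E$v, E$k2v, dt / 2)
  .mac_axpy(E$w, E$k1w, dt / 2); .mac_axpy(E$w, E$k2w, dt / 2)
  pv <- apply_bc_now(E, E$u, E$v, E$w, t1)
  .mac_divergence(E$u, E$v, E$w, E$code, E$cid, E$dims, E$h, E$div)
  b <- (-E$h^2 / dt) * E$div
  qout <- ifelse(E$kind == 1L, pv, 0)
  if (length(E$pcell)) {
    b[E$pcell] <- b[E$pcell] + 2 * qout[E$pport]
  }
  q <- as.numeric(Matrix::solve(E$chol, b, system = "A"))
  .mac_correct(E$u, E$v, E$w, q, E$code, E$cid, E$dims, dt, E$h,
               E$kind, qout)
  E$q <- q
  t1
}

port_fluxes <- function(E, u = E$u) {
  vapply(E$port_faces, function(pf) {
    sum(u[pf$idx] * pf$side) * E$h^2
  }, 0)
}

cell_velocity <- function(E, u = E$u, v = E$v, w = E$w) {
  cbind(0.5 * (u[E$iu_lo] + u[E$iu_hi]),
        0.5 * (v[E$iv_lo] + v[E$iv_hi]),
        0.5 * (w[E$iw_lo] + w[E$iw_hi]))
}

finish_solution <- function(E, mode, instants, fields, fluxes, extra = list()) {
  .mac_divergence(E$u, E$v, E$w, E$code, E$cid, E$dims, E$h, E$div)
  qo <- fluxes[[length(fluxes)]]
  qin <- qo[E$kind == 0L]
  scale <- max(abs(qin), abs(qo))
  imbalance <- abs(sum(qo)) / max(scale, 1e-300)
  if (imbalance > 0.01) {
    stop(sprintf(
      "global mass imbalance %.2g%% exceeds 1%% (port fluxes: %s)",
      100 * imbalance, paste(signif(qo, 4), collapse = ", ")))
  }
  out <- c(list(mode = mode, instants = instants, fields = fields,
                fluxes = do.call(rbind, fluxes),
                ports = E$mesh$ports$name,
                div_l2 = sqrt(mean(E$div^2)),
                mass_error = abs(sum(qo)) / max(scale, 1e-300),
                h = E$h, n_elements = E$mesh$n_elements,
                fluid = E$fluid),
           extra)
  class(out) <- "avf_flow"
  out
}

#' Steady laminar flow at fixed boundary values
#'
#' Pseudo-time marches the pulsatile solver with frozen boundary values
#' until the velocity field stops changing (relative L2 change between
#' checkpoints below `steady_tol`), then time-averages over a short final
#' window (for fields that settle into a small residual oscillation the
#' average is the reported steady state; for converged fields it is
#' identical to the final state).
#'
#' @param mesh an `avf_mesh`.
#' @param bc an `avf_bc` with time-constant values (waveforms are evaluated
#'   at t = 0).
#' @param fluid [fluid_properties()].
#' @param t_max pseudo-time horizon in s.
#' @param min_time minimum pseudo-time before convergence may be declared.
#' @param steady_tol relative L2 change per checkpoint below which the
#'   march stops.
#' @param check_every sub-steps between convergence checks.
#' @param t_avg duration of the final averaging window in s.
#' @param init `"auto"` (plug-flow warm start on AVF meshes, rest
#'   otherwise), `"plug"` or `"rest"`.
#' @param verbose print checkpoint diagnostics.
#' @return an `avf_flow` with one instant (`"steady"`): cell-centred
#'   velocity `U` (n x 3), pressure `p` (Pa), port fluxes, mass/divergence
#'   diagnostics and the convergence history.
#' @export
solve_steady <- function(mesh, bc, fluid = fluid_properties(),
                         t_max = 0.5, min_time = 0.12, steady_tol = 1.5e-3,
                         check_every = 150L, t_avg = 0.04,
                         init = c("auto", "plug", "rest"),
                         verbose = FALSE) {
  init <- match.arg(init)
  E <- solver_setup(mesh, bc, fluid)
  # freeze boundary values at t = 0
  pv0 <- port_values(E, 0)
  E$valfn <- lapply(seq_along(E$valfn), function(p) {
    val <- if (E$kind[p] == 1L) pv0[p] * E$rho else pv0[p]
    function(t) val
  })
  if (init == "plug" || (init == "auto" && identical(mesh$solid$kind, "avf"))) {
    warm_start_plug(E)
  }
  steady_march(E, t_max = t_max, min_time = min_time,
               steady_tol = steady_tol, check_every = check_every,
               t_avg = t_avg, verbose = verbose)
}

# pseudo-time march to steadiness on a prepared solver state
steady_march <- function(E, t_max = 0.5, min_time = 0.12,
                         steady_tol = 1.5e-3, check_every = 150L,
                         t_avg = 0.04, verbose = FALSE) {
  t <- 0; nstep <- 0L
  uprev <- NULL
  converged <- FALSE
  history <- numeric(0)
  dt <- stable_dt(E)
  while (t < t_max) {
    t <- advance(E, t, dt)
    nstep <- nstep + 1L
    if (nstep %% 20L == 0L) dt <- stable_dt(E)
    if (nstep %% check_every == 0L) {
      usnap <- c(E$u, E$v, E$w)
      if (!is.null(uprev)) {
        rel <- sqrt(sum((usnap - uprev)^2)) / max(sqrt(sum(usnap^2)), 1e-300)
        history <- c(history, rel)
        if (verbose) {
          message(sprintf("t=%.3f s, rel change %.3e", t, rel))
        }
        if (rel < steady_tol && t > min_time) { converged <- TRUE; break }
      }
      uprev <- usnap
    }
  }
  # short time-averaging window: identical to the final state when truly
  # converged, a deterministic mean when a weak residual oscillation remains
  su <- 0 * E$u; sv <- 0 * E$v; sw <- 0 * E$w; sq <- 0 * E$q
  na <- 0L
  t_stop <- t + t_avg
  while (t < t_stop) {
    t <- advance(E, t, dt)
    su <- su + E$u; sv <- sv + E$v; sw <- sw + E$w; sq <- sq + E$q
    na <- na + 1L
  }
  E$u <- su / na; E$v <- sv / na; E$w <- sw / na; E$q <- sq / na
  fluxes <- list(port_fluxes(E))
  fields <- list(list(U = cell_velocity(E), p = E$rho * E$q))
  finish_solution(E, "steady_snapshot", "steady", fields, fluxes,
                  extra = list(converged = converged, history = history,
                               t_final = t, n_steps = nstep,
                               dt_sub = dt))
}

# reset a solver state for reuse with new (frozen) boundary values;
# vals: named vector over the mesh port order (velocities in m/s signed
# along +x, pressures in Pa)
reset_state <- function(E, vals) {
  E$u[] <- 0; E$v[] <- 0; E$w[] <- 0; E$q[] <- 0
  E$u1[] <- 0; E$v1[] <- 0; E$w1[] <- 0
  E$valfn <- lapply(seq_along(vals), function(p) {
    val <- vals[[p]]
    function(t) val
  })
  invisible(E)
}

#' Pulsatile laminar flow over full cardiac cycles
#'
#' Integrates the flow under time-dependent boundary waveforms with
#' CFL-limited sub-steps; `dt` is the output/probe cadence (the clinical
#' reporting step of 0.01 s). Fields are captured at `output_instants`, and
#' whenever an instant lies at least one period after start the solution a
#' full period earlier is captured too, giving a phase-matched
#' cycle-periodicity metric.
#'
#' @inheritParams solve_steady
#' @param dt output and probe sampling step in s (default 0.01).
#' @param n_cycles number of cardiac cycles to integrate (default 3).
#' @param output_instants times (s) at which to store full fields; default
#'   the measured extremal/mean instants that fall inside the run.
#' @param period cardiac period in s; defaults to the period carried by the
#'   boundary spec.
#' @param probes optional [probe_set()]; velocity and WSS probe series are
#'   then recorded every `dt`.
#' @return an `avf_flow` with the requested instants, probe series and the
#'   periodicity metric.
#' @export
solve_transient <- function(mesh, bc, fluid = fluid_properties(),
                            dt = 0.01, n_cycles = 3,
                            output_instants = NULL, period = NULL,
                            probes = NULL, verbose = FALSE) {
  E <- solver_setup(mesh, bc, fluid)
  if (is.null(period)) period <- E$bc$period
  if (is.null(period) || is.na(period)) {
    stop("period must be given (or carried by the boundary spec)")
  }
  t_end <- n_cycles * period
  if (is.null(output_instants)) {
    ref <- clinical_reference()
    output_instants <- c(max = ref$t_max, mean = ref$t_mean, min = ref$t_min)
    output_instants <- output_instants[output_instants <= t_end + 1e-9]
  }
  output_instants <- sort(output_instants)
  # capture the same phase one period earlier for the periodicity metric
  capture <- sort(unique(c(output_instants,
                           output_instants - period, t_end, t_end - period)))
  capture <- capture[capture > 1e-12 & capture <= t_end + 1e-9]

  snaps <- list()
  probe_rec <- NULL
  if (!is.null(probes)) {
    probe_rec <- list(t = numeric(0), vel = list(), wss = list())
  }
  t <- 0; nstep <- 0L
  dtsub <- stable_dt(E)
  icap <- 1L
  tick <- dt
  while (t < t_end - 1e-12) {
    t_target <- min(tick, if (icap <= length(capture)) capture[icap]
                    else Inf, t_end)
    while (t < t_target - 1e-12) {
      step <- min(dtsub, t_target - t)
      t <- advance(E, t, step)
      nstep <- nstep + 1L
      if (nstep %% 20L == 0L) dtsub <- stable_dt(E)
    }
    if (icap <= length(capture) && abs(t - capture[icap]) < 1e-9) {
      snaps[[sprintf("%.6f", capture[icap])]] <-
        list(U = cell_velocity(E), p = E$rho * E$q,
             flux = port_fluxes(E), t = capture[icap])
      icap <- icap + 1L
    }
    if (abs(t - tick) < 1e-9) {
      if (!is.null(probes)) {
        probe_rec$t <- c(probe_rec$t, t)
        U <- cell_velocity(E)
        probe_rec$vel[[length(probe_rec$vel) + 1L]] <-
          probe_velocities(mesh, U, probes)
        probe_rec$wss[[length(probe_rec$wss) + 1L]] <-
          probe_wss_vectors(mesh, U, probes, E$fluid$viscosity)
      }
      if (verbose && abs((tick / dt) %% 25) < 1e-9) {
        message(sprintf("t = %.2f / %.2f s", t, t_end))
      }
      tick <- tick + dt
    }
  }
  want <- sprintf("%.6f", output_instants)
  fields <- lapply(want, function(k) snaps[[k]][c("U", "p")])
  fluxes <- lapply(want, function(k) snaps[[k]]$flux)
  # phase-matched periodicity: compare each instant with one period earlier
  periodicity <- vapply(output_instants, function(ti) {
    k1 <- sprintf("%.6f", ti); k0 <- sprintf("%.6f", ti - period)
    if (is.null(snaps[[k0]]) || is.null(snaps[[k1]])) return(NA_real_)
    a <- snaps[[k1]]$U; b <- snaps[[k0]]$U
    sqrt(sum((a - b)^2)) / max(sqrt(sum(a^2)), 1e-300)
  }, 0)
  names(periodicity) <- names(output_instants)
  finish_solution(E, "transient", output_instants, fields, fluxes,
                  extra = list(periodicity = periodicity,
                               probe_series = probe_rec,
                               probes = probes,
                               period = period, n_steps = nstep,
                               dt_out = dt))
}

#' @export
print.avf_flow <- function(x, ...) {
  cat(sprintf(
    "<avf_flow> %s: %d instants, %d elements, mass err %.2e, div L2 %.2e\n",
    x$mode, length(x$fields), x$n_elements, x$mass_error, x$div_l2))
  invisible(x)
}
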