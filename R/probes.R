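# Observation cross-section S1 and probe diagnostics.
#
# S1 is the post-anastomosis cross-section of the proximal vein: a plane
# with normal along the vein axis (the frame's y-axis), placed half a vein
# diameter from the anastomosis centre, cutting through the vortex region.
# Five evenly spaced velocity probes span the lumen chord from the inner
# to the outer edge in the symmetry plane; six evenly spaced WSS probes
# sit on the wall ring of the section (angle 0 = outer edge, angle pi =
# inner edge).

#' Build the S1 probe set
#'
#' @param mesh an `avf_mesh` (typically of the AVF solid).
#' @param n_vel number of velocity probes along the S1 chord (default 5).
#' @param n_wss number of wall WSS probes around the S1 ring (default 6).
#' @param offset requested distance of S1 from the anastomosis centre along
#'   the proximal-vein axis (default 0.5 d_cv). If the section ring at that
#'   offset is still open into the anastomotic mouth (a wall ray escapes the
#'   section), S1 slides outward in steps of 0.25 d_cv to the first closed
#'   ring, so every WSS probe sits on the vein wall of the section itself.
#' @return an `avf_probes` object: probe coordinates, the wall facet rows
#'   used for WSS probes, and the anastomosis frame.
#' @export
probe_set <- function(mesh, n_vel = 5L, n_wss = 6L, offset = NULL) {
  stopifnot(inherits(mesh, "avf_mesh"))
  solid <- mesh$solid
  fr <- mesh$frame
  dref <- if (!is.null(solid$params$d_cv)) solid$params$d_cv else solid$d_ref
  if (is.null(offset)) offset <- 0.5 * dref
  angles <- (seq_len(n_wss) - 1L) * 2 * pi / n_wss
  rmax_ray <- 1.5 * dref
  ring_ok_r <- 0.75 * dref          # a closed section ring stays this tight

  ring_cross <- function(c0) {
    vapply(angles, function(a) {
      dirv <- cos(a) * fr$x_axis + sin(a) * fr$z_axis
      tt <- seq(0, rmax_ray, by = mesh$h / 5)
      pp <- outer(tt, dirv) + rep(c0, each = length(tt))
      ph <- solid$fn(pp[, 1], pp[, 2], pp[, 3], caps = mesh$caps)
      out1 <- which(ph >= 0)
      if (length(out1)) tt[out1[1]] else rmax_ray
    }, 0)
  }
  # slide S1 outward until its wall ring closes
  for (k in 0:8) {
    off_k <- offset + k * 0.25 * dref
    c0 <- fr$origin + off_k * fr$y_axis
    tcross <- ring_cross(c0)
    if (all(tcross <= ring_ok_r)) break
  }
  offset <- off_k

  # lumen chord along the in-plane x-axis (inner edge: -x side)
  s <- seq(-1.5 * dref, 1.5 * dref, by = mesh$h / 5)
  pts <- outer(s, fr$x_axis) + rep(c0, each = length(s))
  inside <- solid$fn(pts[, 1], pts[, 2], pts[, 3], caps = mesh$caps) < 0
  if (!any(inside)) stop("S1 plane does not intersect the lumen")
  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  mid <- which.min(abs(s))
  pick <- cand[vapply(cand, function(r) starts[r] <= mid && mid <= ends[r],
                      TRUE)]
  if (!length(pick)) pick <- cand[which.max(runs$lengths[cand])]
  smin <- s[starts[pick[1]]]; smax <- s[ends[pick[1]]]
  svals <- smin + seq_len(n_vel) * (smax - smin) / (n_vel + 1)
  vel_points <- outer(svals, fr$x_axis) + rep(c0, each = n_vel)

  # wall ring probes: nearest wall facets to the ray crossings
  wall_rows <- which(mesh$facets$tag == "WALL")
  fw <- mesh$facets[wall_rows, ]
  wss_points <- matrix(NA_real_, n_wss, 3)
  rows <- integer(n_wss)
  for (j in seq_len(n_wss)) {
    dirv <- cos(angles[j]) * fr$x_axis + sin(angles[j]) * fr$z_axis
    wp <- c0 + tcross[j] * dirv
    wss_points[j, ] <- wp
    d2 <- (fw$cx - wp[1])^2 + (fw$cy - wp[2])^2 + (fw$cz - wp[3])^2
    rows[j] <- wall_rows[which.min(d2)]
  }
  outer_half <- which(cos(angles) > 1e-9)
  inner_half <- which(cos(angles) < -1e-9)
  structure(list(center = c0, frame = fr, offset = offset,
                 vel_points = vel_points, vel_s = svals,
                 wss_rows = rows, wss_points = wss_points,
                 angles = angles,
                 outer_row = rows[1],
                 inner_row = rows[which.min(abs(angles - pi))],
                 outer_half = outer_half, inner_half = inner_half),
            class = "avf_probes")
}

# trilinear interpolation of a cell-centred field (solid cells read as 0)
interp_cell_field <- function(mesh, U, pts) {
  dims <- mesh$dims; h <- mesh$h
  g <- sweep(pts, 2, mesh$x0, "-") / h - 0.5   # 0-based cell-centre coords
  i0 <- floor(g)
  fr <- g - i0
  out <- matrix(0, nrow(pts), ncol(U))
  getval <- function(ii, jj, kk) {
    ok <- ii >= 0 & jj >= 0 & kk >= 0 & ii < dims[1] & jj < dims[2] &
      kk < dims[3]
    ids <- integer(length(ii))
    lin <- (ii + 1L) + dims[1] * (jj + dims[2] * kk)
    ids[ok] <- mesh$cellid[lin[ok]]
    V <- matrix(0, length(ii), ncol(U))
    hasid <- ids > 0L
    V[hasid, ] <- U[ids[hasid], , drop = FALSE]
    V
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wgt <- (dx * fr[, 1] + (1 - dx) * (1 - fr[, 1])) *
           (dy * fr[, 2] + (1 - dy) * (1 - fr[, 2])) *
           (dz * fr[, 3] + (1 - dz) * (1 - fr[, 3]))
    out <- out + wgt * getval(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)
  }
  out
}

probe_velocities <- function(mesh, U, probes) {
  interp_cell_field(mesh, U, probes$vel_points)
}

probe_wss_vectors <- function(mesh, U, probes, mu) {
  wss_at_facets(mesh, U, probes$wss_rows, mu)
}

#' Extract probe time series from a flow solution
#'
#' For transient solutions run with `probes=`, returns the recorded series;
#' for steady solutions, the instantaneous probe values. Axial components
#' are projections on the proximal-vein axis (the frame y-axis).
#'
#' @param solution an `avf_flow`.
#' @param mesh the mesh the solution was computed on.
#' @param probes an [probe_set()]; required for steady solutions (for
#'   transient runs the recorded probe set is used).
#' @return an `avf_probe_series`: time vector, axial velocity matrix
#'   (time x probe), WSS magnitude and axial-component matrices.
#' @export
probe_series <- function(solution, mesh, probes = NULL) {
  stopifnot(inherits(solution, "avf_flow"))
  if (solution$mode == "transient" && !is.null(solution$probe_series)) {
    probes <- solution$probes
    rec <- solution$probe_series
    ax <- probes$frame$y_axis
    vel <- t(vapply(rec$vel, function(m) as.numeric(m %*% ax),
                    numeric(nrow(probes$vel_points))))
    wmag <- t(vapply(rec$wss, function(d) d$mag,
                     numeric(length(probes$wss_rows))))
    wax <- t(vapply(rec$wss, function(d)
      d$tau_x * ax[1] + d$tau_y * ax[2] + d$tau_z * ax[3],
      numeric(length(probes$wss_rows))))
    out <- list(t = rec$t, vel_axial = vel, wss_mag = wmag, wss_axial = wax,
                probes = probes)
  } else {
    if (is.null(probes)) stop("probes must be supplied for steady solutions")
    ax <- probes$frame$y_axis
    U <- solution$fields[[1]]$U
    vel <- matrix(as.numeric(probe_velocities(mesh, U, probes) %*% ax),
                  nrow = 1)
    wv <- probe_wss_vectors(mesh, U, probes, solution$fluid$viscosity)
    out <- list(t = 0, vel_axial = vel,
                wss_mag = matrix(wv$mag, nrow = 1),
                wss_axial = matrix(
                  wv$tau_x * ax[1] + wv$tau_y * ax[2] + wv$tau_z * ax[3],
                  nrow = 1),
                probes = probes)
  }
  class(out) <- "avf_probe_series"
  out
}

#' Classify a periodic probe signal
#'
#' `"reciprocating"` if the signed along-axis component changes sign within
#' the cycle; `"oscillating"` if the peak-to-trough excursion exceeds 50%
#' of the mean magnitude without a sign change; `"none"` otherwise
#' (including constant signals).
#'
#' @param series numeric vector: the signed along-axis component sampled
#'   over (at least) one cycle.
#' @return one of `"none"`, `"oscillating"`, `"reciprocating"`.
#' @examples
#' detect_reversal(sin(seq(0, 2 * pi, length.out = 50)))      # reciprocating
#' detect_reversal(1 + 0.8 * sin(seq(0, 2 * pi, length.out = 50)))
#' @export
detect_reversal <- function(series) {
  series <- as.numeric(series)
  rng <- range(series)
  tol <- 1e-12 * max(abs(rng), 1)
  if (diff(rng) <= tol) return("none")
  if (rng[1] < -tol && rng[2] > tol) return("reciprocating")
  m <- abs(mean(series))
  if (diff(rng) > 0.5 * m) "oscillating" else "none"
}
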