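# Voxel meshing of implicit solids.
#
# The solid is sampled on a uniform Cartesian grid (spacing h). Cells whose
# centre lies inside the lumen are fluid elements; boundary faces between
# fluid and non-fluid cells form the tagged, watertight boundary. Port cap
# planes are snapped onto grid face planes (extensions are rounded up by at
# most one pitch), so every inlet/outlet patch is exactly planar with an
# axis-aligned normal. Three layers of "ghost" cells are kept beyond each
# port plane to carry boundary values for the solver. Sub-voxel wall
# geometry is retained through the sampled implicit field: wall-crossing
# fractions (theta) and implicit-gradient normals give near-wall distances,
# facet normals and normal-corrected facet areas (a stair-step facet of
# projected area h^2 represents a true wall patch of area h^2 / |n|_1).

mesh_levels <- c(coarse = 8, medium = 10, fine = 12, full = 13.4)

#' Voxelize a solid into a tagged simulation mesh
#'
#' @param solid an `avf_solid` from [build_avf()] or
#'   [build_straight_tube()].
#' @param level mesh resolution: `"coarse"`, `"medium"`, `"fine"` or
#'   `"full"` (cells across the reference diameter: 8, 10, 12, 13.4; for the
#'   default AVF the `"full"` level lands at the ~0.12 million elements of a
#'   grid-independent solution), or a numeric element size h in m.
#' @param n_ghost ghost-cell layers beyond each port plane (default 3).
#' @return an `avf_mesh`: cell codes and fluid numbering, sampled implicit
#'   fields at cell and face centres, the boundary-facet table with tags,
#'   normals, thetas and corrected areas, and per-port summaries.
#' @export
mesh_domain <- function(solid, level = "coarse", n_ghost = 3L) {
  stopifnot(inherits(solid, "avf_solid"))
  if (is.character(level)) {
    if (!level %in% names(mesh_levels)) {
      stop("level must be one of ", paste(names(mesh_levels), collapse = ", "),
           " or a numeric h")
    }
    h <- solid$d_ref / mesh_levels[[level]]
  } else {
    h <- as.numeric(level)
    level <- "custom"
    if (!is.finite(h) || h <= 0) stop("numeric mesh size h must be positive")
  }

  ports <- solid$ports
  plane_x <- vapply(ports, `[[`, 0, "x_plane")
  dirs <- vapply(ports, `[[`, 0L, "dir")
  # snap port planes to the grid anchored at the first port plane,
  # rounding each extension outward (away from the interior)
  xa <- plane_x[1]
  snap <- function(x, dir) xa + (if (dir > 0) -1 else 1) *
    ceiling(round((xa - x) * (if (dir > 0) 1 else -1) / h, 6)) * h
  plane_snap <- vapply(seq_along(ports), function(i) {
    if (i == 1) xa else snap(plane_x[i], dirs[i])
  }, 0)
  caps <- solid$caps
  cap_names <- names(caps)
  caps_snap <- setNames(plane_snap[seq_along(cap_names)], cap_names)

  # grid extents: ghost layers beyond the outermost port planes in x,
  # padding elsewhere
  xlo <- min(plane_snap[dirs > 0]) - n_ghost * h
  xhi <- max(plane_snap[dirs < 0]) + n_ghost * h
  nx <- as.integer(round((xhi - xlo) / h))
  ylo <- floor((solid$bbox$y[1]) / h) * h - h
  nyc <- as.integer(ceiling((solid$bbox$y[2] - ylo) / h)) + 1L
  nzh <- as.integer(ceiling(max(abs(solid$bbox$z)) / h)) + 1L
  zlo <- -nzh * h
  nz <- 2L * nzh
  x0 <- c(xlo, ylo, zlo)
  dims <- c(nx, nyc, nz)

  xc <- xlo + (seq_len(nx) - 0.5) * h
  yc <- ylo + (seq_len(nyc) - 0.5) * h
  zc <- zlo + (seq_len(nz) - 0.5) * h
  xf <- xlo + (0:nx) * h
  yf <- ylo + (0:nyc) * h
  zf <- zlo + (0:nz) * h

  eval_grid <- function(gx, gy, gz) {
    pts <- expand.grid(x = gx, y = gy, z = gz, KEEP.OUT.ATTRS = FALSE)
    array(solid$fn(pts$x, pts$y, pts$z, caps = caps_snap),
          dim = c(length(gx), length(gy), length(gz)))
  }
  phi_c <- eval_grid(xc, yc, zc)
  phi_u <- eval_grid(xf, yc, zc)
  phi_v <- eval_grid(xc, yf, zc)
  phi_w <- eval_grid(xc, yc, zf)

  cellcode <- array(1L, dim = dims)          # 1 = solid
  cellcode[phi_c < 0] <- 0L                  # 0 = fluid
  # ghost regions beyond each port plane, within the port cross-section
  for (p in seq_along(ports)) {
    po <- ports[[p]]
    xp <- plane_snap[p]
    if (po$dir > 0) ix <- which(xc < xp & xc > xp - (n_ghost + 0.5) * h)
    else ix <- which(xc > xp & xc < xp + (n_ghost + 0.5) * h)
    lat <- outer(yc, zc, po$profile)
    inside <- which(lat < 0, arr.ind = TRUE)
    for (i in ix) {
      cellcode[cbind(i, inside)] <- 2L + (p - 1L)
    }
  }

  nfl <- sum(cellcode == 0L)
  cellid <- array(0L, dim = dims)
  cellid[cellcode == 0L] <- seq_len(nfl)

  facets <- extract_facets(cellcode, cellid, phi_c, x0, h, ports)
  port_tab <- data.frame(
    name = vapply(ports, `[[`, "", "name"),
    x_plane = plane_snap,
    dir = dirs,
    radius = vapply(ports, `[[`, 0, "radius"),
    area = vapply(ports, `[[`, 0, "area"),
    area_mesh = vapply(vapply(ports, `[[`, "", "name"), function(nm) {
      sum(facets$tag == nm) * h^2
    }, 0),
    code = 2L + seq_along(ports) - 1L,
    stringsAsFactors = FALSE)

  m <- structure(list(h = h, x0 = x0, dims = dims, level = level,
                      caps = caps_snap,
                      cellcode = cellcode, cellid = cellid,
                      n_elements = nfl,
                      phi_c = phi_c, phi_u = phi_u, phi_v = phi_v,
                      phi_w = phi_w,
                      facets = facets, ports = port_tab,
                      solid = solid, frame = solid$frame),
                 class = "avf_mesh")
  if (any(is.na(facets$tag))) stop("untagged boundary facets present")
  m
}

# shift a 3D array by one cell along an axis, padding the vacated slab;
# shift_arr(a, ax, +1, pad)[i] == a[i + e_ax] (the +side neighbour's value)
shift_arr <- function(a, axis, side, pad) {
  out <- array(pad, dim = dim(a))
  n <- dim(a)[axis]
  src <- lapply(dim(a), seq_len)
  dst <- src
  if (side > 0) { src[[axis]] <- 2:n; dst[[axis]] <- 1:(n - 1) }
  else { src[[axis]] <- 1:(n - 1); dst[[axis]] <- 2:n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# shift by an arbitrary offset: shift_n(a, ax, by)[i] == a[i + by * e_ax]
shift_n <- function(a, axis, by, pad) {
  out <- array(pad, dim = dim(a))
  n <- dim(a)[axis]
  src <- dst <- lapply(dim(a), seq_len)
  if (by > 0) { src[[axis]] <- (1 + by):n; dst[[axis]] <- 1:(n - by) }
  else { src[[axis]] <- 1:(n + by); dst[[axis]] <- (1 - by):n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# boundary facet extraction: fluid cells with a non-fluid axis neighbour
extract_facets <- function(cellcode, cellid, phi_c, x0, h, ports) {
  dims <- dim(cellcode)
  # central-difference gradient of phi at cell centres (one-sided at box rim)
  grad <- lapply(1:3, function(ax) {
    (shift_arr(phi_c, ax, +1, NA) - shift_arr(phi_c, ax, -1, NA)) / (2 * h)
  })
  port_names <- vapply(ports, `[[`, "", "name")

  res <- list()
  fluid <- cellcode == 0L
  for (ax in 1:3) for (sd in c(-1L, 1L)) {
    nb_code <- shift_arr(cellcode, ax, sd, 1L)
    nb_phi <- shift_arr(phi_c, ax, sd, NA)
    sel <- which(fluid & nb_code != 0L)
    if (!length(sel)) next
    idx <- arrayInd(sel, dims)
    cx <- x0[1] + (idx[, 1] - 0.5) * h
    cy <- x0[2] + (idx[, 2] - 0.5) * h
    cz <- x0[3] + (idx[, 3] - 0.5) * h
    fc <- cbind(cx, cy, cz)
    fc[, ax] <- fc[, ax] + sd * h / 2
    code <- nb_code[sel]
    tag <- ifelse(code >= 2L, port_names[pmax(code - 1L, 1L)], "WALL")
    phf <- phi_c[sel]; phn <- nb_phi[sel]
    theta <- ifelse(is.finite(phn) & (phn - phf) > 0,
                    phf / (phf - phn), 0.5)
    theta <- pmin(pmax(theta, 0.05), 1)
    gx <- grad[[1]][sel]; gy <- grad[[2]][sel]; gz <- grad[[3]][sel]
    gn <- sqrt(gx^2 + gy^2 + gz^2)
    bad <- !is.finite(gn) | gn < 1e-12
    if (any(bad)) {   # fall back to the facet axis direction
      gx[bad] <- gy[bad] <- gz[bad] <- 0
      if (ax == 1) gx[bad] <- sd else if (ax == 2) gy[bad] <- sd
      else gz[bad] <- sd
      gn[bad] <- 1
    }
    nxv <- gx / gn; nyv <- gy / gn; nzv <- gz / gn
    n1 <- abs(nxv) + abs(nyv) + abs(nzv)
    area <- ifelse(tag == "WALL", h^2 / n1, h^2)
    # second fluid cell away from the wall, for two-point WSS gradients
    idx2 <- idx
    idx2[, ax] <- idx2[, ax] - sd
    ok2 <- idx2[, ax] >= 1 & idx2[, ax] <= dims[ax]
    id2 <- integer(nrow(idx))
    id2[ok2] <- cellid[idx2[ok2, , drop = FALSE]]
    res[[length(res) + 1L]] <- data.frame(
      cell = sel, id = cellid[sel], axis = ax, side = sd, tag = tag,
      cx = fc[, 1], cy = fc[, 2], cz = fc[, 3],
      nx = nxv, ny = nyv, nz = nzv, theta = theta, area = area,
      id2 = id2, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Mesh summaries
#'
#' `domain_volume()` integrates the fluid volume with a first-order
#' sub-voxel correction from the implicit field; `wall_area()` sums the
#' normal-corrected wall facet areas; `port_areas()` returns analytic and
#' meshed port areas; `check_watertight()` verifies that the tagged
#' boundary closes (the outward facet normals of a closed surface sum to
#' zero) and that every facet carries exactly one tag.
#'
#' @param mesh an `avf_mesh`.
#' @return `domain_volume()`/`wall_area()`: scalar (m^3 / m^2);
#'   `port_areas()`: data.frame; `check_watertight()`: `TRUE` (or an error).
#' @export
domain_volume <- function(mesh) {
  stopifnot(inherits(mesh, "avf_mesh"))
  h <- mesh$h
  # first-order partial-volume fractions; near-wall cells on both sides of
  # the interface contribute, ghost cells beyond the port planes do not
  frac <- pmin(pmax(0.5 - mesh$phi_c[mesh$cellcode <= 1L] / h, 0), 1)
  sum(frac) * h^3
}

#' @rdname domain_volume
#' @export
wall_area <- function(mesh) {
  sum(mesh$facets$area[mesh$facets$tag == "WALL"])
}

#' @rdname domain_volume
#' @export
port_areas <- function(mesh) mesh$ports[c("name", "area", "area_mesh")]

#' @rdname domain_volume
#' @export
check_watertight <- function(mesh) {
  f <- mesh$facets
  if (any(is.na(f$tag))) stop("boundary facet without a tag")
  for (ax in 1:3) {
    s <- sum(f$side[f$axis == ax])
    if (s != 0) stop("boundary is not closed along axis ", ax)
  }
  # ports must be planar: one face-plane coordinate per port
  for (nm in mesh$ports$name) {
    sel <- f$tag == nm
    if (any(sel)) {
      xs <- unique(round(f$cx[sel] / mesh$h, 6))
      if (length(xs) != 1L) stop("port ", nm, " is not planar")
    }
  }
  TRUE
}

#' @export
print.avf_mesh <- function(x, ...) {
  cat(sprintf(
    "<avf_mesh> %s h=%.3g mm, %d x %d x %d box, %d fluid elements\n",
    x$level, x$h * 1e3, x$dims[1], x$dims[2], x$dims[3], x$n_elements))
  print(x$ports[c("name", "x_plane", "area", "area_mesh")])
  invisible(x)
}
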