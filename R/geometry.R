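# Parametric idealized end-to-side AVF lumen.
#
# Internal coordinates: the radial artery runs along +x with the PRA axis at
# (y, z) = (0, 0); blood enters at the -x end. The PRA (d = 3.0 mm) and DRA
# (d = 1.2 mm) are collinear with their outer (floor, -y) edges aligned, so
# the DRA axis is offset to y = -(R_pra - R_dra); a smoothstep taper joins
# them just downstream of the anastomotic opening. The cephalic vein leaves
# the artery top at the anastomosis angle and doubles back: its distal
# segment runs antiparallel to the PRA inflow, parallel with the artery, as
# in a radiocephalic fistula where the vein carries flow back up the
# forearm. The junction is blended with a smooth-minimum fillet of radius
# spline_smoothness * d_cv (tangent to both vessel walls, no sharp interior
# corner). The z = 0 plane is the symmetry plane.

#' Parameters of the idealized end-to-side AVF
#'
#' @param d_pra,d_dra,d_cv lumen diameters in m (defaults 3.0, 1.2, 5.0 mm).
#' @param angle_deg anastomosis angle between vein and artery in degrees
#'   (default 45; must satisfy 0 < angle <= 90).
#' @param ext_pra,ext_dra,ext_cv development-extension lengths in multiples
#'   of the local diameter (default 10, minimum 5): finite stand-ins for the
#'   original "infinite" port conditions.
#' @param spline_smoothness blend radius of the anastomotic fillet as a
#'   fraction of `d_cv` (default 0.25).
#' @return validated `avf_params` object.
#' @export
avf_params <- function(d_pra = 3.0e-3, d_dra = 1.2e-3, d_cv = 5.0e-3,
                       angle_deg = 45,
                       ext_pra = 10, ext_dra = 10, ext_cv = 10,
                       spline_smoothness = 0.25) {
  p <- list(d_pra = d_pra, d_dra = d_dra, d_cv = d_cv,
            angle_deg = angle_deg, ext_pra = ext_pra, ext_dra = ext_dra,
            ext_cv = ext_cv, spline_smoothness = spline_smoothness)
  if (any(c(d_pra, d_dra, d_cv) <= 0)) stop("diameters must be positive")
  if (!(d_dra < d_pra)) stop("DRA diameter must be smaller than PRA diameter")
  if (!(d_pra <= d_cv)) stop("PRA diameter must not exceed CV diameter")
  if (!(angle_deg > 0 && angle_deg <= 90)) {
    stop("anastomosis angle must satisfy 0 < angle <= 90 degrees")
  }
  if (any(c(ext_pra, ext_dra, ext_cv) < 5)) {
    stop("development extensions must be at least 5 diameters")
  }
  if (spline_smoothness <= 0 || spline_smoothness > 1) {
    stop("spline_smoothness must be in (0, 1]")
  }
  class(p) <- "avf_params"
  p
}

# polynomial smooth minimum: C1 blend of two implicit surfaces, fillet
# radius ~k; reduces to min() when the surfaces are further apart than k
smooth_min <- function(a, b, k) {
  h <- pmin(pmax(0.5 + 0.5 * (b - a) / k, 0), 1)
  b * (1 - h) + a * h - k * h * (1 - h)
}

# distance from points to a 3D segment p0-p1 (both in the z = 0 plane)
dist_segment <- function(x, y, z, p0, p1) {
  dx <- p1[1] - p0[1]; dy <- p1[2] - p0[2]
  l2 <- dx * dx + dy * dy
  t <- pmin(pmax(((x - p0[1]) * dx + (y - p0[2]) * dy) / l2, 0), 1)
  sqrt((x - (p0[1] + t * dx))^2 + (y - (p0[2] + t * dy))^2 + z^2)
}

# distance to a circular arc in the z = 0 plane, centre cc, radius r,
# angular span [a0, a1] (a1 > a0, measured CCW)
dist_arc <- function(x, y, z, cc, r, a0, a1) {
  vx <- x - cc[1]; vy <- y - cc[2]
  ang <- pmin(pmax(atan2(vy, vx), a0), a1)
  nx <- cc[1] + r * cos(ang); ny <- cc[2] + r * sin(ang)
  sqrt((x - nx)^2 + (y - ny)^2 + z^2)
}

# all derived geometric constants of the AVF solid
avf_geom <- function(p) {
  beta <- p$angle_deg * pi / 180
  rp <- p$d_pra / 2; rd <- p$d_dra / 2; rv <- p$d_cv / 2
  u1 <- c(-cos(beta), sin(beta))           # proximal-vein direction
  a0 <- c(0, 0)                            # vein centreline start (on PRA axis)
  o <- c(-rp / tan(beta), rp)              # anastomosis centre (opening)
  half_open <- rv / sin(beta)              # opening half-extent along x
  taper_x0 <- o[1] + half_open + 0.5 * p$d_pra
  taper_x1 <- taper_x0 + 1.5 * p$d_pra
  y_dra <- -(rp - rd)                      # aligned outer (floor) edges
  x_in <- o[1] - half_open - p$ext_pra * p$d_pra
  x_dra <- taper_x1 + p$ext_dra * p$d_dra
  s1 <- rp / sin(beta) + 1.2 * p$d_cv      # straight 45-degree vein segment
  p1 <- a0 + s1 * u1
  r_b <- 1.6 * p$d_cv                      # bend radius to parallel course
  cc <- p1 + r_b * c(-sin(beta), -cos(beta))  # bend centre (left of heading)
  arc0 <- pi / 2 - beta; arc1 <- pi / 2       # CCW angular span of the bend
  p2 <- cc + r_b * c(cos(arc1), sin(arc1))    # start of the parallel segment
  x_cv <- p2[1] - p$ext_cv * p$d_cv
  p3 <- c(x_cv, p2[2])
  k <- p$spline_smoothness * p$d_cv
  list(beta = beta, rp = rp, rd = rd, rv = rv, u1 = u1, origin = o,
       half_open = half_open, taper_x0 = taper_x0, taper_x1 = taper_x1,
       y_dra = y_dra, x_in = x_in, x_dra = x_dra, x_cv = x_cv,
       p0 = a0, p1 = p1, p2 = p2, p3 = p3, cc = cc, r_b = r_b,
       arc0 = arc0, arc1 = arc1, k = k)
}

# lateral (uncapped) implicit functions; negative inside the lumen
artery_lateral <- function(g, x, y, z) {
  t <- pmin(pmax((x - g$taper_x0) / (g$taper_x1 - g$taper_x0), 0), 1)
  s <- t * t * (3 - 2 * t)
  r <- g$rp + (g$rd - g$rp) * s
  yc <- g$y_dra * s
  sqrt((y - yc)^2 + z^2) - r
}

vein_lateral <- function(g, x, y, z) {
  d <- pmin(dist_segment(x, y, z, g$p0, g$p1),
            dist_arc(x, y, z, g$cc, g$r_b, g$arc0, g$arc1))
  d <- pmin(d, dist_segment(x, y, z, g$p2, g$p3))
  d - g$rv
}

#' Build the parametric AVF solid
#'
#' Constructs the implicit (signed-distance-like) description of the lumen:
#' collinear PRA/DRA with aligned outer edges, the cephalic vein departing
#' at the anastomosis angle with its distal segment parallel to the artery,
#' and a smooth fillet at the junction. The anastomosis frame (origin at the
#' opening centre, y-axis along the proximal vein, x-axis toward the outer
#' anastomosis edge, right-handed z) is attached.
#'
#' @param params an [avf_params()] object.
#' @return an `avf_solid`: implicit function `fn(x, y, z, caps)`, port
#'   descriptors, the frame, a bounding box and the blend radius.
#' @export
build_avf <- function(params = avf_params()) {
  stopifnot(inherits(params, "avf_params"))
  g <- avf_geom(params)
  caps0 <- c(x_in = g$x_in, x_dra = g$x_dra, x_cv = g$x_cv)
  fn <- function(x, y, z, caps = caps0) {
    fa <- pmax(artery_lateral(g, x, y, z), caps[["x_in"]] - x,
               x - caps[["x_dra"]])
    fv <- pmax(vein_lateral(g, x, y, z), caps[["x_cv"]] - x)
    smooth_min(fa, fv, g$k)
  }
  beta <- g$beta
  frame <- list(origin = c(g$origin, 0),
                x_axis = c(sin(beta), cos(beta), 0),
                y_axis = c(g$u1, 0),
                z_axis = c(0, 0, 1))
  ports <- list(
    list(name = "PRA_INLET", x_plane = g$x_in, dir = +1L,
         center = c(g$x_in, 0, 0), radius = g$rp,
         area = pi * g$rp^2,
         profile = function(y, z) sqrt(y^2 + z^2) - g$rp),
    list(name = "DRA_END", x_plane = g$x_dra, dir = -1L,
         center = c(g$x_dra, g$y_dra, 0), radius = g$rd,
         area = pi * g$rd^2,
         profile = function(y, z) sqrt((y - g$y_dra)^2 + z^2) - g$rd),
    list(name = "CV_OUTLET", x_plane = g$x_cv, dir = +1L,
         center = c(g$x_cv, g$p2[2], 0), radius = g$rv,
         area = pi * g$rv^2,
         profile = function(y, z) sqrt((y - g$p2[2])^2 + z^2) - g$rv))
  pad <- max(2 * g$k, 2e-3)
  bbox <- list(x = c(g$x_cv, g$x_dra),
               y = c(-g$rp - pad, g$p2[2] + g$rv + pad),
               z = c(-g$rv - pad, g$rv + pad))
  structure(list(kind = "avf", params = params, geom = g, fn = fn,
                 caps = caps0, ports = ports, frame = frame, bbox = bbox,
                 d_ref = params$d_pra, blend = g$k),
            class = "avf_solid")
}

#' Build a straight-tube benchmark solid
#'
#' A single cylindrical lumen along x with `INLET`/`OUTLET`/`WALL` tags,
#' used for the Poiseuille and Womersley solver oracles.
#'
#' @param d diameter in m.
#' @param length tube length in m.
#' @return an `avf_solid` of kind `"tube"`.
#' @export
build_straight_tube <- function(d = 3.0e-3, length = 30e-3) {
  if (d <= 0 || length <= 0) stop("tube dimensions must be positive")
  r <- d / 2
  caps0 <- c(x_in = 0, x_out = length)
  fn <- function(x, y, z, caps = caps0) {
    pmax(sqrt(y^2 + z^2) - r, caps[["x_in"]] - x, x - caps[["x_out"]])
  }
  ports <- list(
    list(name = "INLET", x_plane = 0, dir = +1L, center = c(0, 0, 0),
         radius = r, area = pi * r^2,
         profile = function(y, z) sqrt(y^2 + z^2) - r),
    list(name = "OUTLET", x_plane = length, dir = -1L,
         center = c(length, 0, 0), radius = r, area = pi * r^2,
         profile = function(y, z) sqrt(y^2 + z^2) - r))
  pad <- 1e-3
  frame <- list(origin = c(length / 2, 0, 0),
                x_axis = c(0, -1, 0), y_axis = c(1, 0, 0),
                z_axis = c(0, 0, 1))
  structure(list(kind = "tube", params = list(d = d, length = length),
                 fn = fn, caps = caps0, ports = ports, frame = frame,
                 bbox = list(x = c(0, length), y = c(-r - pad, r + pad),
                             z = c(-r - pad, r + pad)),
                 d_ref = d, blend = 0),
            class = "avf_solid")
}

#' Evaluate a solid's implicit function
#'
#' Negative inside the lumen, positive outside; the zero level set is the
#' wall (and the port cap planes).
#'
#' @param solid an `avf_solid`.
#' @param x,y,z coordinates in m (vectors of equal length).
#' @return numeric vector of implicit values.
#' @export
solid_implicit <- function(solid, x, y, z) {
  stopifnot(inherits(solid, "avf_solid"))
  solid$fn(x, y, z)
}

#' @export
print.avf_solid <- function(x, ...) {
  cat(sprintf("<avf_solid> %s with ports: %s\n", x$kind,
              paste(vapply(x$ports, `[[`, "", "name"), collapse = ", ")))
  invisible(x)
}
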