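# Wall shear stress fields and thresholded-area metrics.
#
# WSS is reconstructed per wall facet from the tangential velocity at the
# adjacent cell centre (and, where available, the next cell into the
# lumen): with wall distances d1 < d2 along the facet axis projected onto
# the wall normal, the wall-tangential traction is
#   tau = mu * (u_t(d1) d2^2 - u_t(d2) d1^2) / (d1 d2 (d2 - d1)),
# the two-point wall-gradient formula that is exact for quadratic profiles
# (hence exact for Poiseuille flow). Facet membership in the low/high WSS
# areas uses the facet-averaged magnitude with ties counted low; facet
# areas are the stair-step areas corrected by the implicit-surface normal
# (a facet of projected area h^2 represents a wall patch h^2 / |n|_1).

wss_at_facets <- function(mesh, U, rows, mu) {
  f <- mesh$facets[rows, , drop = FALSE]
  h <- mesh$h
  nmat <- cbind(f$nx, f$ny, f$nz)
  # wall-normal distances straight from the (signed-distance-like) implicit
  # field at the two cell centres behind the facet
  phi_fl <- mesh$phi_c[mesh$cellcode == 0L]   # in fluid-id order
  d1 <- pmax(-mesh$phi_c[f$cell], 0.05 * h)
  U1 <- U[f$id, , drop = FALSE]
  un1 <- rowSums(U1 * nmat)
  t1 <- U1 - un1 * nmat
  grad <- t1 / d1
  ok2 <- f$id2 > 0L
  if (any(ok2)) {
    d2full <- rep(NA_real_, nrow(f))
    d2full[ok2] <- -phi_fl[f$id2[ok2]]
    usable <- ok2 & d2full > d1 + 0.2 * h
    # two-point quadratic fit where the first cell centre is a trustworthy
    # sample (not sitting on the wall itself)
    quad <- usable & d1 >= 0.3 * h
    if (any(quad)) {
      U2 <- U[f$id2[quad], , drop = FALSE]
      n2 <- nmat[quad, , drop = FALSE]
      t2 <- U2 - rowSums(U2 * n2) * n2
      a <- d1[quad]; b <- d2full[quad]
      grad[quad, ] <- (t1[quad, , drop = FALSE] * b^2 - t2 * a^2) /
        (a * b * (b - a))
    }
    # cell centre on the wall: its velocity over a near-zero distance only
    # amplifies noise; fit through the second and third cells instead
    lin2 <- usable & d1 < 0.3 * h
    if (any(lin2)) {
      U2 <- U[f$id2[lin2], , drop = FALSE]
      n2 <- nmat[lin2, , drop = FALSE]
      t2 <- U2 - rowSums(U2 * n2) * n2
      grad[lin2, ] <- t2 / d2full[lin2]
      stride <- c(1L, mesh$dims[1], mesh$dims[1] * mesh$dims[2])
      cell3 <- f$cell[lin2] - 2L * f$side[lin2] * stride[f$axis[lin2]]
      inb <- cell3 >= 1L & cell3 <= length(mesh$cellid)
      id3 <- integer(sum(lin2))
      id3[inb] <- mesh$cellid[cell3[inb]]
      d3 <- rep(NA_real_, sum(lin2))
      d3[id3 > 0L] <- -phi_fl[id3[id3 > 0L]]
      q3 <- id3 > 0L & !is.na(d3) & d3 > d2full[lin2] + 0.2 * h
      if (any(q3)) {
        sel3 <- which(lin2)[q3]
        U3 <- U[id3[q3], , drop = FALSE]
        n3 <- nmat[sel3, , drop = FALSE]
        t3 <- U3 - rowSums(U3 * n3) * n3
        a <- d2full[sel3]; b <- d3[q3]
        grad[sel3, ] <- (t2[q3, , drop = FALSE] * b^2 - t3 * a^2) /
          (a * b * (b - a))
      }
    }
  }
  tau <- mu * grad
  data.frame(tau_x = tau[, 1], tau_y = tau[, 2], tau_z = tau[, 3],
             mag = sqrt(rowSums(tau^2)))
}

#' Compute the wall shear stress field of a flow solution
#'
#' @param solution an `avf_flow` from [solve_steady()] or
#'   [solve_transient()].
#' @param mesh the `avf_mesh` the solution was computed on.
#' @param mu dynamic viscosity in Pa s (default: the solution's fluid).
#' @param instant index of the stored instant to process (default 1).
#' @return a `avf_wss` data.frame over WALL facets: position, corrected
#'   facet area, outward normal, WSS vector (Pa) and magnitude, with the
#'   solution time as attribute `t`.
#' @export
compute_wss <- function(solution, mesh, mu = NULL, instant = 1L) {
  stopifnot(inherits(solution, "avf_flow"), inherits(mesh, "avf_mesh"))
  if (is.null(mu)) mu <- solution$fluid$viscosity
  rows <- which(mesh$facets$tag == "WALL")
  if (!length(rows)) stop("mesh carries no WALL facets")
  U <- solution$fields[[instant]]$U
  tau <- wss_at_facets(mesh, U, rows, mu)
  f <- mesh$facets[rows, c("cx", "cy", "cz", "area", "nx", "ny", "nz",
                           "axis", "side")]
  out <- cbind(f, tau)
  class(out) <- c("avf_wss", "data.frame")
  attr(out, "t") <- if (length(solution$instants) >= instant)
    solution$instants[[instant]] else NA
  attr(out, "total_wall_area") <- sum(f$area)
  attr(out, "h") <- mesh$h
  out
}

#' Wall area where the WSS magnitude passes a threshold
#'
#' Facet-averaged magnitudes decide membership; ties (magnitude equal to
#' the threshold) satisfy both `"le"` and `"ge"`, so the low-WSS area at
#' 1 Pa counts boundary facets as low.
#'
#' @param field an `avf_wss` field.
#' @param comparator `"le"` (at or below) or `"ge"` (at or above).
#' @param threshold WSS threshold in Pa (>= 0).
#' @return area in m^2.
#' @export
thresholded_area <- function(field, comparator = c("le", "ge"),
                             threshold = 1) {
  comparator <- match.arg(comparator)
  stopifnot(inherits(field, "avf_wss"), threshold >= 0)
  keep <- if (comparator == "le") field$mag <= threshold
          else field$mag >= threshold
  sum(field$area[keep])
}

#' Summarize a WSS field into the standard thresholded-area metrics
#'
#' Low (<= 1 Pa), high (>= 10 Pa) and maximum (>= 20 Pa) WSS wall areas.
#'
#' @param field an `avf_wss` field.
#' @param low,high,max thresholds in Pa.
#' @return an `avf_area_metrics` list: `low_area`, `high_area`,
#'   `max_area`, `total_area` (m^2), thresholds and time.
#' @export
area_metrics <- function(field, low = 1, high = 10, max = 20) {
  structure(list(low_area = thresholded_area(field, "le", low),
                 high_area = thresholded_area(field, "ge", high),
                 max_area = thresholded_area(field, "ge", max),
                 total_area = sum(field$area),
                 thresholds = c(low = low, high = high, max = max),
                 t = attr(field, "t")),
            class = "avf_area_metrics")
}

#' Low-WSS area normalized by the clinical reference case
#'
#' @param case an `avf_area_metrics` for the case of interest.
#' @param reference an `avf_area_metrics` for the clinical reference case
#'   computed under the identical mesh and solver protocol.
#' @return dimensionless ratio (1 for the reference itself).
#' @export
normalized_low_wss <- function(case, reference) {
  stopifnot(inherits(case, "avf_area_metrics"),
            inherits(reference, "avf_area_metrics"))
  if (reference$low_area <= 0) stop("reference low-WSS area is zero")
  case$low_area / reference$low_area
}

#' Maximum WSS magnitude, optionally restricted to a wall region
#'
#' @param field an `avf_wss` field.
#' @param center,radius optional sphere (m) restricting the facets, e.g.
#'   the anastomosis region around the frame origin.
#' @return maximum facet WSS magnitude in Pa.
#' @export
max_wss <- function(field, center = NULL, radius = NULL) {
  stopifnot(inherits(field, "avf_wss"))
  m <- field$mag
  if (!is.null(center)) {
    d2 <- (field$cx - center[1])^2 + (field$cy - center[2])^2 +
      (field$cz - center[3])^2
    m <- m[d2 <= radius^2]
    if (!length(m)) stop("no wall facets inside the requested region")
  }
  max(m)
}

#' Oscillatory shear index over a set of WSS fields
#'
#' OSI = 0.5 (1 - |mean tau| / mean |tau|) per facet, a supplementary
#' diagnostic of direction-reversing shear (0: unidirectional, 0.5: purely
#' oscillatory). Assumes the fields sample the cycle uniformly.
#'
#' @param fields list of `avf_wss` fields on the same mesh/facets.
#' @return numeric vector of per-facet OSI values.
#' @export
oscillatory_shear_index <- function(fields) {
  stopifnot(length(fields) >= 2)
  tx <- rowMeans(sapply(fields, `[[`, "tau_x"))
  ty <- rowMeans(sapply(fields, `[[`, "tau_y"))
  tz <- rowMeans(sapply(fields, `[[`, "tau_z"))
  mmean <- rowMeans(sapply(fields, `[[`, "mag"))
  num <- sqrt(tx^2 + ty^2 + tz^2)
  osi <- 0.5 * (1 - num / pmax(mmean, 1e-300))
  pmin(pmax(osi, 0), 0.5)
}

#' @export
print.avf_area_metrics <- function(x, ...) {
  cat(sprintf(
    "<avf_area_metrics> low %.3g / high %.3g / max %.3g mm^2 (wall %.3g mm^2)\n",
    x$low_area * 1e6, x$high_area * 1e6, x$max_area * 1e6,
    x$total_area * 1e6))
  invisible(x)
}
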