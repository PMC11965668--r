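# Closed-form laminar pipe-flow references used to validate the solver.
# These are independent analytic results, not solver output.

#' Poiseuille flow references
#'
#' Steady laminar tube flow with mean velocity `v`: centreline velocity
#' 2 v, wall shear 8 mu v / d, and pressure drop 128 mu L Q / (pi d^4).
#'
#' @param v mean (bulk) velocity in m/s.
#' @param d tube diameter in m.
#' @param mu dynamic viscosity in Pa s.
#' @param L tube length in m.
#' @param Q volumetric rate in m^3/s.
#' @return the corresponding scalar reference value.
#' @export
poiseuille_centerline <- function(v) 2 * v

#' @rdname poiseuille_centerline
#' @export
poiseuille_wall_shear <- function(mu, v, d) 8 * mu * v / d

#' @rdname poiseuille_centerline
#' @export
poiseuille_pressure_drop <- function(mu, L, Q, d) 128 * mu * L * Q / (pi * d^4)

# Bessel J0 for complex argument by power series (|z| modest: the
# Womersley numbers here are ~2, well within fast convergence)
besselJ0_complex <- function(z) {
  s <- rep(1 + 0i, length(z))
  term <- rep(1 + 0i, length(z))
  z2 <- -(z * z) / 4
  for (k in seq_len(60)) {
    term <- term * z2 / (k * k)
    s <- s + term
    if (all(Mod(term) < 1e-18)) break
  }
  s
}

#' Analytic Womersley velocity profile
#'
#' Axial velocity of fully developed oscillatory tube flow driven by a
#' uniform axial body force (equivalently pressure gradient per unit mass)
#' `f(t) = amplitude * cos(omega t)`:
#' u(r, t) = Re\{ (A / (i w)) [1 - J0(lambda r) / J0(lambda R)] e^{i w t} \}
#' with lambda = i^{3/2} alpha / R and Womersley number
#' alpha = R sqrt(omega / nu).
#'
#' @param r radial positions in m (0 at the axis).
#' @param t time in s (scalar).
#' @param R tube radius in m.
#' @param nu kinematic viscosity in m^2/s.
#' @param omega angular frequency in rad/s.
#' @param amplitude body-force amplitude in m/s^2.
#' @return axial velocities in m/s at the positions `r`.
#' @export
womersley_axial_velocity <- function(r, t, R, nu, omega, amplitude) {
  alpha <- R * sqrt(omega / nu)
  lam <- exp(1i * 3 * pi / 4) * alpha / R
  uhat <- (amplitude / (1i * omega)) *
    (1 - besselJ0_complex(lam * r) / besselJ0_complex(lam * R)[1])
  Re(uhat * exp(1i * omega * t))
}

#' @rdname womersley_axial_velocity
#' @export
womersley_number <- function(R, nu, omega) R * sqrt(omega / nu)
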