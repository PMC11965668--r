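# Flow-redistribution case grid.
#
# After fistula creation the arterial inflow splits between the hand circuit
# (distal radial artery, DRA) and the low-resistance venous circuit
# (cephalic vein). Redistribution is modelled by four flow-rate-ratio
# families, each scaling the clinical reference flows by a coefficient
# epsilon:
#   g1: PRA scaled, DRA fixed, anterograde, eps in 0.7..1.3
#   g2: DRA scaled, PRA fixed, anterograde, eps in 0.7..1.3
#   g3: both scaled,           anterograde, eps in 0.7..1.3
#   g4: DRA reversed and scaled, PRA fixed, retrograde, eps in 0.1..0.5
# The clinical measurement itself (eps = 1, anterograde) is the reference
# case against which low-WSS areas are normalized.

#' Clinical reference volumetric flow rates
#'
#' Rates computed from the measured cycle-averaged velocities and diameters:
#' Q = v * pi d^2 / 4.
#'
#' @return list with `Q_PA`, `Q_DA` (m^3/s) and their ratio `Q_DA/Q_PA`.
#' @examples
#' reference_flows()$Q_PA # ~4.08e-6 m^3/s
#' @export
reference_flows <- function() {
  ref <- clinical_reference()
  q_pa <- ref$v_pra * pi * (ref$d_pra / 2)^2
  q_da <- ref$v_dra * pi * (ref$d_dra / 2)^2
  list(Q_PA = q_pa, Q_DA = q_da, ratio = q_da / q_pa)
}

#' A single flow-redistribution case
#'
#' @param family one of `"reference"`, `"g1"`, `"g2"`, `"g3"`, `"g4"`.
#' @param epsilon scaling coefficient (must belong to the family's set:
#'   0.7-1.3 for g1-g3, 0.1-0.5 for g4; 1 for the reference).
#' @param dt,n_cycles,mesh_level,mode solver protocol defaults carried with
#'   the case.
#' @return an `avf_case`: the family, epsilon, DRA direction, the scale
#'   factors applied to the PRA/DRA reference waveforms, and the protocol.
#' @export
case_config <- function(family = c("reference", "g1", "g2", "g3", "g4"),
                        epsilon = 1,
                        dt = 0.01, n_cycles = 3,
                        mesh_level = "coarse",
                        mode = c("steady_snapshot", "transient")) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  eps_ok <- switch(family,
    reference = 1,
    g1 = ,
    g2 = ,
    g3 = seq(0.7, 1.3, by = 0.1),
    g4 = seq(0.1, 0.5, by = 0.1))
  if (!any(abs(epsilon - eps_ok) < 1e-9)) {
    stop(sprintf("epsilon %.3g is not in the %s family set", epsilon, family))
  }
  dir <- if (family == "g4") "retrograde" else "anterograde"
  scales <- switch(family,
    reference = c(pra = 1, dra = 1),
    g1 = c(pra = epsilon, dra = 1),
    g2 = c(pra = 1, dra = epsilon),
    g3 = c(pra = epsilon, dra = epsilon),
    g4 = c(pra = 1, dra = epsilon))
  structure(list(family = family, epsilon = epsilon,
                 dra_direction = dir,
                 pra_scale = unname(scales["pra"]),
                 dra_scale = unname(scales["dra"]),
                 dt = dt, n_cycles = n_cycles,
                 mesh_level = mesh_level, mode = mode),
            class = "avf_case")
}

#' The full redistribution case matrix
#'
#' 26 scaled cases (7 + 7 + 7 anterograde families, 5 retrograde) plus the
#' clinical reference case, listed first.
#'
#' @inheritParams case_config
#' @return list of `avf_case` objects (length 27).
#' @export
case_matrix <- function(mesh_level = "coarse",
                        mode = c("steady_snapshot", "transient")) {
  mode <- match.arg(mode)
  cases <- list(case_config("reference", 1, mesh_level = mesh_level,
                            mode = mode))
  for (fam in c("g1", "g2", "g3")) {
    for (eps in seq(0.7, 1.3, by = 0.1)) {
      cases[[length(cases) + 1L]] <-
        case_config(fam, eps, mesh_level = mesh_level, mode = mode)
    }
  }
  for (eps in seq(0.1, 0.5, by = 0.1)) {
    cases[[length(cases) + 1L]] <-
      case_config("g4", eps, mesh_level = mesh_level, mode = mode)
  }
  cases
}

#' Case inlet waveforms
#'
#' The PRA and DRA waveforms of a case: the clinical reference pulses with
#' the case's epsilon scaling applied to the means (scaling a waveform's
#' mean scales its volumetric rate linearly and exactly).
#'
#' @param case an `avf_case`.
#' @return list with `pra` and `dra` waveforms (`avf_waveform`).
#' @export
case_waveforms <- function(case) {
  stopifnot(inherits(case, "avf_case"))
  ref <- clinical_reference()
  list(pra = synthesize_waveform(case$pra_scale * ref$v_pra, ref$period),
       dra = synthesize_waveform(case$dra_scale * ref$v_dra, ref$period))
}

#' @export
print.avf_case <- function(x, ...) {
  cat(sprintf("<avf_case> %s eps=%.2g (%s; PRA x%.2g, DRA x%.2g)\n",
              x$family, x$epsilon, x$dra_direction, x$pra_scale,
              x$dra_scale))
  invisible(x)
}

#' Export the case matrix as a table
#'
#' @param cases list of `avf_case` (default [case_matrix()]).
#' @param path optional CSV path; if `NULL` the data.frame is returned only.
#' @return data.frame mirroring the simulation condition grid (family,
#'   epsilon, PRA/DRA scale, DRA direction).
#' @export
case_table <- function(cases = case_matrix(), path = NULL) {
  df <- do.call(rbind, lapply(cases, function(cs) {
    data.frame(family = cs$family, epsilon = cs$epsilon,
               pra_scale = cs$pra_scale, dra_scale = cs$dra_scale,
               dra_direction = cs$dra_direction)
  }))
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
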