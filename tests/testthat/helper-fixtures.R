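# Shared heavy fixtures, built once per test run and cached across files.
# The "mini" AVF uses the minimum allowed development extensions (5 D) on
# the coarse grid: same physics, roughly half the elements of the default
# geometry, used for the CI-scale trend checks.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

mini_params <- function() avf_params(ext_pra = 5, ext_dra = 5, ext_cv = 5)

mini_mesh <- function() {
  fixture("mini_mesh", function() mesh_domain(build_avf(mini_params()),
                                              "coarse"))
}

# clinical reference case on the mini mesh (steady, mean-flow surrogate)
mini_reference <- function() {
  fixture("mini_reference", function() {
    ref <- clinical_reference()
    bc <- avf_boundary_spec(ref$v_pra, ref$v_dra, "anterograde", ref$p_cv)
    solve_steady(mini_mesh(), bc)
  })
}

# Poiseuille benchmark: parabolic inlet, medium tube (10 cells/diameter)
tube_fixture <- function() {
  fixture("tube_fixture", function() {
    d <- 3e-3; L <- 30e-3; vbar <- 0.577
    solid <- build_straight_tube(d, L)
    mesh <- mesh_domain(solid, "medium")
    bc <- tube_boundary_spec(inlet = vbar, outlet_pressure = 0,
                             profile = "parabolic")
    sol <- solve_steady(mesh, bc, t_max = 0.3)
    list(d = d, L = L, vbar = vbar, mesh = mesh, sol = sol,
         fluid = fluid_properties())
  })
}

# hand-built WSS field for the thresholded-area unit checks
synthetic_wss_field <- function(mag, area_m2) {
  n <- length(mag)
  df <- data.frame(cx = seq_len(n) * 1e-3, cy = 0, cz = 0,
                   area = area_m2, nx = 0, ny = 1, nz = 0,
                   axis = 2L, side = 1L,
                   tau_x = mag, tau_y = 0, tau_z = 0, mag = mag)
  class(df) <- c("avf_wss", "data.frame")
  attr(df, "total_wall_area") <- sum(area_m2)
  attr(df, "t") <- 0
  df
}
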