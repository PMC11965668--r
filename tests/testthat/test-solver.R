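test_that("Reynolds number definition and the clinical laminar regime", {
  fl <- fluid_properties()
  re <- reynolds(fl, 0.577, 3.0e-3)
  expect_equal(re, 1050 * 0.577 * 3.0e-3 / 4.0e-3, tolerance = 1e-12)
  expect_lt(abs(re - 445) / 445, 0.05)     # recorded laminar regime
  expect_equal(reynolds(fl, 0, 3e-3), 0)
  expect_equal(reynolds(fl, 0.5, 6e-3), 2 * reynolds(fl, 0.5, 3e-3))
  expect_error(fluid_properties(density = -1), "positive")
})

test_that("zero inlet velocity and zero gauge pressure give the zero field", {
  tb <- build_straight_tube(3e-3, 9e-3)
  m <- mesh_domain(tb, "coarse")
  bc <- tube_boundary_spec(inlet = 0, outlet_pressure = 0)
  sol <- solve_steady(m, bc, t_max = 0.05, min_time = 0.01, t_avg = 0.005)
  expect_lt(max(abs(sol$fields[[1]]$U)), 1e-12)
  expect_lt(max(abs(sol$fields[[1]]$p)), 1e-9)
})

test_that("only pressure differences matter: gauge and absolute outlets give
           identical velocity fields", {
  tb <- build_straight_tube(3e-3, 9e-3)
  m <- mesh_domain(tb, "coarse")
  run <- function(p_out) {
    bc <- tube_boundary_spec(inlet = 0.3, outlet_pressure = p_out,
                             profile = "parabolic")
    solve_steady(m, bc, t_max = 0.12, min_time = 0.03, t_avg = 0.01)
  }
  s0 <- run(0)
  s1 <- run(1064)
  expect_equal(s0$fields[[1]]$U, s1$fields[[1]]$U, tolerance = 1e-10)
  # pressure fields differ by the constant offset only
  dp <- s1$fields[[1]]$p - s0$fields[[1]]$p
  expect_lt(diff(range(dp)), 1e-6)
  expect_equal(mean(dp), 1064, tolerance = 1e-6)
})

test_that("the pipeline is deterministic: repeated runs are identical", {
  tb <- build_straight_tube(3e-3, 9e-3)
  m <- mesh_domain(tb, "coarse")
  bc <- tube_boundary_spec(inlet = 0.3, outlet_pressure = 0,
                           profile = "parabolic")
  s1 <- solve_steady(m, bc, t_max = 0.08, min_time = 0.02, t_avg = 0.01)
  s2 <- solve_steady(m, bc, t_max = 0.08, min_time = 0.02, t_avg = 0.01)
  expect_identical(s1$fields[[1]]$U, s2$fields[[1]]$U)
  expect_identical(s1$fluxes, s2$fluxes)
})

test_that("boundary specs are validated", {
  tb <- build_straight_tube(3e-3, 9e-3)
  m <- mesh_domain(tb, "coarse")
  # a velocity condition on every port leaves the pressure level undefined
  bc <- tube_boundary_spec(inlet = 0.3)
  bc$ports$OUTLET <- list(kind = "velocity", value = function(t) 0.3,
                          profile = "flat")
  expect_error(solve_steady(m, bc), "pressure port")
  # missing port
  s <- build_avf(mini_params())
  bc2 <- tube_boundary_spec(inlet = 0.3)
  expect_error(solve_steady(mini_mesh(), bc2), "no boundary condition")
})
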