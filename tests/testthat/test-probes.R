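test_that("the S1 probe set sits inside the lumen with even spacing", {
  m <- mini_mesh()
  pr <- probe_set(m)
  expect_equal(nrow(pr$vel_points), 5L)
  expect_length(pr$wss_rows, 6L)
  # velocity probes strictly inside the lumen
  phi <- solid_implicit(m$solid, pr$vel_points[, 1], pr$vel_points[, 2],
                        pr$vel_points[, 3])
  expect_true(all(phi < 0))
  # even spacing along the chord and around the ring
  expect_equal(diff(pr$vel_s), rep(diff(pr$vel_s)[1], 4), tolerance = 1e-9)
  expect_equal(diff(pr$angles), rep(pi / 3, 5), tolerance = 1e-12)
  # WSS probes reference wall facets
  expect_true(all(m$facets$tag[pr$wss_rows] == "WALL"))
})

test_that("a centreline probe of developed tube flow reads 2 x bulk velocity", {
  fx <- tube_fixture()
  pr <- probe_set(fx$mesh, offset = 0)   # section at mid-tube
  ser <- probe_series(fx$sol, fx$mesh, pr)
  centre <- ser$vel_axial[1, 3]          # middle of five probes
  q <- unname(abs(fx$sol$fluxes[1, 2]))
  vb <- unname(q / fx$mesh$ports$area_mesh[2])
  expect_equal(centre, 2 * vb, tolerance = 0.03)
  # wall probes of a developed parabolic flow agree with 8 mu v / d
  expect_equal(mean(ser$wss_mag[1, ]),
               poiseuille_wall_shear(fx$fluid$viscosity, vb, fx$d),
               tolerance = 0.05)
})
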