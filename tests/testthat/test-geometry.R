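test_that("AVF parameter invariants are enforced", {
  expect_s3_class(avf_params(), "avf_params")
  expect_error(avf_params(angle_deg = 0), "angle")
  expect_error(avf_params(angle_deg = 95), "angle")
  expect_error(avf_params(d_dra = 3.0e-3), "smaller")
  expect_error(avf_params(d_pra = 6e-3), "exceed")
  expect_error(avf_params(ext_cv = 3), "at least 5")
  expect_error(avf_params(d_pra = -1), "positive")
})

test_that("the default solid exposes three ports with exact areas", {
  s <- build_avf(avf_params())
  areas <- vapply(s$ports, `[[`, 0, "area")
  d <- c(3.0e-3, 1.2e-3, 5.0e-3)
  expect_equal(unname(areas), pi * d^2 / 4, tolerance = 5e-3)
  expect_equal(vapply(s$ports, `[[`, "", "name"),
               c("PRA_INLET", "DRA_END", "CV_OUTLET"))
  # interior points of each vessel are inside the lumen, far points outside
  expect_lt(solid_implicit(s, 0, 0, 0), 0)                    # PRA axis
  expect_lt(solid_implicit(s, s$geom$x_dra - 1e-3, s$geom$y_dra, 0), 0)
  expect_gt(solid_implicit(s, 0, -5e-3, 0), 0)
})

test_that("the anastomosis frame is orthonormal and right-handed", {
  for (s in list(build_avf(avf_params()), build_straight_tube())) {
    fr <- s$frame
    M <- rbind(fr$x_axis, fr$y_axis, fr$z_axis)
    expect_equal(M %*% t(M), diag(3), tolerance = 1e-12,
                 ignore_attr = TRUE)
    # right-handed: x cross y = z
    cx <- c(fr$x_axis[2] * fr$y_axis[3] - fr$x_axis[3] * fr$y_axis[2],
            fr$x_axis[3] * fr$y_axis[1] - fr$x_axis[1] * fr$y_axis[3],
            fr$x_axis[1] * fr$y_axis[2] - fr$x_axis[2] * fr$y_axis[1])
    expect_equal(cx, fr$z_axis, tolerance = 1e-12)
  }
  # frame y-axis points along the proximal vein
  s <- build_avf(avf_params(angle_deg = 45))
  expect_equal(s$frame$y_axis, c(-cos(pi / 4), sin(pi / 4), 0),
               tolerance = 1e-12)
})

test_that("a 90-degree anastomosis with equal artery/vein bores is
           mirror-symmetric across the plane normal to the artery", {
  s <- build_avf(avf_params(d_pra = 5.0e-3, d_dra = 1.2e-3, d_cv = 5.0e-3,
                            angle_deg = 90))
  ox <- s$frame$origin[1]
  expect_equal(ox, 0) # vertical vein: opening centred on the take-off point
  set.seed(42)
  n <- 500
  pts <- cbind(x = runif(n, -2.4e-3, 2.4e-3),
               y = runif(n, -3e-3, 5e-3),
               z = runif(n, -2.4e-3, 2.4e-3))
  f1 <- solid_implicit(s, pts[, 1], pts[, 2], pts[, 3])
  f2 <- solid_implicit(s, 2 * ox - pts[, 1], pts[, 2], pts[, 3])
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("the junction blend is smooth: no sharp interior corner", {
  # along the heel line between artery and vein the implicit value varies
  # continuously and the fillet keeps the surface within the blend radius
  s <- build_avf(avf_params())
  g <- s$geom
  # sample the implicit gradient near the heel; a corner would produce a
  # jump in the normalized gradient along a short path
  t <- seq(-1, 1, length.out = 201) * 0.5 * g$k
  p0 <- c(g$origin[1] - g$half_open, g$rp, 0)  # heel of the opening
  vals <- solid_implicit(s, p0[1] + t, p0[2] + abs(t), 0 * t)
  expect_true(all(is.finite(vals)))
  expect_lt(max(abs(diff(vals))), 2 * (t[2] - t[1]) * 1.5)
})

test_that("straight-tube builder: ports, volume and wall area", {
  expect_error(build_straight_tube(0, 1e-2), "positive")
  expect_error(build_straight_tube(3e-3, -1), "positive")
  tb <- build_straight_tube(3.0e-3, 30e-3)
  expect_equal(vapply(tb$ports, `[[`, 0, "area")[1],
               pi * (1.5e-3)^2, tolerance = 1e-12, ignore_attr = TRUE)
  # inlet/outlet normals antiparallel (dir flags on the same axis)
  expect_equal(sum(vapply(tb$ports, `[[`, 0L, "dir")), 0L)
  m <- mesh_domain(tb, "medium")
  vol <- pi * (1.5e-3)^2 * 30e-3
  expect_equal(domain_volume(m), vol, tolerance = 1e-2)    # closed form
  expect_equal(wall_area(m), pi * 3e-3 * 30e-3, tolerance = 5e-2)
})
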