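test_that("mesh levels refine monotonically up to the ~0.12M-element
           elements", {
  s <- build_avf(avf_params())
  n <- vapply(c("coarse", "medium", "fine"), function(lv) {
    mesh_domain(s, lv)$n_elements
  }, 0L)
  expect_true(all(diff(n) > 0))
  np <- mesh_domain(s, "full")$n_elements
  expect_gt(np, n[["fine"]])
  expect_gte(np, 0.10e6)
  expect_lte(np, 0.15e6)
})

test_that("the tagged boundary is watertight and partitions into ports and
           wall", {
  for (solid in list(build_straight_tube(3e-3, 12e-3),
                     build_avf(mini_params()))) {
    m <- mesh_domain(solid, "coarse")
    expect_true(check_watertight(m))
    f <- m$facets
    expect_false(any(is.na(f$tag)))
    port_names <- m$ports$name
    expect_setequal(unique(f$tag), c("WALL", port_names))
    # boundary area partition: wall + ports = total (exact by construction)
    expect_equal(sum(f$area[f$tag == "WALL"]) +
                   sum(f$area[f$tag %in% port_names]),
                 sum(f$area), tolerance = 1e-12)
    # each port patch is planar with an axis-aligned normal
    for (nm in port_names) {
      expect_equal(length(unique(f$cx[f$tag == nm])), 1L)
      expect_true(all(f$axis[f$tag == nm] == 1L))
    }
  }
})

test_that("meshed port areas converge to pi d^2/4 at first order or better", {
  tb <- build_straight_tube(3e-3, 9e-3)
  exact <- pi * (1.5e-3)^2
  errs <- vapply(c("coarse", "medium", "fine"), function(lv) {
    m <- mesh_domain(tb, lv)
    abs(m$ports$area_mesh[1] - exact) / exact
  }, 0)
  hs <- 3e-3 / c(8, 10, 12)
  # error bounded by ~2 h/d (first-order) at every level, decreasing
  expect_true(all(errs <= 2 * hs / 3e-3))
  expect_gte(errs[["coarse"]], errs[["fine"]])
})

test_that("the voxel grid preserves the mirror symmetry of the lumen", {
  m <- mini_mesh()
  cc <- m$cellcode
  expect_identical(cc, cc[, , rev(seq_len(dim(cc)[3]))])
})

test_that("numeric element sizes and bad levels are handled", {
  tb <- build_straight_tube(3e-3, 9e-3)
  m <- mesh_domain(tb, 0.5e-3)
  expect_equal(m$h, 0.5e-3)
  expect_error(mesh_domain(tb, "ultrafine"), "level")
  expect_error(mesh_domain(tb, -1), "positive")
})
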