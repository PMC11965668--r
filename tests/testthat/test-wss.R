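test_that("thresholded areas sum facet areas with ties counted low", {
  # facets of 1, 2, 3 mm^2 with |WSS| 0.5, 1.0, 5.0 Pa
  f <- synthetic_wss_field(mag = c(0.5, 1.0, 5.0),
                           area_m2 = c(1, 2, 3) * 1e-6)
  expect_equal(thresholded_area(f, "le", 1), 3e-6)     # boundary included
  expect_equal(thresholded_area(f, "ge", 10), 0)
  expect_equal(thresholded_area(f, "ge", 0), 6e-6)     # total wall area
  expect_equal(thresholded_area(f, "ge", 1), 5e-6)     # tie counted here too
  expect_error(thresholded_area(f, "le", -1), "threshold")
})

test_that("area partition and threshold monotonicity hold for any tau", {
  set.seed(7)
  f <- synthetic_wss_field(mag = runif(200, 0, 25),
                           area_m2 = runif(200, 0.5, 2) * 1e-6)
  total <- sum(f$area)
  taus <- c(0, 0.5, 1, 5, 10, 20, 30)
  lo <- vapply(taus, function(t) thresholded_area(f, "le", t), 0)
  hi <- vapply(taus, function(t) thresholded_area(f, "ge", t), 0)
  # area(<= tau) + area(> tau) = total; ties belong to the low side
  ties <- vapply(taus, function(t) sum(f$area[f$mag == t]), 0)
  expect_equal(lo + (total - lo), rep(total, length(taus)))
  expect_equal(lo + hi - ties, rep(total, length(taus)), tolerance = 1e-12)
  expect_true(all(diff(lo) >= 0))    # low area non-decreasing in tau
  expect_true(all(diff(hi) <= 0))    # high area non-increasing
})

test_that("normalization against the reference case", {
  f1 <- synthetic_wss_field(c(0.5, 2), c(0.8, 1) * 1e-6)
  f2 <- synthetic_wss_field(c(0.5, 2), c(1.0, 1) * 1e-6)
  m1 <- area_metrics(f1); m2 <- area_metrics(f2)
  expect_equal(normalized_low_wss(m2, m2), 1.0)
  expect_equal(normalized_low_wss(m1, m2), 0.8)
  f0 <- synthetic_wss_field(c(5, 6), c(1, 1) * 1e-6)
  expect_error(normalized_low_wss(m1, area_metrics(f0)), "zero")
})

test_that("WSS vanishes for a fluid at rest and is wall-tangential", {
  m <- mini_mesh()
  rows <- which(m$facets$tag == "WALL")
  U0 <- matrix(0, m$n_elements, 3)
  tau0 <- avfwss:::wss_at_facets(m, U0, rows, 4e-3)
  expect_true(all(tau0$mag == 0))
  # solved field: WSS vector perpendicular to the wall normal
  sol <- mini_reference()
  w <- compute_wss(sol, m)
  dotn <- abs(w$tau_x * w$nx + w$tau_y * w$ny + w$tau_z * w$nz)
  expect_lt(max(dotn / pmax(w$mag, 1e-12)), 1e-6)
  expect_true(all(w$mag >= 0))
  expect_equal(sum(w$area), wall_area(m), tolerance = 1e-12)
})

test_that("oscillatory shear index separates steady from reversing shear", {
  f_pos <- synthetic_wss_field(c(2, 2), c(1, 1) * 1e-6)
  f_neg <- f_pos; f_neg$tau_x <- -f_neg$tau_x
  expect_equal(oscillatory_shear_index(list(f_pos, f_pos)), c(0, 0))
  expect_equal(oscillatory_shear_index(list(f_pos, f_neg)), c(0.5, 0.5))
})

test_that("reversal classification follows the stated rules", {
  th <- seq(0, 2 * pi, length.out = 100)
  expect_equal(detect_reversal(sin(th)), "reciprocating")
  expect_equal(detect_reversal(1 + 0.8 * sin(th)), "oscillating")
  expect_equal(detect_reversal(1 + 0.1 * sin(th)), "none")
  expect_equal(detect_reversal(rep(3, 50)), "none")
})
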