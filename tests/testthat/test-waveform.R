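test_that("clinical unit conversions reproduce the recorded values", {
  expect_equal(mmhg_to_pa(8), 1064)
  expect_equal(mm_to_m(3.0), 3.0e-3)
  expect_equal(cm_s_to_m_s(57.7), 0.577)
})

test_that("default pulse hits the recorded anchors with an exact mean", {
  Tp <- 60 / 70
  wf <- synthesize_waveform(0.577, Tp)
  # extrema anchored at the recorded third-cycle instants
  expect_equal(wf(1.82), 1.4 * 0.577, tolerance = 1e-12)
  expect_equal(wf(2.58), 0.6 * 0.577, tolerance = 1e-12)
  tt <- seq(0, Tp, length.out = 4096L)
  expect_true(all(wf(tt) >= 0.6 * 0.577 - 1e-12))
  expect_true(all(wf(tt) <= 1.4 * 0.577 + 1e-12))
  # time average equals the prescribed mean (adaptive quadrature oracle)
  brk <- sort(c(0, 1.82 %% Tp, 2.58 %% Tp, Tp))
  avg <- sum(vapply(seq_len(length(brk) - 1), function(i) {
    stats::integrate(wf, brk[i], brk[i + 1], rel.tol = 1e-12,
                     abs.tol = 1e-14)$value
  }, 0)) / Tp
  expect_lt(abs(avg - 0.577) / 0.577, 1e-9)
  # C1 periodicity: derivative vanishes at both anchors, signal is periodic
  eps <- 1e-7
  for (t0 in c(1.82, 2.58)) {
    dd <- (wf(t0 + eps) - wf(t0 - eps)) / (2 * eps)
    expect_lt(abs(dd), 1e-4)
  }
  expect_equal(wf(0.123), wf(0.123 + 5 * Tp), tolerance = 1e-12)
})

test_that("harmonic waveforms are exact finite Fourier series", {
  Tp <- 60 / 70
  # zero harmonics: constant signal equal to the mean
  wf0 <- synthesize_waveform(0.3, Tp, shape = "harmonics",
                             harmonics = data.frame(amplitude = 0, phase = 0))
  expect_true(all(abs(wf0(seq(0, 2, 0.01)) - 0.3) < 1e-15))
  # two harmonics: quadrature of one period recovers the mean to 1e-9
  wf2 <- synthesize_waveform(0.577, Tp, shape = "harmonics",
                             harmonics = data.frame(amplitude = c(0.15, 0.08),
                                                    phase = c(0.4, -1.1)))
  avg <- stats::integrate(wf2, 0, Tp, rel.tol = 1e-12,
                          abs.tol = 1e-14)$value / Tp
  expect_lt(abs(avg - 0.577) / 0.577, 1e-9)
  # amplitudes driving an anterograde inlet negative are rejected
  expect_error(
    synthesize_waveform(0.2, Tp, shape = "harmonics",
                        harmonics = data.frame(amplitude = 0.5, phase = 0)),
    "negative")
})

test_that("the third cardiac cycle matches the recorded analysis window", {
  Tp <- 60 / 70
  expect_lt(abs(2 * Tp - 1.72), 0.01)
  expect_lt(abs(3 * Tp - 2.58), 0.01)
})

test_that("waveform serialization writes the sampled signal", {
  wf <- synthesize_waveform(0.343)
  path <- tempfile(fileext = ".csv")
  write_waveform_csv(wf, path)
  d <- read.csv(path)
  expect_equal(names(d), c("t", "v"))
  expect_equal(d$v, wf(d$t), tolerance = 1e-12)
})
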