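test_that("reference flow rates follow from the measured means and diameters", {
  fl <- reference_flows()
  q_pa <- 0.577 * pi * (1.5e-3)^2   # v * pi r^2, arithmetic oracle
  q_da <- 0.343 * pi * (0.6e-3)^2
  expect_equal(fl$Q_PA, q_pa, tolerance = 1e-12)
  expect_equal(fl$Q_DA, q_da, tolerance = 1e-12)
  expect_equal(fl$Q_PA, 4.08e-6, tolerance = 1e-2)
  expect_equal(fl$Q_DA, 3.88e-7, tolerance = 1e-2)
  expect_equal(fl$ratio, 0.095, tolerance = 2e-2)
  expect_gt(fl$Q_PA, fl$Q_DA)
})

test_that("the case matrix reproduces the redistribution condition grid", {
  cm <- case_matrix()
  expect_length(cm, 27L)
  fam <- vapply(cm, `[[`, "", "family")
  expect_equal(sum(fam == "reference"), 1L)
  expect_equal(sum(fam == "g1"), 7L)
  expect_equal(sum(fam == "g2"), 7L)
  expect_equal(sum(fam == "g3"), 7L)
  expect_equal(sum(fam == "g4"), 5L)
  # retrograde flow only in the g4 family, with the reduced epsilon set
  dirs <- vapply(cm, `[[`, "", "dra_direction")
  expect_true(all(dirs[fam == "g4"] == "retrograde"))
  expect_true(all(dirs[fam != "g4"] == "anterograde"))
  eps4 <- sort(vapply(cm[fam == "g4"], `[[`, 0, "epsilon"))
  expect_equal(eps4, seq(0.1, 0.5, 0.1))
  eps1 <- sort(vapply(cm[fam == "g1"], `[[`, 0, "epsilon"))
  expect_equal(eps1, seq(0.7, 1.3, 0.1))
})

test_that("epsilon scales exactly the family's designated flow", {
  ref <- clinical_reference()
  # g1 scales the PRA only
  c1 <- case_config("g1", 0.7)
  wf1 <- case_waveforms(c1)
  expect_equal(waveform_spec(wf1$pra)$mean_velocity, 0.7 * ref$v_pra)
  expect_equal(waveform_spec(wf1$dra)$mean_velocity, ref$v_dra)
  # g2 scales the DRA only; g3 both; g4 the reversed DRA
  c2 <- case_config("g2", 1.2)
  expect_equal(c2$pra_scale, 1); expect_equal(c2$dra_scale, 1.2)
  c3 <- case_config("g3", 0.8)
  expect_equal(c3$pra_scale, 0.8); expect_equal(c3$dra_scale, 0.8)
  c4 <- case_config("g4", 0.3)
  expect_equal(c4$pra_scale, 1); expect_equal(c4$dra_scale, 0.3)
  expect_equal(c4$dra_direction, "retrograde")
  # g3 at epsilon = 1 is the reference flow state
  c31 <- case_config("g3", 1.0)
  wf31 <- case_waveforms(c31)
  expect_equal(waveform_spec(wf31$pra)$mean_velocity, ref$v_pra)
  expect_equal(waveform_spec(wf31$dra)$mean_velocity, ref$v_dra)
  # volumetric scaling is linear and exact: Q = eps * v * A
  area <- pi * (ref$d_pra / 2)^2
  expect_identical(waveform_spec(wf1$pra)$mean_velocity * area,
                   0.7 * ref$v_pra * area)
  # epsilon outside the family set is rejected
  expect_error(case_config("g1", 0.55), "not in the g1 family set")
  expect_error(case_config("g4", 0.7), "not in the g4 family set")
})

test_that("the case table mirrors the condition grid", {
  tb <- case_table()
  expect_equal(nrow(tb), 27L)
  path <- tempfile(fileext = ".csv")
  case_table(path = path)
  expect_equal(read.csv(path)$epsilon, tb$epsilon)
})
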