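COMPS <- default_components(MONT)

test_that("generator cell means reproduce the reported condition means", {
  # P1 printed per cell; latency printed per motion
  expect_equal(unname(COMPS$P1$amplitude["bm_radial"]), 2.27)
  expect_equal(unname(COMPS$P1$amplitude["bm_lateral"]), 1.75)
  expect_equal(unname(COMPS$P1$amplitude["sm_radial"]), 1.81)
  expect_equal(unname(COMPS$P1$amplitude["sm_lateral"]), 1.84)
  expect_equal(unname(COMPS$P1$latency["bm_radial"]), 112)
  expect_equal(unname(COMPS$P1$latency["sm_lateral"]), 118)
  # N1 cells are additive in motion and direction; marginals must be exact
  n1 <- COMPS$N1$amplitude
  expect_equal(mean(n1[c("bm_radial", "bm_lateral")]), -2.84)
  expect_equal(mean(n1[c("sm_radial", "sm_lateral")]), -2.41)
  expect_equal(mean(n1[c("bm_radial", "sm_radial")]), -2.93)
  expect_equal(mean(n1[c("bm_lateral", "sm_lateral")]), -2.32)
  # ESN marginals and their difference
  esn <- COMPS$ESNa$amplitude
  expect_equal(mean(esn[c("bm_radial", "bm_lateral")]), -3.74)
  expect_equal(mean(esn[c("sm_radial", "sm_lateral")]), -2.18)
  expect_equal(unname(esn["bm_radial"] - esn["sm_radial"]), -1.56)
  # receding-minus-approaching N1 difference on radial trials
  expect_equal(-2 * COMPS$N1$direction_split, -0.55)
})

test_that("topographies are average-referenced with unit ROI mean", {
  for (cs in COMPS) {
    expect_lt(abs(sum(cs$topography)), 1e-9)
    idx <- match(cs$roi, MONT$label)
    expect_equal(mean(cs$topography[idx]), 1, tolerance = 1e-9)
  }
  # lateralization pattern: zero sum, zero ESN-ROI-union mean, antisymmetric
  asym <- COMPS$ESNa$asym_topography
  expect_lt(abs(sum(asym)), 1e-9)
  idx <- match(unlist(default_rois("ESN")), MONT$label)
  expect_lt(abs(mean(asym[idx])), 1e-9)
})

test_that("component and noise specifications validate their invariants", {
  expect_error(component_spec("X", "gaussian", latency = 1, amplitude = 1,
                              width = 0, topography = c(1, -1)), "width")
  expect_error(component_spec("X", "gaussian", latency = 1, amplitude = 1,
                              width = 5, topography = c(1, 1)), "sum to zero")
  expect_error(noise_spec(pink_rms = -1), "non-negative")
  expect_error(noise_spec(blink_rate = 1.5), "blink_rate")
})

test_that("the plateau normalization makes the ESN window mean exact", {
  tg <- seq(210, 360, by = 0.25)
  raw <- rowSums(sapply(COMPS[c("ESNa", "ESNb", "ESNc")], function(cs)
    bmerp:::component_waveform(cs, tg)))
  expect_equal(mean(raw), 1, tolerance = 1e-6)
})
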