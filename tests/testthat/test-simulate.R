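test_that("zero noise and zero subject SD reproduce the templates exactly", {
  ep <- tiny_zero_noise_subject()
  comps <- default_components(MONT)
  tpl <- bmerp:::erp_template(comps, "walker", "radial", "approach",
                              ep$times_ms)
  idx <- which(ep$design$motion == "walker" & ep$design$plane == "radial" &
                 ep$design$direction == "approach")
  for (tr in idx)
    expect_lt(max(abs(ep$data[, , tr] - tpl)), 1e-12)
})

test_that("simulation is bit-identical for identical seeds", {
  des <- build_design(blocks = 1, reps = 1, seed = 2)
  comps <- default_components(MONT)
  e1 <- simulate_subject(des, comps, noise_spec(), MONT, seed = 42)
  e2 <- simulate_subject(des, comps, noise_spec(), MONT, seed = 42)
  expect_identical(e1$data, e2$data)
  e3 <- simulate_subject(des, comps, noise_spec(), MONT, seed = 43)
  expect_false(identical(e1$data, e3$data))
})

test_that("behavioral generation honors the error rate", {
  des <- build_design(blocks = 2, reps = 6, seed = 3)
  comps <- default_components(MONT)
  ep <- simulate_subject(des, comps,
                         noise_spec(pink_rms = 0, white_rms = 0),
                         MONT, behavior_error_rate = 0, seed = 1)
  expect_true(all(ep$design$correct))
  expect_true(all(ep$design$response[ep$design$motion == "cyclist"] == "key"))
  expect_true(all(ep$design$response[ep$design$motion != "cyclist"] ==
                    "none"))
  bs <- behavioral_summary(list(ep))
  expect_equal(bs$mean_percent_correct, 100)
})

test_that("blink injection contaminates the expected fraction of trials", {
  set.seed(1)
  ntr <- 1000
  data <- array(rnorm(141 * 64 * ntr, sd = 2), c(141, 64, ntr))
  ep <- make_epochs(data, fs = 128, t0 = -100)
  ns <- noise_spec(blink_rate = 0.2, blink_amp = 150)
  ep2 <- inject_artifacts(ep, ns, MONT, seed = 77)
  hits <- sum(ep2$blink)
  expect_lt(abs(hits - 200), 3 * sqrt(1000 * 0.2 * 0.8))
  # every contaminated trial exceeds the rejection threshold
  mx <- apply(abs(ep2$data[, , ep2$blink]), 3, max)
  expect_true(all(mx > 100))
  # rate 0 leaves the data untouched
  ep3 <- inject_artifacts(ep, noise_spec(blink_rate = 0), MONT, seed = 1)
  expect_identical(ep3$data, ep$data)
})

test_that("noise has the configured per-channel RMS and spatial correlation", {
  ns <- noise_spec(pink_rms = 3, white_rms = 1.5, spatial_scale = 0.8)
  chol_r <- bmerp:::spatial_chol(MONT, ns$spatial_scale)
  set.seed(10)
  nb <- bmerp:::noise_block(1126, 64, 40, ns, chol_r)
  rms <- sqrt(mean(nb^2))
  expect_lt(abs(rms - sqrt(3^2 + 1.5^2)), 0.25)
  # neighboring channels correlate more than distant ones
  x <- nb[, match(c("O1", "O2", "Fpz"), MONT$label), 1:40]
  co <- cor(cbind(as.vector(x[, 1, ]), as.vector(x[, 2, ]),
                  as.vector(x[, 3, ])))
  expect_gt(co[1, 2], co[1, 3])
})
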