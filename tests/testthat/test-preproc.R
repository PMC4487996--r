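test_that("band-pass keeps the passband and rejects stopband and DC", {
  fs <- 1024
  t <- (0:1125) / fs
  x <- cbind(sin(2 * pi * 10 * t), sin(2 * pi * 50 * t), rep(5, 1126))
  y <- bmerp:::filtfilt_matrix(x, filter_spec(), fs)
  mid <- 300:800
  expect_lt(abs(max(abs(y[mid, 1])) - 1), 0.05)        # 10 Hz within 5%
  expect_lt(20 * log10(max(abs(y[mid, 2]))), -20)      # 50 Hz > 20 dB down
  expect_lt(max(abs(y[mid, 3])), 1e-6)                 # DC removed
  # zero phase: peak of the filtered tone aligns with the input
  cc <- ccf(y[mid, 1], x[mid, 1], lag.max = 3, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(bandpass(make_epochs(array(0, c(64, 4, 1))),
                        filter_spec(lp = 600)), "Nyquist")
  expect_error(filter_spec(hp = 30, lp = 1), "hp < lp")
})

test_that("average reference zeroes the channel mean and is idempotent", {
  set.seed(4)
  ep <- make_epochs(array(rnorm(200 * 64 * 3), c(200, 64, 3)))
  r1 <- rereference_average(ep)
  for (tr in 1:3)
    expect_lt(max(abs(rowMeans(r1$data[, , tr]))), 1e-12)
  # common offset invariance
  ep2 <- ep
  ep2$data <- ep$data + 7.5
  expect_equal(rereference_average(ep2)$data, r1$data, tolerance = 1e-12)
  # idempotence
  expect_equal(rereference_average(r1)$data, r1$data, tolerance = 1e-12)
})

test_that("baseline correction removes exactly the pre-stimulus mean", {
  set.seed(5)
  ep <- make_epochs(array(rnorm(1126 * 8 * 2) + 3, c(1126, 8, 2)))
  b <- baseline_correct(ep)
  sel <- ep$times_ms >= -100 & ep$times_ms <= 0
  for (tr in 1:2)
    expect_lt(max(abs(colMeans(b$data[sel, , tr]))), 1e-12)
  # constant trial becomes all zero
  epc <- make_epochs(array(5, c(1126, 4, 1)))
  expect_lt(max(abs(baseline_correct(epc)$data)), 1e-12)
  # linear ramp crossing zero at -50 ms: removed mean equals the ramp mean
  tm <- epc$times_ms
  ramp <- 0.02 * (tm + 50)
  epr <- make_epochs(array(rep(ramp, 4), c(1126, 4, 1)))
  br <- baseline_correct(epr)
  expect_equal(unname(br$data[1, 1, 1]), ramp[1] - mean(ramp[sel]),
               tolerance = 1e-12)
  expect_error(baseline_correct(epc, c(-500, 0)), "outside")
})

test_that("rejection uses a strict threshold and is monotone", {
  data <- array(0, c(100, 4, 4))
  data[50, 2, 2] <- 150          # clearly above
  data[10, 1, 3] <- 100          # exactly at threshold: retained
  data[20, 3, 4] <- -100.0001    # just above in magnitude: rejected
  ep <- make_epochs(data)
  r <- reject_artifacts(ep, 100)
  expect_identical(unname(r$retain), c(TRUE, FALSE, TRUE, FALSE))
  # raising the threshold never rejects more
  r2 <- reject_artifacts(ep, 200)
  expect_true(all(r2$retain >= r$retain))
})

test_that("spherical-spline interpolation is exact on constant/zero maps", {
  epc <- make_epochs(array(5, c(3, 64, 2)))
  out <- interpolate_channels(epc, c("Cz", "P3"), MONT)
  expect_lt(max(abs(out$data - 5)), 1e-6)
  ep0 <- make_epochs(array(0, c(3, 64, 1)))
  out0 <- interpolate_channels(ep0, "Oz", MONT)
  expect_lt(max(abs(out0$data)), 1e-9)
  expect_error(interpolate_channels(epc, "XX9", MONT), "unknown")
  expect_error(interpolate_channels(epc, MONT$label[1:20], MONT),
               "too many")
})

test_that("spline leave-one-out error on a smooth field is small", {
  f <- 3 * POS[, 3]^2 - 1   # low-order zonal harmonic
  gfp_f <- sqrt(mean((f - mean(f))^2))
  ep <- make_epochs(array(rep(f, each = 2), c(2, 64, 1)))
  # the three lowest sites (P9, P10, Iz) sit below the sampled cap, where
  # leave-one-out becomes extrapolation; interpolation proper is tested on
  # the remaining 61 electrodes
  interior <- setdiff(MONT$label, c("P9", "P10", "Iz"))
  errs <- vapply(interior, function(lab) {
    got <- interpolate_channels(ep, lab, MONT)$data[1, lab, 1]
    abs(got - f[match(lab, MONT$label)])
  }, numeric(1))
  expect_lt(max(errs) / gfp_f, 0.05)
})

test_that("averaging uses retained, correct, non-target trials only", {
  ep <- tiny_zero_noise_subject()
  ep <- reject_artifacts(ep, 100)
  erp <- average_erps(ep)
  expect_equal(sort(erp$conditions),
               c("scrambled_lateral", "scrambled_radial",
                 "walker_lateral", "walker_radial"))
  # constant-value average
  data <- array(2.5, c(50, 4, 3))
  epc <- make_epochs(data)
  epc$retain <- c(TRUE, TRUE, FALSE)
  erpc <- average_erps(epc)
  expect_true(all(erpc$data == 2.5))
  expect_equal(unname(erpc$n_trials), 2L)
  # zero retained trials raise an error naming subject and condition
  epc$retain <- rep(FALSE, 3)
  expect_error(average_erps(epc), "T01.*walker_radial")
})

test_that("the preprocessed pipeline output keeps both invariants", {
  ep <- tiny_zero_noise_subject()
  pp <- preprocess(ep)
  sel <- pp$times_ms <= 0
  for (tr in c(1, 5)) {
    expect_lt(max(abs(rowMeans(pp$data[, , tr]))), 1e-9)
    expect_lt(max(abs(colMeans(pp$data[sel, , tr]))), 1e-9)
  }
  expect_false(any(is.na(pp$retain)))
})
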