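test_that("GFP matches its definition and is reference-invariant", {
  expect_equal(gfp(matrix(3, 5, 64)), rep(0, 5))
  half <- matrix(rep(c(1, -1), each = 32), 1, 64)
  expect_equal(gfp(half), 1)
  set.seed(2)
  maps <- matrix(rnorm(10 * 64), 10, 64)
  expect_equal(gfp(maps), gfp(maps + 5), tolerance = 1e-12)
})

test_that("a rank-1 series is explained by a single template", {
  sim <- simulate_microstate_series(MONT, k = 1, n_conditions = 1,
                                    snr = 1000, seed = 2)
  sets <- microstate_segment(sim$series[[1]], k_range = 1:3, restarts = 10,
                             seed = 1)
  expect_gt(1 - sets[["1"]]$residual_var /
              mean(rowSums((sim$series[[1]] / sqrt(64))^2) * 64 / 63), 0.99)
  expect_gt(sets[["1"]]$gev, 0.99)
  expect_equal(select_k(sets), 1)
})

test_that("planted templates are recovered and residuals are nested", {
  sim <- simulate_microstate_series(MONT, k = 5, seed = 3)
  maps <- do.call(rbind, sim$series)
  sets <- microstate_segment(maps, k_range = 1:8, restarts = 20, seed = 2)
  rv <- vapply(sets, function(s) s$residual_var, numeric(1))
  expect_true(all(diff(rv) <= 1e-12))
  tpl <- sets[["5"]]$templates
  co <- abs(cor(t(tpl), t(sim$truth)))
  expect_true(all(apply(co, 2, max) > 0.95))
  # cross-validation criterion: formula and minimum
  cvs <- vapply(sets, function(s) s$cv, numeric(1))
  expect_equal(unname(cvs),
               unname(rv * ((64 - 1) / (64 - 1 - as.numeric(names(sets))))^2),
               tolerance = 1e-12)
  expect_equal(select_k(sets), 5)
  expect_true(all(cvs[["5"]] <= cvs))
  expect_error(microstate_segment(maps[1:3, ], k_range = 5), "distinct")
})

test_that("back-fitting labels, smooths and scores as defined", {
  sim <- simulate_microstate_series(MONT, k = 3, snr = Inf, seed = 4)
  tpl <- sim$truth
  # series equal to template 2 everywhere
  ser <- outer(rep(2, 100), tpl[2, ])
  bf <- backfit(tpl, ser, seq(0, 99))
  expect_true(all(bf$labels == 2))
  expect_equal(bf$gev, 1, tolerance = 1e-9)
  # series orthogonal to every template
  set.seed(9)
  ortho <- matrix(rnorm(64 * 200), 200, 64)
  ortho <- ortho - rowMeans(ortho)
  ortho <- ortho - (ortho %*% t(tpl)) %*% tpl  # project out templates
  bf2 <- backfit(tpl, ortho, seq(0, 199), min_ms = 0)
  expect_lt(bf2$gev, 0.05)
  # two templates alternating in 100 ms blocks: boundaries within 10 ms
  times <- seq(0, by = 1000 / 1024, length.out = 410)
  lab <- rep(c(1, 2, 1, 2), each = 103)[1:410]
  ser3 <- 3 * tpl[lab, ] + 0.05 * matrix(rnorm(410 * 64), 410, 64)
  bf3 <- backfit(tpl[1:2, ], ser3, times)
  expect_equal(bf3$segments$template, c(1, 2, 1, 2))
  true_onsets <- times[c(1, 104, 207, 310)]
  expect_lt(max(abs(bf3$segments$t_start_ms - true_onsets)), 10)
})

test_that("segmentation is deterministic under a fixed seed", {
  sim <- simulate_microstate_series(MONT, k = 4, seed = 6)
  maps <- do.call(rbind, sim$series)
  s1 <- microstate_segment(maps, k_range = 3:5, restarts = 5, seed = 42)
  s2 <- microstate_segment(maps, k_range = 3:5, restarts = 5, seed = 42)
  expect_identical(lapply(s1, `[[`, "templates"),
                   lapply(s2, `[[`, "templates"))
})
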