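test_that("walker sequences have the required frame/marker structure", {
  w <- generate_walker(gait_model(), duration = 1000, fps = 30, seed = 1)
  expect_equal(dim(w$frames), c(30, 13, 3))
  expect_identical(w$kind, "biological")
  # determinism
  w2 <- generate_walker(gait_model(), duration = 1000, fps = 30, seed = 1)
  expect_identical(w$frames, w2$frames)
  expect_error(generate_walker(gait_model(), duration = 0, fps = 30),
               "duration")
  expect_error(generate_walker(gait_model(), duration = 1000, fps = -1),
               "fps")
})

test_that("gait is periodic with period 1/cadence", {
  # cadence 2 Hz at 30 fps: one gait cycle = 15 frames
  w <- generate_walker(gait_model(cadence = 2), duration = 1000, fps = 30,
                       seed = 4)
  expect_lt(max(abs(w$frames[1:15, , ] - w$frames[16:30, , ])), 1e-9)
})

test_that("zero swing amplitudes freeze the figure", {
  g <- gait_model(swing = c(thigh = 0, knee = 0, arm = 0, elbow = 0,
                            bob = 0))
  w <- generate_walker(g, duration = 500, fps = 30, seed = 2)
  for (k in 2:dim(w$frames)[1])
    expect_lt(max(abs(w$frames[k, , ] - w$frames[1, , ])), 1e-12)
})

test_that("scrambling preserves every per-marker displacement exactly", {
  w <- generate_walker(gait_model(), seed = 3)
  s <- scramble(w, seed = 9)
  expect_identical(s$kind, "scrambled")
  disp_w <- apply(w$frames, c(2, 3), diff)
  disp_s <- apply(s$frames, c(2, 3), diff)
  expect_lt(max(abs(disp_w - disp_s)), 1e-12)
  # determinism
  expect_identical(s$frames, scramble(w, seed = 9)$frames)
  # double scrambling is refused
  expect_error(scramble(s, seed = 1), "biological")
})

test_that("scrambled starting positions stay inside the walker area", {
  w <- generate_walker(gait_model(), seed = 3)
  f1 <- w$frames[1, , ]
  lo <- apply(f1, 2, min) - 1e-12
  hi <- apply(f1, 2, max) + 1e-12
  for (sd in 1:1000) {
    s1 <- scramble(w, seed = sd)$frames[1, , ]
    expect_true(all(sweep(s1, 2, lo, `>=`)) && all(sweep(s1, 2, hi, `<=`)),
                info = paste("seed", sd))
  }
})

test_that("projection produces the stated angular size traces", {
  w <- generate_walker(gait_model(), seed = 1)
  rs <- project_view(w, "radial", "approach", "small")
  expect_equal(rs$size_trace[1], 1)
  expect_equal(rs$size_trace[30], 3)
  expect_equal(mean(rs$size_trace), 2)
  rr <- project_view(w, "radial", "recede", "small")
  expect_equal(rr$size_trace[1], 3)
  expect_equal(rr$size_trace[30], 1)
  ls <- project_view(w, "lateral", "left", "small")
  expect_true(all(ls$size_trace == 2))
  # ramp is linear in frame index
  expect_lt(max(abs(diff(rs$size_trace, differences = 2))), 1e-12)
})

test_that("mean angular size matches across plane/direction for each size", {
  w <- generate_walker(gait_model(), seed = 6)
  for (sz in c("small", "big")) {
    m <- c(mean(project_view(w, "lateral", "left", sz)$size_trace),
           mean(project_view(w, "lateral", "right", sz)$size_trace),
           mean(project_view(w, "radial", "approach", sz)$size_trace),
           mean(project_view(w, "radial", "recede", sz)$size_trace))
    expect_lt(diff(range(m)), 1e-9)
    # and the realized angular extent matches the trace frame by frame
    v <- project_view(w, "radial", "approach", sz)
    ext <- apply(v$frames[, , 2], 1, function(x) diff(range(x)))
    expect_lt(max(abs(ext - v$size_trace)), 1e-9)
  }
})

test_that("lateral stimuli keep the centroid fixed (treadmill convention)", {
  w <- generate_walker(gait_model(), seed = 2)
  v <- project_view(w, "lateral", "right", "big")
  centroids <- rowMeans(v$frames[, , 1])
  expect_lt(max(abs(centroids)), 1e-9)
})

test_that("incompatible plane/direction pairs are rejected", {
  w <- generate_walker(gait_model(), seed = 1)
  expect_error(project_view(w, "lateral", "approach", "small"),
               "incompatible")
  expect_error(project_view(w, "radial", "left", "small"), "incompatible")
})

test_that("stimulus CSV export writes frames and a JSON sidecar", {
  w <- generate_walker(gait_model(), seed = 1)
  v <- project_view(w, "radial", "approach", "big")
  path <- file.path(tempdir(), "stim.csv")
  write_stimulus(v, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 30 * 13)
  expect_equal(unique(df$size_deg[df$frame == 1]), 3)
  side <- jsonlite::read_json(sub("csv$", "json", path),
                              simplifyVector = TRUE)
  expect_identical(side$plane, "radial")
  expect_identical(side$direction, "approach")
  unlink(c(path, sub("csv$", "json", path)))
})
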