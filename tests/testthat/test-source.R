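# Small fixtures shared across blocks (built once per file)
HM <- head_model()
GRID_S <- source_grid(HM, spacing = 0.2)
LF_S <- build_leadfield(MONT, HM, GRID_S)

test_that("the dipole expansion matches the closed-form infinite-medium", {
  # independent oracle: direct evaluation of the dipole potential
  sigma <- 0.33; b <- 0.6; p <- c(0, 0, b)
  set.seed(2)
  for (i in 1:4) {
    m <- rnorm(3)
    e <- rnorm(3); e <- e / sqrt(sum(e^2))
    closed <- sum(m * (e - p)) / (4 * pi * sigma * sum((e - p)^2)^1.5)
    nmax <- 80
    cosg <- sum(e * c(0, 0, 1))
    P <- bmerp:::legendre_table(cosg, nmax)
    dP <- bmerp:::legendre_deriv_table(cosg, nmax)
    that <- e - cosg * c(0, 0, 1)
    that <- that / sqrt(sum(that^2))
    n <- seq_len(nmax)
    series <- sum(b^(n - 1) *
                    (n * m[3] * P[, 1] +
                       sum(m * that) * dP[, 1] * sqrt(1 - cosg^2))) /
      (4 * pi * sigma)
    expect_equal(series, closed, tolerance = 1e-6)
  }
})

test_that("shell transfer reduces to the single-sphere closed form", {
  hm1 <- head_model(conductivities = c(0.33, 0.33, 0.33))
  tf <- bmerp:::shell_transfer(hm1, 12)
  n <- 1:12
  expect_equal(tf, (2 * n + 1) / n, tolerance = 1e-10)
})

test_that("lead field is linear, average-referenced and axisymmetric", {
  expect_lt(max(abs(colSums(LF_S$gain))), 1e-9)
  # linearity in the moment is structural; check a random combination
  v <- 5
  cols <- LF_S$gain[, (3 * v - 2):(3 * v)]
  m <- c(0.3, -1.2, 0.7)
  expect_equal(as.numeric(cols %*% (2 * m)),
               2 * as.numeric(cols %*% m), tolerance = 1e-12)
  # radial dipole on the +z axis: equal potential at matched latitudes
  grid1 <- GRID_S
  grid1$pos <- matrix(c(0, 0, 0.5), 1)
  grid1$ijk <- matrix(0L, 1, 3)
  grid1$n <- 1L
  lf1 <- build_leadfield(MONT, HM, grid1)
  map <- lf1$gain[, 3]
  z <- round(MONT$z, 9)
  for (zz in unique(z)) {
    i <- which(z == zz)
    if (length(i) > 1) expect_lt(diff(range(map[i])), 1e-6)
  }
  gbad <- GRID_S
  gbad$pos[1, ] <- c(0, 0, 0.9)
  expect_error(build_leadfield(MONT, HM, gbad), "inside")
})

test_that("sLORETA has zero localization error on noiseless dipoles", {
  set.seed(31)
  alpha <- 1e-8 * sum(LF_S$gain^2) / 64
  draws <- 25
  vs <- sample(GRID_S$n, draws, replace = TRUE)
  phi <- sapply(seq_len(draws), function(i)
    LF_S$gain[, (3 * vs[i] - 2):(3 * vs[i])] %*% rnorm(3))
  sm <- sloreta_inverse(LF_S, phi, alpha = alpha)
  expect_equal(unname(apply(sm$power, 2, which.max)), vs)
})

test_that("sLORETA power is reference-invariant and quadratic", {
  phi <- LF_S$gain[, 10:12] %*% c(1, -2, 0.5)
  s1 <- sloreta_inverse(LF_S, phi)
  expect_equal(sloreta_inverse(LF_S, phi + 3)$power, s1$power,
               tolerance = 1e-9)
  expect_equal(sloreta_inverse(LF_S, -4 * phi)$power, 16 * s1$power,
               tolerance = 1e-9)
  expect_equal(sloreta_inverse(LF_S, 0 * phi)$power,
               rep(0, GRID_S$n), tolerance = 1e-12)
})

test_that("paired SnPM matches exhaustive enumeration at n = 5", {
  set.seed(12)
  n <- 5
  nn <- 40
  a <- matrix(rnorm(n * nn), n, nn) + 0.8
  b <- matrix(rnorm(n * nn), n, nn)
  grid <- list(ijk = cbind(seq_len(nn), 0L, 0L), n = nn)
  res <- snpm_paired(a, b, grid, n_rand = 5000, min_cluster = 1, seed = 3)
  expect_true(res$exhaustive)
  expect_equal(res$n_rand, 32)
  # independent brute force over all 32 sign patterns
  d <- a - b
  tfun <- function(x) mean(x) / (sd(x) / sqrt(length(x)))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  maxt <- apply(signs, 1, function(s)
    max(abs(apply(d * s, 2, tfun))))
  t_obs <- apply(d, 2, tfun)
  p_ref <- vapply(abs(t_obs), function(tv) mean(maxt >= tv - 1e-12),
                  numeric(1))
  expect_equal(res$p_corrected, p_ref, tolerance = 1e-12)
})

test_that("SnPM detects a planted focal difference and is alpha-monotone", {
  set.seed(40)
  grid <- source_grid(HM, spacing = 0.25)
  n <- 12
  nbr <- bmerp:::grid_adjacency_neighbors(grid)
  seednode <- which.min(rowSums(grid$pos^2))
  planted <- unique(c(seednode, unlist(nbr[seednode]),
                      unlist(nbr[unlist(nbr[seednode])])))
  a <- matrix(rnorm(n * grid$n), n, grid$n)
  a[, planted] <- a[, planted] + 5
  b <- matrix(rnorm(n * grid$n), n, grid$n)
  res <- snpm_paired(a, b, grid, n_rand = 1000, min_cluster = 5, seed = 9)
  expect_gte(nrow(res$clusters), 1)
  hit <- which(res$node_cluster > 0)
  expect_gte(length(intersect(hit, planted)) / length(planted), 0.8)
  res_low <- snpm_paired(a, b, grid, n_rand = 1000, alpha = 0.01,
                         min_cluster = 5, seed = 9)
  expect_lte(sum(res_low$node_cluster > 0), sum(res$node_cluster > 0))
  # A = B: no clusters
  res0 <- snpm_paired(b, b, grid, n_rand = 200, min_cluster = 1, seed = 2)
  expect_equal(nrow(res0$clusters), 0)
})
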