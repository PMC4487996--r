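#' Three-shell spherical head model
#'
#' Concentric-spheres volume conductor: brain, skull and scalp shells with
#' the canonical radii (0.87, 0.92, 1.0, normalized to head radius) and
#' conductivities (0.33, 0.0042, 0.33 S/m).
#'
#' @param radii increasing shell radii, outermost 1.
#' @param conductivities shell conductivities (S/m), inner to outer.
#' @return An object of class `head_model`.
#' @export
head_model <- function(radii = c(0.87, 0.92, 1.0),
                       conductivities = c(0.33, 0.0042, 0.33)) {
  if (!(radii[1] > 0 && radii[1] < radii[2] && radii[2] < radii[3] &&
        abs(radii[3] - 1) < 1e-12))
    stop_bad_arg("need 0 < r1 < r2 < r3 = 1")
  if (any(conductivities <= 0))
    stop_bad_arg("conductivities must be positive")
  structure(list(radii = radii, conductivities = conductivities),
            class = "head_model")
}

#' Regular source grid inside the inner shell
#'
#' Cubic lattice clipped to a sphere of radius `max_radius` (inside the
#' brain shell). Default spacing gives about 2,000 nodes.
#'
#' @param headmodel a [head_model()].
#' @param spacing lattice spacing in normalized head-radius units.
#' @param max_radius outer clip radius for node centers (must be < r1).
#' @return An object of class `source_grid`: `pos` (nodes x 3), `ijk`
#'   (integer lattice coordinates), `spacing`, `n`.
#' @export
source_grid <- function(headmodel = head_model(), spacing = 0.09,
                        max_radius = 0.8 * headmodel$radii[1]) {
  if (spacing <= 0) stop_bad_arg("spacing must be positive")
  if (max_radius >= headmodel$radii[1])
    stop_bad_arg("grid must lie strictly inside the inner shell")
  r <- base::seq(-max_radius, max_radius, by = spacing)
  g <- as.matrix(expand.grid(x = r, y = r, z = r))
  keep <- sqrt(rowSums(g^2)) <= max_radius
  pos <- g[keep, , drop = FALSE]
  dimnames(pos) <- NULL
  ijk <- round(sweep(pos, 2, c(min(r), min(r), min(r)), `-`) / spacing)
  structure(list(pos = pos, ijk = ijk, spacing = spacing,
                 n = nrow(pos), max_radius = max_radius),
            class = "source_grid")
}

# Per-degree transfer factors for the concentric three-shell model: solves
# the radial boundary-value problem (continuity of potential and radial
# current at the shell interfaces, zero current at the scalp surface) for a
# unit source coefficient in the innermost compartment. Returns, for each
# degree n, the scalp-surface coefficient multiplying the source term
# Q r^-(n+1) of the infinite-medium expansion.
shell_transfer <- function(headmodel, nmax = 60) {
  r1 <- headmodel$radii[1]; r2 <- headmodel$radii[2]; r3 <- headmodel$radii[3]
  s1 <- headmodel$conductivities[1]
  s2 <- headmodel$conductivities[2]
  s3 <- headmodel$conductivities[3]
  out <- numeric(nmax)
  for (n in base::seq_len(nmax)) {
    # unknowns: A1, A2, B2, A3, B3 (Q = 1)
    # V_i = A_i r^n + B_i r^-(n+1); V_1 has B_1 = Q = 1
    A <- matrix(0, 5, 5)
    b <- numeric(5)
    rp <- function(r) r^n
    rm <- function(r) r^-(n + 1)
    dp <- function(r) n * r^(n - 1)
    dm <- function(r) -(n + 1) * r^-(n + 2)
    # continuity of V at r1: A1 r1^n + rm(r1) = A2 r1^n + B2 rm(r1)
    A[1, ] <- c(rp(r1), -rp(r1), -rm(r1), 0, 0);        b[1] <- -rm(r1)
    # continuity of sigma dV/dr at r1
    A[2, ] <- c(s1 * dp(r1), -s2 * dp(r1), -s2 * dm(r1), 0, 0)
    b[2] <- -s1 * dm(r1)
    # continuity of V at r2
    A[3, ] <- c(0, rp(r2), rm(r2), -rp(r2), -rm(r2));   b[3] <- 0
    # continuity of sigma dV/dr at r2
    A[4, ] <- c(0, s2 * dp(r2), s2 * dm(r2), -s3 * dp(r2), -s3 * dm(r2))
    b[4] <- 0
    # no radial current through the scalp surface
    A[5, ] <- c(0, 0, 0, dp(r3), dm(r3));               b[5] <- 0
    sol <- solve(A, b)
    out[n] <- sol[4] * rp(r3) + sol[5] * rm(r3)   # scalp potential coeff.
  }
  out
}

#' Analytic lead field for a three-shell spherical head
#'
#' Gain matrix mapping dipole moments at the grid nodes to average-referenced
#' potentials at the montage electrodes, computed from the truncated Legendre
#' series (default 60 terms) of the concentric-spheres solution.
#'
#' @param montage electrode montage (electrodes on the outer surface).
#' @param headmodel a [head_model()].
#' @param grid a [source_grid()].
#' @param nterms number of Legendre terms.
#' @return An object of class `leadfield`: `gain` (channels x 3*nodes; node
#'   v occupies columns 3v-2..3v for moments along x, y, z), plus the inputs.
#' @export
build_leadfield <- function(montage, headmodel = head_model(),
                            grid = source_grid(headmodel), nterms = 60) {
  assert_montage(montage)
  rad <- sqrt(rowSums(grid$pos^2))
  if (any(rad >= headmodel$radii[1]))
    stop_bad_arg("all source nodes must lie strictly inside the inner shell")
  el <- montage_positions(montage)
  nch <- nrow(el)
  nn <- grid$n
  tfac <- shell_transfer(headmodel, nterms)
  s1 <- headmodel$conductivities[1]
  gain <- matrix(0, nch, 3 * nn)
  nseq <- base::seq_len(nterms)
  for (v in base::seq_len(nn)) {
    b <- rad[v]
    if (b < 1e-9) {
      phat <- c(0, 0, 1); b <- 1e-9
    } else phat <- grid$pos[v, ] / b
    cosg <- clamp1(as.numeric(el %*% phat))
    P <- legendre_table(cosg, nterms)      # nterms x nch
    dP <- legendre_deriv_table(cosg, nterms)
    sing <- sqrt(pmax(0, 1 - cosg^2))
    # t-hat: unit tangent at the source pointing toward each electrode
    that <- el - outer(cosg, phat)
    tn <- sqrt(rowSums(that^2))
    that[tn > 1e-12, ] <- that[tn > 1e-12, ] / tn[tn > 1e-12]
    that[tn <= 1e-12, ] <- 0
    wn <- tfac * b^(nseq - 1) / (4 * pi * s1)
    rad_sum <- as.numeric((wn * nseq) %*% P)          # per electrode
    tan_sum <- as.numeric(wn %*% (dP * rep(sing, each = nterms)))
    for (ax in 1:3) {
      m <- c(0, 0, 0); m[ax] <- 1
      mr <- sum(m * phat)
      mt <- as.numeric(that %*% m)
      gain[, 3 * (v - 1) + ax] <- mr * rad_sum + mt * tan_sum
    }
  }
  gain <- gain - matrix(colMeans(gain), nch, 3 * nn, byrow = TRUE)
  structure(list(gain = gain, montage = montage, headmodel = headmodel,
                 grid = grid, nterms = nterms),
            class = "leadfield")
}

#' sLORETA inverse solution
#'
#' Standardized minimum-norm estimate: the regularized minimum-norm current
#' density is standardized node-wise by the corresponding 3 x 3 block of the
#' resolution matrix, yielding a non-negative pseudo-power per node. This
#' estimator has zero localization error for noiseless single-dipole fields.
#'
#' @param leadfield a [build_leadfield()] object.
#' @param scalp numeric vector (or channels x k matrix) of average-referenced
#'   scalp potentials.
#' @param alpha Tikhonov regularization; default scales with the mean sensor
#'   power of the gain. `alpha = 0` uses the pseudo-inverse.
#' @return An object of class `source_map`: `power` (nodes [x k]), `alpha`,
#'   `j` (3 x nodes x k current estimates).
#' @export
sloreta_inverse <- function(leadfield, scalp,
                            alpha = 1e-3 * sum(leadfield$gain^2) /
                              nrow(leadfield$gain)) {
  K <- leadfield$gain
  nch <- nrow(K)
  nn <- leadfield$grid$n
  scalp <- as.matrix(scalp)
  if (nrow(scalp) != nch) stop_bad_arg("scalp map has wrong channel count")
  scalp <- scalp - matrix(colMeans(scalp), nch, ncol(scalp), byrow = TRUE)
  H <- diag(nch) - 1 / nch
  M <- tcrossprod(K) + alpha * H
  Minv <- sym_pinv(M)
  TT <- crossprod(K, Minv)          # 3n x channels
  J <- TT %*% scalp                 # 3n x k
  B <- Minv %*% K                   # for the resolution-matrix blocks
  power <- matrix(0, nn, ncol(scalp))
  for (v in base::seq_len(nn)) {
    ix <- (3 * v - 2):(3 * v)
    S <- crossprod(K[, ix, drop = FALSE], B[, ix, drop = FALSE])
    Sinv <- tryCatch(solve(S), error = function(e)
      stop_bad_arg("singular resolution block at node ", v,
                   "; use alpha > 0"))
    for (kk in base::seq_len(ncol(scalp)))
      power[v, kk] <- crossprod(J[ix, kk], Sinv %*% J[ix, kk])
  }
  power[power < 0] <- 0
  structure(list(power = if (ncol(power) == 1) as.numeric(power) else power,
                 alpha = alpha, j = J, grid = leadfield$grid),
            class = "source_map")
}

grid_adjacency_neighbors <- function(grid) {
  key <- grid$ijk %*% c(1L, 100003L, 100003L^2)
  lookup <- new.env(hash = TRUE, size = grid$n)
  for (i in base::seq_len(grid$n))
    assign(as.character(key[i]), i, envir = lookup)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  lapply(base::seq_len(grid$n), function(i) {
    out <- integer(0)
    for (o in base::seq_len(6)) {
      kk <- as.character(sum((grid$ijk[i, ] + offs[o, ]) *
                               c(1L, 100003L, 100003L^2)))
      j <- lookup[[kk]]
      if (!is.null(j)) out <- c(out, j)
    }
    out
  })
}

#' Paired sign-flip permutation test on source maps (SnPM style)
#'
#' Per-node paired t statistics between two conditions, family-wise corrected
#' with the max-statistic distribution over sign-flip randomizations
#' (exhaustive enumeration when `2^n` does not exceed `n_rand`). Surviving
#' nodes are grouped by 6-neighbor lattice adjacency and clusters smaller
#' than `min_cluster` nodes are discarded.
#'
#' @param maps_a,maps_b subjects x nodes matrices of source power.
#' @param grid the [source_grid()] the maps live on.
#' @param n_rand number of randomizations (default 5000).
#' @param alpha family-wise alpha.
#' @param min_cluster minimum cluster extent in nodes (default 30).
#' @param seed integer seed.
#' @return An object of class `snpm_result`: `t` (per node), `t_crit`,
#'   `p_corrected` (per node, max-statistic), `clusters` (data frame),
#'   `node_cluster` (cluster id per node, 0 = none), `exhaustive`.
#' @export
snpm_paired <- function(maps_a, maps_b, grid, n_rand = 5000, alpha = 0.05,
                        min_cluster = 30, seed = 1) {
  n <- nrow(maps_a)
  if (n < 3) stop_bad_arg("need at least 3 subjects")
  if (!all(dim(maps_a) == dim(maps_b)))
    stop_bad_arg("condition maps must have matching dimensions")
  d <- maps_a - maps_b
  nn <- ncol(d)
  ss <- colSums(d^2)
  tstat_for <- function(signs) {
    m <- as.numeric(signs %*% d) / n
    v <- (ss - n * m^2) / (n - 1)
    ifelse(v <= 0, 0, m / sqrt(v / n))
  }
  t_obs <- tstat_for(matrix(1, 1, n))
  exhaustive <- 2^n <= n_rand
  if (exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  } else {
    set.seed(child_seed(seed, "snpm"))
    signs <- matrix(sample(c(-1, 1), n_rand * n, replace = TRUE), n_rand, n)
  }
  maxt <- numeric(nrow(signs))
  chunk <- 500L
  for (st in base::seq(1L, nrow(signs), by = chunk)) {
    ix <- st:min(st + chunk - 1L, nrow(signs))
    m <- (signs[ix, , drop = FALSE] %*% d) / n
    v <- sweep(-n * m^2, 2, ss, `+`) / (n - 1)
    tt <- abs(m / sqrt(v / n))
    tt[!is.finite(tt)] <- 0
    maxt[ix] <- apply(tt, 1, max)
  }
  t_crit <- stats::quantile(maxt, 1 - alpha, type = 1, names = FALSE)
  p_corr <- vapply(abs(t_obs), function(tv) mean(maxt >= tv - 1e-12),
                   numeric(1))
  sig <- abs(t_obs) > t_crit

  node_cluster <- integer(nn)
  clusters <- list()
  if (any(sig)) {
    nbrs <- grid_adjacency_neighbors(grid)
    lab <- 0L
    for (v0 in which(sig)) {
      if (node_cluster[v0] != 0) next
      lab <- lab + 1L
      stack <- v0
      node_cluster[v0] <- lab
      members <- integer(0)
      while (length(stack)) {
        v <- stack[length(stack)]
        stack <- stack[-length(stack)]
        members <- c(members, v)
        for (w in nbrs[[v]]) if (sig[w] && node_cluster[w] == 0) {
          node_cluster[w] <- lab
          stack <- c(stack, w)
        }
      }
      clusters[[lab]] <- data.frame(cluster = lab, n_nodes = length(members),
                                    t_max = max(abs(t_obs[members])),
                                    stringsAsFactors = FALSE)
    }
    cl <- do.call(rbind, clusters)
    drop <- cl$cluster[cl$n_nodes < min_cluster]
    node_cluster[node_cluster %in% drop] <- 0L
    cl <- cl[!cl$cluster %in% drop, , drop = FALSE]
  } else cl <- data.frame(cluster = integer(), n_nodes = integer(),
                          t_max = numeric())
  structure(list(t = t_obs, t_crit = t_crit, p_corrected = p_corr,
                 clusters = cl, node_cluster = node_cluster,
                 n_rand = nrow(signs), exhaustive = exhaustive,
                 alpha = alpha, min_cluster = min_cluster, seed = seed),
            class = "snpm_result")
}

#' @export
print.snpm_result <- function(x, ...) {
  cat(sprintf("<snpm_result> %s randomizations: %d, |t| > %.3f, %d cluster(s)\n",
              if (x$exhaustive) "exhaustive" else "Monte Carlo",
              x$n_rand, x$t_crit, nrow(x$clusters)))
  invisible(x)
}

#' Subject-level mean scalp maps over a component window
#'
#' Averages an `erp_set` over a time window, returning one scalp map per
#' condition -- the input format for [sloreta_inverse()] followed by
#' [snpm_paired()].
#'
#' @param erp an `erp_set`.
#' @param window `c(t0, t1)` ms.
#' @return channels x conditions matrix.
#' @export
window_maps <- function(erp, window) {
  sel <- erp$times_ms >= window[1] & erp$times_ms <= window[2]
  sapply(base::seq_along(erp$conditions), function(ci)
    colMeans(erp$data[sel, , ci]))
}
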