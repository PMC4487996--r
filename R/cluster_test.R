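#' Point-wise paired t-test with a spatiotemporal contiguity criterion
#'
#' Computes a paired t statistic at every (sample, electrode), thresholds it
#' at the Bonferroni-corrected (over electrodes) two-sided alpha level, and
#' groups suprathreshold points of the same sign into spatiotemporally
#' connected clusters (adjacent samples within an electrode, neighboring
#' electrodes within a sample). A cluster counts as significant only if its
#' temporal extent is strictly greater than `min_duration` ms and it spans
#' strictly more than `min_electrodes` adjacency-connected electrodes.
#'
#' @param erps_a,erps_b lists of per-subject ERP matrices (samples x
#'   channels), same subjects in the same order.
#' @param times_ms sample times (ms).
#' @param adjacency logical electrode adjacency matrix
#'   (see [montage_adjacency()]).
#' @param alpha two-sided alpha before electrode correction.
#' @param min_duration minimal cluster duration (ms, strict).
#' @param min_electrodes minimal number of contiguous electrodes (strict).
#' @return An object of class `pointwise_test`: `t` (samples x channels),
#'   `mask` (suprathreshold), `t_crit`, `clusters` (data frame with
#'   `cluster`, `t_start_ms`, `t_end_ms`, `n_electrodes`, `electrodes`,
#'   `sign`), and `cluster_map` (cluster index per suprathreshold point, 0
#'   elsewhere).
#' @export
pointwise_cluster_test <- function(erps_a, erps_b, times_ms, adjacency,
                                   alpha = 0.05, min_duration = 10,
                                   min_electrodes = 3) {
  n <- length(erps_a)
  if (n != length(erps_b)) stop_bad_arg("subject lists differ in length")
  if (n < 3) stop_bad_arg("need at least 3 subjects")
  ns <- nrow(erps_a[[1]])
  nch <- ncol(erps_a[[1]])
  fs <- 1000 / stats::median(diff(times_ms))
  dsum <- matrix(0, ns, nch)
  dsq <- matrix(0, ns, nch)
  for (i in base::seq_len(n)) {
    di <- erps_a[[i]] - erps_b[[i]]
    dsum <- dsum + di
    dsq <- dsq + di^2
  }
  mu <- dsum / n
  s2 <- (dsq - n * mu^2) / (n - 1)
  s2[s2 < 0] <- 0
  tmat <- ifelse(s2 == 0, 0, mu / sqrt(s2 / n))
  t_crit <- stats::qt(1 - (alpha / nch) / 2, n - 1)
  mask <- abs(tmat) > t_crit

  clusters <- list()
  cluster_map <- matrix(0L, ns, nch)
  if (any(mask)) {
    sgn <- sign(tmat) * mask
    lab <- 0L
    visited <- matrix(FALSE, ns, nch)
    idx <- which(mask, arr.ind = TRUE)
    nbr_ch <- lapply(base::seq_len(nch), function(c1) which(adjacency[c1, ]))
    for (r in base::seq_len(nrow(idx))) {
      s0 <- idx[r, 1]; c0 <- idx[r, 2]
      if (visited[s0, c0]) next
      lab <- lab + 1L
      sgn0 <- sgn[s0, c0]
      queue <- list(c(s0, c0))
      visited[s0, c0] <- TRUE
      members <- matrix(0L, 0, 2)
      while (length(queue) > 0) {
        pt <- queue[[length(queue)]]
        queue[[length(queue)]] <- NULL
        members <- rbind(members, pt)
        s <- pt[1]; ch <- pt[2]
        cand <- rbind(
          if (s > 1) c(s - 1, ch),
          if (s < ns) c(s + 1, ch),
          cbind(s, nbr_ch[[ch]]))
        for (j in base::seq_len(nrow(cand))) {
          ss <- cand[j, 1]; cc <- cand[j, 2]
          if (!visited[ss, cc] && sgn[ss, cc] == sgn0) {
            visited[ss, cc] <- TRUE
            queue[[length(queue) + 1]] <- c(ss, cc)
          }
        }
      }
      cluster_map[members] <- lab
      span <- range(members[, 1])
      dur <- (span[2] - span[1] + 1) / fs * 1000
      chans <- unique(members[, 2])
      clusters[[lab]] <- data.frame(
        cluster = lab, t_start_ms = times_ms[span[1]],
        t_end_ms = times_ms[span[2]], duration_ms = dur,
        n_electrodes = length(chans),
        electrodes = paste(sort(chans), collapse = ","),
        sign = sgn0, keep = dur > min_duration &&
          length(chans) > min_electrodes,
        stringsAsFactors = FALSE)
    }
  }
  cl <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(cluster = integer(), t_start_ms = numeric(),
               t_end_ms = numeric(), duration_ms = numeric(),
               n_electrodes = integer(), electrodes = character(),
               sign = numeric(), keep = logical())
  structure(list(t = tmat, mask = mask, t_crit = t_crit,
                 clusters = cl[cl$keep, , drop = FALSE],
                 all_clusters = cl, cluster_map = cluster_map,
                 times_ms = times_ms, alpha = alpha,
                 min_duration = min_duration,
                 min_electrodes = min_electrodes, n_subjects = n),
            class = "pointwise_test")
}

#' @export
print.pointwise_test <- function(x, ...) {
  cat(sprintf("<pointwise_test> n = %d, |t| > %.3f; %d significant cluster(s)\n",
              x$n_subjects, x$t_crit, nrow(x$clusters)))
  if (nrow(x$clusters) > 0)
    print(x$clusters[, c("cluster", "t_start_ms", "t_end_ms", "duration_ms",
                         "n_electrodes", "sign")], row.names = FALSE)
  invisible(x)
}
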