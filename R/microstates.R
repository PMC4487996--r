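#' Global field power
#'
#' Spatial standard deviation of each map (row) of a time x channels series;
#' reference-invariant index of momentary response strength.
#'
#' @param maps matrix (time x channels) or an `erp_set` condition slice.
#' @return Numeric vector of GFP values (uV).
#' @export
gfp <- function(maps) {
  maps <- as.matrix(maps)
  m <- rowMeans(maps)
  sqrt(rowMeans((maps - m)^2))
}

# Concatenate the analysis-span maps of several conditions of a grand
# average into one time x channels matrix with bookkeeping.
concat_condition_maps <- function(erp, span = c(80, 500),
                                  conditions = erp$conditions) {
  sel <- erp$times_ms >= span[1] & erp$times_ms <= span[2]
  maps <- do.call(rbind, lapply(conditions, function(cc)
    erp$data[sel, , match(cc, erp$conditions)]))
  list(maps = maps, condition = rep(conditions, each = sum(sel)),
       times_ms = rep(erp$times_ms[sel], length(conditions)))
}

#' Polarity-sensitive spatial k-means segmentation
#'
#' Clusters GFP-normalized scalp maps (polarity matters: maps are not
#' sign-invariant, as appropriate for ERP data) with k-means, best of
#' `restarts` starts, for each candidate number of template maps. The
#' residual topographic variance and the predictive cross-validation score
#' are recorded for each K.
#'
#' @param maps matrix of maps (time x channels), average-referenced.
#' @param k_range candidate numbers of template maps.
#' @param restarts random restarts per K.
#' @param seed integer seed (results are deterministic given the seed).
#' @return A list of `template_set` objects (one per K), each with `templates`
#'   (K x channels, unit norm), `K`, `labels`, `residual_var`, `cv`,
#'   `gev`, `restarts`, `seed`.
#' @export
microstate_segment <- function(maps, k_range = 1:8, restarts = 100,
                               seed = 1) {
  maps <- as.matrix(maps)
  nc <- ncol(maps)
  g <- gfp(maps)
  if (any(g <= 0)) stop_bad_arg("maps with zero GFP cannot be normalized")
  X <- maps / (g * sqrt(nc))      # unit-norm rows, topography only
  ndistinct <- nrow(unique(round(X, 12)))
  out <- list()
  for (K in k_range) {
    if (K > ndistinct)
      stop_bad_arg("K = ", K, " exceeds the number of distinct maps")
    set.seed(child_seed(seed, paste0("kmeans", K)))
    km <- stats::kmeans(X, centers = K, nstart = restarts, iter.max = 100)
    tpl <- km$centers
    tpl <- tpl / sqrt(rowSums(tpl^2))
    # residual topographic variance of the normalized maps
    fit <- rowSums(X * tpl[km$cluster, , drop = FALSE])
    sigma2 <- sum(rowSums(X^2) - fit^2) / (nrow(X) * (nc - 1))
    cv <- sigma2 * ((nc - 1) / (nc - 1 - K))^2
    gev_t <- (g * fit)^2
    out[[as.character(K)]] <- structure(
      list(templates = tpl, K = K, labels = km$cluster,
           residual_var = sigma2, cv = cv,
           gev = sum(gev_t) / sum(g^2), restarts = restarts, seed = seed),
      class = "template_set")
  }
  out
}

#' Cross-validation choice of the number of template maps
#'
#' Picks the K minimizing the modified predictive-residual criterion
#' CV(K) = sigma2_K * ((C - 1) / (C - 1 - K))^2, with C the channel count
#' and sigma2_K the residual topographic variance: the smallest set of maps
#' that still explains the series.
#'
#' @param templatesets list returned by [microstate_segment()].
#' @return The selected K (integer).
#' @export
select_k <- function(templatesets) {
  if (length(templatesets) < 2)
    stop_bad_arg("need at least two candidate K values")
  cvs <- vapply(templatesets, function(ts) ts$cv, numeric(1))
  templatesets[[which.min(cvs)]]$K
}

#' Back-fit template maps to a condition's map series
#'
#' Labels every timepoint with the template of highest (signed) spatial
#' correlation, merges segments shorter than `min_ms` into their
#' better-correlated neighbor, and computes the global explained variance
#' GEV = sum_t (GFP_t corr_t)^2 / sum_t GFP_t^2.
#'
#' @param templates a `template_set` (or K x channels matrix).
#' @param maps condition map series (time x channels).
#' @param times_ms sample times (ms).
#' @param min_ms minimum segment duration for the smoothing pass.
#' @return An object of class `segmentation`: `labels`, `segments` (data
#'   frame `t_start_ms`, `t_end_ms`, `template`), `gev`, `gev_per_template`.
#' @export
backfit <- function(templates, maps, times_ms, min_ms = 20) {
  tpl <- if (inherits(templates, "template_set")) templates$templates
  else as.matrix(templates)
  maps <- as.matrix(maps)
  ctr <- function(m) m - rowMeans(m)
  A <- ctr(maps)
  B <- ctr(tpl)
  co <- (A %*% t(B)) /
    (sqrt(rowSums(A^2)) %o% sqrt(rowSums(B^2)))
  co[!is.finite(co)] <- 0
  labels <- max.col(co, ties.method = "first")
  # merge short segments into the neighbor with higher mean correlation
  fs <- 1000 / stats::median(diff(times_ms))
  min_len <- ceiling(min_ms / 1000 * fs)
  repeat {
    r <- rle(labels)
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths < min_len)
    if (length(short) == 0) break
    j <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    span <- starts[j]:ends[j]
    left <- if (j > 1) r$values[j - 1] else NA
    right <- if (j < length(r$values)) r$values[j + 1] else NA
    cand <- stats::na.omit(c(left, right))
    sc <- vapply(cand, function(tp) mean(co[span, tp]), numeric(1))
    labels[span] <- cand[which.max(sc)]
  }
  g <- gfp(maps)
  fit_corr <- co[cbind(base::seq_along(labels), labels)]
  gev_t <- (g * fit_corr)^2 / sum(g^2)
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  segments <- data.frame(t_start_ms = times_ms[starts],
                         t_end_ms = times_ms[ends], template = r$values)
  structure(list(labels = labels,
                 segments = segments,
                 gev = sum(gev_t),
                 gev_per_template = tapply(gev_t, factor(labels,
                   levels = base::seq_len(nrow(tpl))), sum, default = 0),
                 times_ms = times_ms),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d segments, GEV = %.3f\n",
              nrow(x$segments), x$gev))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Synthetic multi-condition map series with planted stable topographies
#'
#' Builds grand-average-like map series for several conditions from K
#' quasi-orthogonal average-referenced topographies active in consecutive
#' stable periods, with condition-specific amplitude envelopes and optional
#' sensor noise. Used to exercise the segmentation and model-selection
#' stages under known ground truth.
#'
#' @param montage electrode montage.
#' @param k number of planted topographies.
#' @param n_conditions number of conditions.
#' @param span analysis span in ms.
#' @param fs sampling rate (Hz).
#' @param snr amplitude-to-noise ratio (RMS); `Inf` for noise-free.
#' @param seed integer seed.
#' @return List with `series` (list of time x channels matrices per
#'   condition), `times_ms`, `truth` (K x channels planted topographies),
#'   `labels` (true period per timepoint).
#' @export
simulate_microstate_series <- function(montage = biosemi64_montage(), k = 5,
                                       n_conditions = 4, span = c(80, 500),
                                       fs = 1024, snr = 10, seed = 1) {
  set.seed(child_seed(seed, "msseries"))
  nch <- nrow(montage)
  raw <- matrix(rnorm(k * nch), k, nch)
  raw <- raw - rowMeans(raw)
  tpl <- qr.Q(qr(t(raw)))[, base::seq_len(k)]
  tpl <- t(tpl)
  tpl <- tpl - rowMeans(tpl)           # re-center (QR can offset slightly)
  tpl <- tpl / sqrt(rowSums(tpl^2))
  times <- base::seq(span[1], span[2], by = 1000 / fs)
  nt <- length(times)
  period <- rep(base::seq_len(k), each = ceiling(nt / k))[base::seq_len(nt)]
  series <- vector("list", n_conditions)
  for (cc in base::seq_len(n_conditions)) {
    amp <- 2 + runif(k, 0, 2)          # condition-specific strengths
    env <- amp[period] * (1 + 0.3 * sin(2 * pi * (times - span[1]) / 180 + cc))
    m <- env * tpl[period, , drop = FALSE]
    if (is.finite(snr)) {
      noise <- matrix(rnorm(nt * nch), nt, nch)
      noise <- noise - rowMeans(noise)
      noise <- noise * (mean(abs(env)) / snr) / sqrt(rowMeans(noise^2))
    } else noise <- 0
    series[[cc]] <- m + noise
  }
  names(series) <- paste0("cond", base::seq_len(n_conditions))
  list(series = series, times_ms = times, truth = tpl, labels = period)
}
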