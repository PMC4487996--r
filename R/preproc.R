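#' Band-pass filter specification
#'
#' @param hp high-pass cutoff (Hz), 0.17 by default.
#' @param lp low-pass cutoff (Hz), 30 by default.
#' @param order low-pass Butterworth order (the high-pass stage uses order
#'   2); both stages are applied forward and backward, so the effective
#'   response is zero-phase with squared magnitude.
#' @param zero_phase logical; kept for provenance (always applied zero-phase).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(hp = 0.17, lp = 30, order = 4, zero_phase = TRUE) {
  if (!(hp > 0 && lp > hp)) stop_bad_arg("need 0 < hp < lp")
  structure(list(hp = hp, lp = lp, order = order, zero_phase = zero_phase),
            class = "filter_spec")
}

# Zero-phase Butterworth band-pass of a samples x k matrix.
filtfilt_matrix <- function(x, spec, fs) {
  ny <- fs / 2
  if (spec$lp >= ny) stop_bad_arg("low-pass cutoff must be below Nyquist")
  bh <- signal::butter(2, spec$hp / ny, type = "high")
  bl <- signal::butter(spec$order, spec$lp / ny, type = "low")
  # no edge extension: with the mean-steady-state initialization the edge
  # transients are smaller than with odd extension for the very low
  # high-pass cutoff (the extension itself injects low-frequency content)
  y <- .filtfilt_mat(bh$b, bh$a, x, 0L, filter_zi(bh$b, bh$a))
  .filtfilt_mat(bl$b, bl$a, y, 0L, filter_zi(bl$b, bl$a))
}

#' Offline band-pass filtering of epochs
#'
#' Applies the 0.17-30 Hz (by default) Butterworth band-pass forward and
#' backward (zero phase, no group delay) to every trial and channel.
#'
#' @param epochs an `epochs_set`.
#' @param spec a [filter_spec()].
#' @return The filtered `epochs_set`.
#' @export
bandpass <- function(epochs, spec = filter_spec()) {
  stopifnot(inherits(epochs, "epochs_set"))
  d <- dim(epochs$data)
  dn <- dimnames(epochs$data)
  x <- epochs$data
  dim(x) <- c(d[1], d[2] * d[3])
  x <- filtfilt_matrix(x, spec, epochs$fs)
  dim(x) <- d
  dimnames(x) <- dn
  epochs$data <- x
  epochs$filter <- spec
  epochs
}

#' Average-reference re-referencing
#'
#' Subtracts the instantaneous mean over channels from every channel, so the
#' channel mean is zero at every sample of every trial.
#'
#' @param epochs an `epochs_set`.
#' @return The re-referenced `epochs_set`.
#' @export
rereference_average <- function(epochs) {
  stopifnot(inherits(epochs, "epochs_set"))
  d <- dim(epochs$data)
  if (d[2] < 2) stop_bad_arg("average reference needs at least 2 channels")
  epochs$data <- .avg_ref(epochs$data, d[1], d[2], d[3])
  epochs
}

#' Pre-stimulus baseline correction
#'
#' Removes, per trial and channel, the mean over the baseline window
#' (default -100..0 ms).
#'
#' @param epochs an `epochs_set`.
#' @param window `c(t0, t1)` in ms; must lie within the epoch.
#' @return The baseline-corrected `epochs_set`.
#' @export
baseline_correct <- function(epochs, window = c(-100, 0)) {
  stopifnot(inherits(epochs, "epochs_set"))
  sel <- epochs$times_ms >= window[1] & epochs$times_ms <= window[2]
  if (!any(sel) || window[1] < min(epochs$times_ms) - 1e-9 ||
      window[2] > max(epochs$times_ms) + 1e-9)
    stop_bad_arg("baseline window outside the epoch span")
  d <- dim(epochs$data)
  epochs$data <- .baseline(epochs$data, d[1], d[2], d[3], which(sel))
  epochs
}

#' Amplitude-threshold artifact rejection
#'
#' Flags a trial as rejected when any channel sample strictly exceeds the
#' threshold in absolute value. Data are not modified; the retention mask is
#' stored in `$retain`.
#'
#' @param epochs an `epochs_set`.
#' @param threshold rejection threshold in uV (default 100).
#' @return The `epochs_set` with `$retain` filled in.
#' @export
reject_artifacts <- function(epochs, threshold = 100) {
  stopifnot(inherits(epochs, "epochs_set"))
  if (threshold <= 0) stop_bad_arg("threshold must be positive")
  d <- dim(epochs$data)
  mx <- .max_abs_trial(epochs$data, d[1], d[2], d[3])
  epochs$retain <- mx <= threshold   # rejected iff strictly exceeding
  epochs$reject_threshold <- threshold
  epochs
}

# Perrin-style spherical-spline basis g(cos angle), elementwise on a matrix.
spline_g_mat <- function(cosmat, m = 4, nterms = 50) {
  out <- matrix(0, nrow(cosmat), ncol(cosmat))
  n <- base::seq_len(nterms)
  w <- (2 * n + 1) / (n * (n + 1))^m
  p <- legendre_table(as.numeric(cosmat), nterms)
  out[] <- as.numeric(w %*% p) / (4 * pi)
  out
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces the listed channels with Perrin-style spherical-spline estimates
#' computed from the remaining channels (stiffness order m = 4, 50 Legendre
#' terms, ridge regularization 1e-5). Good channels are untouched.
#'
#' @param epochs an `epochs_set`.
#' @param bad_labels character vector of channel labels to re-interpolate.
#' @param montage electrode montage.
#' @param m spline stiffness order.
#' @param nterms number of Legendre terms.
#' @param lambda ridge regularization added to the spline system.
#' @return The `epochs_set` with bad channels replaced.
#' @export
interpolate_channels <- function(epochs, bad_labels,
                                 montage = biosemi64_montage(), m = 4,
                                 nterms = 50, lambda = 1e-5) {
  stopifnot(inherits(epochs, "epochs_set"))
  if (length(bad_labels) == 0) return(epochs)
  if (!all(bad_labels %in% epochs$labels))
    stop_bad_arg("unknown channel label(s): ",
                 paste(setdiff(bad_labels, epochs$labels), collapse = ", "))
  if (length(bad_labels) >= 0.25 * length(epochs$labels))
    stop_bad_arg("too many bad channels (>= 25% of the montage)")
  pos <- montage_positions(montage)[match(epochs$labels, montage$label), ]
  bad <- match(bad_labels, epochs$labels)
  good <- setdiff(base::seq_along(epochs$labels), bad)
  cg <- pos[good, ] %*% t(pos[good, ])
  cb <- pos[bad, , drop = FALSE] %*% t(pos[good, ])
  cg[cg > 1] <- 1; cg[cg < -1] <- -1
  cb[cb > 1] <- 1; cb[cb < -1] <- -1
  G <- spline_g_mat(cg, m, nterms) + diag(lambda, length(good))
  Gb <- spline_g_mat(cb, m, nterms)
  # solve [G 1; 1' 0] [c; d] = [v; 0], then v_bad = Gb c + d
  A <- rbind(cbind(G, 1), c(rep(1, length(good)), 0))
  d <- dim(epochs$data)
  x <- epochs$data
  for (tr in base::seq_len(d[3])) {
    v <- t(x[, good, tr])                      # good channels x samples
    sol <- solve(A, rbind(v, 0))
    cs <- sol[base::seq_len(length(good)), , drop = FALSE]
    ds <- sol[length(good) + 1, ]
    est <- Gb %*% cs + matrix(ds, nrow(Gb), ncol(cs), byrow = TRUE)
    x[, bad, tr] <- t(est)
  }
  epochs$data <- x
  epochs$interpolated <- bad_labels
  epochs
}

#' Average retained trials into per-condition ERPs
#'
#' Averages, per analysis condition, the retained (artifact-free),
#' behaviorally correct, non-target trials. Cyclist (target) trials are
#' excluded, leaving the four analysis conditions walker/scrambled x
#' radial/lateral; with `split_direction = TRUE` each condition is further
#' split by motion direction.
#'
#' @param epochs an `epochs_set` with retention mask and behavior present.
#' @param split_direction split conditions by direction as well.
#' @return An object of class `erp_set`: `data` (samples x channels x
#'   conditions), `conditions`, `n_trials`, `times_ms`, `fs`, `labels`,
#'   `subject`.
#' @export
average_erps <- function(epochs, split_direction = FALSE) {
  stopifnot(inherits(epochs, "epochs_set"))
  if (all(is.na(epochs$retain)))
    stop_bad_arg("run reject_artifacts() before averaging")
  des <- epochs$design
  keep <- epochs$retain & des$correct & des$motion != "cyclist"
  cond <- if (split_direction)
    paste(des$condition, des$direction, sep = "_") else des$condition
  levels <- sort(unique(cond[des$motion != "cyclist"]))
  d <- dim(epochs$data)
  out <- array(0, dim = c(d[1], d[2], length(levels)),
               dimnames = list(NULL, epochs$labels, levels))
  ntr <- stats::setNames(integer(length(levels)), levels)
  for (i in base::seq_along(levels)) {
    idx <- which(keep & cond == levels[i])
    if (length(idx) == 0)
      stop_bad_arg("subject ", epochs$subject, ", condition ", levels[i],
                   ": no retained trials")
    ntr[i] <- length(idx)
    out[, , i] <- rowMeans(epochs$data[, , idx, drop = FALSE], dims = 2)
  }
  structure(list(data = out, conditions = levels, n_trials = ntr,
                 times_ms = epochs$times_ms, fs = epochs$fs,
                 labels = epochs$labels, subject = epochs$subject),
            class = "erp_set")
}

#' Grand average across subjects
#'
#' Unweighted mean of per-subject ERP sets sharing conditions and time grid.
#' @param erps list of `erp_set`s.
#' @return An `erp_set` with `subject = "grand"`.
#' @export
grand_average <- function(erps) {
  stopifnot(length(erps) >= 1)
  ref <- erps[[1]]
  acc <- array(0, dim = dim(ref$data), dimnames = dimnames(ref$data))
  for (e in erps) {
    stopifnot(identical(e$conditions, ref$conditions))
    acc <- acc + e$data
  }
  ref$data <- acc / length(erps)
  ref$subject <- "grand"
  ref$n_subjects <- length(erps)
  ref
}

#' Standard preprocessing pipeline
#'
#' Filter, average reference, baseline correction, artifact rejection (and
#' optional bad-channel interpolation), in the standard offline order.
#'
#' @param epochs raw `epochs_set`.
#' @param fspec [filter_spec()].
#' @param baseline baseline window (ms).
#' @param threshold rejection threshold (uV).
#' @param bad_labels channels to re-interpolate (optional).
#' @param montage montage (for interpolation).
#' @return Preprocessed `epochs_set` with retention mask.
#' @export
preprocess <- function(epochs, fspec = filter_spec(), baseline = c(-100, 0),
                       threshold = 100, bad_labels = character(),
                       montage = biosemi64_montage()) {
  epochs <- bandpass(epochs, fspec)
  epochs <- rereference_average(epochs)
  epochs <- baseline_correct(epochs, baseline)
  epochs <- reject_artifacts(epochs, threshold)
  if (length(bad_labels) > 0)
    epochs <- interpolate_channels(epochs, bad_labels, montage)
  epochs
}

#' @export
print.erp_set <- function(x, ...) {
  cat(sprintf("<erp_set> subject %s: %d conditions (%s), %d channels\n",
              x$subject, length(x$conditions),
              paste(x$conditions, collapse = ", "), dim(x$data)[2]))
  invisible(x)
}
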