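epoch_times <- function(fs = 1024, t0 = -100, t1 = 1000) {
  n <- round((t1 - t0) / 1000 * fs)
  (base::seq_len(n) - 1) / fs * 1000 + t0
}

cell_key <- function(motion, plane) {
  m <- c(walker = "bm", scrambled = "sm", cyclist = "sm")[motion]
  paste(m, plane, sep = "_")
}

# Waveform of one component on the time grid (ms), peak/plateau height 1.
component_waveform <- function(cs, times, lat_shift = 0) {
  if (cs$kind == "gaussian") {
    lat <- lat_shift
    exp(-((times - lat)^2) / (2 * cs$width^2))
  } else {
    (stats::pnorm((times - cs$window[1]) / cs$width) -
       stats::pnorm((times - cs$window[2]) / cs$width)) / cs$norm_scale
  }
}

# Noise-free ERP template for one (motion, plane, direction) cell:
# samples x channels matrix.
erp_template <- function(components, motion, plane, direction, times,
                         amp_off = NULL, lat_off = NULL) {
  nch <- length(components[[1]]$topography)
  out <- matrix(0, length(times), nch)
  key <- cell_key(motion, plane)
  for (nm in names(components)) {
    cs <- components[[nm]]
    amp <- cs$amplitude[[key]] + (amp_off[[nm]] %||% 0)
    if (plane == "radial" && cs$direction_split != 0) {
      amp <- amp + ifelse(direction == "approach", 1, -1) * cs$direction_split
    }
    lat <- cs$latency[[key]] + (lat_off[[nm]] %||% 0)
    w <- component_waveform(cs, times, lat)
    out <- out + amp * outer(w, cs$topography)
    if (!is.null(cs$asym_topography) && motion == "walker")
      out <- out + cs$asym_weight * outer(w, cs$asym_topography)
  }
  out
}

# Spatially correlated pink + white noise for a block of trials.
# Returns array samples x channels x trials. Pink noise is built by shaping
# a white complex spectrum with 1/sqrt(f) and inverse FFT (two independent
# series per complex column via the real/imaginary parts).
noise_block <- function(n, nch, ntr, noise, chol_r) {
  if (noise$pink_rms <= 0 && noise$white_rms <= 0)
    return(array(0, dim = c(n, nch, ntr)))
  ncols <- nch * ntr
  # one spectral draw covers both components: independent Gaussians add in
  # power, so the combined spectrum is sqrt(pink^2 * 1/f + white^2); the
  # real and imaginary parts of the inverse FFT give two independent series
  L <- 1280L  # 2^8 * 5, fast FFT length >= epoch samples
  stopifnot(L >= n)
  fbin <- pmin(base::seq_len(L) - 1, L - (base::seq_len(L) - 1))
  pinkpow <- ifelse(fbin == 0, 0, 1 / fbin)
  pinkpow <- pinkpow * noise$pink_rms^2 * L^2 / sum(pinkpow)
  shape <- sqrt(pinkpow + noise$white_rms^2 * L)
  nhalf <- ceiling(ncols / 2)
  z <- matrix(complex(real = rnorm(L * nhalf), imaginary = rnorm(L * nhalf)),
              L, nhalf) * shape
  y <- stats::mvfft(z, inverse = TRUE) / L
  total <- cbind(Re(y), Im(y))[base::seq_len(n), base::seq_len(ncols),
                               drop = FALSE]
  dim(total) <- c(n, nch, ntr)
  if (!is.null(chol_r))
    for (tr in base::seq_len(ntr))
      total[, , tr] <- total[, , tr] %*% chol_r
  total
}

spatial_chol <- function(montage, scale) {
  if (is.null(scale) || scale <= 0) return(NULL)
  k <- exp(-greatcircle_dist(montage_positions(montage)) / scale)
  chol(k + diag(1e-8, nrow(k)))
}

#' Simulate one subject's trial-resolved EEG epochs
#'
#' Each trial is the noise-free condition template (sum of the component
#' specifications projected through their scalp topographies) plus spatially
#' correlated 1/f and white noise. Subject-level random offsets on component
#' amplitudes and latencies are drawn once per subject; components whose
#' names share a leading alphabetic prefix (e.g. the three ESN sub-periods)
#' share one offset. Behavioral responses are generated for the cyclist
#' target (correct with probability `1 - behavior_error_rate`) and false
#' alarms on non-targets (probability `behavior_error_rate`).
#'
#' @param design a [build_design()] schedule.
#' @param components named list of [component_spec()]s.
#' @param noise a [noise_spec()].
#' @param montage electrode montage.
#' @param subject_sd_scale multiplier on the per-component between-subject
#'   SDs (0 disables subject variability).
#' @param behavior_error_rate per-trial probability of incorrect behavior.
#' @param seed integer seed; identical inputs and seed give bit-identical
#'   output.
#' @param subject subject identifier stored in the result.
#' @param fs sampling rate (Hz).
#' @param epoch_span `c(t0, t1)` epoch span in ms relative to stimulus onset.
#' @return An object of class `epochs_set`: list with `data` (array samples
#'   x channels x trials, uV), `times_ms`, `fs`, `labels`, `design` (trial
#'   table with behavioral columns `response`, `correct`), `retain`
#'   (retention mask, `NA` until [reject_artifacts()]), `subject`.
#' @export
simulate_subject <- function(design, components, noise = noise_spec(),
                             montage = biosemi64_montage(),
                             subject_sd_scale = 1, behavior_error_rate = 0.014,
                             seed = 1, subject = "S01", fs = 1024,
                             epoch_span = c(-100, 1000)) {
  if (behavior_error_rate < 0 || behavior_error_rate > 1)
    stop_bad_arg("behavior_error_rate must be in [0, 1]")
  assert_montage(montage)
  times <- epoch_times(fs, epoch_span[1], epoch_span[2])
  n <- length(times)
  nch <- nrow(montage)
  ntr <- nrow(design)
  set.seed(child_seed(seed, paste0("subject", subject)))

  # subject random effects, shared within component groups
  grp <- ifelse(grepl("^ESN", names(components)), "ESN", names(components))
  amp_off <- lat_off <- stats::setNames(numeric(length(components)),
                                        names(components))
  for (g in unique(grp)) {
    a <- rnorm(1, 0, 1)
    l <- rnorm(1, 0, 1)
    for (nm in names(components)[grp == g]) {
      amp_off[nm] <- a * components[[nm]]$amp_sd * subject_sd_scale
      lat_off[nm] <- l * components[[nm]]$lat_sd * subject_sd_scale
    }
  }

  # templates for each distinct (motion, plane, direction)
  cells <- unique(design[, c("motion", "plane", "direction")])
  tpl <- vector("list", nrow(cells))
  names(tpl) <- paste(cells$motion, cells$plane, cells$direction, sep = ".")
  for (i in base::seq_len(nrow(cells)))
    tpl[[i]] <- erp_template(components, cells$motion[i], cells$plane[i],
                             cells$direction[i], times,
                             as.list(amp_off), as.list(lat_off))
  trial_key <- paste(design$motion, design$plane, design$direction, sep = ".")

  chol_r <- spatial_chol(montage, noise$spatial_scale)
  data <- array(0, dim = c(n, nch, ntr))
  chunk <- 128L
  for (start in base::seq(1L, ntr, by = chunk)) {
    idx <- start:min(start + chunk - 1L, ntr)
    nb <- noise_block(n, nch, length(idx), noise, chol_r)
    for (j in base::seq_along(idx))
      data[, , idx[j]] <- nb[, , j] + tpl[[trial_key[idx[j]]]]
  }
  dimnames(data) <- list(NULL, montage$label, NULL)

  # behavior
  err <- runif(ntr) < behavior_error_rate
  is_target <- design$motion == "cyclist"
  response <- ifelse(is_target & !err, "key",
                     ifelse(is_target & err,
                            ifelse(runif(ntr) < 0.5, "key", "none"),
                            ifelse(err, "key", "none")))
  correct <- !err
  design$response <- response
  design$correct <- correct

  structure(list(data = data, times_ms = times, fs = fs,
                 labels = montage$label, design = design,
                 retain = rep(NA, ntr), subject = subject,
                 seed = as.integer(seed)),
            class = "epochs_set")
}

#' Inject blink artifacts into epochs
#'
#' A random subset of trials (probability `noise$blink_rate` each) receives a
#' frontally weighted blink transient (Gaussian time course, SD 40 ms, random
#' latency) whose peak amplitude at the frontopolar channels is
#' `noise$blink_amp` uV, exceeding the +/-100 uV rejection threshold.
#' Contaminated trials are flagged in `$blink`.
#'
#' @param epochs an `epochs_set`.
#' @param noise a [noise_spec()] (uses `blink_rate`, `blink_amp`).
#' @param montage montage (for the frontal topography).
#' @param seed integer seed.
#' @return The `epochs_set` with artifacts added and a logical `$blink` flag.
#' @export
inject_artifacts <- function(epochs, noise, montage = biosemi64_montage(),
                             seed = 1) {
  stopifnot(inherits(epochs, "epochs_set"))
  if (noise$blink_rate < 0 || noise$blink_rate > 1)
    stop_bad_arg("blink_rate must be in [0, 1]")
  set.seed(child_seed(seed, "blinks"))
  ntr <- dim(epochs$data)[3]
  hit <- runif(ntr) < noise$blink_rate
  epochs$blink <- hit
  if (!any(hit)) return(epochs)
  pos <- montage_positions(montage)
  fpz <- pos[match("Fpz", montage$label), ]
  d <- acos(pmin(1, pmax(-1, pos %*% fpz)))
  topo <- as.numeric(exp(-(d / 0.45)^2))
  for (tr in which(hit)) {
    lat <- runif(1, 100, 800)
    wave <- exp(-((epochs$times_ms - lat)^2) / (2 * 40^2))
    epochs$data[, , tr] <- epochs$data[, , tr] +
      noise$blink_amp * outer(wave, topo)
  }
  epochs
}

#' Mean correct-response rate across subjects
#'
#' @param trial_tables list of per-subject trial tables (the `$design`
#'   element of each `epochs_set`), or of `epochs_set`s.
#' @return A list with per-subject percent-correct and their mean.
#' @export
behavioral_summary <- function(trial_tables) {
  tabs <- lapply(trial_tables, function(x)
    if (inherits(x, "epochs_set")) x$design else x)
  pc <- vapply(tabs, function(d) 100 * mean(d$correct), numeric(1))
  list(per_subject = pc, mean_percent_correct = mean(pc))
}

#' @export
print.epochs_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epochs_set> subject %s: %d trials x %d channels x %d samples @ %g Hz\n",
              x$subject, d[3], d[2], d[1], x$fs))
  if (!all(is.na(x$retain)))
    cat(sprintf("  retained: %d/%d trials\n", sum(x$retain), d[3]))
  invisible(x)
}
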