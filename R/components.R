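#' ROI definitions for component measurement
#'
#' Peak components (P1, N1) use bilateral occipito-parietal ROIs
#' (left P5/P7/PO7, right P6/P8/PO8); the early sustained negativity (ESN)
#' uses three ROIs: left P9/P7/P5/PO7, central O1/Oz/O2/Iz and right
#' P10/P8/P6/PO8.
#'
#' @param component `"P1"`, `"N1"` or `"ESN"`.
#' @return Named list of character vectors (electrode labels per ROI).
#' @export
default_rois <- function(component = c("P1", "N1", "ESN")) {
  component <- match.arg(component)
  if (component == "ESN") {
    list(left = c("P9", "P7", "P5", "PO7"),
         central = c("O1", "Oz", "O2", "Iz"),
         right = c("P10", "P8", "P6", "PO8"))
  } else {
    list(left = c("P5", "P7", "PO7"), right = c("P6", "P8", "PO8"))
  }
}

# Average-referenced scalp pattern: sum of spherical Gaussians centered at
# the given electrodes, normalized so the mean over the measurement ROI
# channels equals 1 (so component amplitudes are in uV "as measured").
make_topography <- function(montage, centers, roi_labels, width = 0.55,
                            sign = 1) {
  pos <- montage_positions(montage)
  ctr <- pos[match(centers, montage$label), , drop = FALSE]
  d <- acos(clamp1(tcrossprod(pos, ctr)))
  w <- rowSums(exp(-(d / width)^2)) * sign
  w <- w - mean(w)                       # average reference
  idx <- match(roi_labels, montage$label)
  w / mean(w[idx])
}

# Right-minus-left antisymmetric pattern over the ESN ROIs, zero channel sum
# and zero mean over the ROI union; used to lateralize the BM-SM difference.
make_asym_topography <- function(montage, left_center = "PO7",
                                 right_center = "PO8", width = 0.5) {
  pos <- montage_positions(montage)
  g <- function(lab) {
    c0 <- pos[match(lab, montage$label), ]
    d <- acos(clamp1(pos %*% c0))
    exp(-(d / width)^2)
  }
  w <- as.numeric(g(right_center) - g(left_center))
  w <- w - mean(w)
  roi <- unlist(default_rois("ESN"), use.names = FALSE)
  idx <- match(roi, montage$label)
  # enforce an exactly zero ROI-union mean without breaking the zero sum
  m <- mean(w[idx])
  adj <- rep(0, nrow(pos))
  adj[idx] <- m
  adj[-idx] <- -m * length(idx) / (nrow(pos) - length(idx))
  w <- w - adj
  sc <- max(abs(w[idx]))
  if (sc > 0) w <- w / sc
  w
}

#' Specification of one ERP component of the generator
#'
#' @param name component name.
#' @param kind `"gaussian"` (transient peak) or `"plateau"` (boxcar convolved
#'   with a Gaussian edge).
#' @param latency named numeric: peak latency (ms) per condition cell
#'   (`bm_radial`, `bm_lateral`, `sm_radial`, `sm_lateral`; cyclists reuse the
#'   scrambled values).
#' @param amplitude named numeric: amplitude per condition cell, in uV as
#'   measured at the component's ROI (peak value for transients, mean over
#'   the measurement window for plateaus).
#' @param width temporal scale in ms (Gaussian SD, or edge SD for plateaus).
#' @param window for plateaus, `c(on, off)` in ms.
#' @param measure_window window used by the measurement stage (ms); plateau
#'   amplitudes are normalized against it.
#' @param topography per-channel weights (average-referenced, ROI mean 1).
#' @param asym_topography optional lateralization pattern added (scaled by
#'   `asym_weight`) on biological-motion trials only.
#' @param asym_weight lateralization weight in uV.
#' @param direction_split for radial cells, half-difference (uV) added to
#'   approaching trials and subtracted from receding trials.
#' @param amp_sd,lat_sd between-subject SDs of the amplitude (uV) and latency
#'   (ms) random offsets.
#' @param roi ROI label set used for normalization/measurement.
#' @param norm_scale divisor applied to plateau waveforms so that the mean
#'   over `measure_window` equals the nominal amplitude (accounts for edge
#'   smoothing; 1 for transient components).
#' @return An object of class `component_spec`.
#' @export
component_spec <- function(name, kind = c("gaussian", "plateau"), latency,
                           amplitude, width, window = NULL,
                           measure_window = NULL, topography,
                           asym_topography = NULL, asym_weight = 0,
                           direction_split = 0, amp_sd = 0, lat_sd = 0,
                           roi = NULL, norm_scale = 1) {
  kind <- match.arg(kind)
  if (width <= 0) stop_bad_arg("component width must be positive")
  if (abs(sum(topography)) > 1e-6)
    stop_bad_arg("topography weights must sum to zero (average reference)")
  structure(list(name = name, kind = kind, latency = latency,
                 amplitude = amplitude, width = width, window = window,
                 measure_window = measure_window, topography = topography,
                 asym_topography = asym_topography, asym_weight = asym_weight,
                 direction_split = direction_split, amp_sd = amp_sd,
                 lat_sd = lat_sd, roi = roi, norm_scale = norm_scale),
            class = "component_spec")
}

#' Default generator components calibrated to the reported condition means
#'
#' Builds the P1, N1 and ESN component specifications whose cell means
#' reproduce the study's reported grand-average statistics: P1 amplitudes per
#' cell (BM radial 2.27, BM lateral 1.75, SM radial 1.81, SM lateral 1.84 uV)
#' and latencies (BM 112 ms, SM 118 ms); N1 cells built additively from the
#' motion marginals (BM -2.84, SM -2.41 uV) and direction marginals (radial
#' -2.93, lateral -2.32 uV); ESN cells from the motion marginals (BM -3.74,
#' SM -2.18 uV). The N1 additionally carries an approach/recede split on
#' radial trials reproducing the reported 0.55 uV receding-minus-approaching
#' difference, and the ESN a right-lateralized enhancement of the BM-SM
#' difference. Between-subject SDs are the printed SEMs scaled by sqrt(15).
#'
#' The ESN drives three successive scalp topographies (posterior negativities
#' with shifting centroids) so that, together with the P1 and N1 maps, the
#' grand-average map series contains five quasi-stable topographic periods
#' between 80 and 500 ms.
#'
#' @param montage montage used to build the scalp topographies.
#' @param n_subjects reference sample size used to convert printed SEMs into
#'   between-subject SDs.
#' @return A named list of `component_spec` objects.
#' @export
default_components <- function(montage = biosemi64_montage(),
                               n_subjects = 15) {
  assert_montage(montage)
  roi_pn <- unlist(default_rois("P1"), use.names = FALSE)
  roi_esn <- unlist(default_rois("ESN"), use.names = FALSE)
  cells <- c("bm_radial", "bm_lateral", "sm_radial", "sm_lateral")
  sem <- sqrt(n_subjects)

  # N1 additive cells: grand mean -2.625, motion effect +/-0.215,
  # direction effect +/-0.305 (radial more negative)
  n1_grand <- (-2.84 - 2.41) / 2
  n1_mot <- (-2.84 - (-2.41)) / 2
  n1_dir <- (-2.93 - (-2.32)) / 2
  n1_cells <- c(bm_radial = n1_grand + n1_mot + n1_dir,
                bm_lateral = n1_grand + n1_mot - n1_dir,
                sm_radial = n1_grand - n1_mot + n1_dir,
                sm_lateral = n1_grand - n1_mot - n1_dir)

  esn_cells <- c(bm_radial = -3.74, bm_lateral = -3.74,
                 sm_radial = -2.18, sm_lateral = -2.18)

  p1 <- component_spec(
    name = "P1", kind = "gaussian",
    latency = c(bm_radial = 112, bm_lateral = 112,
                sm_radial = 118, sm_lateral = 118),
    amplitude = c(bm_radial = 2.27, bm_lateral = 1.75,
                  sm_radial = 1.81, sm_lateral = 1.84),
    width = 14,
    measure_window = c(80, 150),
    topography = make_topography(montage, c("PO7", "O1", "PO8", "O2"),
                                 roi_pn, width = 0.5),
    amp_sd = 0.30 * sem, lat_sd = 3.13 * sem, roi = roi_pn)

  n1 <- component_spec(
    name = "N1", kind = "gaussian",
    latency = c(bm_radial = 186, bm_lateral = 186,
                sm_radial = 186, sm_lateral = 186),
    amplitude = n1_cells,
    width = 13,
    measure_window = c(170, 200),
    topography = make_topography(montage, c("P7", "PO7", "P8", "PO8"),
                                 roi_pn, width = 0.5, sign = -1),
    direction_split = 0.55 / 2,
    amp_sd = 0.51 * sem, lat_sd = 2.0 * sem, roi = roi_pn)

  # three ESN sub-period topographies with shifting centroids
  esn_centers <- list(a = c("PO7", "PO8", "O1", "O2"),
                      b = c("P7", "P8", "Oz", "Iz"),
                      c = c("P5", "P6", "POz", "Pz"))
  esn_spans <- list(a = c(210, 310), b = c(310, 400), c = c(400, 500))
  asym <- make_asym_topography(montage)
  esn <- lapply(names(esn_centers), function(k) {
    component_spec(
      name = paste0("ESN", k), kind = "plateau",
      latency = c(bm_radial = 0, bm_lateral = 0, sm_radial = 0,
                  sm_lateral = 0),
      amplitude = esn_cells,
      width = 10, window = esn_spans[[k]],
      measure_window = c(210, 360),
      topography = make_topography(montage, esn_centers[[k]], roi_esn,
                                   width = 0.5, sign = -1),
      asym_topography = asym, asym_weight = -0.6,
      amp_sd = 0.38 * sem, lat_sd = 0, roi = roi_esn)
  })
  names(esn) <- paste0("ESN", names(esn_centers))

  # joint normalization of the ESN plateaus: the 210-360 ms window mean of
  # the summed (edge-smoothed) sub-waveforms must equal the cell amplitude
  tg <- base::seq(210, 360, by = 0.25)
  raw <- rowSums(sapply(esn, function(cs) {
    stats::pnorm((tg - cs$window[1]) / cs$width) -
      stats::pnorm((tg - cs$window[2]) / cs$width)
  }))
  m <- mean(raw)
  esn <- lapply(esn, function(cs) { cs$norm_scale <- m; cs })

  c(list(P1 = p1, N1 = n1), esn)
}

#' Noise specification for the epoch simulator
#'
#' @param pink_rms RMS amplitude (uV) of the 1/f (pink) noise per channel.
#' @param white_rms RMS amplitude (uV) of the white noise per channel.
#' @param spatial_scale e-folding great-circle distance (radians) of the
#'   exponential between-channel correlation kernel.
#' @param blink_rate probability per trial of a blink artifact.
#' @param blink_amp peak blink amplitude (uV) at the frontopolar channels.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(pink_rms = 3, white_rms = 1.5, spatial_scale = 0.8,
                       blink_rate = 0.195, blink_amp = 150) {
  if (pink_rms < 0 || white_rms < 0 || blink_amp < 0)
    stop_bad_arg("noise amplitudes must be non-negative")
  if (blink_rate < 0 || blink_rate > 1)
    stop_bad_arg("blink_rate must be in [0, 1]")
  structure(list(pink_rms = pink_rms, white_rms = white_rms,
                 spatial_scale = spatial_scale, blink_rate = blink_rate,
                 blink_amp = blink_amp),
            class = "noise_spec")
}
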