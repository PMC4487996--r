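roi_average <- function(erp, roi_labels, condition) {
  idx <- match(roi_labels, erp$labels)
  if (any(is.na(idx))) stop_bad_arg("ROI label(s) missing from ERP data")
  ci <- match(condition, erp$conditions)
  if (is.na(ci)) stop_bad_arg("condition not found: ", condition)
  rowMeans(erp$data[, idx, ci, drop = FALSE], dims = 1)
}

#' Peak amplitude and latency of P1 / N1 over an ROI
#'
#' ROI channels are averaged first, then the P1 is taken as the signed
#' maximum within 80-150 ms and the N1 as the signed minimum within
#' 170-200 ms; latency is the time of the extremum sample. A peak falling on
#' the window boundary is flagged as possibly clipped.
#'
#' @param erp an `erp_set`.
#' @param component `"P1"` or `"N1"`.
#' @param roi character vector of ROI electrode labels.
#' @param condition condition name in `erp$conditions`.
#' @param window override the search window (ms).
#' @return A one-row data frame: `component`, `condition`, `latency_ms`,
#'   `amplitude_uV`, `boundary_flag`, `subject`.
#' @export
measure_peak <- function(erp, component = c("P1", "N1"), roi, condition,
                         window = NULL) {
  component <- match.arg(component)
  if (is.null(window))
    window <- if (component == "P1") c(80, 150) else c(170, 200)
  if (window[1] < min(erp$times_ms) || window[2] > max(erp$times_ms))
    stop_bad_arg("search window outside the epoch")
  tr <- roi_average(erp, roi, condition)
  sel <- which(erp$times_ms >= window[1] & erp$times_ms <= window[2])
  seg <- tr[sel]
  k <- if (component == "P1") which.max(seg) else which.min(seg)
  data.frame(component = component, condition = condition,
             latency_ms = erp$times_ms[sel[k]], amplitude_uV = seg[k],
             boundary_flag = k == 1 || k == length(seg),
             subject = erp$subject, stringsAsFactors = FALSE)
}

#' Mean amplitude over a fixed window (ESN)
#'
#' Averages the ROI channels and the samples of the window (default
#' 210-360 ms).
#'
#' @inheritParams measure_peak
#' @param window analysis window in ms.
#' @return A one-row data frame: `component`, `condition`, `amplitude_uV`,
#'   `subject`.
#' @export
measure_window <- function(erp, roi, condition, window = c(210, 360)) {
  if (length(roi) == 0) stop_bad_arg("empty ROI")
  if (window[1] < min(erp$times_ms) || window[2] > max(erp$times_ms))
    stop_bad_arg("window outside the epoch")
  tr <- roi_average(erp, roi, condition)
  sel <- erp$times_ms >= window[1] & erp$times_ms <= window[2]
  data.frame(component = "ESN", condition = condition,
             amplitude_uV = mean(tr[sel]), subject = erp$subject,
             stringsAsFactors = FALSE)
}

#' Measure all components for all conditions and ROIs of an ERP set
#'
#' Convenience wrapper producing the tidy measures table (one row per
#' condition x component x ROI) used by the ANOVA stage.
#'
#' @param erp an `erp_set` (one subject).
#' @param conditions conditions to measure (default: all in the set).
#' @return A data frame with columns `subject`, `condition`, `motion`,
#'   `plane`, `roi`, `component`, `latency_ms`, `amplitude_uV`.
#' @export
measure_components <- function(erp, conditions = erp$conditions) {
  rows <- list()
  for (cond in conditions) {
    for (comp in c("P1", "N1")) {
      rois <- default_rois(comp)
      for (rn in names(rois)) {
        m <- measure_peak(erp, comp, rois[[rn]], cond)
        rows[[length(rows) + 1]] <-
          data.frame(subject = erp$subject, condition = cond, roi = rn,
                     component = comp, latency_ms = m$latency_ms,
                     amplitude_uV = m$amplitude_uV, stringsAsFactors = FALSE)
      }
    }
    rois <- default_rois("ESN")
    for (rn in names(rois)) {
      m <- measure_window(erp, rois[[rn]], cond)
      rows[[length(rows) + 1]] <-
        data.frame(subject = erp$subject, condition = cond, roi = rn,
                   component = "ESN", latency_ms = NA_real_,
                   amplitude_uV = m$amplitude_uV, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  cond_bits <- strsplit(out$condition, "_")
  out$motion <- vapply(cond_bits, `[`, "", 1)
  out$plane <- vapply(cond_bits, `[`, "", 2)
  out[, c("subject", "condition", "motion", "plane", "roi", "component",
          "latency_ms", "amplitude_uV")]
}
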