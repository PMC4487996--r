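#' Simulate and preprocess one subject end to end
#'
#' Runs simulation, artifact injection, filtering, average reference,
#' baseline correction and rejection, and returns the per-condition ERPs
#' (with and without the direction split) plus the behavioral trial table.
#' The raw epochs are discarded to keep memory bounded.
#'
#' @param subject subject label.
#' @param design a [build_design()] schedule.
#' @param components component specifications.
#' @param noise a [noise_spec()].
#' @param montage electrode montage.
#' @param seed study-level seed (per-subject seeds derive from it).
#' @param behavior_error_rate per-trial behavioral error probability.
#' @param fspec [filter_spec()].
#' @param subject_sd_scale multiplier on between-subject SDs.
#' @return List with `erp`, `erp_dir` (direction-split), `design`,
#'   `retention` (fraction of retained trials).
#' @export
process_subject <- function(subject, design, components,
                            noise = noise_spec(),
                            montage = biosemi64_montage(), seed = 1,
                            behavior_error_rate = 0.014,
                            fspec = filter_spec(), subject_sd_scale = 1) {
  ep <- simulate_subject(design, components, noise, montage,
                         subject_sd_scale = subject_sd_scale,
                         behavior_error_rate = behavior_error_rate,
                         seed = seed, subject = subject)
  ep <- inject_artifacts(ep, noise, montage,
                         seed = child_seed(seed, paste0("art", subject)))
  ep <- preprocess(ep, fspec)
  out <- list(erp = average_erps(ep, split_direction = FALSE),
              erp_dir = average_erps(ep, split_direction = TRUE),
              design = ep$design[, c("block", "trial", "motion", "plane",
                                     "condition", "direction", "size_class",
                                     "response", "correct")],
              retention = mean(ep$retain))
  rm(ep)
  gc(FALSE)
  out
}

#' Run the full multi-subject synthetic study
#'
#' Simulates `n_subjects` subjects under the default study conditions
#' (7 blocks x 24 repetitions x 6 conditions), preprocesses each, and
#' assembles per-subject ERPs, grand averages, the tidy component-measures
#' table and the behavioral summary.
#'
#' @param n_subjects number of subjects.
#' @param blocks,reps design size per [build_design()].
#' @param components component specifications (default
#'   [default_components()]).
#' @param noise a [noise_spec()].
#' @param montage electrode montage.
#' @param seed top-level integer seed.
#' @param behavior_error_rate per-trial behavioral error probability.
#' @param subject_sd_scale multiplier on between-subject SDs.
#' @param progress print one line per subject.
#' @return An object of class `bm_study`: `erps`, `erps_dir` (lists per
#'   subject), `grand`, `grand_dir`, `measures` (tidy table), `behavior`,
#'   `retention`, `design_attrs`.
#' @export
run_study <- function(n_subjects = 15, blocks = 7, reps = 24,
                      components = NULL, noise = noise_spec(),
                      montage = biosemi64_montage(), seed = 1,
                      behavior_error_rate = 0.014, subject_sd_scale = 1,
                      progress = FALSE) {
  if (is.null(components)) components <- default_components(montage)
  erps <- erps_dir <- vector("list", n_subjects)
  designs <- vector("list", n_subjects)
  retention <- numeric(n_subjects)
  measures <- list()
  for (s in base::seq_len(n_subjects)) {
    lab <- sprintf("S%02d", s)
    design <- build_design(blocks, reps,
                           seed = child_seed(seed, paste0("design", lab)))
    res <- process_subject(lab, design, components, noise, montage,
                           seed = child_seed(seed, lab),
                           behavior_error_rate = behavior_error_rate,
                           subject_sd_scale = subject_sd_scale)
    erps[[s]] <- res$erp
    erps_dir[[s]] <- res$erp_dir
    designs[[s]] <- res$design
    retention[s] <- res$retention
    measures[[s]] <- measure_components(res$erp)
    if (progress)
      message(sprintf("subject %s done (retention %.1f%%)", lab,
                      100 * res$retention))
  }
  structure(list(erps = erps, erps_dir = erps_dir,
                 grand = grand_average(erps),
                 grand_dir = grand_average(erps_dir),
                 measures = do.call(rbind, measures),
                 behavior = behavioral_summary(designs),
                 retention = retention,
                 design_attrs = list(blocks = blocks, reps = reps),
                 seed = seed),
            class = "bm_study")
}

#' @export
print.bm_study <- function(x, ...) {
  cat(sprintf("<bm_study> %d subjects, mean retention %.1f%%, %.1f%% correct\n",
              length(x$erps), 100 * mean(x$retention),
              x$behavior$mean_percent_correct))
  invisible(x)
}

#' Simulate null (noise-only) subject ERPs
#'
#' Per-subject ERP-level difference noise with the generator's spatial
#' correlation structure and a 1/f + white spectral mix, scaled to a given
#' residual RMS -- the null input for calibrating the point-wise contiguity
#' test.
#'
#' @param n_subjects number of subjects.
#' @param montage electrode montage.
#' @param n_samples samples per ERP.
#' @param fs sampling rate (Hz).
#' @param rms per-channel residual RMS (uV).
#' @param seed integer seed.
#' @return List of `n_subjects` matrices (samples x channels).
#' @export
simulate_null_erps <- function(n_subjects, montage = biosemi64_montage(),
                               n_samples = 512, fs = 1024, rms = 0.4,
                               seed = 1) {
  set.seed(child_seed(seed, "nullerps"))
  chol_r <- spatial_chol(montage, 0.8)
  ns <- noise_spec(pink_rms = rms / sqrt(2), white_rms = rms / sqrt(2),
                   blink_rate = 0)
  lapply(base::seq_len(n_subjects), function(s) {
    nb <- noise_block(n_samples, nrow(montage), 1, ns, chol_r)
    nb[, , 1]
  })
}
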