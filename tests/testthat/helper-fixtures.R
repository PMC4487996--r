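# Shared fixtures, built in code at test time.

MONT <- biosemi64_montage()
POS <- as.matrix(MONT[, c("x", "y", "z")])

# Small epochs_set built directly from an array (bypasses the simulator).
make_epochs <- function(data, fs = 1024, t0 = -100, design = NULL,
                        subject = "T01") {
  d <- dim(data)
  dimnames(data) <- list(NULL, MONT$label[seq_len(d[2])], NULL)
  if (is.null(design))
    design <- data.frame(motion = rep("walker", d[3]),
                         plane = "radial",
                         condition = "walker_radial",
                         direction = "approach", size_class = "small",
                         response = "none", correct = TRUE,
                         stringsAsFactors = FALSE)
  structure(list(data = data,
                 times_ms = (seq_len(d[1]) - 1) / fs * 1000 + t0,
                 fs = fs, labels = MONT$label[seq_len(d[2])],
                 design = design, retain = rep(NA, d[3]),
                 subject = subject),
            class = "epochs_set")
}

# One-condition erp_set from a samples x channels matrix.
make_erp <- function(mat, fs = 1024, t0 = -100, condition = "walker_radial",
                     subject = "T01") {
  data <- array(mat, dim = c(nrow(mat), ncol(mat), 1),
                dimnames = list(NULL, MONT$label[seq_len(ncol(mat))],
                                condition))
  structure(list(data = data, conditions = condition,
                 n_trials = stats::setNames(1L, condition),
                 times_ms = (seq_len(nrow(mat)) - 1) / fs * 1000 + t0,
                 fs = fs, labels = MONT$label[seq_len(ncol(mat))],
                 subject = subject),
            class = "erp_set")
}

# Tiny noise-free study fixture shared by several files.
tiny_zero_noise_subject <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      des <- build_design(blocks = 1, reps = 2, seed = 7)
      ep <- simulate_subject(des, default_components(MONT),
                             noise_spec(pink_rms = 0, white_rms = 0,
                                        blink_rate = 0),
                             MONT, subject_sd_scale = 0,
                             behavior_error_rate = 0, seed = 5)
      cache <<- ep
    }
    cache
  }
})
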