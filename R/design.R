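#' Build the experimental trial schedule
#'
#' Six conditions ({walker, scrambled, cyclist} x {radial, lateral}) are
#' repeated `reps` times per block in randomized order; with the default 7
#' blocks of 24 repetitions this gives 144 trials per block and 168 trials
#' per condition. Each trial is also assigned a concrete direction (radial:
#' approach/recede; lateral: left/right, balanced within block and condition)
#' and a size class (small/big, balanced), plus a uniformly drawn
#' inter-stimulus interval in [1000, 1400] ms.
#'
#' @param blocks number of blocks (>= 1).
#' @param reps repetitions of each condition per block (>= 1).
#' @param seed integer seed for trial-order randomization.
#' @return An object of class `study_design`: a data frame with columns
#'   `block`, `trial`, `motion` (walker/scrambled/cyclist), `plane`
#'   (radial/lateral), `condition`, `direction`, `size_class`, `isi_ms`.
#' @examples
#' d <- build_design(blocks = 7, reps = 24, seed = 1)
#' nrow(d)                 # 1008 trials
#' table(d$condition)[1]   # 168 per condition
#' @export
build_design <- function(blocks = 7, reps = 24, seed = 1) {
  if (blocks < 1 || reps < 1) stop_bad_arg("blocks and reps must be >= 1")
  set.seed(as.integer(seed))
  motions <- c("walker", "scrambled", "cyclist")
  planes <- c("radial", "lateral")
  out <- vector("list", blocks)
  for (b in seq_len(blocks)) {
    grid <- expand.grid(rep = seq_len(reps), motion = motions, plane = planes,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    # balanced direction and size assignment within condition
    grid$direction <- NA_character_
    grid$size_class <- NA_character_
    for (m in motions) for (p in planes) {
      idx <- which(grid$motion == m & grid$plane == p)
      dirs <- if (p == "radial") c("approach", "recede") else c("left", "right")
      grid$direction[idx] <- sample(rep(dirs, length.out = length(idx)))
      grid$size_class[idx] <-
        sample(rep(c("small", "big"), length.out = length(idx)))
    }
    grid <- grid[sample(nrow(grid)), ]
    grid$block <- b
    grid$trial <- seq_len(nrow(grid))
    out[[b]] <- grid
  }
  d <- do.call(rbind, out)
  d$condition <- paste(d$motion, d$plane, sep = "_")
  d$isi_ms <- runif(nrow(d), 1000, 1400)
  d <- d[, c("block", "trial", "motion", "plane", "condition", "direction",
             "size_class", "isi_ms")]
  rownames(d) <- NULL
  attr(d, "blocks") <- blocks
  attr(d, "reps") <- reps
  attr(d, "seed") <- as.integer(seed)
  class(d) <- c("study_design", "data.frame")
  d
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %d blocks x %d trials = %d trials (%d/condition)\n",
              attr(x, "blocks"), nrow(x) / attr(x, "blocks"), nrow(x),
              nrow(x) / 6))
  invisible(x)
}
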