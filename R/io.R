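# Epochs / ERP containers: a JSON header (<path>.json) plus a little-endian
# float32 payload (<path>.dat). Voltages are stored as 32-bit floats in uV,
# so write -> read -> write round-trips are bit-exact.

#' Write an epochs container
#'
#' @param epochs an `epochs_set`.
#' @param path base path (without extension); writes `path.json` and
#'   `path.dat`.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epochs_set"))
  d <- dim(epochs$data)
  header <- list(
    container = "bmerp-epochs", version = 1L,
    subject = epochs$subject, fs = epochs$fs,
    t0_ms = epochs$times_ms[1], units = "uV",
    n_samples = d[1], n_channels = d[2], n_trials = d[3],
    labels = epochs$labels,
    design = as.list(as.data.frame(epochs$design)),
    retain = as.logical(epochs$retain),
    blink = if (is.null(epochs$blink)) NULL else as.logical(epochs$blink),
    seed = epochs$seed)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(epochs$data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an epochs container written by [write_epochs()]
#' @param path base path (without extension).
#' @return An `epochs_set`.
#' @export
read_epochs <- function(path) {
  jf <- paste0(path, ".json")
  if (!file.exists(jf))
    stop_bad_arg("missing epochs container: ", jf)
  h <- jsonlite::read_json(jf, simplifyVector = TRUE)
  if (!identical(h$container, "bmerp-epochs"))
    stop_bad_arg("not an epochs container: ", jf)
  if (anyDuplicated(h$labels)) stop_bad_arg("duplicate channel labels")
  n <- h$n_samples * h$n_channels * h$n_trials
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n + 1, size = 4, endian = "little")
  if (length(x) != n)
    stop_bad_arg("payload size does not match header shape")
  data <- array(x, dim = c(h$n_samples, h$n_channels, h$n_trials))
  dimnames(data) <- list(NULL, h$labels, NULL)
  design <- as.data.frame(h$design, stringsAsFactors = FALSE)
  times <- (base::seq_len(h$n_samples) - 1) / h$fs * 1000 + h$t0_ms
  structure(list(data = data, times_ms = times, fs = h$fs,
                 labels = h$labels, design = design,
                 retain = as.logical(h$retain),
                 blink = if (is.null(h$blink)) NULL else as.logical(h$blink),
                 subject = h$subject, seed = h$seed),
            class = "epochs_set")
}

#' Write / read an ERP-set container (same format as epochs)
#' @param erp an `erp_set`.
#' @param path base path (without extension).
#' @export
write_erps <- function(erp, path) {
  stopifnot(inherits(erp, "erp_set"))
  d <- dim(erp$data)
  header <- list(container = "bmerp-erps", version = 1L,
                 subject = erp$subject, fs = erp$fs,
                 t0_ms = erp$times_ms[1], units = "uV",
                 n_samples = d[1], n_channels = d[2],
                 conditions = erp$conditions,
                 n_trials = as.integer(erp$n_trials), labels = erp$labels)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(erp$data), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_erps
#' @export
read_erps <- function(path) {
  jf <- paste0(path, ".json")
  if (!file.exists(jf)) stop_bad_arg("missing ERP container: ", jf)
  h <- jsonlite::read_json(jf, simplifyVector = TRUE)
  if (!identical(h$container, "bmerp-erps"))
    stop_bad_arg("not an ERP container: ", jf)
  n <- h$n_samples * h$n_channels * length(h$conditions)
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n + 1, size = 4, endian = "little")
  if (length(x) != n) stop_bad_arg("payload size does not match header")
  data <- array(x, dim = c(h$n_samples, h$n_channels, length(h$conditions)),
                dimnames = list(NULL, h$labels, h$conditions))
  times <- (base::seq_len(h$n_samples) - 1) / h$fs * 1000 + h$t0_ms
  structure(list(data = data, conditions = h$conditions,
                 n_trials = stats::setNames(h$n_trials, h$conditions),
                 times_ms = times, fs = h$fs, labels = h$labels,
                 subject = h$subject),
            class = "erp_set")
}

#' Write a data frame as TSV (and read it back)
#' @param df data frame.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end pipeline with their defaults;
#' the full-scale study uses `n_subjects = 15`, `blocks = 7`, `reps = 24`.
#'
#' @param n_subjects,blocks,reps study size.
#' @param seed top-level seed (stage seeds are derived from it).
#' @return Nested list of class `run_config`.
#' @export
default_config <- function(n_subjects = 3, blocks = 2, reps = 4, seed = 1) {
  structure(list(
    seed = seed,
    study = list(n_subjects = n_subjects, blocks = blocks, reps = reps,
                 behavior_error_rate = 0.014),
    noise = list(pink_rms = 3, white_rms = 1.5, spatial_scale = 0.8,
                 blink_rate = 0.195, blink_amp = 150),
    filter = list(hp = 0.17, lp = 30, order = 4),
    preproc = list(baseline = c(-100, 0), threshold = 100),
    windows = list(P1 = c(80, 150), N1 = c(170, 200), ESN = c(210, 360)),
    microstates = list(span = c(80, 500), k_range = 1:8, restarts = 20),
    source = list(spacing = 0.16, alpha_scale = 1e-3, n_rand = 1000,
                  min_cluster = 10)),
    class = "run_config")
}

config_schema <- function() {
  list("seed" = "numeric",
       "study.n_subjects" = "numeric", "study.blocks" = "numeric",
       "study.reps" = "numeric", "study.behavior_error_rate" = "numeric",
       "noise.pink_rms" = "numeric", "noise.white_rms" = "numeric",
       "noise.spatial_scale" = "numeric", "noise.blink_rate" = "numeric",
       "noise.blink_amp" = "numeric",
       "filter.hp" = "numeric", "filter.lp" = "numeric",
       "filter.order" = "numeric",
       "preproc.baseline" = "numeric2", "preproc.threshold" = "numeric",
       "windows.P1" = "numeric2", "windows.N1" = "numeric2",
       "windows.ESN" = "numeric2",
       "microstates.span" = "numeric2", "microstates.k_range" = "numeric",
       "microstates.restarts" = "numeric",
       "source.spacing" = "numeric", "source.alpha_scale" = "numeric",
       "source.n_rand" = "numeric", "source.min_cluster" = "numeric")
}

get_path <- function(lst, path) {
  for (p in strsplit(path, ".", fixed = TRUE)[[1]]) {
    if (!is.list(lst) || is.null(lst[[p]])) return(NULL)
    lst <- lst[[p]]
  }
  lst
}

#' Validate a pipeline configuration
#'
#' Checks every schema field for presence and type; returns (invisibly) the
#' config or raises an error naming the offending field path.
#' @param config list as returned by [read_config()] / [default_config()].
#' @export
validate_config <- function(config) {
  sch <- config_schema()
  for (field in names(sch)) {
    v <- get_path(config, field)
    if (is.null(v)) stop_bad_arg("config field missing: ", field)
    if (!is.numeric(v)) stop_bad_arg("config field not numeric: ", field)
    if (sch[[field]] == "numeric2" && length(v) != 2)
      stop_bad_arg("config field must have length 2: ", field)
  }
  if (config$study$behavior_error_rate < 0 ||
      config$study$behavior_error_rate > 1)
    stop_bad_arg("config field out of range: study.behavior_error_rate")
  if (config$noise$blink_rate < 0 || config$noise$blink_rate > 1)
    stop_bad_arg("config field out of range: noise.blink_rate")
  invisible(config)
}

#' Read / write a YAML pipeline configuration
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_bad_arg("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  cfg$microstates$k_range <- as.integer(cfg$microstates$k_range)
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Persist a lead field (gain matrix + grid) to disk
#'
#' Binary container with a JSON header: `path.json` records the head-model
#' radii and conductivities, grid spacing and node count, and the series
#' truncation; `path.dat` holds the node positions, lattice indices and the
#' gain matrix as little-endian float64.
#'
#' @param leadfield a [build_leadfield()] object.
#' @param path base path (without extension).
#' @export
write_leadfield <- function(leadfield, path) {
  stopifnot(inherits(leadfield, "leadfield"))
  g <- leadfield$grid
  header <- list(container = "bmerp-leadfield", version = 1L,
                 radii = leadfield$headmodel$radii,
                 conductivities = leadfield$headmodel$conductivities,
                 spacing = g$spacing, max_radius = g$max_radius,
                 n_nodes = g$n, n_channels = nrow(leadfield$gain),
                 nterms = leadfield$nterms,
                 labels = leadfield$montage$label)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(g$pos), con, size = 8, endian = "little")
  writeBin(as.integer(g$ijk), con, size = 4, endian = "little")
  writeBin(as.numeric(leadfield$gain), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_leadfield
#' @export
read_leadfield <- function(path) {
  jf <- paste0(path, ".json")
  if (!file.exists(jf)) stop_bad_arg("missing lead-field container: ", jf)
  h <- jsonlite::read_json(jf, simplifyVector = TRUE)
  if (!identical(h$container, "bmerp-leadfield"))
    stop_bad_arg("not a lead-field container: ", jf)
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  pos <- matrix(readBin(con, "numeric", h$n_nodes * 3, size = 8,
                        endian = "little"), h$n_nodes, 3)
  ijk <- matrix(readBin(con, "integer", h$n_nodes * 3, size = 4,
                        endian = "little"), h$n_nodes, 3)
  gain <- matrix(readBin(con, "numeric", h$n_channels * 3 * h$n_nodes,
                         size = 8, endian = "little"),
                 h$n_channels, 3 * h$n_nodes)
  hm <- head_model(h$radii, h$conductivities)
  grid <- structure(list(pos = pos, ijk = ijk, spacing = h$spacing,
                         n = h$n_nodes, max_radius = h$max_radius),
                    class = "source_grid")
  structure(list(gain = gain, montage = NULL, headmodel = hm, grid = grid,
                 nterms = h$nterms, labels = h$labels),
            class = "leadfield")
}
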