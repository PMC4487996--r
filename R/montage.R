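#' Idealized BioSemi-64 electrode montage
#'
#' Builds the 64-channel BioSemi (10-10 naming) montage on a unit sphere from
#' the idealized geometry of the extended 10-20 system: the vertex at Cz, the
#' circumferential ring (Fpz...Oz through T7/T8) at 72 degrees of inclination,
#' midline sites at 18-degree steps, the below-ring row (P9/P10/Iz) at 90
#' degrees, and interior sites placed by great-circle interpolation between
#' the midline and ring site of the same row. Positions are idealized, not
#' digitized; x points to the right ear, y to the nasion, z to the vertex.
#'
#' @return A data frame of class `montage` with columns `label`, `x`, `y`, `z`.
#' @examples
#' m <- biosemi64_montage()
#' stopifnot(nrow(m) == 64, all(abs(sqrt(m$x^2 + m$y^2 + m$z^2) - 1) < 1e-9))
#' @export
biosemi64_montage <- function() {
  sph <- function(incl_deg, az_deg) {
    i <- incl_deg * pi / 180
    a <- az_deg * pi / 180
    c(sin(i) * cos(a), sin(i) * sin(a), cos(i))
  }
  pos <- list()
  add <- function(label, p) pos[[label]] <<- p

  # midline (front azimuth 90, back azimuth -90)
  mid <- c(Fpz = 72, AFz = 54, Fz = 36, FCz = 18, Cz = 0,
           CPz = -18, Pz = -36, POz = -54, Oz = -72, Iz = -90)
  for (lab in names(mid)) {
    incl <- abs(mid[[lab]])
    az <- if (mid[[lab]] >= 0) 90 else -90
    if (lab == "Cz") add(lab, c(0, 0, 1)) else add(lab, sph(incl, az))
  }

  # circumferential ring, inclination 72, azimuth in 18-degree steps
  ring_left <- c(Fp1 = 108, AF7 = 126, F7 = 144, FT7 = 162, T7 = 180,
                 TP7 = 198, P7 = 216, PO7 = 234, O1 = 252)
  ring_right <- c(Fp2 = 72, AF8 = 54, F8 = 36, FT8 = 18, T8 = 0,
                  TP8 = -18, P8 = -36, PO8 = -54, O2 = -72)
  for (lab in names(ring_left)) add(lab, sph(72, ring_left[[lab]]))
  for (lab in names(ring_right)) add(lab, sph(72, ring_right[[lab]]))

  # below-ring row
  add("P9", sph(90, 216))
  add("P10", sph(90, -36))

  # interior rows: slerp between the midline site and the ring site
  rows <- list(
    list(mid = "Fz",  left = "F7",  right = "F8",
         lab_l = c("F1", "F3", "F5"),  lab_r = c("F2", "F4", "F6")),
    list(mid = "FCz", left = "FT7", right = "FT8",
         lab_l = c("FC1", "FC3", "FC5"), lab_r = c("FC2", "FC4", "FC6")),
    list(mid = "Cz",  left = "T7",  right = "T8",
         lab_l = c("C1", "C3", "C5"),  lab_r = c("C2", "C4", "C6")),
    list(mid = "CPz", left = "TP7", right = "TP8",
         lab_l = c("CP1", "CP3", "CP5"), lab_r = c("CP2", "CP4", "CP6")),
    list(mid = "Pz",  left = "P7",  right = "P8",
         lab_l = c("P1", "P3", "P5"),  lab_r = c("P2", "P4", "P6")),
    list(mid = "AFz", left = "AF7", right = "AF8",
         lab_l = "AF3", lab_r = "AF4"),
    list(mid = "POz", left = "PO7", right = "PO8",
         lab_l = "PO3", lab_r = "PO4")
  )
  for (rw in rows) {
    nl <- length(rw$lab_l)
    fr <- seq_len(nl) / (nl + 1)
    for (k in seq_len(nl)) {
      add(rw$lab_l[k], slerp(pos[[rw$mid]], pos[[rw$left]], fr[k]))
      add(rw$lab_r[k], slerp(pos[[rw$mid]], pos[[rw$right]], fr[k]))
    }
  }

  m <- do.call(rbind, pos)
  out <- data.frame(label = rownames(m), x = m[, 1], y = m[, 2], z = m[, 3],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("montage", "data.frame")
  out
}

montage_positions <- function(montage) {
  as.matrix(montage[, c("x", "y", "z")])
}

assert_montage <- function(montage) {
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(montage)))
    stop_bad_arg("montage must have columns label, x, y, z")
  if (anyDuplicated(montage$label))
    stop_bad_arg("montage labels must be unique")
  nrm <- sqrt(rowSums(montage_positions(montage)^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop_bad_arg("montage positions must lie on the unit sphere")
  invisible(montage)
}

#' Electrode adjacency from a montage
#'
#' Two electrodes are neighbors when their great-circle distance is below
#' `factor` times the median nearest-neighbor distance of the montage.
#'
#' @param montage montage data frame (see [biosemi64_montage()]).
#' @param factor multiplier on the median nearest-neighbor distance.
#' @return A logical adjacency matrix (diagonal `FALSE`), dimnames = labels.
#' @export
montage_adjacency <- function(montage, factor = 1.3) {
  assert_montage(montage)
  d <- greatcircle_dist(montage_positions(montage))
  diag(d) <- Inf
  thr <- factor * stats::median(apply(d, 1, min))
  adj <- d < thr
  dimnames(adj) <- list(montage$label, montage$label)
  adj
}

#' Read / write a montage CSV (`label,x,y,z`, unit sphere)
#' @param path file path.
#' @return `read_montage` returns a `montage` data frame.
#' @export
read_montage <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_montage(m)
  class(m) <- c("montage", "data.frame")
  m
}

#' @rdname read_montage
#' @param montage montage to write.
#' @export
write_montage <- function(montage, path) {
  assert_montage(montage)
  utils::write.csv(as.data.frame(montage), path, row.names = FALSE)
  invisible(path)
}
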