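#' Parametric gait model for 13-marker point-light figures
#'
#' Defines the kinematics of a point-light walker (or cyclist) as a small
#' hierarchy of sinusoidally driven limb pendula. Thirteen markers are used:
#' head, both shoulders, elbows, wrists, hips, knees and ankles. All joint
#' angles are periodic in the gait cycle, so marker trajectories have period
#' `1/cadence` seconds.
#'
#' @param cadence gait cycles per second (> 0). One cycle = two steps.
#' @param stimulus_class `"walker"` or `"cyclist"`. The cyclist shares the
#'   marker set but drives the legs with circular (pedaling) trajectories and
#'   keeps the arms nearly static; it exists as the behavioral target class.
#' @param segment_lengths named numeric vector of body-segment lengths in
#'   arbitrary body units (defaults approximate human proportions).
#' @param swing named numeric vector of swing amplitudes (radians) for
#'   `thigh`, `knee`, `arm`, `elbow`; set all to 0 for a static figure.
#' @param phase named numeric vector of phase offsets (radians).
#' @return An object of class `gait_model`.
#' @export
gait_model <- function(cadence = 1.0,
                       stimulus_class = c("walker", "cyclist"),
                       segment_lengths = NULL,
                       swing = NULL,
                       phase = NULL) {
  stimulus_class <- match.arg(stimulus_class)
  if (!is.numeric(cadence) || length(cadence) != 1 || cadence <= 0)
    stop_bad_arg("cadence must be a single positive number")
  seg <- c(head = 0.28, neck = 0.10, torso = 0.55, shoulder_w = 0.22,
           hip_w = 0.14, upper_arm = 0.30, forearm = 0.28,
           thigh = 0.42, shank = 0.42)
  if (!is.null(segment_lengths)) seg[names(segment_lengths)] <- segment_lengths
  sw_def <- if (stimulus_class == "walker")
    c(thigh = 0.55, knee = 0.7, arm = 0.45, elbow = 0.35, bob = 0.025)
  else
    c(thigh = 0.9, knee = 0.9, arm = 0.05, elbow = 0.05, bob = 0.01)
  if (!is.null(swing)) sw_def[names(swing)] <- swing
  ph <- c(global = 0, arm_vs_leg = pi)
  if (!is.null(phase)) ph[names(phase)] <- phase
  structure(list(cadence = cadence, stimulus_class = stimulus_class,
                 segments = seg, swing = sw_def, phase = ph),
            class = "gait_model")
}

marker_names <- function() {
  c("head", "l_shoulder", "r_shoulder", "l_elbow", "r_elbow",
    "l_wrist", "r_wrist", "l_hip", "r_hip", "l_knee", "r_knee",
    "l_ankle", "r_ankle")
}

# One frame of the gait model at time t (seconds). Body frame: x lateral
# (left negative), y walking direction, z up. Returns 13 x 3 matrix.
gait_frame <- function(gait, t, phase0 = 0) {
  sg <- gait$segments
  sw <- gait$swing
  w <- 2 * pi * gait$cadence
  th <- w * t + phase0
  hip_z <- sg[["thigh"]] + sg[["shank"]]
  bob <- sw[["bob"]] * cos(2 * th)
  pelvis <- c(0, 0, hip_z + bob)
  chest <- pelvis + c(0, 0, sg[["torso"]])
  head <- chest + c(0, 0, sg[["neck"]] + sg[["head"]])
  out <- matrix(0, 13, 3, dimnames = list(marker_names(), c("x", "y", "z")))
  out["head", ] <- head

  side <- c(l = -1, r = 1)
  for (s in names(side)) {
    sgn <- side[[s]]
    leg_ph <- th + ifelse(s == "l", 0, pi)
    hip <- pelvis + c(sgn * sg[["hip_w"]], 0, 0)
    shoulder <- chest + c(sgn * sg[["shoulder_w"]], 0, 0)
    if (gait$stimulus_class == "walker") {
      # pendular legs: thigh angle about the hip in the sagittal plane,
      # knee flexion only during swing (half-wave rectified)
      a_th <- sw[["thigh"]] * sin(leg_ph)
      flex <- sw[["knee"]] * pmax(0, sin(leg_ph + pi / 3))
      knee <- hip + sg[["thigh"]] * c(0, sin(a_th), -cos(a_th))
      a_sh <- a_th - flex
      ankle <- knee + sg[["shank"]] * c(0, sin(a_sh), -cos(a_sh))
    } else {
      # cyclist: feet on circular pedal paths below the hip
      cr <- 0.22 * sw[["thigh"]] / 0.9 + 0.08
      cz <- hip_z - sg[["thigh"]] - 0.1
      ankle <- c(hip[1], cr * sin(leg_ph), cz + cr * cos(leg_ph))
      # knee bends to reach the pedal: midpoint pushed forward/up
      mid <- (hip + ankle) / 2
      knee <- mid + c(0, 0.18, 0.12)
    }
    arm_ph <- leg_ph + gait$phase[["arm_vs_leg"]]
    a_arm <- sw[["arm"]] * sin(arm_ph)
    elbow <- shoulder + sg[["upper_arm"]] * c(0, sin(a_arm), -cos(a_arm))
    a_fa <- a_arm + sw[["elbow"]] * (1 + sin(arm_ph)) / 2
    wrist <- elbow + sg[["forearm"]] * c(0, sin(a_fa), -cos(a_fa))
    out[paste0(s, "_hip"), ] <- hip
    out[paste0(s, "_shoulder"), ] <- shoulder
    out[paste0(s, "_knee"), ] <- knee
    out[paste0(s, "_ankle"), ] <- ankle
    out[paste0(s, "_elbow"), ] <- elbow
    out[paste0(s, "_wrist"), ] <- wrist
  }
  out
}

#' Generate a point-light walker sequence
#'
#' Evaluates the periodic gait model at `fps` frames per second for
#' `duration` ms. The figure walks "in place" (treadmill convention): there is
#' no net body translation, only the periodic limb motion. The seed sets the
#' initial gait phase, so different seeds give different starting postures of
#' the same gait.
#'
#' @param gait a [gait_model()].
#' @param duration stimulus duration in ms (> 0).
#' @param fps frame rate in Hz (> 0).
#' @param seed integer seed (initial-phase determinism).
#' @return An object of class `plight_seq`: list with `frames` (array
#'   `n_frames x 13 x 3`, body units), `fps`, `duration`, `kind`
#'   (`"biological"`), and the generating parameters.
#' @examples
#' w <- generate_walker(gait_model(), duration = 1000, fps = 30, seed = 1)
#' dim(w$frames)  # 30 frames x 13 markers x 3 coords
#' @export
generate_walker <- function(gait = gait_model(), duration = 1000, fps = 30,
                            seed = 1) {
  if (!inherits(gait, "gait_model")) stop_bad_arg("gait must be a gait_model")
  if (!is.numeric(duration) || duration <= 0)
    stop_bad_arg("duration must be positive")
  if (!is.numeric(fps) || fps <= 0) stop_bad_arg("fps must be positive")
  set.seed(as.integer(seed))
  phase0 <- runif(1, 0, 2 * pi)
  nf <- round(duration / 1000 * fps)
  frames <- array(0, dim = c(nf, 13, 3),
                  dimnames = list(NULL, marker_names(), c("x", "y", "z")))
  for (k in seq_len(nf))
    frames[k, , ] <- gait_frame(gait, (k - 1) / fps, phase0)
  structure(list(frames = frames, fps = fps, duration = duration,
                 kind = "biological", gait = gait, seed = as.integer(seed),
                 phase0 = phase0),
            class = "plight_seq")
}

#' Momentum-preserving scrambling of a point-light sequence
#'
#' Each marker receives a single random translation, drawn so that its
#' first-frame position falls uniformly inside the axis-aligned bounding box
#' of the original first frame ("the walker-defined area"). The same
#' translation is applied to every subsequent frame of that marker, so every
#' per-marker frame-to-frame displacement -- and hence the total momentum of
#' the display -- is preserved exactly.
#'
#' @param seq a biological `plight_seq`.
#' @param seed integer seed.
#' @return A `plight_seq` with `kind = "scrambled"`.
#' @export
scramble <- function(seq, seed = 1) {
  if (!inherits(seq, "plight_seq")) stop_bad_arg("seq must be a plight_seq")
  if (!identical(seq$kind, "biological"))
    stop_bad_arg("can only scramble a biological sequence ",
                 "(double scrambling would not preserve the walker area)")
  set.seed(as.integer(seed))
  f1 <- seq$frames[1, , ]
  lo <- apply(f1, 2, min)
  hi <- apply(f1, 2, max)
  nm <- nrow(f1)
  newstart <- sapply(seq_len(3), function(d) runif(nm, lo[d], hi[d]))
  shift <- newstart - f1
  out <- seq
  nf <- dim(seq$frames)[1]
  for (m in seq_len(nm)) {
    fm <- matrix(seq$frames[, m, ], nrow = nf, ncol = 3)
    out$frames[, m, ] <- sweep(fm, 2, shift[m, ], `+`)
  }
  out$kind <- "scrambled"
  out$scramble_seed <- as.integer(seed)
  out
}

#' Project a point-light sequence to a viewed stimulus
#'
#' Projects body-space coordinates orthographically into the image plane and
#' scales each frame to the required angular size. Lateral stimuli keep a
#' fixed angular extent (2 degrees small, 4 degrees big) with the centroid
#' fixed at the screen center (treadmill convention); radial stimuli ramp
#' linearly between the endpoint sizes (1-3 degrees small, 3-5 degrees big;
#' reversed when receding) so that the mean size matches the lateral stimulus
#' of the same size class exactly.
#'
#' @param seq a `plight_seq`.
#' @param plane `"lateral"` or `"radial"`.
#' @param direction `"left"`/`"right"` (lateral) or
#'   `"approach"`/`"recede"` (radial).
#' @param size_class `"small"` or `"big"`.
#' @return An object of class `viewed_stimulus`: `frames` (`n x 13 x 2`,
#'   degrees of visual angle), `size_trace` (degrees per frame), and the
#'   projection parameters.
#' @export
project_view <- function(seq, plane = c("lateral", "radial"),
                         direction = c("left", "right", "approach", "recede"),
                         size_class = c("small", "big")) {
  if (!inherits(seq, "plight_seq")) stop_bad_arg("seq must be a plight_seq")
  plane <- match.arg(plane)
  direction <- match.arg(direction)
  size_class <- match.arg(size_class)
  lat_ok <- plane == "lateral" && direction %in% c("left", "right")
  rad_ok <- plane == "radial" && direction %in% c("approach", "recede")
  if (!lat_ok && !rad_ok)
    stop_bad_arg("incompatible plane/direction pair: ", plane, "/", direction)

  nf <- dim(seq$frames)[1]
  if (plane == "lateral") {
    base <- if (size_class == "small") 2 else 4
    size_trace <- rep(base, nf)
    # sagittal view: walking axis y horizontal, z vertical
    xy <- seq$frames[, , c("y", "z"), drop = FALSE]
    if (direction == "left") xy[, , 1] <- -xy[, , 1]
  } else {
    ends <- if (size_class == "small") c(1, 3) else c(3, 5)
    if (direction == "recede") ends <- rev(ends)
    size_trace <- base::seq(ends[1], ends[2], length.out = nf)
    # frontal view: lateral axis x horizontal, z vertical
    xy <- seq$frames[, , c("x", "z"), drop = FALSE]
  }
  out <- array(0, dim = c(nf, dim(seq$frames)[2], 2),
               dimnames = list(NULL, dimnames(seq$frames)[[2]],
                               c("h", "v")))
  for (k in seq_len(nf)) {
    fr <- xy[k, , ]
    extent <- max(fr[, 2]) - min(fr[, 2])   # body height sets the size
    sc <- size_trace[k] / extent
    fr <- fr * sc
    fr[, 1] <- fr[, 1] - mean(fr[, 1])      # centroid fixed at screen center
    fr[, 2] <- fr[, 2] - mean(fr[, 2])
    out[k, , ] <- fr
  }
  structure(list(frames = out, plane = plane, direction = direction,
                 size_class = size_class, size_trace = size_trace,
                 fps = seq$fps, duration = seq$duration, kind = seq$kind),
            class = "viewed_stimulus")
}

#' Export a viewed stimulus as CSV plus JSON sidecar
#'
#' Writes one row per (frame, marker) with angular coordinates and the frame
#' size, and a `.json` sidecar holding the projection parameters.
#' @param stim a `viewed_stimulus`.
#' @param path output CSV path (sidecar gets extension `.json`).
#' @export
write_stimulus <- function(stim, path) {
  if (!inherits(stim, "viewed_stimulus"))
    stop_bad_arg("stim must be a viewed_stimulus")
  nf <- dim(stim$frames)[1]
  nm <- dim(stim$frames)[2]
  df <- data.frame(
    frame = rep(seq_len(nf), each = nm),
    marker_id = rep(dimnames(stim$frames)[[2]], nf),
    x = as.vector(t(stim$frames[, , 1])),
    y = as.vector(t(stim$frames[, , 2])),
    size_deg = rep(stim$size_trace, each = nm))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(plane = stim$plane, direction = stim$direction,
               size_class = stim$size_class, fps = stim$fps,
               duration_ms = stim$duration, kind = stim$kind)
  jsonlite::write_json(meta, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.plight_seq <- function(x, ...) {
  cat(sprintf("<plight_seq> %s, %d frames @ %g fps (%g ms), 13 markers\n",
              x$kind, dim(x$frames)[1], x$fps, x$duration))
  invisible(x)
}

#' @export
print.viewed_stimulus <- function(x, ...) {
  cat(sprintf("<viewed_stimulus> %s/%s, size %s (%.3g-%.3g deg), %d frames\n",
              x$plane, x$direction, x$size_class, min(x$size_trace),
              max(x$size_trace), dim(x$frames)[1]))
  invisible(x)
}
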