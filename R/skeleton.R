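#' The 25-joint depth-camera body model
#'
#' Canonical joint names of the Kinect V2 skeletal model, in device order.
#' All skeleton containers in this package key their positions by these names.
#'
#' @return Character vector of 25 unique joint names.
#' @export
#' @examples
#' kinect_joints()
kinect_joints <- function() {
  c("spine_base", "spine_mid", "neck", "head",
    "shoulder_left", "elbow_left", "wrist_left", "hand_left",
    "shoulder_right", "elbow_right", "wrist_right", "hand_right",
    "hip_left", "knee_left", "ankle_left", "foot_left",
    "hip_right", "knee_right", "ankle_right", "foot_right",
    "spine_shoulder", "hand_tip_left", "thumb_left",
    "hand_tip_right", "thumb_right")
}

# joints the three-joint CoM estimator and first-frame alignment require
core_joints <- function() c("hip_left", "hip_right", "spine_mid")

tracking_states <- function() c("tracked", "inferred", "not_tracked")

# Camera-space axis convention, used everywhere:
#   axis 1 = mediolateral (ML), axis 2 = superior-inferior (SI),
#   axis 3 = anterior-posterior (AP, the camera's depth axis).
axis_names <- function() c("ml", "si", "ap")

#' Construct a skeleton-joint recording
#'
#' A `skeleton_sequence` holds timestamped frames of the 25-joint body model:
#' joint positions in metres in camera space (axis 1 = mediolateral, axis 2 =
#' superior-inferior, axis 3 = anterior-posterior/depth), a per-joint tracking
#' state per frame, the nominal frame rate, and subject/trial metadata.
#'
#' @param t Numeric vector of frame timestamps in seconds, strictly increasing,
#'   length at least 2.
#' @param pos Numeric array `n_frames x 25 x 3` of joint positions in metres;
#'   the joint dimension must be named with [kinect_joints()] (or unnamed, in
#'   which case device order is assumed). `NA` positions are only allowed where
#'   the tracking state is `"not_tracked"`.
#' @param state Character matrix `n_frames x 25` with entries from
#'   `"tracked"`, `"inferred"`, `"not_tracked"`. Defaults to all `"tracked"`.
#' @param rate_hz Nominal frame rate in Hz (default 30, the device rate).
#' @param height_cm,mass_kg,subject Subject metadata (height in cm, mass in kg,
#'   optional identifier).
#' @param condition Sensory Organisation Test condition label, one of
#'   `"a"`..`"f"`, or `NA`.
#' @param repeat_idx Repeat index of the trial within its condition, or `NA`.
#' @return An object of class `skeleton_sequence`.
#' @export
skeleton_sequence <- function(t, pos, state = NULL, rate_hz = 30,
                              height_cm = NA_real_, mass_kg = NA_real_,
                              subject = NA_character_,
                              condition = NA_character_,
                              repeat_idx = NA_integer_) {
  t <- as.numeric(t)
  if (length(t) < 2L)
    stop("a skeleton_sequence needs at least 2 frames")
  if (any(!is.finite(t)))
    stop("frame timestamps must be finite")
  if (any(diff(t) <= 0))
    stop("frame timestamps must be strictly increasing")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("nominal rate must be a single positive number")

  joints <- kinect_joints()
  pos <- unclass(pos)
  if (length(dim(pos)) != 3L || dim(pos)[1] != length(t) ||
      dim(pos)[2] != 25L || dim(pos)[3] != 3L)
    stop("pos must be an n_frames x 25 x 3 array matching length(t)")
  jn <- dimnames(pos)[[2]]
  if (!is.null(jn)) {
    if (!setequal(jn, joints))
      stop("pos joint names must be exactly the 25 canonical joints")
    pos <- pos[, joints, , drop = FALSE]
  }
  dimnames(pos) <- list(NULL, joints, axis_names())

  if (is.null(state)) {
    state <- matrix("tracked", nrow = length(t), ncol = 25L)
  }
  state <- matrix(as.character(state), nrow = length(t), ncol = 25L)
  colnames(state) <- joints
  if (!all(state %in% tracking_states()))
    stop("tracking states must be one of: ",
         paste(tracking_states(), collapse = ", "))

  missing_pos <- apply(is.na(pos), c(1, 2), any)
  bad <- missing_pos & state != "not_tracked"
  if (any(bad))
    stop("positions must be present (finite) for every joint not marked not_tracked")

  structure(
    list(t = t, pos = pos, state = state, rate_hz = rate_hz,
         meta = list(height_cm = height_cm, mass_kg = mass_kg,
                     subject = subject, condition = condition,
                     repeat_idx = repeat_idx)),
    class = "skeleton_sequence")
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  dur <- x$t[length(x$t)] - x$t[1]
  cat(sprintf("<skeleton_sequence> %d frames, %.2f s at %g Hz nominal\n",
              n_frames(x), dur, x$rate_hz))
  m <- x$meta
  cat(sprintf("  subject: %s  height: %s cm  condition: %s  repeat: %s\n",
              m$subject, format(m$height_cm), m$condition,
              format(m$repeat_idx)))
  untracked <- colSums(x$state == "not_tracked")
  if (any(untracked > 0))
    cat("  not_tracked frames: ",
        paste(sprintf("%s=%d", names(untracked)[untracked > 0],
                      untracked[untracked > 0]), collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in a skeleton sequence
#' @param seq A `skeleton_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) length(seq$t)

#' Duration of a skeleton sequence in seconds
#' @param seq A `skeleton_sequence`.
#' @return Last timestamp minus first, seconds.
#' @export
duration_s <- function(seq) seq$t[n_frames(seq)] - seq$t[1]

#' Extract a single frame
#'
#' @param seq A `skeleton_sequence`.
#' @param i Frame index.
#' @return A `skeleton_frame`: list with `t` (seconds), `pos` (25 x 3 matrix,
#'   metres, rows named by joint) and `state` (named character vector).
#' @export
skeleton_frame <- function(seq, i) {
  stopifnot(i >= 1L, i <= n_frames(seq))
  p <- seq$pos[i, , , drop = TRUE]
  structure(list(t = seq$t[i], pos = p, state = seq$state[i, ]),
            class = "skeleton_frame")
}

#' Positions of one joint across all frames
#'
#' @param seq A `skeleton_sequence`.
#' @param joint A joint name from [kinect_joints()].
#' @return `n_frames x 3` matrix (ml, si, ap), metres.
#' @export
joint_positions <- function(seq, joint) {
  joint <- match.arg(joint, kinect_joints())
  seq$pos[, joint, , drop = TRUE]
}

# rebuild a sequence from an existing one with new positions/state
replace_positions <- function(seq, pos, state = seq$state) {
  out <- seq
  dimnames(pos) <- dimnames(seq$pos)
  out$pos <- pos
  out$state <- state
  out
}
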