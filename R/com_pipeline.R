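#' Mirror the mediolateral axis of a skeleton recording
#'
#' A rear-facing camera sees the subject's left on the image's left, so its
#' mediolateral axis is reversed relative to the plate (subject) frame.
#' `flip_ml()` negates the ML coordinate of every joint in every frame and
#' leaves everything else untouched. It is an involution:
#' `flip_ml(flip_ml(x))` is `x`.
#'
#' @param seq A [skeleton_sequence()].
#' @return The mirrored `skeleton_sequence`.
#' @export
flip_ml <- function(seq) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  pos <- seq$pos
  pos[, , 1] <- -pos[, , 1]
  replace_positions(seq, pos)
}

#' Align a recording to its first frame
#'
#' Rigidly translates every frame by minus the frame-1 position of the
#' three-joint centroid (`hip_left`, `hip_right`, `spine_mid`), so that all
#' subsequent movement is expressed relative to the initial stance. The
#' translation is whole-frame and per-recording constant: intra-frame joint
#' geometry is preserved exactly, and applying the operation twice changes
#' nothing (idempotence).
#'
#' @param seq A [skeleton_sequence()] with at least 2 frames.
#' @return The aligned `skeleton_sequence`; the frame-1 three-joint centroid
#'   of the result is the origin.
#' @export
align_to_first <- function(seq) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  f1 <- skeleton_frame(seq, 1L)
  if (any(f1$state[core_joints()] == "not_tracked"))
    stop("cannot align: a core joint (hip_left/hip_right/spine_mid) is ",
         "not_tracked in the first frame")
  anchor <- com_three_joint(f1)
  pos <- seq$pos
  for (a in 1:3) pos[, , a] <- pos[, , a] - anchor[a]
  replace_positions(seq, pos)
}

#' Three-joint centre-of-mass estimate
#'
#' Estimates the body's centre of mass for one frame as the coordinate-wise
#' (euclidean) mean of the left hip, right hip and mid-spine joints — three
#' joints a depth camera tracks reliably at standing height. The estimate is
#' computed on all three axes and commutes with rigid translation of the
#' frame.
#'
#' @param frame A `skeleton_frame` (see [skeleton_frame()]), or any list with
#'   a `pos` 25 x 3 matrix (rows named by joint) and a named `state` vector.
#' @return Numeric length-3 vector `(ml, si, ap)` in the frame's units.
#' @export
com_three_joint <- function(frame) {
  jj <- core_joints()
  if (any(frame$state[jj] == "not_tracked"))
    stop("com_three_joint: core joint not_tracked in this frame")
  p <- frame$pos[jj, , drop = FALSE]
  colMeans(p)
}

#' Body-segment parameter table for the segmental comparator
#'
#' A segment table drives the total-body centre-of-mass (TBCM) comparator:
#' each row names a segment, its mass as a fraction of body mass, its
#' proximal and distal joints, and the segment CoM's position as a fraction
#' of the proximal-to-distal distance. Mass fractions must sum to 1.
#'
#' `default_segment_table()` ships a 14-segment table with classical cadaver
#' mass and CoM-location fractions (Dempster's coefficients) mapped onto the
#' 25-joint camera model; hands are collapsed into a single wrist-to-hand
#' segment per side.
#'
#' @param segment,mass_fraction,proximal,distal,com_fraction Columns of the
#'   table; see Details.
#' @return A data frame of class `segment_table`.
#' @export
segment_table <- function(segment, mass_fraction, proximal, distal,
                          com_fraction) {
  df <- data.frame(segment = segment, mass_fraction = mass_fraction,
                   proximal = proximal, distal = distal,
                   com_fraction = com_fraction)
  if (abs(sum(df$mass_fraction) - 1) > 1e-6)
    stop("segment mass fractions must sum to 1 (got ",
         format(sum(df$mass_fraction)), ")")
  if (any(df$mass_fraction < 0 | df$mass_fraction > 1) ||
      any(df$com_fraction < 0 | df$com_fraction > 1))
    stop("mass and CoM fractions must lie in [0, 1]")
  joints <- kinect_joints()
  bad <- setdiff(c(df$proximal, df$distal), joints)
  if (length(bad)) stop("unknown joint(s) in segment table: ",
                        paste(bad, collapse = ", "))
  class(df) <- c("segment_table", "data.frame")
  df
}

#' @rdname segment_table
#' @export
default_segment_table <- function() {
  segment_table(
    segment = c("head_neck", "trunk",
                "upper_arm_left", "upper_arm_right",
                "forearm_left", "forearm_right",
                "hand_left", "hand_right",
                "thigh_left", "thigh_right",
                "shank_left", "shank_right",
                "foot_left", "foot_right"),
    mass_fraction = c(0.081, 0.497,
                      0.028, 0.028, 0.016, 0.016, 0.006, 0.006,
                      0.100, 0.100, 0.0465, 0.0465, 0.0145, 0.0145),
    proximal = c("spine_shoulder", "spine_shoulder",
                 "shoulder_left", "shoulder_right",
                 "elbow_left", "elbow_right",
                 "wrist_left", "wrist_right",
                 "hip_left", "hip_right",
                 "knee_left", "knee_right",
                 "ankle_left", "ankle_right"),
    distal = c("head", "spine_base",
               "elbow_left", "elbow_right",
               "wrist_left", "wrist_right",
               "hand_left", "hand_right",
               "knee_left", "knee_right",
               "ankle_left", "ankle_right",
               "foot_left", "foot_right"),
    com_fraction = c(0.500, 0.500,
                     0.436, 0.436, 0.430, 0.430, 0.506, 0.506,
                     0.433, 0.433, 0.433, 0.433, 0.500, 0.500))
}

#' Total-body centre of mass from a segment table
#'
#' Computes the segmental (TBCM) estimate for one frame: each segment's CoM
#' is placed by linear interpolation between its proximal and distal joints
#' at the table's CoM fraction, and the body CoM is the mass-fraction
#' weighted mean of segment CoMs, on all three axes.
#'
#' @param frame A `skeleton_frame`.
#' @param table A [segment_table()]; defaults to [default_segment_table()].
#' @return Numeric length-3 vector `(ml, si, ap)` in the frame's units.
#' @export
com_tbcm <- function(frame, table = default_segment_table()) {
  if (!inherits(table, "segment_table")) {
    table <- segment_table(table$segment, table$mass_fraction,
                           table$proximal, table$distal, table$com_fraction)
  }
  need <- unique(c(table$proximal, table$distal))
  if (any(frame$state[need] == "not_tracked"))
    stop("com_tbcm: a joint referenced by the segment table is not_tracked")
  p <- frame$pos[table$proximal, , drop = FALSE]
  d <- frame$pos[table$distal, , drop = FALSE]
  seg_com <- p + table$com_fraction * (d - p)
  colSums(seg_com * table$mass_fraction) / sum(table$mass_fraction)
}

# Linear-in-time interpolation of not_tracked gaps for the given joints.
# Only sequences that already passed validation should reach this (gaps are
# a small fraction of frames); endpoints extrapolate by rule = 2 (carry
# nearest tracked value).
interpolate_gaps <- function(seq, joints) {
  state <- seq$state
  pos <- seq$pos
  for (j in joints) {
    gap <- state[, j] == "not_tracked"
    if (!any(gap)) next
    if (all(gap))
      stop("joint ", j, " is not_tracked in every frame; cannot interpolate")
    ok <- !gap
    for (a in 1:3) {
      pos[gap, j, a] <- stats::approx(seq$t[ok], pos[ok, j, a],
                                      xout = seq$t[gap], rule = 2)$y
    }
    state[gap, j] <- "inferred"
  }
  replace_positions(seq, pos, state)
}

#' Run the CoM-path pipeline on a skeleton recording
#'
#' The full camera-side pipeline: (1) mirror the mediolateral axis (rear
#' camera), (2) align every frame to the first frame's three-joint centroid,
#' (3) estimate the CoM per frame with the chosen method, (4) drop the
#' superior-inferior axis and emit the 2D mediolateral/anterior-posterior
#' path in millimetres at the recording's native timestamps (no resampling).
#'
#' Core-joint dropouts within the validation tolerance are linearly
#' interpolated in time before CoM computation; recordings failing
#' [validate_recording()] are refused when `validate = TRUE`.
#'
#' @param seq A [skeleton_sequence()] in metres.
#' @param method `"three_joint"` (primary) or `"tbcm"` (segmental
#'   comparator).
#' @param table Segment table for `method = "tbcm"`.
#' @param validate Screen the recording first (default `TRUE`).
#' @param ... Passed to [validate_recording()].
#' @return A `com_path` (mm) with the method tag set and subject/trial
#'   metadata carried through.
#' @export
com_path <- function(seq, method = c("three_joint", "tbcm"),
                     table = default_segment_table(), validate = TRUE, ...) {
  method <- match.arg(method)
  stopifnot(inherits(seq, "skeleton_sequence"))
  if (validate) {
    v <- validate_recording(seq, ...)
    if (v$status == "excluded")
      stop("recording excluded [", v$reason, "]: ", v$detail)
  }
  need <- if (method == "three_joint") core_joints()
          else unique(c(table$proximal, table$distal, core_joints()))
  seq <- interpolate_gaps(seq, need)
  seq <- flip_ml(seq)
  seq <- align_to_first(seq)

  if (method == "three_joint") {
    jj <- core_joints()
    com <- (seq$pos[, jj[1], ] + seq$pos[, jj[2], ] + seq$pos[, jj[3], ]) / 3
  } else {
    p <- seq$pos[, table$proximal, , drop = FALSE]
    d <- seq$pos[, table$distal, , drop = FALSE]
    w <- table$mass_fraction / sum(table$mass_fraction)
    com <- matrix(0, n_frames(seq), 3L)
    for (k in seq_len(nrow(table))) {
      seg <- p[, k, ] + table$com_fraction[k] * (d[, k, ] - p[, k, ])
      com <- com + w[k] * seg
    }
  }
  com_path_new(seq$t, ml_mm = com[, 1] * 1000, ap_mm = com[, 3] * 1000,
               rate_hz = seq$rate_hz, method = method, meta = seq$meta)
}
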