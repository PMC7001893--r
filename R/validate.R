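#' Exclusion reason codes
#'
#' Reason codes used when screening recordings, mirroring the categories a
#' paired camera/force-plate balance study must police: skeletons whose core
#' joints the camera failed to track, recordings that did not start in sync
#' with the comparator, one trial recorded over another, the tracker mistaking
#' the safety harness for a limb, and trials in which the participant fell.
#' `"none"` marks a recording that passed.
#'
#' @return Character vector of reason codes, in screening precedence order
#'   (first match wins when several rules fire): `out_of_sync`,
#'   `malformed_skeleton`, `fall`, `over_recording`, `harness_confusion`,
#'   then `extra_recording` for supernumerary repeats, and `none`.
#' @export
exclusion_reasons <- function() {
  c("out_of_sync", "malformed_skeleton", "fall", "over_recording",
    "harness_confusion", "extra_recording", "none")
}

new_verdict <- function(status, reason, detail) {
  stopifnot(status %in% c("ok", "excluded"),
            reason %in% exclusion_reasons(),
            (status == "excluded") == (reason != "none"))
  structure(list(status = status, reason = reason, detail = detail),
            class = "validation_verdict")
}

#' @export
print.validation_verdict <- function(x, ...) {
  cat(sprintf("<verdict> %s%s: %s\n", x$status,
              if (x$reason != "none") paste0(" [", x$reason, "]") else "",
              x$detail))
  invisible(x)
}

#' Screen a skeleton recording for analysability
#'
#' Automated operationalisation of the manual exclusion screening of a paired
#' recording session. Two machine-checkable rules are applied, in precedence
#' order:
#'
#' 1. *out of sync*: if `reference_duration_s` is given (the duration of the
#'    simultaneous comparator recording) and the sequence duration differs
#'    from it by more than `sync_tol_s`, the recording cannot be paired.
#' 2. *malformed skeleton*: if any of the core joints (`hip_left`,
#'    `hip_right`, `spine_mid`) is `not_tracked` in more than
#'    `max_untracked_frac` of frames, the tracker failed to follow the body.
#'
#' The function is total: every input yields exactly one verdict, and the
#' verdict depends only on durations and tracking states, so it is invariant
#' to a uniform time-shift of all timestamps.
#'
#' @param seq A [skeleton_sequence()].
#' @param expected_duration_s Nominal trial duration in seconds (default 20,
#'   a standard Sensory Organisation Test trial); informational, used in the
#'   verdict detail.
#' @param reference_duration_s Duration of the comparator recording, seconds,
#'   or `NULL` to skip the sync check.
#' @param max_untracked_frac Maximum tolerated fraction of frames with a core
#'   joint `not_tracked` (default 0.05).
#' @param sync_tol_s Tolerated absolute duration mismatch, seconds
#'   (default 0.5).
#' @return A `validation_verdict` with fields `status` (`"ok"`/`"excluded"`),
#'   `reason` (a code from [exclusion_reasons()]) and `detail`.
#' @export
validate_recording <- function(seq, expected_duration_s = 20,
                               reference_duration_s = NULL,
                               max_untracked_frac = 0.05,
                               sync_tol_s = 0.5) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  dur <- duration_s(seq)
  if (!is.null(reference_duration_s) && !is.na(reference_duration_s)) {
    gap <- abs(dur - reference_duration_s)
    if (gap > sync_tol_s)
      return(new_verdict("excluded", "out_of_sync",
                         sprintf("duration %.2f s vs reference %.2f s (tol %.2f s)",
                                 dur, reference_duration_s, sync_tol_s)))
  }
  n <- n_frames(seq)
  for (j in core_joints()) {
    frac <- mean(seq$state[, j] == "not_tracked")
    if (frac > max_untracked_frac)
      return(new_verdict("excluded", "malformed_skeleton",
                         sprintf("%s not_tracked in %.0f%% of %d frames (max %.0f%%)",
                                 j, 100 * frac, n, 100 * max_untracked_frac)))
  }
  new_verdict("ok", "none",
              sprintf("%d frames, %.2f s (expected %.2f s)", n, dur,
                      expected_duration_s))
}

#' Record accounting after exclusion screening
#'
#' Given exclusion verdicts for a batch of trials, `filter_counts()` returns
#' the number of records remaining for analysis, and `exclusion_table()`
#' tabulates the excluded trials by reason.
#'
#' @param verdicts A list of `validation_verdict` objects, or a character
#'   vector of reason codes (with `"none"` for retained trials).
#' @param initial_count Number of trials recorded; defaults to
#'   `length(verdicts)`.
#' @return `filter_counts()`: integer count of remaining records.
#'   `exclusion_table()`: named integer vector of exclusion counts by reason.
#' @export
filter_counts <- function(verdicts, initial_count = length(verdicts)) {
  reasons <- verdict_reasons(verdicts)
  initial_count - sum(reasons != "none")
}

#' @rdname filter_counts
#' @export
exclusion_table <- function(verdicts) {
  reasons <- verdict_reasons(verdicts)
  reasons <- reasons[reasons != "none"]
  lv <- setdiff(exclusion_reasons(), "none")
  table(factor(reasons, levels = lv))
}

verdict_reasons <- function(verdicts) {
  if (is.character(verdicts)) {
    bad <- setdiff(unique(verdicts), exclusion_reasons())
    if (length(bad)) stop("unknown reason code(s): ",
                          paste(bad, collapse = ", "))
    return(verdicts)
  }
  vapply(verdicts, function(v) v$reason, "")
}
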