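#' Construct a 2D centre-of-mass path
#'
#' A `com_path` is the common currency of the pipeline: a timestamped 2D
#' (mediolateral, anterior-posterior) trajectory in millimetres, tagged with
#' the method that produced it (`"three_joint"`, `"tbcm"` or `"pendulum"`)
#' and carrying subject/trial metadata. Sway metrics are method-agnostic on
#' this container.
#'
#' @param t Timestamps in seconds (finite, non-decreasing).
#' @param ml_mm,ap_mm Mediolateral and anterior-posterior displacement, mm.
#' @param rate_hz Sampling rate in Hz.
#' @param method One of `"three_joint"`, `"tbcm"`, `"pendulum"`.
#' @param meta Optional list of subject/trial metadata carried through.
#' @return A data frame of class `com_path` with columns `t`, `ml_mm`,
#'   `ap_mm` and attributes `rate_hz`, `method`, `meta`.
#' @export
com_path_new <- function(t, ml_mm, ap_mm, rate_hz, method, meta = list()) {
  method <- match.arg(method, c("three_joint", "tbcm", "pendulum"))
  t <- as.numeric(t); ml_mm <- as.numeric(ml_mm); ap_mm <- as.numeric(ap_mm)
  if (length(t) != length(ml_mm) || length(t) != length(ap_mm))
    stop("t, ml_mm, ap_mm must have equal length")
  if (any(!is.finite(c(t, ml_mm, ap_mm))))
    stop("com_path values must be finite")
  out <- data.frame(t = t, ml_mm = ml_mm, ap_mm = ap_mm)
  attr(out, "rate_hz") <- rate_hz
  attr(out, "method") <- method
  attr(out, "meta") <- meta
  class(out) <- c("com_path", "data.frame")
  out
}

#' @export
print.com_path <- function(x, ...) {
  cat(sprintf("<com_path> %d samples at %g Hz, method %s\n",
              nrow(x), attr(x, "rate_hz"), attr(x, "method")))
  print.data.frame(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat(sprintf("  ... %d more rows\n", nrow(x) - 4L))
  invisible(x)
}

#' Plot a CoM path as a stabilogram
#'
#' Mediolateral on the x axis, anterior-posterior on the y axis, mean
#' position marked.
#'
#' @param x A `com_path`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.com_path <- function(x, ...) {
  graphics::plot(x$ml_mm, x$ap_mm, type = "l", asp = 1,
                 xlab = "mediolateral (mm)", ylab = "anterior-posterior (mm)",
                 main = sprintf("CoM path (%s)", attr(x, "method")), ...)
  graphics::points(mean(x$ml_mm), mean(x$ap_mm), pch = 3, col = 2)
  invisible(x)
}

#' Construct a centre-of-force trace
#'
#' Force-plate centre-of-force samples in plate coordinates (mediolateral,
#' anterior-posterior, mm) at a uniform rate, with the subject's height
#' attached for the inverted-pendulum projection.
#'
#' @param ml_mm,ap_mm CoF coordinates in mm.
#' @param rate_hz Sampling rate in Hz (default 100, the plate rate).
#' @param height_cm Subject height in cm; must be positive.
#' @param t Optional explicit timestamps; defaults to `(0:(n-1))/rate_hz`.
#' @return A data frame of class `cof_trace` with columns `t`, `ml_mm`,
#'   `ap_mm` and attributes `rate_hz`, `height_cm`.
#' @export
cof_trace <- function(ml_mm, ap_mm, rate_hz = 100, height_cm, t = NULL) {
  if (rate_hz <= 0) stop("rate must be positive")
  if (missing(height_cm) || is.na(height_cm) || height_cm <= 0)
    stop("subject height (cm) must be a positive number")
  n <- length(ml_mm)
  if (length(ap_mm) != n) stop("ml_mm and ap_mm must have equal length")
  if (is.null(t)) t <- (seq_len(n) - 1) / rate_hz
  out <- data.frame(t = as.numeric(t), ml_mm = as.numeric(ml_mm),
                    ap_mm = as.numeric(ap_mm))
  attr(out, "rate_hz") <- rate_hz
  attr(out, "height_cm") <- height_cm
  class(out) <- c("cof_trace", "data.frame")
  out
}

#' @export
print.cof_trace <- function(x, ...) {
  cat(sprintf("<cof_trace> %d samples at %g Hz, subject height %g cm\n",
              nrow(x), attr(x, "rate_hz"), attr(x, "height_cm")))
  print.data.frame(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat(sprintf("  ... %d more rows\n", nrow(x) - 4L))
  invisible(x)
}
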