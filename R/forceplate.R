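#' Inverted-pendulum model parameters
#'
#' The force-plate comparator estimates the vertical projection of the CoM
#' from the centre of force under a rigid inverted-pendulum assumption: the
#' body pivots at the ankle, the CoM sits at a fixed fraction of the
#' subject's height (default 0.5527), and quiet standing carries an average
#' anterior lean (default -2.3 degrees) which is removed as a static offset
#' on the anterior-posterior axis.
#'
#' @param height_cm Subject height, cm (> 0).
#' @param com_height_fraction CoM height as a fraction of stature, in (0, 1).
#' @param static_lean_deg Average anterior lean, degrees; |lean| < 30.
#' @return A list of class `pendulum_params`.
#' @export
pendulum_params <- function(height_cm, com_height_fraction = 0.5527,
                            static_lean_deg = -2.3) {
  if (is.na(height_cm) || height_cm <= 0)
    stop("subject height (cm) must be positive")
  if (com_height_fraction <= 0 || com_height_fraction >= 1)
    stop("com_height_fraction must lie strictly between 0 and 1")
  if (abs(static_lean_deg) >= 30)
    stop("|static_lean_deg| must be below 30 degrees")
  structure(list(height_cm = height_cm,
                 com_height_fraction = com_height_fraction,
                 static_lean_deg = static_lean_deg),
            class = "pendulum_params")
}

#' Pendulum CoM height
#'
#' Height of the modelled CoM above the ankle pivot: the model fraction times
#' the subject's stature.
#'
#' @param height_cm Subject height, cm.
#' @param com_height_fraction Fraction of stature (default 0.5527).
#' @return CoM height in cm.
#' @export
#' @examples
#' com_height(172) # 95.0644 cm
com_height <- function(height_cm, com_height_fraction = 0.5527) {
  if (any(height_cm <= 0)) stop("height must be positive")
  com_height_fraction * height_cm
}

#' Project a centre-of-force trace to a CoM path
#'
#' Implements the comparator's rigid inverted-pendulum geometry. With
#' `c` the pendulum CoM height (mm) and lean angle `phi`:
#' the anterior-posterior CoF is first corrected for the modelled static
#' anterior lean, `a' = a_AP - c * tan(phi)`; the sway angles are
#' `theta_AP = atan(a'/c)` and `theta_ML = atan(a_ML/c)` (no lean correction
#' mediolaterally); and the horizontal CoM displacement is `c * tan(theta)`
#' — under this rigid model, exactly the lean-corrected CoF. Because sway
#' metrics de-mean the path, any constant-offset convention here yields
#' identical sway.
#'
#' @param trace A [cof_trace()] (mm, with subject height attached).
#' @param params A [pendulum_params()]; defaults to the trace's height with
#'   standard fraction and lean.
#' @return A `com_path` (mm) at the trace's rate, method tag `"pendulum"`.
#' @export
cof_to_com <- function(trace, params = NULL) {
  stopifnot(inherits(trace, "cof_trace"))
  if (is.null(params)) params <- pendulum_params(attr(trace, "height_cm"))
  c_mm <- 10 * com_height(params$height_cm, params$com_height_fraction)
  lean_mm <- c_mm * tan(params$static_lean_deg * pi / 180)
  theta_ap <- atan((trace$ap_mm - lean_mm) / c_mm)
  theta_ml <- atan(trace$ml_mm / c_mm)
  com_path_new(trace$t,
               ml_mm = c_mm * tan(theta_ml),
               ap_mm = c_mm * tan(theta_ap),
               rate_hz = attr(trace, "rate_hz"), method = "pendulum",
               meta = list(height_cm = params$height_cm))
}

#' Forward pendulum model: CoM path to centre of force
#'
#' Exact inverse of [cof_to_com()], used by the simulator to synthesise what
#' the plate would record for a known CoM trajectory: the static-lean offset
#' is added back on the anterior-posterior axis.
#'
#' @param path A `com_path` (mm).
#' @param params A [pendulum_params()].
#' @return A [cof_trace()] at the path's rate.
#' @export
com_to_cof <- function(path, params) {
  stopifnot(inherits(path, "com_path"), inherits(params, "pendulum_params"))
  c_mm <- 10 * com_height(params$height_cm, params$com_height_fraction)
  lean_mm <- c_mm * tan(params$static_lean_deg * pi / 180)
  cof_trace(ml_mm = path$ml_mm, ap_mm = path$ap_mm + lean_mm,
            rate_hz = attr(path, "rate_hz"),
            height_cm = params$height_cm, t = path$t)
}
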