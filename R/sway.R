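#' Resultant-distance time series
#'
#' Places the mean position of the whole movement at the origin and returns,
#' per sample, the euclidean distance from it:
#' `RD_i = sqrt((ML_i - mean(ML))^2 + (AP_i - mean(AP))^2)`.
#' Precise foot placement differs between trials and methods, so sway is
#' always computed on this de-meaned series, making it invariant to constant
#' offsets of the path.
#'
#' @param path A `com_path` (mm) with at least 2 samples, or a data frame
#'   with `ml_mm` and `ap_mm` columns.
#' @return Numeric vector of resultant distances, mm, same length as the
#'   path.
#' @export
resultant_distance <- function(path) {
  if (nrow(path) < 2L)
    stop("resultant distance needs at least 2 samples")
  sqrt((path$ml_mm - mean(path$ml_mm))^2 + (path$ap_mm - mean(path$ap_mm))^2)
}

#' RMS sway of a resultant-distance series
#'
#' `sqrt(sum(RD^2) / N)`: the root-mean-square deviation from the mean
#' position. Note the population (1/N) normalisation; equivalently,
#' `sway_rms` equals `sqrt(popvar(ML) + popvar(AP))` of the source path.
#'
#' @param rd Non-empty numeric vector of resultant distances (mm).
#' @return RMS sway in mm.
#' @export
sway_rms <- function(rd) {
  if (!length(rd)) stop("empty resultant-distance series")
  sqrt(sum(rd^2) / length(rd))
}

#' Sway metrics for one CoM path
#'
#' Computes the resultant-distance series and RMS sway for a single trial /
#' method. With `extras = TRUE`, additional stabilometric summaries are
#' attached (sway path length, mean velocity, and the 95% prediction-ellipse
#' area); these are supplementary and not part of the core agreement surface.
#'
#' @param path A `com_path` (mm).
#' @param extras Also compute supplementary stabilometric metrics.
#' @return An object of class `sway_result`: list with `rd` (mm),
#'   `sway_rms_mm`, `n`, `method`, `meta`, and optionally `extras`.
#' @export
sway <- function(path, extras = FALSE) {
  rd <- resultant_distance(path)
  out <- list(rd = rd, sway_rms_mm = sway_rms(rd), n = length(rd),
              method = attr(path, "method"), meta = attr(path, "meta"))
  if (extras) {
    dml <- diff(path$ml_mm); dap <- diff(path$ap_mm)
    plen <- sum(sqrt(dml^2 + dap^2))
    dur <- path$t[nrow(path)] - path$t[1]
    v <- stats::cov(cbind(path$ml_mm, path$ap_mm))
    out$extras <- list(
      path_length_mm = plen,
      mean_velocity_mm_s = plen / dur,
      ellipse_area_95_mm2 = pi * stats::qchisq(0.95, 2) *
        sqrt(max(det(v), 0)))
  }
  class(out) <- "sway_result"
  out
}

#' @export
print.sway_result <- function(x, ...) {
  cat(sprintf("<sway_result> method %s: sway RMS %.3f mm over %d samples\n",
              x$method, x$sway_rms_mm, x$n))
  if (!is.null(x$extras))
    cat(sprintf("  path length %.1f mm, mean velocity %.2f mm/s, 95%% ellipse %.1f mm^2\n",
                x$extras$path_length_mm, x$extras$mean_velocity_mm_s,
                x$extras$ellipse_area_95_mm2))
  invisible(x)
}
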