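#' Kinetic curve classes for contrast enhancement
#'
#' DCE-MRI lesions are conventionally described by the shape of their
#' signal-enhancement curve after contrast injection: *persistent* uptake
#' (still rising at the end of the acquisition, typical of benign lesions),
#' *plateau* (rises then levels off), and *washout* (peaks early and then
#' loses signal, the classic malignant pattern). The phantom generator uses
#' these classes to give lesions a contrast-uptake time course that the
#' fuzzy c-means segmenter can exploit.
#'
#' @param name one of `"persistent"`, `"plateau"`, `"washout"`.
#' @param peak_enhancement relative enhancement at the curve peak, as a
#'   fraction of the precontrast signal (>= 0). Defaults per class: 0.8
#'   (persistent), 1.0 (plateau), 1.2 (washout).
#' @param time_to_peak seconds from injection to the curve peak (> 0).
#'   Defaults: 300 s (persistent, i.e. beyond a typical acquisition window),
#'   120 s (plateau), 150 s (washout).
#' @param washout_fraction for washout curves, the fraction of the peak lost
#'   per `time_to_peak` seconds after the peak (default 0.3).
#' @return an object of class `kinetic_class`.
#' @examples
#' kc <- kinetic_class("washout")
#' enhancement_curve(kc, c(0, 75, 150, 225))
#' @export
kinetic_class <- function(name = c("persistent", "plateau", "washout"),
                          peak_enhancement = NULL, time_to_peak = NULL,
                          washout_fraction = 0.3) {
  name <- match.arg(name)
  defaults <- list(
    persistent = list(peak = 0.8, ttp = 300),
    plateau    = list(peak = 1.0, ttp = 120),
    washout    = list(peak = 1.2, ttp = 150)
  )[[name]]
  peak <- peak_enhancement %||% defaults$peak
  ttp <- time_to_peak %||% defaults$ttp
  if (peak < 0) stop_dceseg("peak_enhancement must be >= 0", "dceseg_value_error")
  if (ttp <= 0) stop_dceseg("time_to_peak must be > 0", "dceseg_value_error")
  structure(list(name = name, peak_enhancement = peak, time_to_peak = ttp,
                 washout_fraction = washout_fraction),
            class = "kinetic_class")
}

#' Evaluate a relative-enhancement curve at acquisition timepoints
#'
#' Relative enhancement e(t) = (S(t) - S(0)) / S(0) for a voxel following the
#' given kinetic class: linear uptake to `peak_enhancement` at `time_to_peak`,
#' then class-specific behaviour (persistent/plateau stay at or below the
#' peak without declining; washout declines by `washout_fraction` of the peak
#' per `time_to_peak` seconds).
#'
#' @param kinetic a [kinetic_class()] object.
#' @param timepoints_s acquisition times in seconds; the first must be 0 (the
#'   precontrast acquisition) and times must be strictly increasing. At least
#'   3 timepoints (one precontrast + two postcontrast) are required.
#' @return numeric vector of relative enhancement fractions, one per
#'   timepoint; the value at t = 0 is exactly 0.
#' @export
enhancement_curve <- function(kinetic, timepoints_s) {
  stopifnot(inherits(kinetic, "kinetic_class"))
  if (length(timepoints_s) < 3L)
    stop_dceseg("a DCE protocol needs >= 3 timepoints (1 precontrast + >= 2 postcontrast)",
                "dceseg_invalid_protocol")
  if (timepoints_s[1] != 0 || any(diff(timepoints_s) <= 0))
    stop_dceseg("timepoints must start at 0 and be strictly increasing",
                "dceseg_invalid_protocol")
  t <- timepoints_s
  peak <- kinetic$peak_enhancement
  ttp <- kinetic$time_to_peak
  e <- peak * pmin(t / ttp, 1)
  if (kinetic$name == "washout") {
    after <- t > ttp
    e[after] <- peak * pmax(0, 1 - kinetic$washout_fraction * (t[after] - ttp) / ttp)
  }
  e[1] <- 0
  e
}

#' @export
print.kinetic_class <- function(x, ...) {
  cat(sprintf("<kinetic_class> %s: peak enhancement %.2f at %.0f s\n",
              x$name, x$peak_enhancement, x$time_to_peak))
  invisible(x)
}

# Default pathology -> kinetic class mapping used by the cohort generator:
# benign lesions enhance persistently, malignant lesions wash out.
default_kinetic_for <- function(pathology) {
  switch(pathology,
         benign = kinetic_class("persistent"),
         malignant = kinetic_class("washout"),
         kinetic_class("plateau"))
}
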