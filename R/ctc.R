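## Spike-in standard curve: OLS of luminescence on spiked cell count
## (classical calibration), then algebraic inversion of readings into
## circulating-tumor-cell counts per ml.

#' Fit a spike-in luminescence calibration line
#'
#' Ordinary least squares of luminescence on cell count. With
#' `zeroIntercept = TRUE` the line is forced through the origin.
#'
#' @param counts spiked cell counts (>= 3 points, non-negative, not all
#'   equal).
#' @param luminescence measured luminescence, parallel to `counts`.
#' @param zeroIntercept force the intercept to zero (default `FALSE`).
#' @return A [CalibrationFit-class] object.
#' @examples
#' fitCalibration(c(12, 37, 111, 333, 1000),
#'                1 + 2 * c(12, 37, 111, 333, 1000))
#' @export
fitCalibration <- function(counts, luminescence, zeroIntercept = FALSE) {
  if (length(counts) != length(luminescence))
    stop("counts and luminescence must have the same length")
  if (length(counts) < 3) stop("need >= 3 calibration points")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (var(counts) == 0) stop("counts must not all be equal")
  fit <- if (zeroIntercept) lm(luminescence ~ 0 + counts)
         else lm(luminescence ~ counts)
  cf <- coef(fit)
  slope <- unname(if (zeroIntercept) cf[1] else cf[2])
  intercept <- if (zeroIntercept) 0 else unname(cf[1])
  sm <- suppressWarnings(summary(fit))  # collinear designs are legitimate here
  new("CalibrationFit", slope = slope, intercept = intercept,
      r.squared = min(1, max(0, sm$r.squared)), sigma = sm$sigma,
      counts = as.numeric(counts))
}

#' Invert luminescence readings into CTC counts per ml
#'
#' Inverts the calibration line: `cells = (reading - intercept) / slope`,
#' clamped at zero (readings at or below the intercept — e.g. blanks — give
#' zero cells with the `clamped` flag set), then normalized by the sample
#' volume.
#'
#' @param readings numeric vector of luminescence readings.
#' @param fit a [CalibrationFit-class] from [fitCalibration()]; its slope
#'   must be positive.
#' @param sampleVolumeMl blood sample volume in ml (default 0.4, i.e.
#'   400 ul).
#' @return A `data.frame` with one row per reading: `reading`, `cells`,
#'   `cellsPerMl`, `clamped`.
#' @export
estimateCtc <- function(readings, fit, sampleVolumeMl = 0.4) {
  if (fit@slope <= 0) stop("calibration slope must be positive")
  if (sampleVolumeMl <= 0) stop("sample volume must be positive")
  cells_raw <- (readings - fit@intercept) / fit@slope
  clamped <- cells_raw < 0
  cells <- pmax(cells_raw, 0)
  data.frame(reading = readings, cells = cells,
             cellsPerMl = cells / sampleVolumeMl, clamped = clamped)
}
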