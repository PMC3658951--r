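# Curve Adjustment (CA): the position-reweighting comparator. The mean PM
# intensity per position inside a window is lowess-smoothed, normalised to
# unit mean over the window, and its reciprocal is used as a multiplicative
# weight for probes at that position. Unlike the model-based correction it
# uses no generative model and no noise-amplification floor.

#' Position weights for Curve Adjustment
#'
#' Computes the CA weight table: mean PM per (integer) position inside
#' \code{window}, lowess smooth, normalisation of the smoothed values to mean
#' 1 over the window, and reciprocal weights.
#'
#' @param probes long probe table or [ProbeIntensitySet-class]; when a
#'   \code{present} column exists only present-flagged rows are used.
#' @param window position window in bp from the 3' end, default c(12, 588).
#' @param lowessFraction lowess smoother span, default 0.3.
#' @return data.frame with columns \code{z}, \code{mean_pm},
#'   \code{smoothed}, \code{normalized}, \code{weight}.
#' @export
computePositionWeights <- function(probes, window = c(12, 588),
                                   lowessFraction = 0.3) {
  if (is(probes, "ProbeIntensitySet")) probes <- longFormat(probes)
  probes <- .checkProbeColumns(probes)
  if (!is.null(probes$present)) probes <- probes[probes$present > 0, ]
  zr <- round(probes$z)
  keep <- zr >= window[1] & zr <= window[2]
  if (!any(keep)) stop("no probes inside the position window [",
                       window[1], ", ", window[2], "]")
  prof <- tapply(probes$pm[keep], zr[keep], mean)
  z <- as.numeric(names(prof))
  meanPm <- as.numeric(prof)
  lo <- lowess(z, meanPm, f = lowessFraction)
  smoothed <- approx(lo$x, lo$y, xout = z, rule = 2)$y
  normalized <- smoothed / mean(smoothed)
  if (any(normalized <= 0))
    stop("non-positive smoothed intensity: weights undefined")
  data.frame(z = z, mean_pm = meanPm, smoothed = smoothed,
             normalized = normalized, weight = 1 / normalized)
}

#' Apply Curve Adjustment weights to a probe table
#'
#' Multiplies each probe's PM by the weight of the nearest tabulated
#' position. Probes outside the weight table's position range pass through
#' unweighted with \code{flag = "outside_window"}.
#'
#' @param probes long probe table or [ProbeIntensitySet-class].
#' @param weights a weight table from [computePositionWeights()].
#' @return the long table with added columns \code{weight}, \code{pm_adj}
#'   and \code{flag}.
#' @export
applyCurveAdjustment <- function(probes, weights) {
  if (is(probes, "ProbeIntensitySet")) probes <- longFormat(probes)
  probes <- .checkProbeColumns(probes)
  stopifnot(all(c("z", "weight") %in% names(weights)))
  o <- order(weights$z)
  zs <- weights$z[o]
  ws <- weights$weight[o]
  rng <- range(zs)
  inWin <- probes$z >= rng[1] & probes$z <= rng[2]
  # nearest tabulated position (ties resolved toward the lower position)
  idx <- findInterval(probes$z, zs[-1] - diff(zs) / 2) + 1L
  w <- ifelse(inWin, ws[idx], 1)
  out <- probes
  out$weight <- w
  out$pm_adj <- probes$pm * w
  out$flag <- ifelse(inWin, "ok", "outside_window")
  out
}
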