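# Probe-level bias correction.
#
# Observed PM intensities follow the linear model
#   IP_ijk = IPS_jk * p_j(z_ik) + eps_ijk,   eps_ijk ~ N(0, sigma_jk^2),
# so for a probe set the least-squares estimator of the ideal intensity,
#   IPS = sum_i IP_i p_i / sum_i p_i^2,
# is the maximum-likelihood estimator. Correction happens on the linear
# intensity scale; IPS is estimated per probe set per sample.

#' Maximum-likelihood estimate of the ideal probe-set intensity
#'
#' Closed-form MLE (equivalently ordinary least squares through the origin)
#' of IPS in the linear degradation model, with the root-mean-square residual
#' as scale estimate. Negative estimates are clamped to 0 and flagged.
#'
#' @param pm observed PM intensities of one probe set (>= 1 probe).
#' @param p matching retaining rates p_j(z_i).
#' @return list with elements \code{ips}, \code{residualScale} and
#'   \code{flag} (\code{"ok"} or \code{"clamped_negative"}).
#' @examples
#' estimateIps(c(10, 5), c(1, 0.5))$ips  # 10
#' @export
estimateIps <- function(pm, p) {
  stopifnot(length(pm) == length(p), length(pm) >= 1,
            all(is.finite(pm)), all(is.finite(p)))
  ips <- sum(pm * p) / sum(p^2)
  flag <- "ok"
  if (ips < 0) {
    ips <- 0
    flag <- "clamped_negative"
  }
  list(ips = ips,
       residualScale = sqrt(mean((pm - ips * p)^2)),
       flag = flag)
}

#' Bias-correct probe-level intensities
#'
#' Adjusts PM (and MM, when present) intensities of every probe set in every
#' sample using a retaining-rate curve. Two modes:
#' \describe{
#'   \item{\code{mle-residual} (default)}{adjusted PM_i = IPS + (PM_i -
#'     IPS * p_i): the lost expected signal is restored while the noise term
#'     is left unscaled, so small retaining rates do not amplify noise.}
#'   \item{\code{invert}}{adjusted PM_i = PM_i / max(p_i, pFloor): direct
#'     inversion of the noise-free model; the floor bounds noise
#'     amplification where p_i is tiny.}
#' }
#' Probe sets whose retaining rates are all at or below \code{pFloor} are
#' passed through unadjusted (\code{flag = "uncorrectable"}); sets with fewer
#' than 3 probes above the floor are passed through with
#' \code{flag = "low_p_passthrough"}. Negative mle-residual values are
#' clamped to 0 (\code{flag = "clamped_negative"} on the affected rows).
#'
#' @param probes long probe table (columns sample_id, probeset_id, probe_id,
#'   z, pm; optional mm) or a [ProbeIntensitySet-class].
#' @param curve a [RetainingRateCurve-class] covering all probe positions.
#' @param mode \code{"mle-residual"} or \code{"invert"}.
#' @param pFloor lower bound applied to retaining rates (default 0.05).
#' @return the long table with added columns \code{p_retain}, \code{ips},
#'   \code{pm_adj} (and \code{mm_adj}), and \code{flag}; untouched columns
#'   are returned bit-exact. Attribute \code{mode} records the mode.
#' @examples
#' sim <- generateProbeData(syntheticSpec(nProbeSets = 10, seed = 1))
#' crv <- retainingRateCurve(degradationParams(1000, 300, 200), cycle = 2,
#'                           gridStep = 25, quadStep = 5)
#' head(adjustProbes(sim$probes, crv))
#' @export
adjustProbes <- function(probes, curve, mode = c("mle-residual", "invert"),
                         pFloor = 0.05) {
  if (is(probes, "ProbeIntensitySet")) probes <- longFormat(probes)
  probes <- .checkProbeColumns(probes)
  mode <- match.arg(mode)
  stopifnot(is(curve, "RetainingRateCurve"))
  p <- retainingRate(curve, probes$z)
  grp <- factor(paste(probes$sample_id, probes$probeset_id, sep = "\r"))
  gi <- as.integer(grp)
  nAbove <- rowsum(as.numeric(p > pFloor), gi)[, 1]
  sumPmP <- rowsum(probes$pm * p, gi)[, 1]
  sumP2 <- rowsum(p^2, gi)[, 1]
  ips <- sumPmP / sumP2
  ipsClamped <- ips < 0
  ips[ipsClamped] <- 0
  gFlag <- ifelse(nAbove == 0, "uncorrectable",
                  ifelse(nAbove < 3, "low_p_passthrough", "ok"))
  out <- probes
  out$p_retain <- p
  out$ips <- ips[gi]
  adjustOne <- function(x) {
    if (mode == "invert") x / pmax(p, pFloor)
    else out$ips + (x - out$ips * p)
  }
  pmAdj <- adjustOne(probes$pm)
  mmAdj <- if (!is.null(probes$mm)) adjustOne(probes$mm) else NULL
  flag <- gFlag[gi]
  flag[gFlag[gi] == "ok" & ipsClamped[gi]] <- "ips_clamped"
  pass <- gFlag[gi] != "ok"
  pmAdj[pass] <- probes$pm[pass]
  if (!is.null(mmAdj)) mmAdj[pass] <- probes$mm[pass]
  neg <- !pass & pmAdj < 0
  pmAdj[neg] <- 0
  flag[neg] <- "clamped_negative"
  if (!is.null(mmAdj)) mmAdj[mmAdj < 0] <- 0
  out$pm_adj <- pmAdj
  if (!is.null(mmAdj)) out$mm_adj <- mmAdj
  out$flag <- flag
  attr(out, "mode") <- mode
  out
}

#' Fit global degradation limits (a, b) from probe intensities
#'
#' The degradation model leaves (a, b) free; this routine estimates them from
#' the data by profile matching: the mean PM intensity at each (integer)
#' position inside \code{window}, normalised to unit mean, is compared with
#' c * p2(z) for every candidate (a, b) on a search grid, c being the
#' least-squares scale, and the candidate minimising the sum of squared
#' differences is returned. Deterministic; ties broken toward smaller a,
#' then smaller b. When the table has a \code{present} column, only
#' present-flagged rows enter the profile.
#'
#' @param probes long probe table or [ProbeIntensitySet-class].
#' @param L transcript length (bp) assumed for the model (default 1000, or
#'   the table's \code{L} column maximum when present).
#' @param aGrid,bGrid candidate degradation limits (bp).
#' @param window positions (bp from the 3' end) used for the profile,
#'   default c(12, 577).
#' @param quadStep quadrature step for the candidate p2 curves (default 2).
#' @param curveStep tabulation step for candidate curves (default 10).
#' @return list with \code{params} (the fitted [DegradationParams-class]),
#'   \code{scale} (the least-squares c), \code{sse} (data.frame of the full
#'   grid search) and \code{profile} (the normalised position profile).
#' @export
fitDegradationLimits <- function(probes, L = NULL,
                                 aGrid = seq(150, 450, by = 50),
                                 bGrid = seq(100, 300, by = 50),
                                 window = c(12, 577),
                                 quadStep = 2, curveStep = 10) {
  if (is(probes, "ProbeIntensitySet")) probes <- longFormat(probes)
  probes <- .checkProbeColumns(probes)
  if (is.null(L)) L <- if (!is.null(probes$L)) max(probes$L) else 1000
  if (!is.null(probes$present)) probes <- probes[probes$present > 0, ]
  zr <- round(probes$z)
  keep <- zr >= window[1] & zr <= window[2]
  if (!any(keep)) stop("no probes inside the position window [",
                       window[1], ", ", window[2], "]")
  prof <- tapply(probes$pm[keep], zr[keep], mean)
  zpos <- as.numeric(names(prof))
  prof <- as.numeric(prof)
  if (sd(prof) == 0) stop("flat mean-intensity profile: degradation limits ",
                          "are not identifiable")
  prof <- prof / mean(prof)
  grid <- expand.grid(a = aGrid, b = bGrid)
  grid <- grid[order(grid$a, grid$b), ]   # tie-break: smaller a, then b
  sse <- scale <- numeric(nrow(grid))
  zgrid <- seq(0, L, by = curveStep)
  if (zgrid[length(zgrid)] < L) zgrid <- c(zgrid, L)
  for (i in seq_len(nrow(grid))) {
    a <- grid$a[i]; b <- grid$b[i]
    if (a + b >= L) { sse[i] <- Inf; next }
    pg <- .p2Quadrature(zgrid, new("DegradationParams", L = L, a = a, b = b),
                        quadStep)
    pv <- approx(zgrid, pg, xout = zpos)$y
    cc <- sum(prof * pv) / sum(pv^2)
    scale[i] <- cc
    sse[i] <- sum((prof - cc * pv)^2)
  }
  best <- which.min(sse)   # first minimum in (a, b) order: documented tie-break
  list(params = degradationParams(L, grid$a[best], grid$b[best]),
       scale = scale[best],
       sse = data.frame(a = grid$a, b = grid$b, sse = sse, scale = scale),
       profile = data.frame(z = zpos, mean_pm_norm = prof))
}
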