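# Synthetic probe-level data with the statistical structure the degradation
# model assumes: PM_i = IPS_k * p_cycle(z_i) + eps_i, truncated at zero.
# The generator is first-class: every downstream module is validated against
# data whose ground truth is known.

#' Specification of a synthetic probe-level dataset
#'
#' Defaults emulate a two-cycle Affymetrix-style experiment: 11-probe sets,
#' probe positions uniform on [12, 600] bp from the 3' end (rounded to
#' integer bp), fixed transcript length 1000 bp, log-normal true intensities
#' (log2 mean 8, sd 1.5), degradation limits a = 300, b = 200, and Gaussian
#' probe noise with sd = noiseFrac x IPS per probe set (the literal linear
#' model; set \code{noiseModel = "proportional"} for sd proportional to each
#' probe's expected signal instead).
#'
#' @param nProbeSets number of probe sets.
#' @param probesPerSet probes per probe set (default 11).
#' @param transcriptLength transcript length L in bp (default 1000).
#' @param positionRange probe-position range in bp from the 3' end,
#'   default c(12, 600).
#' @param log2Mean,log2Sd log2-scale mean and sd of the true intensities.
#' @param params a [DegradationParams-class] (default L = 1000, a = 300,
#'   b = 200).
#' @param noiseFrac noise scale as a fraction of IPS (default 0.1).
#' @param noiseModel \code{"constant"} (sd = noiseFrac x IPS within a probe
#'   set) or \code{"proportional"} (sd = noiseFrac x IPS x p(z_i)).
#' @param nSamples number of samples (independent noise, shared truth).
#' @param seed RNG seed.
#' @return a list of class \code{"syntheticSpec"}.
#' @export
syntheticSpec <- function(nProbeSets = 20000, probesPerSet = 11,
                          transcriptLength = 1000,
                          positionRange = c(12, 600),
                          log2Mean = 8, log2Sd = 1.5,
                          params = degradationParams(transcriptLength, 300, 200),
                          noiseFrac = 0.1,
                          noiseModel = c("constant", "proportional"),
                          nSamples = 1, seed = 1L) {
  noiseModel <- match.arg(noiseModel)
  stopifnot(nProbeSets >= 1, probesPerSet >= 1, noiseFrac >= 0, nSamples >= 1,
            is(params, "DegradationParams"),
            positionRange[1] >= 0,
            positionRange[2] <= transcriptLength,
            transcriptLength == params@L)
  structure(list(nProbeSets = nProbeSets, probesPerSet = probesPerSet,
                 transcriptLength = transcriptLength,
                 positionRange = positionRange, log2Mean = log2Mean,
                 log2Sd = log2Sd, params = params, noiseFrac = noiseFrac,
                 noiseModel = noiseModel, nSamples = nSamples,
                 seed = as.integer(seed)),
            class = "syntheticSpec")
}

# shared machinery: given per-set IPS matrix (sets x samples), positions and
# a curve, emit the long probe table and the ground-truth table
.emitProbeData <- function(spec, ips, z, p, sampleIds) {
  ns <- spec$nProbeSets; np <- spec$probesPerSet
  setId <- sprintf("ps%05d", seq_len(ns))
  probeId <- paste0("p", seq_len(np))
  probes <- NULL
  for (s in seq_along(sampleIds)) {
    ipsRep <- rep(ips[, s], each = np)
    sdNoise <- if (spec$noiseModel == "constant") spec$noiseFrac * ipsRep
               else spec$noiseFrac * ipsRep * as.vector(t(p))
    pm <- ipsRep * as.vector(t(p)) + rnorm(ns * np, 0, sdNoise)
    truncated <- pm < 0
    pm[truncated] <- 0
    df <- data.frame(sample_id = sampleIds[s],
                     probeset_id = rep(setId, each = np),
                     probe_id = rep(probeId, ns),
                     z = as.vector(t(z)),
                     pm = pm,
                     present = 1L,
                     L = spec$transcriptLength,
                     truncated = as.integer(truncated),
                     stringsAsFactors = FALSE)
    probes <- if (is.null(probes)) df else rbind(probes, df)
  }
  truth <- data.frame(sample_id = rep(sampleIds, each = ns * np),
                      probeset_id = rep(rep(setId, each = np),
                                        length(sampleIds)),
                      probe_id = rep(rep(probeId, ns), length(sampleIds)),
                      z = rep(as.vector(t(z)), length(sampleIds)),
                      p_true = rep(as.vector(t(p)), length(sampleIds)),
                      ips_true = as.vector(apply(ips, 2, rep, each = np)),
                      stringsAsFactors = FALSE)
  list(probes = probes, truth = truth)
}

#' Generate a synthetic probe-level dataset
#'
#' Draws probe positions and true intensities per the spec, computes the
#' cycle-specific retaining rate at each position, and emits observed PM
#' intensities under the linear degradation model. Deterministic given the
#' spec's seed.
#'
#' @param spec a [syntheticSpec()].
#' @param cycle amplification cycle whose retaining-rate curve biases the
#'   data (default 2).
#' @param curve optional precomputed [RetainingRateCurve-class] (must match
#'   the spec's params and cycle); computed by quadrature when NULL.
#' @return list with \code{probes} (long probe table: sample_id,
#'   probeset_id, probe_id, z, pm, present, L, truncated), \code{truth}
#'   (per-probe ground truth: p_true, ips_true) and \code{curve}.
#' @examples
#' sim <- generateProbeData(syntheticSpec(nProbeSets = 3, seed = 42))
#' head(sim$probes)
#' @export
generateProbeData <- function(spec, cycle = 2L, curve = NULL) {
  stopifnot(inherits(spec, "syntheticSpec"))
  if (is.null(curve))
    curve <- retainingRateCurve(spec$params, cycle = cycle, gridStep = 2)
  stopifnot(curveCycle(curve) == cycle)
  .withSeed(spec$seed, {
    ns <- spec$nProbeSets; np <- spec$probesPerSet
    z <- matrix(round(runif(ns * np, spec$positionRange[1],
                            spec$positionRange[2])), ns, np)
    ips <- matrix(rep(2^rnorm(ns, spec$log2Mean, spec$log2Sd),
                      spec$nSamples), ns, spec$nSamples)
    p <- matrix(retainingRate(curve, as.vector(z)), ns, np)
    out <- .emitProbeData(spec, ips, z, p,
                          sprintf("s%02d", seq_len(spec$nSamples)))
    out$curve <- curve
    out
  })
}

#' Generate replicate groups for clustering/correlation fixtures
#'
#' Emulates a multi-stage design: all groups share one base IPS vector,
#' each group multiplies it by its own log-normal per-probe-set effect, and
#' replicates within a group differ by measurement noise only.
#'
#' @param spec a [syntheticSpec()]; \code{nSamples} is ignored.
#' @param nGroups number of groups (>= 2).
#' @param repsPerGroup replicates per group (default 3).
#' @param groupEffectSd log2-scale sd of the per-probe-set group effect
#'   (default 1; 0 makes all groups share identical truth).
#' @param cycle,curve as in [generateProbeData()].
#' @return list with \code{probes}, \code{truth}, \code{curve} and
#'   \code{groups} (data.frame sample_id, group). Sample ids are
#'   \code{g<g>_r<r>}.
#' @export
generateReplicateGroups <- function(spec, nGroups, repsPerGroup = 3,
                                    groupEffectSd = 1, cycle = 2L,
                                    curve = NULL) {
  stopifnot(inherits(spec, "syntheticSpec"), nGroups >= 2, repsPerGroup >= 1)
  if (is.null(curve))
    curve <- retainingRateCurve(spec$params, cycle = cycle, gridStep = 2)
  .withSeed(spec$seed, {
    ns <- spec$nProbeSets; np <- spec$probesPerSet
    z <- matrix(round(runif(ns * np, spec$positionRange[1],
                            spec$positionRange[2])), ns, np)
    base <- 2^rnorm(ns, spec$log2Mean, spec$log2Sd)
    effects <- matrix(2^rnorm(ns * nGroups, 0, groupEffectSd), ns, nGroups)
    grp <- rep(seq_len(nGroups), each = repsPerGroup)
    ips <- base * effects[, grp]    # sets x samples
    sampleIds <- sprintf("g%d_r%d", grp,
                         rep(seq_len(repsPerGroup), nGroups))
    p <- matrix(retainingRate(curve, as.vector(z)), ns, np)
    specN <- spec; specN$nSamples <- length(sampleIds)
    out <- .emitProbeData(specN, ips, z, p, sampleIds)
    out$curve <- curve
    out$groups <- data.frame(sample_id = sampleIds, group = grp,
                             stringsAsFactors = FALSE)
    out
  })
}
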