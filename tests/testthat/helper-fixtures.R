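# Shared fixtures: the reference parameter set (L = 1000, a = 300, b = 200),
# its cycle-1/2 retaining-rate curves, and a small synthetic dataset.
# Everything is built in code; nothing is read from disk.

fixtureParams <- degradationParams(1000, 300, 200)
fixtureCurve1 <- retainingRateCurve(fixtureParams, cycle = 1, gridStep = 5)
fixtureCurve2 <- retainingRateCurve(fixtureParams, cycle = 2, gridStep = 5,
                                    quadStep = 2)

smallSim <- generateProbeData(syntheticSpec(nProbeSets = 400, seed = 7),
                              curve = fixtureCurve2)

# independent piecewise implementation of the cycle-1 retaining rate,
# used as the closed-form oracle
p1Oracle <- function(z, L, a, b) {
  ifelse(z <= a, z / a, ifelse(z < L - b, 1, (L - z) / b))
}

# tiny long probe table builder
makeProbeTable <- function(z, pm, probeset = "ps1", sample = "s1",
                           mm = NULL) {
  df <- data.frame(sample_id = sample, probeset_id = probeset,
                   probe_id = paste0("p", seq_along(z)), z = z, pm = pm,
                   stringsAsFactors = FALSE)
  if (!is.null(mm)) df$mm <- mm
  df
}
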