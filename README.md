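# ivtBias

Probe-level correction of RNA degradation bias in two-cycle amplification
microarray data.

## The problem

Small-input samples (nanograms of total RNA) need the **two-cycle IVT
labeling protocol** before Affymetrix-style hybridization: two rounds of
reverse transcription and T7 in vitro transcription. Each long IVT
incubation degrades the RNA from both ends, and the random-primed
first-strand synthesis of the second cycle truncates products anywhere
along the molecule. The result is a strong positional bias: probes near the
5' end — and probes *very* close to the 3' terminus — systematically
under-report. Expression summaries, sample correlations and clusterings all
inherit the bias.

`ivtBias` is for analysts working with two-cycle (or otherwise
amplification-biased) probe-level intensity data who want the bias removed
*before* standard preprocessing (PDNN, RMA, dChip, ...) runs.

## The model

A transcript occupies positions [0, L] bp, z measured from the 3' end.
Three shortenings act on the endpoints (A, B), with degradation limits
a (3') and b (5'):

1. cycle-1 IVT: A₁ ~ U[0, a], B₁ ~ U[L−b, L]
2. random priming: A₂ = A₁, B₂ ~ U[A₁, B₁]
3. cycle-2 IVT: A₃ ~ A₂ + U[0, a], B₃ ~ B₂ − U[0, b]

The **retaining rate** p_j(z) = P(A ≤ z ≤ B after cycle j) is the
probability that position z survives. p₁ is piecewise linear
(z/a, then 1, then (L−z)/b); p₂ is built by deterministic quadrature and
cross-validated against a Monte-Carlo trajectory oracle. Observed
intensities follow IP_i = IPS · p(z_i) + ε, ε ~ N(0, σ²), so the
maximum-likelihood ideal intensity is the closed form

    IPS = Σᵢ IPᵢ p(zᵢ) / Σᵢ p²(zᵢ)

and probes are corrected either by restoring the lost expected signal
(`mle-residual`, default) or by floored inversion (`invert`). A
reciprocal-weight "Curve Adjustment" baseline, qPCR degradation-proportion
statistics (R = 2^−ΔCT, DP = 1 − R/max R), evaluation utilities (CV +
Wilcoxon, correlation, clustering) and a ground-truth synthetic generator
round out the package. See the vignette in `vignettes/` for the full
account.

## Worked example

```r
library(ivtBias)

params <- degradationParams(L = 1000, a = 300, b = 200)
curve  <- retainingRateCurve(params, cycle = 2, gridStep = 5, quadStep = 1)
curve
#> RetainingRateCurve: cycle 2, quadrature, 201 grid points on [0, 1000]
#>   params: L = 1000, a = 300, b = 200; max p = 0.4072

round(retainingRate(curve, c(12, 100, 300, 500, 600)), 4)
#> [1] 0.0007 0.0449 0.3141 0.3757 0.2658

# synthetic two-cycle dataset: 20,000 probe sets x 11 probes, noise 10%
sim <- generateProbeData(syntheticSpec(seed = 1), curve = curve)
adj <- adjustProbes(sim$probes, curve)          # default mle-residual mode
ev  <- evaluateAdjustment(adj)

median(ev$cvPairs$cv_before, na.rm = TRUE)      #> 0.645
median(ev$cvPairs$cv_after,  na.rm = TRUE)      #> 0.088
ev$wilcoxon$pValue                              #> 0  (underflows; << 2.2e-16)

# recover the degradation limits from the data alone
fitDegradationLimits(sim$probes, L = 1000)$params
#> DegradationParams: L = 1000 bp, a = 300 bp (3'), b = 200 bp (5')
```

Reading: position 12 bp survives two-cycle amplification with probability
7e-4 while position 500 survives with 0.38 — a ~500-fold dynamic range of
pure protocol bias. Model adjustment collapses the median within-probe-set
coefficient of variation from 0.645 to 0.088, and the profile fit recovers
the true degradation limits (300, 200) exactly.

A subcommand CLI wrapping the same functions
(`simulate`, `fit-params`, `retaining-rate`, `adjust`, `curve-adjust`,
`evaluate`, `qpcr-dp`, `cluster`) ships in
`inst/scripts/ivtbias-cli.R`:

```sh
Rscript ivtbias-cli.R simulate --n-probe-sets 1000 --seed 5 --out sim/
Rscript ivtbias-cli.R adjust --probes sim/probes.tsv --curve sim/curve.tsv --out adj/
Rscript ivtbias-cli.R evaluate --adjusted adj/adjusted.tsv --out eval/
```

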