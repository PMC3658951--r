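---
title: "Modeling and correcting RNA degradation bias in two-cycle amplification microarrays"
author: "ivtBias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and correcting RNA degradation bias in two-cycle amplification microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivtBias)
```

## The problem

Small-input microarray experiments (a few nanograms of total RNA, as in
developing plant organs or sorted cell populations) require the two-cycle
in vitro transcription (IVT) labeling protocol: two rounds of reverse
transcription and T7 amplification. The price is a pronounced positional
bias in probe intensities. During each long IVT incubation the RNA is
exonucleolytically shortened from both ends, and the random-primed
first-strand synthesis of the second cycle truncates products anywhere along
the molecule. Probes interrogating positions close to the 5' end — and, less
obviously, positions very close to the 3' terminus — therefore report
systematically less signal than probes in the middle of the 3' region.
Downstream summaries (probe-set expression values, sample correlations,
clusterings) inherit this bias.

`ivtBias` models the shortening process explicitly, computes the resulting
probability that each transcript position survives amplification (the
*retaining rate*), and corrects probe-level intensities before any standard
preprocessing (PDNN, RMA, dChip, ...) is applied. Background correction,
normalization and summarization are deliberately left to those tools.

## The endpoint-shortening model

A transcript occupies positions $[0, L]$ (bp), with $z$ the distance of a
probe's middle nucleotide from the 3' end. Three shortenings act on the
endpoints $(A_i, B_i)$, starting from $A_0 = 0$, $B_0 = L$:

1. **Cycle-1 IVT degradation.** $A_1 \sim U[0, a]$ and
   $B_1 \sim U[L-b, L]$, where $a$ and $b$ are the 3' and 5' degradation
   limits — the maximal extents of exonucleolytic shortening per cycle.
2. **Random-primer truncation.** The random primer binds anywhere on the
   cycle-1 product, so $A_2 = A_1$ and $B_2 \sim U[A_1, B_1]$.
3. **Cycle-2 IVT degradation.** $A_3 \sim A_2 + U[0, a]$,
   $B_3 \sim B_2 - U[0, b]$.

Degradation is assumed uniform in position (no sequence or GC dependence)
and positions are treated as continuous — transcripts are long relative to
one base. Fully degraded products ($B_3 < A_3$) have positive probability
and are retained; they simply cover no position.

The cycle-$j$ retaining rate is $p_j(z) = P(A_{2j-1} \le z \le B_{2j-1})$.
For cycle 1 it has the closed piecewise form $z/a$ on $[0,a]$, $1$ on
$(a, L-b)$, $(L-z)/b$ on $[L-b, L]$ (equivalently the product
$\min(z/a,1)\,\min((L-z)/b,1)$, which also covers short transcripts with
$a+b \ge L$, where the plateau vanishes). For cycle 2 no convenient closed
form is used; `ivtBias` constructs $p_2$ numerically.

### Numerical construction of $p_2$

Conditional on $(A_1, B_1, B_2)$ the two cycle-2 endpoints are independent,
so

$$p_2(z) \;=\; E\!\left[\,\mathrm{clamp}_{[0,1]}\!\Big(\frac{z-A_1}{a}\Big)\,
\mathrm{clamp}_{[0,1]}\!\Big(\frac{B_2-z}{b}\Big)\right].$$

The inner expectation over $B_2 \mid (A_1,B_1) \sim U[A_1,B_1]$ has a
piecewise-quadratic antiderivative, leaving a two-dimensional integral over
the independent uniforms $A_1$ and $B_1$, evaluated by composite trapezoid
with step $\max(1, L/2000)$ bp (the integrand is piecewise smooth with kinks
at integer offsets of $z$, so integer grids keep the trapezoid error near
$10^{-5}$). A Monte-Carlo mode — the empirical coverage fraction over
sampled trajectories — serves as an independent cross-check: the test suite
requires agreement within three Monte-Carlo standard errors at every tested
position for three parameter settings. Curves are tabulated on an even grid
(default 5 bp) and interpolated linearly; halving the tabulation step moves
interpolated values by less than 0.01.

Useful sanity properties, all asserted in the tests: $p_2 \le p_1 \le 1$
pathwise; $p_1(0) = p_1(L) = p_2(L) = 0$; and as $a, b \to 0$ only the
random-primer truncation remains, $p_2(z) \to 1 - z/L$ on $(0, L]$ (the 3'
terminus itself, $z = 0$, never survives: $p_2(0) = 0$ for every $a > 0$).

## Correcting probe intensities

Observed PM intensities follow the linear model
$IP_{ijk} = IPS_{jk}\, p_j(z_{ik}) + \varepsilon_{ijk}$ with
$\varepsilon_{ijk} \sim N(0, \sigma_{jk}^2)$, where $IPS_{jk}$ is the ideal
(unbiased) intensity of probe set $k$ in cycle $j$. Least squares is then
maximum likelihood, giving the closed form

$$\widehat{IPS}_{jk} \;=\; \frac{\sum_i IP_{ijk}\, p_j(z_{ik})}
{\sum_i p_j^2(z_{ik})},$$

computed per probe set per sample (no information sharing across samples).
Negative estimates are clamped to zero and flagged. The same retaining
rates apply to MM probes: coverage is a property of the position, not of
the binding chemistry.

Two per-probe correction modes are provided:

* **`mle-residual`** (default): $\widehat{PM}_i = \widehat{IPS} +
  (PM_i - \widehat{IPS}\, p_i)$. The lost expected signal is restored and
  the noise term is left unscaled.
* **`invert`**: $\widehat{PM}_i = PM_i / \max(p_i, p_\mathrm{floor})$, the
  direct inversion of the noise-free model, with a floor (default 0.05)
  bounding noise amplification where $p_i$ is tiny.

The default is a deliberate design choice. Inversion divides the *noise*
as well as the signal by $p_i$; at positions with $p_i$ near the floor this
multiplies probe noise twenty-fold, and on synthetic data the within-set
coefficient of variation barely improves. The residual form shrinks CV
strongly (median ≈ 0.64 → ≈ 0.09 under the default generator) without
amplifying noise, which is what a downstream summarization should see. Both
modes coincide when all retaining rates are 1, and both are exact on
noise-free data. Probe sets with no retaining rate above the floor are
passed through unadjusted and flagged `uncorrectable`; sets with fewer than
three usable probes are flagged `low_p_passthrough`. All correction happens
on the linear intensity scale.

### Fitting the degradation limits

$(a, b)$ are protocol-level constants, not per-transcript quantities. They
are estimated once by profile matching: the mean PM per integer position
inside a window (default 12–577 bp, where probes actually sit), normalized
to unit mean, is compared with $c \cdot p_2(z)$ for each candidate $(a,b)$
on a grid (defaults $a \in \{150,\dots,450\}$, $b \in \{100,\dots,300\}$,
step 50 bp), $c$ being the least-squares scale; the smallest
sum-of-squares candidate wins, ties resolved toward smaller $a$ then
smaller $b$. Because probes rarely sit beyond ~600 bp of the 3' end, $b$
(which mostly shapes the far-5' decline) is the more weakly identified of
the two: recovery within one grid step needs on the order of $10^4$ probe
sets, and at the default generator scale (20,000 sets) the truth is
recovered exactly.

## The Curve Adjustment baseline

A model-free comparator is included: mean PM per position in a window
(default 12–588 bp) → lowess smooth (span 0.3) → normalize the smoothed
values to mean 1 → use reciprocals as multiplicative weights
(nearest-position lookup). On data whose only bias is positional this
flattens the mean profile, but the weights near the steep 3' ramp are large
and floorless, so probe noise there is amplified and the per-probe-set CV
improves far less than under model adjustment — the quantitative argument
for modeling the process rather than reweighting the curve. Two caveats
from our own measurements: with probes confined to 600 bp of a 1000-bp
transcript the profile at the *upper* window edge sits above the window
mean (weight < 1 there; only the 3' edge is up-weighted), and re-deriving
weights after adjustment leaves a residual worst-case deviation of ~0.06
from unity (lowess bias at the steep ramp), though the median re-derived
weight is within 0.03 of 1.

## qPCR degradation proportions

To quantify positional degradation independently of the array, CT values
for several amplicons along a transcript are compared across an
unamplified reference pool (PAM) and amplified samples (OCS, TCS):
$R_{ij} = 2^{-(CT(i,j) - CT(i,\mathrm{PAM}))}$ and
$DP_{ij} = 1 - R_{ij}/\max_i R_{ij}$. DP is 0 at the best-preserved
amplicon by construction (ties all map to 0), lies in $[0,1]$, and is
invariant to any constant CT offset within a sample. Replicate CT rows are
averaged before the computation.

## The synthetic-data generator

All validation runs on synthetic data drawn from the generative direction
of the model itself: 11-probe sets, probe positions uniform on
$[12, 600]$ bp (rounded to integer bp so position profiles are
well-defined), fixed $L = 1000$, log-normal true intensities
($\log_2$ mean 8, sd 1.5), $a = 300$, $b = 200$, and Gaussian noise with
per-set sd $= 0.1 \times IPS$ (`constant`, the literal linear model; a
`proportional` mode with sd $\propto IPS \cdot p(z)$ models
signal-dependent probe noise instead). Negative draws are truncated at
zero and flagged. A replicate-group generator overlays per-probe-set
log-normal group effects on a shared intensity vector for
clustering/correlation fixtures.

What the generator does *not* emulate: cross-hybridization, MM binding
chemistry, chip saturation, sequence/GC-dependent degradation speeds, and
the non-uniform real distribution of probe positions. Passing tests
therefore demonstrate internal consistency of model, estimator and
evaluation — not performance on real arrays, which additionally depends on
those unmodeled effects.

One accuracy limit is worth stating explicitly: with 11 probes at the
default positions, $\sum_i p_2^2(z_i) \approx 0.6$, so under constant
per-set noise sd $= 0.1\,IPS$ the MLE's sampling sd is
$\sigma/\sqrt{\sum p^2} \approx 0.13\,IPS$ — a median relative error of
about 7%. That is the information bound of the model itself, not an
estimator defect; under proportional noise of the same fraction the median
error is ≈ 3.6%.

## Evaluation

Per-probe-set CV (sample sd over mean, linear scale, sets with ≥ 2 probes
and positive mean) is compared before/after adjustment with a one-sided
paired Wilcoxon signed-rank test (zero differences dropped; exact null for
≤ 25 untied pairs, normal approximation with continuity correction above).
Inter-sample structure is assessed by Pearson correlation of probe-set
summary values and average-linkage hierarchical clustering on the $1 - r$
distance (the most common microarray convention; both are configurable),
exported as Newick. On replicate-group fixtures the k-group dendrogram cut
recovers the groups exactly.

Problem sizes used throughout the shipped tests: retaining-rate
cross-checks at $10^5$–$10^6$ trajectories; end-to-end correction and CV
comparisons at the generator default of 20,000 probe sets; unit-scale
variants at 400–8,000 sets.

## Limitations

* Degradation is position-uniform; sequence and GC effects are real but out
  of scope.
* Chip saturation is not modeled.
* The correction operates strictly at probe level; it neither replaces nor
  interacts with background correction and normalization.
* $(a, b)$ identification relies on probes spanning enough of the position
  axis; arrays whose probes sit in a very narrow 3' window constrain $b$
  only weakly.
* Real CEL/CDF parsing is out of scope by design: the interchange format is
  a long TSV of (sample, probe set, probe, position, intensity).
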