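---
title: "Methods: quantifying visual habituation from behavior and whole-brain calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying visual habituation from behavior and whole-brain calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

A dark looming disc carries two separable components: a drop in luminance
(delivered in isolation by a whole-field *dim*) and expanding moving edges
(delivered by an isoluminant expanding *checkerboard*). `habitrace`
implements the analysis chain used to ask how larval zebrafish — behaviorally
and neuron by neuron — respond and habituate to these components:

1. **Stimulus model** — trains of loom/checkerboard/dim events with a
   hyperbolic expansion and linear fade, and calcium-kernel regressors on
   the 2 Hz imaging clock.
2. **Behavior** — escape probability per stimulus from 1 s tracking bins,
   a rank-based longitudinal habituation test (ANOVA-type statistic),
   Mann-Whitney comparisons with Bonferroni correction, and one-phase-decay
   curve fits.
3. **Responsiveness** — per-ROI regression against stimulus regressors with
   the median + 2 SD r² threshold, and baseline-subtracted maximum
   responses averaged per fish then per group.
4. **Clustering** — over-clustered k-means on responsive traces, four
   cluster-validation criteria, profile-based merging, and per-region
   composition.
5. **Habituation** — component-sensitivity classification, robust
   least-absolute-residual (LAR) fits of f(x) = a + b·e^(−cx) to
   per-presentation response maxima, goodness-of-fit filtering, and a
   per-fish Friedman comparison of median decay constants across classes.
6. **Synthetic cohorts** — a seeded generator with known ground truth that
   stands in for the (out-of-scope) raw imaging data and underpins every
   quantitative validation in the test suite.

# Stimulus model

Each event rises from zero size at onset to its maximum 5 s later and fades
linearly back over 15 s. The expansion follows the standard looming-angle
form θ(t) = 2·atan(r/(v·(t_c − t))). "Hyperbolic" fixes the family but not
its two constants, so the package anchors the curve to rise from 1% to 99%
of θ_max = π across the expansion and rescales to [0, 1]; this makes the
profile exactly 0 at onset, exactly 1 at the end of expansion, fully
reproducible, and free of tuning knobs.

Regressors convolve each event's expansion-period indicator (the fade is
not part of the drive; responses align to expansion) with a causal
single-exponential calcium kernel e^(−t/τ). The default τ = 3.5 s emulates
nuclear GCaMP6s decay and matches the first-order autoregressive model used
for trace extraction; it is configurable everywhere it appears.

Protocols: behavioral trains present 20 stimuli of one kind then 10 looms
(or 30 looms), ISIs drawn uniformly from {20, 25, 30, 35} s under a seed;
imaging trains use fixed 20 s ISIs (10 + 5 composition), a paired protocol
with 1 min spacing and a 5 min break, and the flanked-loom component
protocol d,c,d,c + 10 looms + d,c,d,c. Imaging trains start after 30 s of
baseline, behavioral trains after 5 min.

# Synthetic cohorts

`generate_cohort()` draws per-ROI ground truth (fish, class, brain region,
centroid, amplitude, decay constant, noise sd) and builds each trace as the
superposition of kernel-convolved, peak-normalized transients:
a presentation of kind g at same-kind index k contributes amplitude
A·e^(−c(k−1)) for every ROI whose class responds to g. Looms drive the sum
of an ROI's dim and checkerboard component amplitudes, so a both-class
trace is exactly the sum of the corresponding single-component traces and
no loom-specific signal exists in the data — mirroring the additive-input
interpretation of loom responses. Noise is i.i.d. Gaussian; photobleaching
and motion artifacts are deliberately not modeled (z-scoring removes slow
scale/offset structure, and source-extraction artifacts are out of scope),
so passing tests demonstrate correctness of the analysis chain, not
robustness to extraction pathologies.

Key defaults, chosen once:

* **Class mixture** none .90 / checker .05 / both .03 / dim .02. Visually
  responsive neurons are a small minority of all extracted ROIs, with
  motion responses several-fold more numerous than luminance responses and
  multi-component ROIs in between. The median + 2 SD selection rule
  *presupposes* a heavy non-responsive majority: with ~40% responders,
  2·SD of the pooled r² distribution lands almost exactly on the responder
  mean, and the rule stops behaving like a noise-floor threshold.
* **Amplitude 3 z, noise 1 z** — peak transient height relative to trace
  noise, the regime in which the pipeline's recovery is evaluated.
* **Decay constants** c ~ U(0.2, 1.2) per presentation, bracketing the
  reported group medians (~0.58–0.67) of loom habituation.
* **Regions** — nine categorical labels with class-conditional priors
  (both-class concentrated in tectum, dim-class in habenula/thalamus/
  tectum); positions are plausible-looking atlas coordinates and are never
  analyzed quantitatively.

Behavioral records emulate 1 s tracking bins: baseline bins are an 80/20
drift/scoot mixture (|N(0.1, 0.1)| mm and U(0.5, 5) mm), and each stimulus
elicits an escape (one 35–80 mm bin inside the 5 s response window) with
probability p_k — for looms p_k = p₀·e^(−λ(k−1)) + floor, constant for
checkerboards, near zero for dims. The default floor is 0 because the
fitted one-phase decay fixes its plateau at 0; a nonzero floor would bias
rate recovery by model mismatch rather than estimator error.

# Behavioral analysis

Bins are classified as drift (< 0.5 mm/s), scoot (0.5–30 mm/s, closed
interval) or escape (> 30 mm/s); fish that never escape are excluded.
Escape probability per stimulus is the fraction of fish with an escape bin
within the 5 s expansion window (the attribution window is not stated in
the source protocols; the expansion period is the conservative choice, and
windows are truncated at the next onset).

Habituation is tested with the Brunner–Langer ANOVA-type statistic (ATS)
for a one-group longitudinal design on (first stimulus, last stimulus of
the block, first probe stimulus): joint mid-ranks, the time contrast
P = I − J/T, statistic n·R̄'PR̄ / tr(PS) with the box-type numerator
adjustment f̂ = tr(PS)²/tr(PSPS), referred to F(f̂, f̂·(n−1)). The
denominator degrees of freedom were chosen by simulation: the common
infinite-denominator reference is liberal by 1–2 points for binary
responses at n = 10–20, while f̂·(n−1) holds the 5% level to within half a
point across binary and continuous nulls. The implementation is
self-contained so it can be validated against a within-fish permutation
oracle. Degenerate inputs are defined explicitly: all-constant
data give p = 1; a perfectly consistent time effect with zero rank
covariance gives p = 0.

Mann–Whitney U uses full enumeration of rank assignments for combined
n ≤ 20 (exact under ties) and the tie-corrected normal approximation with
continuity correction otherwise; Bonferroni correction multiplies by the
family size (the three-train comparison family of eight tests implies the
0.05/8 = 0.00625 significance level used throughout).

One-phase decay fits minimize least squares for p_k = Y₀·e^(−Kk) on
stimuli 1–20 with the plateau fixed at zero (profile solution for Y₀,
multi-start over K), and an ordinary linear regression covers the probe
block (21–30). An all-zero curve reports Y₀ = 0 with K flagged
unidentifiable.

# Responsiveness

Traces are z-scored per ROI over the full recording with the sample sd;
"pooled" is read as assembling all fish's ROIs into one matrix before
thresholding, because a single cohort-wide scale would leave ROI-specific
offsets that break regression comparability (the cohort-wide variant is
available behind `pooled = TRUE`). The responsiveness threshold is
median(r²) + 2·sd(r²) over all pooled ROIs, exceeded strictly.

For the single-kind protocol the selection regression uses one spanning
regressor over the first 10 stimuli, and r² is the squared correlation
(verified against the closed form). For protocols that mix kinds the
package uses an event-wise design — one regressor per flanking component
presentation, joint OLS r². Two structural facts force this: a combined
regressor halves the attainable r² of single-component ROIs (they match
only half its lobes), and any static regressor is blind to habituation
(fast-habituating ROIs respond mainly to the first presentations). On
ground-truth cohorts the measured selection sensitivity rises from ~0.45
(combined) through ~0.67 (per-kind) to ~0.91 (event-wise) at matched
specificity ~1.0.

Maximum responses are the peak z value in a stimulus window minus the mean
of a pre-onset baseline. The operation's default window spans expansion +
fade; the habituation pipeline instead uses a 1 s window centered on the
end of expansion ("peak"), where the kernel-convolved response provably
peaks. The tight window matters: the expected maximum of n noise samples
grows like √(2 log n), and over a 40-sample window this extreme-value
plateau (~1.4–2 z at noise 1) swallows the decaying tail of small
responses and biases decay fits; the 4-sample peak window reduces the
plateau by ~50% and was adopted after ground-truth simulations showed it
removed most of the resulting bias. The pipeline also uses a 15 s response
baseline (the 20 s loom ISI leaves that much stimulus-free, kernel-decayed
time), which removes a third of the variance of each maximum response.

Group response curves average ROI → fish → group so every fish carries
equal weight.

# Clustering

Responsive traces (for the paired protocol, selected by per-kind
regressions — one per stimulus pair — with the union of the per-kind
median + 2 SD rules) are over-clustered with Euclidean k-means, k = 10 and
20 random starts under a seed (`stats::kmeans`, best total within-cluster
sum of squares). Validation retains a cluster only if: every member
correlates > 0.5 with the cluster mean (applied by pruning weaker members
first; a strict-rejection mode is available), it holds ≥ 100 ROIs, spans
≥ 75% of fish, and no fish contributes > 33% of members. Retained cluster
means are merged by transitive closure of pairwise correlation. The
operation default threshold is 0.8; the pipeline passes 0.9 because under
additive loom responses the mean profiles of *different* classes correlate
up to ~0.87 (a dim-only and a both-class profile share their dim and loom
lobes), and 0.9 separates that ceiling from same-class splits. Region
composition divides responsive counts by total counts per region and fish,
averages across fish, and normalizes the three-class composition within
region.

Two scale notes, both visible in the test suite: the >0.5 member-to-mean
correlation criterion presumes strongly responsive populations (at
amplitude 3 z a four-transient ROI cannot correlate 0.5 with its cluster
mean over a 10-minute record, so validation cohorts use amplitude 5,
consistent with the high r² threshold this protocol produced); and the
paired protocol spaces presentations a minute apart precisely to minimize
habituation, so its cohorts are generated with near-zero decay.

# Habituation analysis

Component sensitivity is classified by a single threshold θ (default 1 z)
on each ROI's dim and checkerboard response evidence. The evidence is the
mean *per-event regression amplitude* over the first-block presentations
of each kind: coefficients from the event-wise design are unbiased
amplitude estimates in z units (no extreme-value bias), and restricting to
the pre-loom block measures inherent sensitivity rather than habituation
state. The original classification criteria are not recoverable, so this
rule is the package's reconstruction; θ is exposed, and the
trial-averaged-maximum variant is available as `method = "eta"`.

The decay f(x) = a + b·e^(−cx) (x = 1-based loom index; the origin only
rescales b, and only c is compared across groups) is fitted to the 10
per-loom maxima by LAR: for each candidate c the linear subproblem in
(a, b) is solved as an L1 regression by iteratively reweighted least
squares with weights 1/max(|r|, 10⁻⁶), and c is found by a global grid on
[0, 10] (a superset of the multi-start values 0.05/0.3/0.7/1.5) plus local
refinement. The IRLS solution was verified to reach the Nelder–Mead L1
optimum. Fits are accepted iff adjusted r² > 0.5 (n = 10, p = 3) and raw
SSE < 20 z²; constant series give b ≈ 0 with undefined adjusted r² and are
rejected. A plain least-squares mode exists solely as the comparison arm
for robustness checks.

A known limitation, quantified in the validation outputs rather than
hidden: the three-parameter exponential on 10 points is weakly identified.
Near c → 0 the model degenerates into a line (a flat objective ridge), and
at large c only the first points carry information, so at response noise
0.5 z the median |relative error| of the *global* optimum is ~0.3 — an
independent optimizer reproduces the same figure, i.e. this is intrinsic
estimator variance, not an optimization failure. Per-fish medians over
tens of accepted fits are accordingly the unit of inference, never single
ROIs.

Per-fish, per-class medians of accepted ĉ enter a Friedman test
(within-block mid-ranks, tie-corrected statistic, exact permutation p by
dynamic programming for ≤ 8 blocks, chi-squared otherwise; fish missing a
class are dropped, since the block design must be complete). The
goodness-of-fit filter is applied before the medians.

The acceptance filter interacts with the decay-constant *distribution*:
at amplitude 3 the acceptance probability of single-component ROIs depends
on their true c (slow decays have low curve variance, fast decays vanish
into noise), so when c is drawn from a wide distribution the filter
selects different c for different amplitudes and biases class comparisons
by construction. The class-comparison simulations therefore use
class-constant decay — equal (0.6, 0.6, 0.6) for the no-effect arm, the
paper-typical median, and (0.2, 0.8, 0.8) for the effect arm — at 11 fish
x 200 ROIs with the richer dim .05 / checker .25 / both .10 mixture
(per-fish class counts large enough for stable medians). Under these
frozen conditions the no-effect arm is not rejected in ~95% of seeded runs
and the effect arm is detected with power ~1.

# Problem sizes used in validation

Unit tests run on cohorts of 4–8 fish with 100–250 ROIs each; the
end-to-end recovery checks use the default 11 × 500 cohort; calibration
uses 1000 null replicates per test; the class-comparison simulations use
2 × 50 seeded cohorts of 11 × 200; and the behavioral arm uses 2 × 50
cohorts of 24 fish. The acceptance script regenerates all of these from a
single command-line seed.

# Known limitations

* Noise is white; temporally correlated noise would widen all calibration
  statements.
* Fish are statistically identical replicas (no between-fish random
  effects), which makes between-cohort comparisons of absolute response
  levels sharper than in real data.
* The component-sensitivity rule is a reconstruction (single threshold on
  regression-amplitude evidence); alternative rules would shift class
  boundaries, and θ's effect is covered by its exported parameter rather
  than by re-deriving the unavailable original criteria.
* The decay-constant estimator's intrinsic variance at low SNR (above)
  means ROI-level ĉ values should never be interpreted individually.
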