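---
title: "Methods: resting-state EEG features, permutation inference and prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-state EEG features, permutation inference and prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

zolpiscope implements a complete resting-state EEG analysis for paired
pharmacological studies in disorders of consciousness: spectral features,
brain symmetry indices, phase-locking-value (PLV) connectivity with
network-based-statistic (NBS) inference, microstate dynamics, and
leakage-safe nested-LOOCV classification and prediction. Because clinical
recordings of this kind cannot be redistributed, the package ships a
synthetic-EEG generator with known ground truth; every stage has a
parameter-recovery or calibration test against it. This vignette records the
models, the parameters that matter, and the design decisions taken where the
methodology left choices open.

## Containers and montage

A recording is a channels x samples matrix (µV) with a sampling rate, channel
labels, a reference flag, and an ordered list of *continuity segments* —
half-open, 0-based sample intervals of artifact-free signal. Every windowed
or filtered stage operates per segment, so artifact-removal cut points never
leak across a discontinuity. This per-segment contract is a deliberate
choice: filters, Hilbert transforms and Welch windows all see only continuous
data.

The packaged montage is a 59-channel 10-10 layout (26 homologous left/right
pairs plus 7 midline electrodes) with unit-sphere positions from the standard
10-05 electrode geometry. Homologous pairs are derived from label parity (odd
trailing digit = left, its successor = right; trailing "z" = midline); with
59 channels there are 59·58/2 = 1,711 undirected connections. Any 10-10
subset with complete pairing is accepted, and all test fixtures use a
23-channel subset for speed.

## Preprocessing

Filters are linear-phase hamming-window FIR designs specified by order and
the −6 dB (half-amplitude) cutoff — the convention of the windowed-sinc
design family. Defaults: a low-pass of order 660, transition 5 Hz, cutoff
45 Hz applied at the acquisition rate (2,500 Hz), downsampling to 250 Hz,
then a high-pass of order 826, transition 1 Hz, cutoff 0.5 Hz. Zero-phase
output is obtained by compensating the known group delay (order/2 samples)
of the causal filter. Note that with a 0.5 Hz cutoff and ~1 Hz transition,
DC sits at the very edge of the stop band: a DC offset is attenuated to
about 0.5% amplitude, not annihilated.

Bad channels are caller-supplied (their detection is semi-automatic and
manual in practice) and reconstructed by spherical-spline interpolation
(order m = 4, 50 Legendre terms, ridge 1e-5). The same spline machinery
provides the surface-Laplacian (current-source-density) transform used
before connectivity, with the analogous m − 1 kernel. ICA-based artifact
removal is out of scope: it is a visual, manual step that a deterministic
pipeline cannot reproduce.

## Spectral features

The PSD is Welch's periodogram: 2-s hamming windows, 50% overlap, windows
tiled within continuity segments only (0.5 Hz resolution at 250 Hz).
Relative power divides the summed PSD over a band's bins by the sum over
1.0–42.0 Hz. Two band schemes coexist: an 8-band spectral scheme (delta
1.0–3.5, theta 4.0–7.5, alpha 8.0–12.5, three beta sub-bands, broadband beta
13.0–29.5, gamma 30.0–42.0 Hz) whose edges only tile the 0.5 Hz grid under
*inclusive* band edges — the reason band sums include both edge bins — and a
5-band contiguous scheme (1–4, 4–8, 8–13, 13–30, 30–42 Hz) for band-limited
connectivity. The sum-to-one invariant applies to the five primary spectral
bands (delta, theta, alpha, broadband beta, gamma).

Both brain symmetry indices build on the bin-level asymmetry
|(R − L)/(R + L)| of the PSD. The pairwise-derived index (pdBSI) evaluates it
per homologous pair and averages over pairs and bins; the revised index
(rBSI) first averages the PSD over each hemisphere. Midline channels are
excluded; a bin with R + L = 0 is skipped.

## Connectivity

After the Laplacian transform, the signal is band-pass filtered (hamming FIR,
order = 3 cycles of the band's low edge — the stage's filter parameters are
not fixed by the methodology, so the order scales with the band), the
analytic signal is computed per continuity segment, and 10% of each
segment's phase signal is discarded per side: edge effects arise at every
discontinuity, so the trim is per segment, not per recording. The remainder
is tiled into non-overlapping 2-s epochs (tails shorter than one epoch are
dropped) and the PLV of channels i, j is the epoch-average of the magnitude
of the mean phase-difference phasor.

Two estimator properties matter for interpreting tests. First, PLV is
invariant to constant phase offsets and exactly 1 for identical phase
trajectories. Second, the magnitude-of-mean estimator has a positive floor
for finite epochs of *narrowband* signals: a 5 Hz-wide alpha signal carries
roughly 10 independent phase samples per 2-s epoch, so two independent
channels show PLV ≈ 0.28 no matter how many epochs are averaged (averaging
magnitudes does not cancel). Fully white phases give the much smaller
1/√N-type floor. Tests against the null therefore use Monte-Carlo-derived
levels rather than an idealized zero.

FCSCC — the mean functional connectivity strength over a connected
component's edges — is a plain arithmetic mean over the component's edge
values and serves as the one-dimensional connectivity summary fed to the
models.

## Microstates

GFP is the population (divide-by-C) standard deviation across channels at
each sample; the divisor choice is pinned by the convention GFP([1, −1]) = 1.
Clustering maps are taken at GFP local maxima inside continuity segments,
after discarding the lowest 15% of peaks (rank-based: the ⌊0.15 n⌋ smallest,
stable under ties — the rule that discards *all* tied peaks would empty an
equal-height recording) and peaks whose GFP exceeds the mean by more than
three standard deviations of the peak GFP values (the mean-anchored form is
the only one that keeps an all-equal-peaks recording intact while removing a
10× outlier).

The modified k-means is polarity-invariant: maps are assigned by maximal
squared spatial correlation (Pearson across channels of average-referenced
maps), and each template update is the dominant eigenvector of the
cross-product matrix of its assigned maps; iteration stops when the relative
GEV change falls below 1e-6, an emptied cluster is re-seeded from the
worst-fit map, and the best of 10 restarts by GEV is kept. Group templates
come from a second modified k-means over the pooled per-recording templates,
then receive canonical A–D names by maximal absolute correlation to
reference topographies under a one-to-one assignment (exhaustive over the
4! pairings; ties broken by the larger correlation sum). The reference
topographies are *synthetic parametric reconstructions* built from the
montage geometry (two diagonal gradients, an anterior–posterior gradient and
a fronto-central radial pattern); they anchor naming only and never act as
templates.

Back-fitting labels every in-segment sample (all samples, not only GFP
peaks, since the smoothed sequence labels everything anyway) by maximal
|spatial correlation|. Temporal smoothing is segment-rejection style: while
any non-truncated segment is shorter than ⌈30 ms · fs / 1000⌉ samples (8 at
250 Hz), the shortest such segment is dissolved, each sample joining
whichever neighboring class correlates better. The first and last segments
of every continuity segment are flagged truncated and excluded from all
segment-based features.

Eight feature families are computed per class: GEV (GFP-weighted squared
correlation summed over the class's samples, normalized by the total squared
GFP over all labeled samples), mean duration, occurrence (non-truncated
segments per second of labeled time), coverage, mean interval (the average
gap between the end of one segment of the class and the start of the next,
within a continuity segment), mean GFP, the K × K spatial-correlation metric
SC (mean |correlation| of template X with the maps labeled Y), and the K × K
transition probabilities over consecutive non-truncated segments. An absent
class yields NA, never zero.

## Permutation inference

All tests are two-sided permutation tests. Within-subjects designs flip the
signs of the per-subject condition differences (2^n possibilities) with the
one-sample t statistic; between-subjects designs shuffle condition labels
(C(n1+n2, n1)) with the Welch t; correlations shuffle the outcome order (n!)
with the Spearman coefficient. Enumeration is exhaustive when the count does
not exceed 2,000, otherwise 2,000 uniform random draws are used. The
add-one-corrected p-value counts strictly more extreme permutations:
p = (#{|t_perm| > |t_obs|} + 1)/(n_perm + 1). The strict inequality is what
makes the analytic floors come out exactly: 1/17 = 0.059 for n = 4 within,
1/257 = 0.004 for n = 8 within, 1/71 = 0.014 for 4-vs-4 between — with "≥"
the mirror permutation (all signs flipped), which always ties |t_obs|, would
double the floor.

The NBS test controls family-wise error over the 1,711-edge network.
Edge-wise p-value maps use the Wilcoxon signed-rank test on paired
differences (within), the rank-sum test (between) — both with exact null
distributions when there are no ties, mid-ranks and a tie-corrected normal
approximation otherwise — or Spearman correlation. The sign map is +1 where
the median difference (or correlation) is positive, −1 otherwise.
Significant maps (edge p < 0.05, split by sign) are decomposed into
connected components by union-find; each permutation records the largest
positive and largest negative component size, and each observed component is
referred to the sign-matched null through
p = (2·#{|S_null| > |s_obs|} + 1)/(N + 1). This formula uses a strict
inequality (unlike a tie-counting permutation p), and on small networks,
where component sizes are small integers and ties with the null are common,
it is measurably anti-conservative: in our calibration simulations on
8-node networks the family-wise rate is ≈ 0.10 at nominal 0.05. The effect
shrinks as component sizes diversify (larger networks); we keep the formula
exactly as specified and report the measured rate rather than silently
substituting a tie-counting variant.

## Classification and prediction

Feature selection keeps every feature tying the smallest p-value. The SVM
pipeline is scaling → PCA (2 components) → linear SVM, the SVR pipeline
scaling → PCA (1 component) → linear SVR; all three stages are refitted
inside every training fold of a nested LOOCV, so no statistic of held-out
data influences a fit — the leakage guard is asserted by test (corrupting a
held-out row leaves its fold's fit bit-identical). The outer loop leaves out
one recording row per fold by default (16 folds for 8 paired subjects); a
`folds = "subject"` switch leaves out both of a subject's rows, since the
methodology's "one subject was split as the test dataset" is ambiguous
between the two. Grids default to C ∈ {0.01, 0.1, 1, 10, 100} and
ε ∈ {0.01, 0.1, 1}; the inner LOOCV picks by accuracy (SVM) or RMSE (SVR).
AUC is computed from decision scores pooled across outer folds. The
"RMSE without the outlier" report requires an explicit subject identifier —
there is no automatic outlier detection.

One caveat worth stating: under a *global* label permutation, small-sample
LOOCV is anti-learning-biased (pooled AUC centers near 0.35, a well-known
artifact of imbalanced training folds). The paired design's natural null —
flipping each subject's T0/T1 labels, which keeps every training fold
balanced — centers the AUC at 0.5, and that is the chance-level check the
tests use.

## The synthetic generator and what it does (not) show

`gen_oscillatory()` builds each channel as a sum over the five bands of
amplitude-scaled narrowband noise (hamming-FIR filtered white noise with a
~2 Hz transition; sinusoids would make PLV degenerate and Welch trivial).
Phase coupling is planted by mixing a shared narrowband source into coupled
channels with weight √strength; rows of the coupling table sharing a
`source` id use one common source, so a clique subnetwork can be coupled
coherently. `gen_microstate_eeg()` emits template-switching EEG with
gamma-distributed segment durations (shape 4, floor 40 ms), a rectified
alpha-noise amplitude envelope, and white sensor noise at a stated
signal-to-noise amplitude ratio. `gen_paired_study()` assembles a paired
design: per-subject band-power targets jittered around (0.25, 0.30, 0.20,
0.15, 0.10), a planted −0.07 theta change at T1 renormalized over the other
bands, a coupled 4-channel clique whose strength (drawn per subject from
U(0.4, 0.8), wide enough that the outcome signal dominates its noise) drops
by 0.3 at T1, and outcomes 6 + 10·coupling_T0 + N(0, 0.5²).

All draws flow from one explicitly seeded generator; the same seed gives
bit-identical output, and generators restore the caller's RNG state. The
generator emulates band structure, phase coupling and topographic switching
— it does not emulate eye-blink or muscle artifacts (the ICA stage is out of
scope), 1/f background, volume conduction between correlated neural sources,
or electrode drift. Passing parameter-recovery tests therefore validates the
estimators' algebra and calibration, not their robustness to real-world
artifacts.

## Problem sizes used by the test-suite and acceptance script

Unit and acceptance runs use scaled study conditions chosen to exercise every
code path with comfortable statistical margins: a 23-channel montage subset;
recordings of 10–60 s at 250 Hz; four 25-s recordings for two-level template
recovery at SNR 5 (recovered |correlation| > 0.999 in practice); 8-node
networks with 300–500 permutations for NBS calibration; 200 null replicates
for the scalar type-I rate; 50 repeats for chance-level AUC. The permutation
floors, montage arithmetic and Welch configuration are exact and
size-independent.
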