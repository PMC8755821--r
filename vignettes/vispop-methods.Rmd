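---
title: "Models and methods behind vispop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vispop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vispop)
```

vispop implements a complete analysis chain for single-unit recordings from
the pigeon visual forebrain — responsiveness typing, stimulus-grouping
selectivity, chance-level calibration, pseudo-population decoding, and
Fourier characterisation of the stimulus images — together with a synthetic
session generator that stands in for raw recordings. This vignette documents
the underlying models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic data can and cannot tell you.

## The task model and the session generator

An experimental session presents 20 images (5 stimulus groupings × 4
exemplars) 8 times each, 160 trials in total, in a seeded random order. Each
trial has a pause period (response inhibition, uniform 2–4 s), a stimulus
period (uniform 1.5–3 s) and a 6 s inter-trial interval; firing rates are
measured in a 0.5 s analysis window for the baseline (ITI) and stimulus
periods and over the whole pause period. All of these are `task_config()`
fields; the defaults are the task as run, and `n_groupings × n_exemplars ×
n_reps` always equals the trial count.

Spiking is homogeneous Poisson per period: a neuron with baseline rate
$\lambda$ emits $\mathrm{Poisson}(\lambda w)$ spikes in a window of length
$w$, reported as a rate in spikes/s. Response classes are multiplicative
gains on $\lambda$ during the stimulus window — excitatory ($g>1$),
inhibitory ($g<1$), nonresponsive ($g=1$) — and pause activity is a separate
multiplicative pause gain. Only completed trials exist in the generator:
correction trials and peck-driven period extensions are behavioural details
that never enter the analysed data.

Category tuning is planted by inverting the selectivity-index definition.
With non-preferred stimulus rate $O = \lambda g$ and target index $s$, the
preferred-grouping rate is $P = O(1+s)/(1-s)$ for excitatory neurons (and
$O(1-s)/(1+s)$ for inhibitory ones, whose preferred grouping is the most
*suppressed*). $s = 1$ would require a zero or infinite rate and is
rejected. This construction makes parameter recovery testable: the empirical
SI of a planted neuron is an asymptotically unbiased estimate of $s$, and
the test suite verifies unbiasedness within three standard errors over 200
replicate sessions at $s \in \{0.2, 0.33, 0.5\}$.

One synthetic "session" holds all neurons for convenience, but the real
design — one neuron per day — is respected where it matters: the decoder
never uses across-neuron single-trial covariance (see below). The trial
schedule (order, durations) is shared across neurons within a session;
spike counts are independent across neurons.

## Responsiveness typing

`classify_responsiveness()` runs a two-tailed paired t-test of the
stimulus-window rate against the per-trial baseline rate (and likewise for
the pause period), at $\alpha = 0.05$ by default. Two-tailed is the right
choice because both excitatory and inhibitory changes are reported as
discoveries. The baseline is paired per trial with the window drawn from the
ITI preceding the stimulus. If every paired difference is exactly zero the
neuron is nonresponsive with $p = 1$; a constant non-zero difference (zero
variance, non-zero mean) is treated as infinitely strong evidence. On null
(gain 1) neurons the false-positive rate matches $\alpha$; the suite checks
this on 500 simulated neurons.

The normalised time courses z-score each neuron's per-period mean rate
against its own baseline mean and standard deviation before averaging within
class. "Normalisation" is deliberately a configurable strategy reduced to
baseline z-scoring here: it forces the baseline period to 0 for every class,
makes excitatory/inhibitory classes symmetric around it, and needs no
cross-neuron scale assumptions. Neurons with zero baseline variance cannot
be z-scored and are dropped with a warning rather than silently propagating
`Inf`.

## Selectivity: ANOVA, Tukey HSD, and the selectivity index

The selectivity screen is the classic fixed-effects one-way ANOVA on
stimulus-window rates grouped by stimulus grouping
(`oneway.test(var.equal = TRUE)`, identical to the textbook F). Selective
neurons go to Tukey's HSD; the preferred grouping is the one whose mean rate
deviates most from the neuron's baseline mean — sign-aware, so an inhibitory
neuron's preference is its deepest suppression — and it must appear in at
least one significant pairwise contrast, otherwise the preference is
ambiguous (`NA`). Ties in the extreme deviation are also ambiguous.

The selectivity index is computed on raw window rates, not
baseline-subtracted ones: only raw-rate ratios make the anchor "SI 0.33 ⇔
2:1 response ratio" exact. Negative values (the nominal preferred direction
violated) are clipped to zero. SI is invariant to any common multiplicative
rescaling of rates.

The chance-level simulation answers "how many selective neurons would the
screen find in pure noise?": per simulated neuron, every trial's rate is
drawn i.i.d. uniformly between that neuron's own min and max — per-trial
draws, not per-grouping means, because the ANOVA needs within-group variance
— and the same ANOVA is applied. The significant fraction converges to
$\alpha$ regardless of the rate ranges; defaults are 77 neurons, 32 trials
per grouping (8 reps × 4 exemplars) and ranges 0–20 spikes/s.

## Pseudo-population decoding

Since neurons are recorded sequentially, population vectors are surrogate
constructions: within each grouping, each neuron's trials are independently
shuffled, truncated to the common per-grouping minimum $k$, and the $i$-th
shuffled trial of every neuron is concatenated into vector $i$; labels
attach after the shuffle. Any single-trial noise correlation between neurons
is destroyed by construction, which is exactly the property that makes the
construction legitimate for sequentially recorded data.

Each resample rebuilds the pseudo-population with a fresh shuffle, fits a
linear discriminant classifier (`MASS::lda`) on a stratified 75/25
train/test split, and measures per-grouping performance as the one-vs-rest
area under the ROC built from the classifier's posterior score for that
grouping (0.5 = chance). The AUC itself is computed by the Mann–Whitney
rank identity for speed inside the 2 × 1200-resample loop; it is verified
against `pROC::auc` in the test suite. If the within-class scatter is
singular (few vectors, many neurons) a shrinkage-regularised discriminant
(pooled covariance blended 10% towards its diagonal average) takes over,
and the result records that this happened.

The null ("no information") distribution repeats the identical procedure
with grouping labels randomly permuted across vectors before training. The
permutation p-value per grouping is the add-one estimator
$p = (1 + \#\{\mathrm{null} \ge \mathrm{median(labelled)}\}) / (1 + n)$
with error $\sqrt{p(1-p)/n}$; it can never be exactly zero, and the median
of the labelled distribution is used as the observed statistic because a
single resample would confound assembly noise with signal. Both
distributions default to 1200 resamples each. Multiclass LDA with
one-vs-rest ROC readout was chosen over five binary problems; the binary
alternative is reachable by filtering the trial table to two groupings.

Two calibration facts shape how results should be read. First, under a
truly uninformative population the p-values are approximately — not exactly —
uniform across datasets: the null draws carry per-resample split/assembly
noise that the labelled median averages out, which compresses p slightly
towards 0.5 (conservative, never anticonservative). The suite verifies
approximate uniformity (Kolmogorov–Smirnov) and chance-level ROC over 60
seeded uninformative populations of 10 neurons under the full 160-trial
task with 150 resamples each — sizes chosen to keep the whole calibration
inside a few minutes while leaving the conclusion unchanged at larger
sizes. Second, power: 77 neurons planted at SI 0.5 drive every grouping's
labelled median above the entire 1200-sample null, i.e. the add-one minimum
p ≈ 8.3 × 10⁻⁴.

Generalisation to held-out exemplars uses fold $j$ = (the $j$-th exemplar of
every grouping): training vectors are built from the remaining exemplars'
trials only, test vectors from the held-out exemplars' trials, and
per-grouping ROC is averaged over folds and resamples. Populations tuned at
the grouping level transfer (held-out ≈ within-exemplar performance);
populations tuned to single exemplars collapse to chance on average, though
individual groupings wobble with the particular draw.

## Stimulus images and their spectra

Three generators cover the stimulus set. Sine gratings are
$0.5 + 0.5\sin(2\pi f x / N)$ with $1 \le f < N/2$ (Nyquist). Naturalistic
surrogates are random-phase fields with amplitude $\propto 1/f$ radially
(power $1/f^2$), rescaled to $[0,1]$ — they reproduce the two properties
the analysis needs from face photographs, low-frequency dominance and
shared low-frequency correlation, while avoiding copyrighted images; they
contain no faces, so nothing about face *perception* follows from them.
Grid scrambling divides the image into a 15-column × 32-row tile lattice
(480 tiles), permutes tile positions and randomises tile orientation. For
non-square tiles only 180° rotation and horizontal/vertical flips map a
tile onto its own footprint, so those are the allowed orientations (flips
are included so the orientation shuffle remains meaningful, and can be
disabled); square tiles additionally allow 90°/270°. Every allowed
operation is a pixel permutation, so the pixel multiset — and mean
luminance — is conserved exactly.

Cross-section spectra are 1-D FFT amplitude spectra along an axis, averaged
over all lines of the orthogonal axis (a single central line is an option;
the mean is the default because it does not depend on an arbitrary line
choice). Frequencies run 1…Nyquist in cycles/image with DC omitted; no
windowing is applied by default. The energy-weighted spectral average is
the spectral centroid with $|A|^2$ weights ("energy-weighted" is read as
power weighting; amplitude weighting is exposed as an option). For a pure
grating it equals the grating frequency exactly; it is invariant to
intensity scaling; it is undefined (error) for a constant image, and the
batch summary reports `NA` for such axes — notably the direction orthogonal
to a grating's stripes. Scrambling raises the centroid on the vertical axis
for essentially every 1/f surrogate (32 tile rows insert many transitions)
and on the horizontal axis for about 96% of them (15 columns are coarser),
so the directional claim is tested as a sign test across 20 surrogates
rather than as a universal. Spectral correlation matrices normalise each
spectrum to unit energy and take Pearson correlations, horizontal direction
in the upper triangle, vertical in the lower.

## Contingency comparisons

Between-region proportion comparisons use the uncorrected Pearson
chi-square statistic with margins-based expected counts — no Yates
correction even for 2×2 tables, which is the convention in this literature
for region-proportion comparisons. Reported percentages are
integer-rounded.

## The pipeline

`run_pipeline()` wires the stages together for a configurable set of
region-like neuron populations: simulate → classify responsiveness → filter
to visually-responsive neurons → selectivity + chance simulation →
between-region chi-squares (responsive proportions, excitatory/inhibitory
ratios, pause activity, selective-vs-chance) → decoding per region → image
spectra. Every stage's randomness derives from the single config seed plus
fixed offsets, so the same config yields byte-identical artifacts; stage
outputs are written as CSV/JSON so the report can be regenerated without
recomputation.

## Limitations

* Poisson spiking with multiplicative gains is the simplest mechanism
  consistent with window rates; it has no refractoriness, bursting,
  latency structure or adaptation, so passing tests say nothing about
  temporal spike statistics of real neurons.
* The generator plants tuning at the grouping level (or, in test fixtures,
  the exemplar level); real tuning is graded and mixed.
* The synthetic surrogates share the spectra-level properties of natural
  images, not their content; region-specific quantities that depend on
  actual recordings (responsive counts per region, SI means, region-wise
  decoding histograms) cannot be reproduced from synthetic data — the
  pipeline reproduces the *procedures*, their calibration, and any
  contingency statistic that is fully determined by reported counts.
* `scrambled_vs_original()` reports the t statistic, its degrees of
  freedom and the p-value side by side rather than deriving one from
  another, so an internally inconsistent pair in a source table (a large
  |t| printed next to a non-significant p) is detectable instead of being
  silently reproduced.
* Permutation p-values from the median-of-labelled statistic are mildly
  conservative under the null (see above); they are never anticonservative.
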