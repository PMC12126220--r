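---
title: "Quantifying fear generalization in neural ensembles: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fear generalization in neural ensembles: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fearsemble)
```

## Overview

`fearsemble` measures how well neural and behavioral responses distinguish a
threat-predictive conditioned tone (CS⁺) from a neutral novel tone (NT), and
how that distinction degrades under fear generalization. The pipeline runs
from raw neuron-by-time activity matrices to ensemble taxonomies, preference
indices, response clusters, and population-trajectory geometry, with
companion modules for fiber photometry, freezing behavior, and human
fear-potentiated startle. This vignette explains each model and procedure,
the parameters that matter, the numerical conventions, and what the
synthetic-data tests do and do not establish about real recordings.

## Peri-tone alignment and Z-scoring

Traces are sampled at a fixed rate (10 Hz by default, the rate of the
miniscope recordings the pipeline targets). For each tone presentation we
extract a window from 15 s before onset to 15 s after, average samples into
1-second bins, and average presentations into blocks of 2 in order of
presentation. Each neuron × block slice is then Z-transformed against the
mean and SD of its own 15 pre-tone baseline bins.

Conventions that the data do not dictate, fixed once here:

* **Bin edges.** Bins are half-open, `[onset + b, onset + b + 1)`, 0-based,
  with the onset sample included in bin 0. Any consistent convention works;
  this one makes bin membership a pure floor operation.
* **Baseline SD.** The unbiased (n − 1) estimator, computed from the 15
  one-second bins (not from raw samples). At n = 15 the biased/unbiased
  difference is immaterial scientifically, but exactness tests need one
  fixed choice.
* **Zero-SD baselines.** A constant baseline would make Z undefined. We set
  Z = 0 and flag the slice instead of erroring, so a degenerate synthetic
  neuron cannot abort a batch run. Flags propagate in the returned objects.
* **Odd trial counts.** Block averaging drops a trailing unpaired trial with
  a warning (the block is meant to be an average of 2 like-positioned
  presentations; a singleton block would have different variance).

For the preference index a second normalization is used: the average of the
first 2 presentations of each tone type is Z-scored against the neuron's
whole-session mean and SD, then averaged over the 15 tone seconds, giving
one scalar per neuron per stimulus (`ztransform_whole_session()`). Both
normalizations are invariant to shifting a trace by a constant or scaling it
by a positive factor, which the test suite verifies.

## Responsive-neuron classification and the 9-type taxonomy

A neuron is **(+)responsive** to a stimulus if any 2 consecutive tone-period
bins both exceed +3 Z, **(−)responsive** if any 2 consecutive bins fall
below −3 Z, and non-responsive otherwise. The threshold (3), run length (2),
and the reading of "during the tone period" as bins 0..14 inclusive of the
onset bin are parameters with those defaults.

Two edge cases are underdetermined by the rule and resolved as follows:

* A trace with qualifying runs of *both* signs is labelled by the run with
  the larger mean |Z|. This case is vanishingly rare in real data (it
  requires a ±3 crossing in both directions within 15 s) but must be
  deterministic.
* When classification is run per block, a neuron's session label is the
  label of its strongest qualifying run across blocks; a neuron is NONE only
  if no block qualifies.

Crossing the NT label with the CS⁺ label yields 3² = 9 response types; every
neuron lands in exactly one, and proportions sum to 1 (a partition, checked
to 1e-12). The "dual" aggregate — both labels non-NONE — is the headline
generalization statistic at the ensemble level. Group comparisons of type
proportions use Fisher's exact test on the 2×2 (in-type vs not) × (group)
table. Per-trial classification (no block averaging) feeds the
consecutive-tone stability measure: the proportion of neurons responsive on
at least two adjacent presentations of the same tone type.

Spontaneous activity outside tone periods has no agreed event definition;
for internal consistency we reuse the excursion rule (whole-window Z above
+3 for ≥ 2 consecutive 1-s bins, each excursion counted once) and report
events per minute.

## Stimulus preference strength

Per neuron, with `z_nt` and `z_cs` the whole-session-normalized scalars,

```
magnitude = |z_nt − z_cs| / (|z_nt| + |z_cs|)
```

signed positive when |z_nt| > |z_cs| and negative when |z_nt| < |z_cs|. The
magnitude is bounded in [0, 1]; it reaches 1 when the responses have
opposite signs or one is 0. Exact ties (|z_nt| = |z_cs|) and zero
denominators are not covered by the strict definition; we return a signed
value of 0, keep the magnitude separately, and flag the case, so the sign
histogram is unaffected by an arbitrary choice. Distributions are compared
with the asymptotic two-sample Kolmogorov–Smirnov test; for reporting,
histograms use 20 equal bins on [−1, 1].

## Clustering

The clustergram recipe: concatenate each neuron's NT and CS⁺ mean block
Z-traces (NT first), rescale linearly from the input range [−5, 5] onto
[−3, 3] with saturation (damping neurons with huge excursions without
destroying their pattern), compute Ward minimum-variance linkage on
Euclidean distances, cut the dendrogram at 5% of the maximum merge height,
and remap cluster mean profiles to the *unscaled* traces so magnitudes are
faithful. The cut is applied to raw merge heights; merges strictly above the
threshold are removed and the surviving connected components are the
clusters. Note that the rescale is an affine map, so applying it twice is
not a no-op — only its saturation step is idempotent; the pipeline applies
it exactly once, before linkage.

The Ward implementation is `stats::hclust(method = "ward.D2")`; the test
suite checks it against an independently written O(n³) Lance–Williams
reference via cophenetic-matrix equality on random instances, and verifies
that decreasing the cut fraction never decreases the number of clusters and
that shuffling neuron order only relabels the partition.

## Population geometry

The population matrix concatenates, per neuron, the NT and CS⁺ mean block
traces along time (rows = time bins, NT segment then CS⁺ segment) and the
two treatment groups along the neuron axis (columns = reference group block
then treated block). The larger group is subsampled without replacement,
with a required, logged seed, to match the smaller — distances are always
computed on equal neuron counts. PCA treats time bins as observations and
neurons as features (mean-centered); this is the standard population-vector
reading and makes "trajectory in PC space" well-defined per bin. Because a
bin's score is a sum over neurons of centered activity times loading, it
decomposes exactly into per-group partial sums; those partial projections
are the per-group trajectories, and the NT / CS⁺ row segments split each
into the two stimulus trajectories. The test suite verifies the
decomposition reproduces the full scores.

Separation measures, per group:

* **Mahalanobis**: for each NT bin, the distance to the CS⁺ point cloud
  using the CS⁺ bins' mean and covariance. With ~15 bins in 15 dimensions
  the sample covariance is singular, so it is shrinkage-regularized as
  Σ + λI with λ = 10⁻³ · tr(Σ)/K — enough to guarantee invertibility while
  perturbing well-conditioned cases by well under 0.1%. An explicit
  covariance can be supplied instead (used by tests to verify the
  identity-covariance reduction to Euclidean distance exactly). The CS⁺
  cloud is the reference by default because the question is how far the NT
  representation sits from the conditioned one; the roles can be swapped by
  exchanging arguments.
* **Instantaneous Euclidean**: per-bin distance between the NT and CS⁺
  trajectory points over the first 15 components.

Group comparison of per-bin distance vectors uses a pooled-variance
two-sample t-test with df = n_binsA + n_binsB − 2 (with 16-bin windows per
stimulus this gives t(30)).

## Photometry

The sensor channel is corrected with the isosbestic channel by ordinary
least squares: fit isosbestic → signal over the whole session, then
ΔF/F = (signal − fit)/fit. This removes shared artifacts (motion, slow
drift) while preserving sensor-specific transients; a zero-variance
isosbestic triggers a flagged fallback to the session-median baseline.
Recordings are downsampled to 10 Hz by non-overlapping window means (the
source rate must be an integer multiple; a trailing partial window is
truncated). Peri-tone traces are Z-scored per trial against the 2-s pre-tone
baseline. Trials are pooled by behavioral generalization: freezing > 75% is
the high pool, < 25% the low pool, with strict inequalities so boundary
trials are excluded; empty pools are flagged, not errors. Peak response is
the maximum Z in the tone window; for pool contrasts the peak of the pooled
mean trace is the robust statistic (per-trial maxima are inflated by noise
in proportion to trial count, which biases pool differences toward zero).

## Behavior

Freezing is the percentage of frames scored frozen within a half-open
interval; per-tone percentages are averaged into blocks of 2 in presentation
order, keeping a trailing unpaired tone as its own block (odd tone counts
occur in partial-reinforcement designs). The generalization index is
freezing to the neutral cue/context *relative to* the trained reference; the
exact functional form is a genuine design choice, and we default to the
ratio neutral/reference (scale-invariant, undefined and flagged at reference
0) with the difference available behind a flag for sensitivity analyses.

## Human startle and endocannabinoids

Startle is the peak-to-peak EMG amplitude per trial. Within each subject and
phase, cue responses are standardized by dividing the cue-trial mean by the
ITI-trial mean, removing individual gain; the subtraction variant is
available behind a flag. At recall only the first 4 trials per cue enter
(the generalization-test window, before extinction sets in). CS
generalization is (CS⁻) − (CS⁺) of the standardized values. Endocannabinoid
baselines are the mean of two time points, natural-log transformed (base
affects slope units only, not correlations); subjects with non-positive
values cannot be log-transformed and error out rather than silently
dropping. The association is a complete-case Pearson correlation plus a
linear regression with a 1,000-resample case bootstrap percentile CI for the
slope, under a required seed; complete-case accounting (n in = n out +
n dropped) is preserved in the result.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture. It emulates:

* **Calcium sessions**: each neuron is i.i.d. Gaussian frame noise plus, for
  its archetype's stimulus types, a tone-locked difference-of-exponentials
  kernel (rise 0.5 s, decay 3 s, peak-normalized; negated for suppressed
  archetypes) with multiplicative trial gain `max(0, 1 + N(0, 0.2))`.
  Amplitude is expressed in units of the SD of 1-s-binned baseline noise, so
  "amplitude 6" plants a ~6-Z response under the pipeline's own
  normalization. Archetype counts use largest-remainder apportionment, so
  planted fractions are exact. Seeding is counter-based per neuron:
  enlarging a population never reshuffles existing neurons.
* **Photometry**: shared slow artifact on both channels, transients on the
  signal channel only, with peak amplitude a linearly decreasing function of
  trial freezing (the planted inverse coupling between generalization and
  sensor response), plus a binary freezing series realizing the per-trial
  percentages.
* **Human cohorts**: per-subject multiplicative startle gain (removed by ITI
  standardization), 4 trials per cue and phase, and two positive
  endocannabinoid measurements whose log-mean correlates with the planted
  generalization score at the requested Pearson r in expectation. Trial
  noise is kept small relative to between-subject spread so measurement
  attenuation of the correlation is negligible (< 0.01 at the defaults).

Session defaults — 10 Hz, 15-s tones, 4 NT + 4 CS⁺ presentations
interleaved, 30-s inter-tone intervals, 30 s of pre-session baseline — are
the smallest schedule that exercises every pipeline stage (2 blocks of 2 per
stimulus, baselines fully inside inter-tone intervals); recovery statistics
are computed at 200–400 neurons, where binomial error on proportions is
1–2 percentage points.

What the generator does **not** emulate: biophysical calcium indicator
dynamics, spike-to-fluorescence nonlinearity, slow drift (the per-block
baseline normalization makes it orthogonal to the classification contract),
correlated noise across neurons, motion artifacts, or ensemble drift across
days. Passing recovery tests therefore establishes that the pipeline's
statistics are correct and well-calibrated *given* tone-locked transient
responses in Gaussian noise — not that the classifier is optimal for real
indicator kinetics.

## Problem sizes and runtime choices

The shipped tests and the reproduction script use 10⁴ traces for the
classifier-oracle comparison, 10 seeds × 400 neurons for taxonomy recovery,
50 random 12-neuron instances for the Ward oracle, 1,000 replicates for the
null-calibration rates (KS at n = 200 per group; correlation at n = 80),
200 cohort seeds for recovery of the planted human correlation, and 10
seeds for the photometry direction check. These sizes put Monte-Carlo error
comfortably inside each test's tolerance while keeping a full run in the
low minutes on one core.

## Known limitations

* Classification operates on block-averaged traces by default (per-trial
  mode exists for the stability analysis); with very few presentations the
  two modes can disagree for weakly responsive neurons.
* The 5%-of-maximum dendrogram cut is sensitive to the largest merge height
  and, on unstructured data, yields many singleton clusters; it is the
  prescribed recipe, not an optimality claim. The threshold is exposed.
* The Mahalanobis distance with ~15 reference points in 15 dimensions leans
  on the shrinkage term; distances in near-null covariance directions are
  regularization-dominated. Comparisons between groups use identical K and
  bin counts, so this affects both arms symmetrically.
* The human module implements the correlation/regression analysis;
  factorial ANOVA interaction modelling is left to standard model-fitting
  functions on the returned per-subject tables.
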