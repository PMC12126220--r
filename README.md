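# fearsemble

Analysis pipeline for fear-generalization experiments that combine
single-neuron calcium imaging in prelimbic prefrontal cortex (PL), fiber
photometry, freezing behavior, and human fear-potentiated startle with plasma
endocannabinoid measurements.

## The problem

After auditory fear conditioning, an animal should freeze to the conditioned
tone (CS⁺) but not to a novel tone (NT); a human should startle more to the
threat cue (CS⁺) than to the safe cue (CS⁻). *Fear generalization* is the
erosion of that distinction, and it has a neural signature: PL neurons that
are normally CS⁺-specific start responding to neutral stimuli too, and the
population activity trajectories for the two stimuli converge. This package
implements the quantitative pipeline for measuring that erosion at every
level — single neurons, ensembles, population geometry, behavior, and human
psychophysiology — together with a synthetic-data generator with planted
ground truth, so that every stage has a recovery test.

## The core methods

**Peri-tone Z-scoring.** Calcium traces (neurons × time, 10 Hz) are aligned
to tone onsets, averaged into 1-s bins over a 15-s pre-tone baseline and the
15-s tone period, averaged into blocks of 2 presentations, and Z-transformed
per neuron × block against that block's own baseline bins:
`z = (x − μ_baseline) / σ_baseline`.

**Responsive-neuron classification.** A neuron is (+)responsive to a
stimulus if any 2 consecutive tone-period bins exceed +3 Z, (−)responsive if
any 2 consecutive bins fall below −3 Z, else non-responsive. Crossing the NT
label with the CS⁺ label gives 3² = 9 response types; the "dual" aggregate
(both labels non-NONE) indexes generalization at the ensemble level. Group
differences in type proportions are tested with Fisher's exact test.

**Stimulus preference.** Per neuron,
`|Z_NT − Z_CS+| / (|Z_NT| + |Z_CS+|)`, signed positive when |Z_NT| is larger,
negative when |Z_CS+| is larger, with Z_NT and Z_CS+ the whole-session-
normalized average responses. Distributions are compared between groups with
the two-sample Kolmogorov–Smirnov test.

**Clustering.** Concatenated NT+CS⁺ Z-traces are rescaled from [−5, 5] onto
[−3, 3] (saturating), Ward-linked with Euclidean distance, cut at 5% of the
maximum linkage, and cluster profiles are remapped to the unscaled traces.

**Population geometry.** Per-group NT and CS⁺ traces are concatenated, the
larger group subsampled (seeded) to match the smaller, PCA applied with time
bins as observations and neurons as features, and the NT-vs-CS⁺ separation
quantified with the 15-dimensional Mahalanobis distance per bin and the
instantaneous Euclidean distance over the first 15 components.

**Photometry and behavior.** Two-channel photometry is corrected by
regressing the isosbestic onto the sensor channel (ΔF/F = (signal − fit) /
fit), Z-scored per trial against the 2-s pre-tone baseline, and pooled into
high- (>75% freezing) and low- (<25%) generalization trials. Freezing is
quantified per interval and summarized as a generalization index (neutral
cue/context freezing relative to the trained reference).

**Human analysis.** Startle amplitudes are standardized to each subject's
mean ITI startle; CS generalization = (CS⁻) − (CS⁺) at recall (first 4
trials per cue); plasma endocannabinoid baselines are log(mean of two time
points); the association is a Pearson correlation plus a linear regression
with a 1,000-resample case bootstrap CI for the slope.

## Worked example

```r
library(fearsemble)

pop  <- population_spec(400, c(dual_plus = 0.2, cs_plus = 0.3, none = 0.5),
                        response_amplitude = 6, seed = 1)
sim  <- generate_session(pop, session_spec())

zt_nt <- ztransform_pretone(block_average(
  align_and_bin(sim$traces, sim$schedule, "NT")))
zt_cs <- ztransform_pretone(block_average(
  align_and_bin(sim$traces, sim$schedule, "CS_PLUS")))

tx <- response_taxonomy(classify_neurons(zt_nt), classify_neurons(zt_cs))
tx
#> <response_taxonomy> 400 neurons; dual-responsive 20.2%
#>   PLUS/PLUS       81  (20.2%)
#>   NONE/PLUS      120  (30.0%)
#>   PLUS/NONE        2  (0.5%)
#>   MINUS/NONE       1  (0.2%)
#>   NONE/NONE      196  (49.0%)
```

The planted composition (20% dual-responsive, 30% CS⁺-only, 50% silent) is
recovered to within a percentage point: 81/400 neurons are classified
PLUS/PLUS (respond to both tones), 120 respond to CS⁺ only, and 3 noise
neurons cross the threshold spuriously (a ~1% false-positive rate,
consistent with the ±3 Z / 2-consecutive-bin rule). The preference-strength
means in the snippet below come out at 0.99 for planted CS⁺-only neurons and
0.17 for balanced dual responders.

Preference and geometry on the same session:

```r
z_nt <- ztransform_whole_session(sim$traces, sim$schedule, "NT")
z_cs <- ztransform_whole_session(sim$traces, sim$schedule, "CS_PLUS")
pref <- preference_strength(z_nt, z_cs)
mean(abs(pref$value[sim$truth$archetype == "cs_plus"]))   # near 1: selective
mean(abs(pref$value[sim$truth$archetype == "dual_plus"])) # near 0: generalizing
```

Or run everything at once:

```r
res <- run_pipeline(list(seeds = list(session = 1, match = 2)),
                    out_dir = "run1")
```

which writes the taxonomy, preference table, linkage, cluster assignments,
PCA variance spectrum, and a manifest with digests of every output.

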