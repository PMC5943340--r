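---
title: "Estimating the heritability of sleep EEG topography: methods and design"
author: "sleeptopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the heritability of sleep EEG topography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleeptopo)
```

## The scientific problem

The scalp distribution of sleep EEG spectral power — how much delta, sigma
or beta power each electrode carries relative to the rest of the montage —
is a stable, individual-specific trait. In a twin design, comparing the
topographic similarity of monozygotic (MZ) co-twins, who share essentially
all their genes, with dizygotic (DZ) co-twins, who share about half of the
segregating ones, separates genetic from environmental contributions to
that trait. `sleeptopo` implements the full chain from multichannel sleep
recordings to Falconer heritability estimates, together with a synthetic
cohort generator with known ACE structure so that every stage can be
validated without access to any real recordings.

## Pipeline model

**Spectra.** Recordings are decimated to the analysis rate (a zero-phase
FIR low-pass with cutoff at 0.8 x the new Nyquist precedes decimation;
its forward-backward application attenuates content at the new Nyquist by
well over 60 dB), re-referenced to the average of all good derivations,
and cut into 30-s scoring epochs. Each epoch's power density spectrum is
the mean of six contiguous non-overlapping 5-s Hanning-windowed
periodograms, so the frequency resolution is 0.2 Hz; the density scaling
divides by the sampling rate times the window power (the absolute scale
cancels later under topographic normalization, but a fixed convention
makes the spectral core testable against Parseval and a direct-DFT
oracle). The DC bin is discarded and the analysis retained to 44 Hz.

**Artifact rejection.** A channel-epoch is flagged when its summed power
in a low (0.8--4.6 Hz) or high (20--40 Hz) screening band exceeds a
multiple (defaults 4 and 3) of the centered moving median (half-width 10
epochs) of that channel-band series, computed within the same stage class
— NREM (stages 2 + slow-wave sleep) and REM separately, because REM's much
lower slow-wave power would otherwise inflate NREM thresholds. The
multiplicative, subject-relative threshold makes flagging invariant to
global gain differences between recordings. Channels flagged in more than
20% of epochs are excluded outright; epochs in which more than 10% of the
good channels are flagged are dropped; the interactive visual-inspection
step of a human pipeline is represented by an optional user-supplied drop
list, never guessed. Channel exclusion precedes the final average
reference, so condemned channels do not contaminate it. All of these
constants live in `ArtifactPolicy()` and are surfaced in the run
configuration; their defaults were calibrated only against the package's
own injection/recovery simulations.

**Topography.** For each pair, the maximal common number of clean NREM and
REM epochs is used (each twin contributes its first n clean epochs in
chronological order; the unrelated and retest comparisons reuse the same
per-subject maps). Mean spectra are normalized per frequency bin: each
derivation's power is divided by the total across derivations at that bin,
so every bin is a point on the channel simplex and global power
differences between subjects cancel. Bands (delta 1--4.6 through gamma2
34.2--44 Hz, membership by 0.2-Hz bin center, inclusive edges) and 1-Hz
bins (five 0.2-Hz bins each, labelled by upper edge) are aggregated as
unweighted means of the per-bin fractions, which preserves the sum-to-one
invariant; NREM excludes stage 1, the conventional choice for spectral
analysis. Excluded channels are repaired at the map level by the
inverse-distance-weighted mean of the 3 nearest good channels followed by
per-band renormalization — cheaper than signal-level interpolation and
sufficient because all downstream statistics consume maps.

**Similarity and heritability.** Per band, state and time point, the
topographic similarity of a pair is the Pearson correlation of the two
channel vectors. Four groups are compared: MZ co-twins, DZ co-twins, all
cross-family pairs (NR, both zygosities pooled), and each subject against
itself six months later (Self). Correlations are Fisher-z transformed
before averaging; group means are back-transformed for reporting, and the
per-pair values are exported so external ANOVA tooling can consume exactly
the quantities the pipeline computed. Heritability uses Falconer's
formula, h^2 = 2(r_MZ − r_DZ), and shared environment
c^2 = r_MZ − h^2 = r_DZ − h^2/2; estimates are reported raw with
out-of-range flags (Falconer estimates can leave [0, 1] by construction),
with clipping available as an explicit, always-flagged option. Whether
Falconer is applied to back-transformed means (default) or z-domain means
is an exposed option, since averaging domain and estimation domain need
not coincide. Cross-state similarity correlates the NREM and REM
grand-average maps per band, with a two-sided p-value from the plain
correlation t-statistic on (channels − 2) degrees of freedom; no
spatial-autocorrelation correction is attempted, so these p-values are
anti-conservative for spatially smooth maps and are not comparable to
published tables computed with unknown corrections.

## The synthetic cohort generator

Each band's topography is built from a shared population template plus a
unit-variance subject deviation sqrt(a2)·A + sqrt(c2)·C + sqrt(e2)·E: A is
identical in MZ co-twins and correlated 0.5 in DZ co-twins (constructed
explicitly as 0.5·A1 + sqrt(0.75)·A′, which has the same law as a joint
multivariate draw), C is shared within a pair, E is unique. Across the two
assessments A and C persist while E is partially re-drawn with correlation
`retestStability` (default 0.85, echoing the high within-subject retest
correlations such designs report; no quantitative retest model exists to
estimate it from, so it is a free parameter). Spatial structure comes from
circular moving-average smoothing of channel-indexed white noise on a
synthetic circular layout — real electrode geometry is not needed for
validation, only relative distances.

Two rendering modes serve two purposes. *Linear* maps (template +
deviation) admit a closed-form expected pair correlation,
(v + a2·rho_A + c2·rho_C)/(v + 1) with v the template variance — the exact
oracle used in tests. *Compositional* maps, exp(template + deviation)
renormalized per band, are positive, sum to one and look like real
normalized topographies; their oracle is Monte-Carlo only. The closed form
also documents a structural property of Falconer's formula: a shared
template inflates all group correlations equally and attenuates estimated
h^2 to a2/(1 + v). Only when v = 0 does the Falconer estimate recover the
generating a2 directly; the parameter-recovery study therefore sets v = 0,
and a separate study checks the attenuated value at v = 1. Those oracle
studies also use white channel fields (smoothness 0): smoothing leaves the
expected correlation unchanged but reduces the effective number of
independent channels, widening the sampling variance around the closed
form; elsewhere the generator defaults to a smoothness of 2 channels for
realism.

At the signal level, each 30-s epoch is synthesized in the frequency
domain: every channel receives independent band-limited Gaussian noise
whose in-band amplitude is proportional to the square root of the
channel's target normalized band power times a stage-dependent band
amplitude (defaults follow the canonical profile: slow-wave dominance in
SWS, spindle-band power in stage 2, attenuated slow activity in REM), plus
a 1/f background component common to all channels, which average
referencing removes. Hypnograms come from a first-order Markov chain over
Wake/S1/S2/SWS/REM started at its stationary distribution. Artifact epochs
multiply randomly chosen channels by a gain factor and are logged as
(subject, epoch, channel) triples, so detection sensitivity and
false-positive rates can be scored exactly. A master seed spawns
independent named substreams (maps, hypnogram, signal, artifacts) so
adding draws to one stage never perturbs another; identical inputs give
byte-identical outputs.

What the generator does *not* emulate: discrete spindle and slow-wave
events, sleep cycles, ocular and myographic artifact morphology, real
electrode geometry, or volume-conduction correlation between channels.
Passing the round-trip studies therefore shows that the pipeline's
statistics are correct under the stated noise model, not that the artifact
thresholds are optimal for any particular real recording system.

## Validation studies and problem sizes

The package's standing validation (run by the test suite and recomputed by
`scripts/acceptance.R`) uses these sizes, chosen to give comfortable
statistical margins at interactive runtimes on one CPU:

- spectral oracle: 100 random 30-s epochs, 58 channels, 250 Hz, against an
  independently coded direct DFT (agreement demanded to 1e-10 relative);
- Falconer algebra: 1e4 random correlation pairs, machine-precision
  identities;
- parameter recovery: a 3 x 3 grid of a2 in {0, 0.25, 0.5} by c2 in
  {0, 0.3, 0.6}, 500 MZ + 500 DZ pairs per cell, linear mode, template
  variance 0, smoothness 0 — group means within 0.03 of the closed form,
  h^2 and c^2 within 0.05 of truth;
- template attenuation: v = 1, a2 = 0.5, estimate within 0.08 of 0.25;
- signal-level round trip: 4 MZ + 4 DZ pairs at 58 channels, 440-epoch
  nights of alternating 10-epoch S2/REM blocks (so both states supply at
  least 200 clean epochs after exclusions), synthesis at 100 Hz (the
  band content ends at 44 Hz, leaving ample Nyquist headroom), 5% of
  epochs corrupted at gain 10 on 4 channels each; demanded: detection
  sensitivity at least 0.95 at a false-positive rate at most 0.05,
  recovered-vs-true band topography correlation above 0.9 everywhere, and
  mean r_MZ >= r_DZ >= r_NR in every band and state;
- null calibration: 1e4 independent random map pairs; the fraction of
  cross-state p-values below 0.05 must sit within 0.01 of 0.05;
- determinism: a small on-disk cohort analyzed twice must yield
  byte-identical tables.

## Numerical and design choices

- Periodogram scaling is one-sided density, 2/(fs · sum(w^2)); the 5-s
  windows are contiguous from epoch start; epoch k covers samples
  [k·30·rate, (k+1)·30·rate), 0-based and half-open.
- The Hann window is the periodic variant, the standard choice for
  averaged periodograms.
- The anti-alias filter is specified by its contract (>= 60 dB at the new
  Nyquist) rather than a named design; the implementation uses a
  reflection-padded forward-backward FIR with unity DC gain.
- Moving medians clip their window near series ends (`runmed`,
  median end-rule); series shorter than the window fall back to the class
  median.
- Undefined correlations (zero-variance maps) are excluded from their
  cell with a warning, never imputed.
- Epoch matching uses the first n clean epochs chronologically; whether
  the original analysis sampled epochs differently is unknowable, and the
  chronological rule is deterministic.
- The unrelated group is all cross-family unordered pairs at one time
  point, sexes pooled; a subject-exclusion list lets users reproduce
  cohorts in which some subjects were unavailable, since published NR pair
  counts depend on exactly who was excluded.
- EDF is the recording interchange format (a minimal 16-bit classic-EDF
  reader/writer is built in); stage labels are normalized through an alias
  table covering classic and AASM conventions, with N3/S3/S4 mapped to
  SWS.

## Known limitations

Falconer estimation from group correlations cannot separate additive
genetics from non-additive effects, can exceed [0, 1], and — as the
template-attenuation study shows — underestimates heritability whenever a
population-wide topographic template inflates all group correlations. No
SEM-based ACE fitting, confidence intervals beyond an optional bootstrap
over pairs, or absolute-power analyses are provided. The cross-state
p-values ignore spatial autocorrelation. The synthetic signal model is
stationary band-limited noise and does not reproduce sleep
microstructure.
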