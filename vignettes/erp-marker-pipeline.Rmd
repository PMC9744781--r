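---
title: "Category-specific ERP markers: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Category-specific ERP markers: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Event-related potentials (ERPs) carry reliable markers of what kind of
stimulus a person is perceiving: faces evoke an occipitotemporal N170,
checkerboards an occipital N80, spoken language a centroparietal N400, and so
on. A brain-computer-interface (BCI) system that knows the spatiotemporal
coordinates of such markers can, in principle, decode the semantic category
of a percept from averaged EEG alone. `erpmarkers` implements that whole
chain as a tested pipeline: it *simulates* category-specific multichannel
EEG under a fixed passive-stimulation paradigm, *preprocesses* it the way an
ERP lab would (epoching, peak-to-peak artifact rejection, baseline
correction, trial averaging), *extracts* the mean area amplitude of sixteen
literature-defined markers, runs the *repeated-measures ANOVA* battery that
establishes category sensitivity, and *decodes* the stimulus category with a
transparent nearest-centroid classifier.

Because raw human EEG for this paradigm is not publicly deposited, the
synthetic-data generator is a first-class module, not a test fixture: it
defines the study conditions under which every downstream claim is checked.

## The paradigm and the additive signal model

The simulated experiment presents 10 stimulus categories - 7 visual (infant,
adult and animal faces; human bodies; written words; checkerboards; objects)
and 3 auditory (spoken words, emotional vocalizations, music) - with 40
trials per category: 280 visual stimuli in 8 runs and 120 auditory stimuli
in 4 runs, 400 events per subject. Stimuli last 1500 ms with an
inter-stimulus interval drawn uniformly from 500 +/- 100 ms, so successive
onsets are 1900-2100 ms apart. EEG is synthesized at 512 Hz on a 126-channel
10/5 montage (plus bipolar HEOG/VEOG), referenced to averaged ears.

Each single trial is modeled additively: the recorded segment is
`x_i = s_i + n_i`, where `s_i` is the deterministic category-specific ERP
signal and `n_i` is background EEG noise. Averaging `m` kept trials
suppresses the noise by `1/sqrt(m)` - the property the averaging module's
tests pin down for `m` in {5, 10, 20, 40}.

### Component templates

`s_i` is a sum of 16 component templates, one per marker in
`marker_registry()`. A template is rank-1 in space-time: a Gaussian time
course (peak latency inside the marker's measurement window; sd roughly a
quarter of the window) times a spatial map that equals 1 at the marker's
registered electrodes and decays as `exp(-(d/15 deg)^2)` with great-circle
distance `d` to the nearest center. Each category has a signed peak
amplitude per template; categories absent from a template contribute
nothing.

The source literature constrains *orderings*, not magnitudes (its amplitude
figures are graphical), so absolute amplitudes are package defaults on a 1-8
microvolt scale with at least 1 uV between every constrained pair - e.g.
N170 is -8 uV to human faces vs -5 uV to animal faces; the auditory P300 is
+6 uV to music vs +3/+3.5 uV to voice. The word-sensitive N170 is built
left-lateralized: left-hemisphere amplitudes differ across words,
checkerboards and objects (-9/-5/-3 uV) while right-hemisphere amplitudes
are equal (-4 uV each), which reproduces both the pooled word advantage and
the hemisphere-restricted category effect. The cross-modal PN300 template is
-4 uV on every visual trial and +4 uV on every auditory trial at Fz/Cz - a
category-constant shift within each modality, so it can never flip a
within-modality ordering even though its window overlaps other markers.

Because several markers share electrodes and overlapping windows (the
anterior N2, AN and frontal P300 all load on midline frontal sites), the
*measured* window means include cross-component leakage. The template
latencies, widths and amplitudes were chosen once, at design time, such that
the noiseless pipeline reproduces every registered ordering after that
leakage; the test suite asserts this invariant exactly, and
`validate_templates()` re-checks the amplitude maps themselves on every
call.

Inter-individual variability is a log-normal multiplicative gain per subject
and per component (`subject_gain_sd = 0.2`, mean gain 1). The gain scales a
whole component - all categories alike - which preserves each marker's
orderings within subject while making absolute amplitudes vary across
subjects, the pattern described for real cohorts.

### Background noise

`n_i` is channel-wise independent noise with three spectral ingredients:

* a flat (white) floor,
* a `1/f^a` power-law bulk (default exponent `a = 1`), and
* a 10 Hz alpha-band oscillation with a slowly varying random envelope.

The broadband part is realized as one white stream passed through a linear
shaping filter: a direct (flat) path plus a cascade of nine first-order
pole/zero sections whose log-spaced corners approximate an `f^(-a/2)`
magnitude between ~0.01 and ~100 Hz. A log-periodogram regression over
1-30 Hz recovers the configured exponent to well within +/-0.1 (the test
tolerance is the +/-0.3 the design allows). The alpha component is an
independently drawn quadrature envelope at 4 Hz, linearly interpolated and
modulated onto a 10 Hz carrier - giving the waxing-and-waning alpha bursts
of resting EEG rather than a fixed sinusoid. Each channel is rescaled so its
total standard deviation equals `noise_sd` (default 4 uV), with the alpha
part contributing `alpha_amplitude` (default 1.5 uV RMS) of that budget.

Two deliberate simplifications: channels are spatially *independent* (no
volume-conduction correlation), and the default `noise_sd` is below typical
raw-scalp values. The two choices compensate for each other with respect to
the rejection rule: with 128 independent channels, the maximum peak-to-peak
excursion over channels grows with the channel count, and realistic
amplitudes would push clean epochs over the 50 uV criterion that real
(spatially correlated) EEG stays under. The chosen default keeps the clean
epoch peak-to-peak comfortably below threshold so that rejection is driven
by the modeled artifacts, as in the source protocol (~5% rejection).

### Ocular artifacts

Blinks are biphasic 300 ms deflections at Poisson-distributed times:
peak-to-peak `blink_amplitude` (120 uV) on VEOG, 25% on HEOG, and an
anterior-posterior exponential falloff over the scalp (30 deg space
constant from the anterior pole). The default `blink_rate` of 1.75/min is the
generator's calibration target for the rejection stage: at these defaults a
20-subject cohort rejects ~5% of its 8000 epochs (the accepted band is
3-7%). The low rate reflects instructed blink suppression during trials.
Muscle and amplifier artifacts are not modeled separately; the rejection
rule does not care about the artifact's physiological origin, only its
amplitude.

### Reproducibility

Every subject's data is fully determined by `(config, subject_index)`: the
per-subject seed is derived from the cohort seed, and all draws - schedule
shuffling, ISIs, component gains, noise (via an internal xoshiro256++
stream seeded from R's RNG), blink times - flow from it. Identical seeds
give bit-identical recordings.

## Preprocessing conventions

* **Epoch geometry.** Epochs span -100 to +1500 ms around stimulus onset.
  Millisecond bounds convert to samples by `floor(ms/1000 * fs)` with
  half-open ends - the single convention used everywhere. At 512 Hz that is
  51 baseline samples plus 768 post-stimulus samples (768 = 1.5 s x 512),
  819 in total; the 768-sample post-stimulus block is the canonical epoch
  length of the averaging algebra.
* **Artifact rejection.** An epoch is rejected iff the within-epoch
  max-minus-min on *any* channel - scalp and EOG alike - strictly exceeds
  50 uV. "Exceeding" is read strictly: a peak-to-peak of exactly 50 uV is
  kept. The protocol this emulates does not state whether EOG channels were
  scanned; both are scanned here, and the rejection log records the worst
  channel per rejected epoch so either subset can be audited after the
  fact.
* **Baseline correction** subtracts the per-epoch, per-channel mean over
  [-100, 0) ms; it is idempotent and leaves the baseline mean at zero to
  float precision.
* **Band-pass filtering.** The acquisition emulated here records DC;
  the 0.016-30 Hz band-pass of the source protocol was applied for display
  only. The pipeline therefore rejects/averages unfiltered data and offers
  `bandpass()` for waveform display. The filter is zero-phase by
  construction: a frequency-domain filter whose magnitude is the *squared*
  Butterworth response - exactly the response forward-backward IIR
  filtering would give - so the half-amplitude (gain 0.5) points land
  exactly on the stated corner frequencies. A time-domain IIR realization
  was rejected because a 0.016 Hz high-pass at 512 Hz (normalized corner
  6e-5) puts poles too close to the unit circle for reliable
  double-precision filtering of 13-minute records.

## Markers and feature extraction

`marker_registry()` fixes the 16 markers: name, modality, measurement
window, electrode set, polarity, the categories it is measured on, and the
expected category orderings. "Mean area amplitude" is the arithmetic mean of
baseline-referenced voltage over the window (units uV), per electrode, plus
the mean pooled over the marker's electrodes - not a uV*ms integral.

Two structural decisions resolve ambiguities in the source protocol: the
living-stimuli N170 analysis covers the three *face* categories (the
printed degrees of freedom imply 3 levels), while N2/P2/P300/AN cover all
four living categories; and where the narrative text and the measurement
protocol disagree on a window (e.g. an occipitoparietal P2 at "280-380 ms"
in the discussion vs 300-350 ms in the protocol), the registry follows the
measurement protocol.

## The statistical battery

`rm_anova()` implements the univariate repeated-measures ANOVA for balanced,
fully crossed within-subject designs directly: for each effect, subjects'
cell vectors are projected onto an orthonormal effect-contrast basis
(Kronecker products of per-factor Helmert contrasts and averaging vectors);
the effect and its subject-interaction error term are sums of squares of
the projected scores. This reproduces `stats::aov`'s error-stratum
decomposition to 1e-8 (a test asserts this against both `aov` and an
explicit design-matrix GLM projection). The same projected scores give the
Greenhouse-Geisser epsilon - `tr(S)^2 / (d tr(S^2))` of their covariance,
clipped to [1/d, 1] - which equals 1 for any 2-level factor and under
compound symmetry, and reaches 1/d for rank-1 covariance. Epsilon-adjusted
p-values use `pf(F, e*df1, e*df2)`; partial eta squared is
`SS_effect / (SS_effect + SS_error)`.

Tukey HSD post hoc comparisons use the studentized-range distribution with
the repeated-measures error term of the factor under test (its
subject-interaction mean square, with n = number of subjects per level
mean). The implementation is checked against numerical quadrature of the
studentized-range CDF and against `TukeyHSD` on a balanced between-subjects
design.

Contrasts on negative components are evaluated on polarity-adjusted values
(sign-flipped, so "larger" uniformly means larger adjusted value / more
negative voltage); signed amplitudes are retained in all outputs. The
`run_paper_contrasts()` battery runs category x electrode ANOVAs (category
x site x hemisphere where a marker is measured at homologous lateral
pairs; modality x electrode for PN300) and scores every registered
ordering: expected direction *and* Tukey-adjusted p below the 0.01 level.

## The decoder

Classification operates on per-subject averaged evokeds (m ~ 40 kept
trials), not single trials - small components are simply invisible at the
single-trial SNR. The decoder is deliberately parameter-free: stage 1 gates
sensory modality on the sign of the pooled PN300 amplitude (negative ->
visual, non-negative -> auditory); stage 2 picks the nearest category
centroid by Euclidean distance in z-scored marker-feature space within the
gated modality. Standardization statistics and centroids come from the
training subjects only; exact ties resolve lexicographically and are
flagged. Leave-one-subject-out cross-validation on the default 20-subject
cohort yields ~96% 10-class accuracy, comfortably above the ~70%
meaningful-communication threshold and at 100% on the coarser
visual-vs-auditory distinction. Chance for the 10-class balanced problem is
10%; on uninformative features the decoder sits inside the binomial
confidence band around chance (the modality gate then routes each evoked
essentially at random, and 0.7 x 1/7 + 0.3 x 1/3 = 10% as well).

## What the tests do and do not show

The generator emulates: the trial counts, timing and run structure of the
paradigm; realistic 1/f-plus-alpha background spectra; blink-driven epoch
loss near 5%; marker topographies and latencies; between-subject amplitude
variability with preserved orderings. It does not emulate: volume-conducted
spatial noise correlation, electrode drift or impedance artifacts,
latency jitter between trials, habituation across runs, or any content
difference *within* a category (every trial of a category carries the same
deterministic signal). Passing tests therefore demonstrate that the
pipeline, statistics and decoder are correct and recover what was injected
under faithful study conditions - not that real human EEG would yield the
same effect sizes.

Problem sizes used by the checks: the cohort-level properties (rejection
calibration, ordering recovery, decoder accuracy) run on full-scale default
cohorts - 20 subjects x 400 epochs x 128 channels x 819 samples - across
10 seeds. Purely statistical properties run at the natural scale of the
statistic: the type-I-error calibration uses 500 null feature tables
(20 subjects x 3 conditions of Gaussian features) rather than 500 full EEG
cohorts, which is distributionally equivalent for the F statistic under
test; the chance-level decoder property likewise uses Gaussian feature
tables.

## Known limitations

* The exact 126-label electrode set of the emulated recording system is not
  recoverable; the montage is a standard 10/5 subset frozen as a text
  asset, guaranteed to contain all 26 analysis electrodes. Positions are
  idealized spherical angles - adequate for the qualitative topographies
  produced here, not for source modeling.
* Continuous data I/O is in-memory plus plain text (events TSV, features
  and waveforms CSV); no binary EEG interchange format is written.
* The ANOVA engine requires balanced, fully crossed within-subject designs
  (exactly what the pipeline produces) and refuses anything else rather
  than imputing.
* One printed amplitude anchor in the source material (-0.34 uV for the
  anterior-positivity animal-vs-adult difference) conflicts in sign with
  its own verbal description; it is not used for calibration.
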