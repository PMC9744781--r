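# erpmarkers

Category-specific ERP markers of visual and auditory perception: simulation,
extraction, statistics and decoding.

## What this package is for

Event-related potentials (ERPs) carry reliable signatures of *what kind* of
stimulus a person is perceiving: human faces evoke an occipitotemporal N170
(150–190 ms) that is larger than for animal faces; checkerboards drive an
occipital N80 (90–130 ms); music evokes a larger frontocentral P300
(400–500 ms) than the human voice; speech a larger centroparietal N400
(450–650 ms) than music; and visual vs. auditory stimulation flips the sign
of a fronto-central 200–400 ms deflection (PN300). Such markers are
candidate building blocks for brain–computer interfaces (BCI) that decode
the semantic category of a percept from averaged EEG.

`erpmarkers` is for researchers who want that full chain as auditable,
tested code:

1. **Simulate** continuous 126-channel (10/5 montage) EEG at 512 Hz under a
   passive audiovisual paradigm — 10 stimulus categories × 40 trials
   (280 visual stimuli in 8 runs, 120 auditory in 4), 1500 ms stimuli,
   ISI 500 ± 100 ms. Single trials follow the additive model
   `x_i = s_i + n_i`: deterministic component templates `s_i` (peak
   amplitudes encode every category ordering above) plus background noise
   `n_i` (white + 1/f + 10 Hz alpha) and blink artifacts.
2. **Preprocess**: epoch −100…+1500 ms (51 + 768 samples), reject any epoch
   whose peak-to-peak amplitude exceeds 50 µV on any channel (≈5 % of
   epochs at default settings), baseline-correct to the −100–0 ms mean.
3. **Average** kept trials per subject and category
   (`ERP_i = (1/m) Σ_k a(i,k)`, SNR gain `1/√m`) and pool grand averages.
4. **Extract** the mean area amplitude (µV) of 16 markers over their
   registered windows and electrode sets into a tidy feature table.
5. **Test** each marker with repeated-measures ANOVAs
   (category × electrode × hemisphere) with Greenhouse–Geisser ε, adjusted
   p, partial η², and Tukey HSD post hocs — all implemented in the package
   and verified against independent oracles.
6. **Decode** stimulus category from marker features with a two-stage
   nearest-centroid classifier (PN300 sign gates modality, then nearest
   centroid in z-scored feature space), evaluated by leave-one-subject-out
   (LOSO) cross-validation against the ~70 % meaningful-communication
   threshold.

## Worked example

```r
library(erpmarkers)

# a reduced cohort for a quick tour (defaults: 20 subjects, 40 trials/category)
cfg <- sim_config(n_subjects = 6, seed = 1)
cohort <- simulate_cohort(cfg)
cohort
#> <erp_cohort> 6 subjects, 2400 epochs (5.6% rejected)

# the ANOVA battery over all 16 markers
contrasts <- run_paper_contrasts(cohort$features)
contrasts
#> <erp_contrasts> 16 markers, 37 registered orderings, 36 recovered at alpha = 0.01
head(format_contrast_report(contrasts), 3)
#> [1] "N170_living category: [F(2, 10) = 115.84, p = 1.2e-07; eps = 0.93, adjusted p = 3.1e-07; partial eta2 = 0.96]"
#> [2] "N170_living site: [F(1, 5) = 0.06, p = 0.82; eps = 1.00, adjusted p = 0.82; partial eta2 = 0.01]"
#> [3] "N170_living hemisphere: [F(1, 5) = 0.08, p = 0.79; eps = 1.00, adjusted p = 0.79; partial eta2 = 0.02]"

# marker-based decoding, leave-one-subject-out
evaluate_loso(cohort$features_full)
#> <erp_evaluation> leave-one-subject-out: accuracy 95.0% (modality 100.0%) over 60 evoked responses
```

The first block simulates and preprocesses six subjects; 5.6 % of their
2400 epochs trip the 50 µV rejection rule (the calibration target is ~5 %).
The contrast report mirrors the bracket notation of the ERP literature: the
living-N170 category effect is significant with the injected direction
(larger response to human than animal faces), and 36 of the 37 registered
orderings are recovered at p < 0.01 even at this reduced cohort size (all
37 at the default 20 subjects). The decoder identifies the correct category
for 57 of 60 held-out evoked responses (95 %) and the correct sensory
modality for all of them — above the ~70 % threshold usually quoted for
meaningful BCI communication.

Waveforms and topographies:

```r
sub <- process_subject(cfg, 1)
plot_waveforms(list(sub$evokeds$adult_face, sub$evokeds$music),
               channels = c("Fz", "Cz", "Pz"))   # negative-up ERP convention
plot_topomap(sub$evokeds$adult_face, c(200, 400)) # PN300 window: frontal negativity
```

## Package layout

| Area | Functions |
|---|---|
| Montage | `build_default_montage()`, `hemisphere_of()`, `homolog()`, `project_2d()` |
| Simulation | `sim_config()`, `default_templates()`, `generate_schedule()`, `synthesize_noise()`, `pink_noise()`, `inject_blinks()`, `simulate_subject()`, `simulate_cohort()` |
| Preprocessing | `bandpass()`, `extract_epochs()`, `reject_artifacts()`, `baseline_correct()` |
| Averaging | `average_epochs()`, `grand_average()`, `pool_categories()` |
| Features | `marker_registry()`, `mean_amplitude()`, `extract_feature_table()` |
| Statistics | `rm_anova()`, `gg_epsilon()`, `tukey_hsd()`, `run_paper_contrasts()` |
| Decoding | `fit_centroid_classifier()`, `predict()`, `evaluate_loso()` |
| Driver & plots | `run_pipeline()`, `design_counts()`, `plot_waveforms()`, `plot_topomap()` |

Fitted objects support `tidy()` / `glance()`; evoked responses support
`autoplot()`. The methods vignette
(`vignettes/erp-marker-pipeline.Rmd`) documents the signal model, every
numerical convention (sample conversion, strict thresholds, filter
realization), the statistical implementation and its oracles, and the
design decisions taken where the emulated protocol is ambiguous.
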