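---
title: "Methods: EHG windowed-feature classification of preterm birth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EHG windowed-feature classification of preterm birth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis

The electrohysterogram (EHG) records uterine electrical activity from
abdominal surface electrodes. Its spectral content below a few hertz
changes as pregnancy progresses toward labor: contraction bursts become
more energetic, their oscillatory content more coherent, and maternal-ECG
interference occupies part of the 1–3 Hz range. `ehgtools` implements a
windowed feature pipeline that turns three-channel, 20 Hz, 30-minute EHG
records into a preterm (P) versus term (T) classification:

1. **Normalization.** Each raw channel is z-scored over the whole record
   (population SD, divide by N). Normalizing the *record* rather than each
   subband preserves the natural energy ordering of the subbands; whether
   one normalizes before or after filtering is genuinely open, and we fix
   the order z-score → filter → window as a documented convention.
2. **Subband filtering.** Three pass-bands partition the EHG range:
   F1 (0.3–1 Hz), F2 (1–2 Hz), F3 (2–3 Hz). The filter family and order
   are not dictated by the problem; we use a 4th-order Butterworth
   band-pass applied forward–backward (`signal::filtfilt`), i.e. an
   effective 8th-order zero-phase response, which keeps window contents
   phase-aligned with the raw signal. In-band gain exceeds 0.99 and the
   response one octave outside either edge is below 0.1 (both tested).
3. **Windowing.** 120-second windows with 50% overlap, fully contained in
   the record: a 30-minute record yields 29 windows of 2400 samples.
   Windows are the unit of feature extraction; *records* are the unit of
   splitting, so all windows of one record share one split.
4. **Features.** 33 per window: 5 linear (peak and median Welch-PSD
   frequency within the subband, RMS, zero-crossing rate, peak-to-peak
   amplitude), 18 entropy-based (SampEn, fuzzy entropy in local and global
   variants, permutation, dispersion, bubble, and a 12-value phase-entropy
   profile), and 10 wavelet features (Morse-CWT scalogram Energy and Flux
   at 0°/45°/90°, and six Daubechies-12 DWT adjacent-level log-energy
   differences).
5. **Selection.** Four algorithms on training windows only — F-test top
   10, chi-square top 10 (10 equal-width bins), multivariate OLS of the
   0/1 label keeping coefficients with p < 0.05 (ascending, at most 10),
   and greedy sequential forward selection — combined as:
   `(seqsel ∩ (ftest ∪ chi2 ∪ regression)) ∪ (regression ∩ (ftest ∪ chi2))`,
   padded with the highest-F unused features to at least 7 and truncated
   by F rank to at most 13. The combination prose this formalizes is
   ambiguous about order and duplicates; the rule above is one consistent
   reading and is recorded with per-feature provenance in every run.
6. **Classification.** Seven families mirroring common interactive-toolbox
   presets: quadratic/cubic SVM (polynomial kernel, box constraint 1),
   fine Gaussian SVM (RBF, kernel scale √p/4), weighted KNN (k = 10,
   squared-inverse-distance weights), bagged tree (30 learners), and
   linear/quadratic discriminants. The family with the best validation
   accuracy (AUC tie-break) is then evaluated by k-fold cross-validation
   (k = 23) over the pooled train+validation windows, with every fold
   model also scored on a fixed test set whose records never enter the
   pool — any overlap is a hard error, not a warning.
7. **Screening.** Per-feature two-sided Mann-Whitney tests between classes
   (exact for ≤ 20 values without ties, else the tie-corrected normal
   approximation), with star codes at 0.05/0.01/0.001/0.0001.

## Entropy parameters and conventions

| feature | parameters | notes |
|---|---|---|
| SampEn | m = 2, r = 0.15·SD | relative tolerance; Chebyshev distance, self-matches excluded; both template counts over the first N−m templates |
| FuzzEn | m = 2, r = 0.0077, n = 3 | **absolute** tolerance — the printed value is far below any plausible relative coefficient, and on z-scored records an absolute r is the reading that keeps the estimator informative; consequently FuzzEn is the one feature that is not gain-invariant (tested) |
| FuzzEn variants | local, global | local removes each template's own mean, global the whole-window mean; both are emitted as separate features (needed to reach the 33 total) |
| PerEn | order π = 3, delay d = 2 | "d = 2, π = 3" read as delay 2, pattern length 3; ties broken by order of appearance; normalized by ln 3! |
| DispEn | m = 2, c = 3 | linear min–max mapping into classes, embedding delay 1, normalized by ln c^m; zero-range windows return 0 |
| bEn | m = 10 | no order is dictated for 2400-sample windows; 10 is the value recommended in the method's original description; Rényi-2 entropy of bubble-sort swap counts, normalized difference across orders m+1 and m |
| PhEn | k = 2, 4, …, 24 | sector occupancy **counts** (not radius-weighted), sector 1 starting at angle 0, origin points dropped; twelve separate features |

Natural logarithms are used throughout.

The two O(N²) estimators (SampEn, FuzzEn) are implemented in C++ with a
sorted first-coordinate neighbour scan. For the local fuzzy variant at
m = 2 the baseline-removed Chebyshev distances have closed forms in the
first differences of the signal, which both enables the sorted scan and
removes redundant arithmetic. Membership terms too small to move the
result are dropped under an explicit error budget: terms below
`max_term · 1e-13 / n_pairs` are skipped, bounding the induced error on
the entropy by ~1e-13 — an order of magnitude tighter than the 1e-10
agreement the test suite demands against naive double-loop oracles.

## Wavelet conventions

The CWT uses an analytic generalized Morse wavelet with symmetry γ = 3
and time-bandwidth product 60 (β = 20), evaluated in closed form in the
frequency domain on a dyadic grid of 10 voices per octave over the 7
octaves below Nyquist. The filter is peak-normalized so a unit-amplitude
tone attains ridge magnitude 1 at any frequency (the L1 convention;
tested to within 5% across tones, and exactly equal for tones a whole
number of octaves apart). Energy sums |W|² over the whole plane — the
boundary cone is kept, since the features sum over the plane rather than
read off ridges. Flux compares the magnitude plane with a copy shifted by
(k1, k2) cells along (time, frequency) — (0,1), (1,1), (1,0) for 0°, 45°,
90° — and averages the absolute difference over valid cells, making the
value comparable across scalogram sizes.

The DWT uses the orthonormal Daubechies-12 filter over 7 levels. The
2400-sample window is zero-padded to 4096 and the transform is fully
periodized, so the analysis is exactly orthonormal and Parseval holds to
machine precision (asserted at 1e-8 relative). Zero-padding was chosen
over symmetric extension precisely because symmetric extension breaks
Parseval; padding with zeros adds no energy. The six DWT features are
differences of *log* level energies, `ln E(j+1) − ln E(j)`: the phrase
"difference between adjacent level coefficients" admits either reading,
and log differences make the features gain-invariant and well-scaled
(the raw difference is available via `dwt_adjacent_differences(log =
FALSE)`).

"Maximum frequency" is read as the frequency of the largest in-band PSD
value (ties to the lowest frequency); "medium frequency" as the median
(50%-power) frequency, linearly interpolated within the crossing bin —
the standard surface-EMG usage. Welch estimation uses 512-sample Hann
segments at 50% overlap (Δf ≈ 0.039 Hz, ≥ 8 averages per window).

## The synthetic cohort generator

Clinical EHG archives cannot ship with a package, so every stage is
exercised against a generator whose records have the statistical
structure the analysis assumes: a 1/f^α Gaussian noise floor (α = 1 by
default, spectrally flattened below 0.05 Hz so 30-minute records stay
stationary at the window scale — surface amplifiers are AC-coupled and
unbounded 1/f drift would confound the windowed variance); Hann-enveloped
contraction bursts with shared timing across channels but independent
per-channel gains; a burst carrier that mixes a coherent tone with
band-limited noise in a configurable carrier band, with a single
`regularity` knob in [0, 1] controlling the mixture — this is the dial
that produces entropy contrasts between classes; and an optional
maternal-ECG-like pulse train at 1.4 Hz with two harmonics. Records carry
their burst ground truth as annotations, and a cohort is a pure function
of (profiles, config): one integer seed fans out deterministically to
records, channels and stages.

The shipped class profiles define the simulated study conditions used by
the test suite: preterm records have burst rate 6/30 min, duration
60 ± 15 s, burst gain 4, regularity 0.8; term records 4/30 min, 50 ± 15 s,
gain 2, regularity 0.3 — a gain ratio of 2 and a regularity contrast of
0.5 — with identical carrier band (0.4–0.9 Hz, inside F1), baseline noise
and ECG interference (relative RMS 0.2), so class information lives only
in burst energy and burst regularity. Amplitudes are unitless by design:
the records are z-scored on entry anyway.

What the generator does *not* emulate — and what passing tests therefore
do not establish about clinical data: electrode-placement physiology,
inter-channel propagation of contractions (channels share timing but not
waveform), slow gestational-age trends, movement and electrode artifacts,
and the heavy-tailed amplitude statistics of real abdominal recordings.
Recovery of a simulated contrast shows the pipeline is correct and
leak-free, not that the features are clinically sufficient.

## Problem sizes and numerical choices

The end-to-end recovery check runs the full pipeline (selection, family
choice, 23-fold CV) on ten seeded contrast cohorts of 20 + 20 records of
30 minutes each, plus three matched null cohorts generated with identical
profiles for both groups, on the S1/F1 dataset — the channel-band where
the generator places the class contrast; the pipeline itself handles all
nine channel-band datasets, and `run_full_study()` iterates whatever the
config names. Mean held-out test accuracy must reach 0.85 on contrast
cohorts while staying at chance (≤ 0.65) on null cohorts.

Other conventions worth recording: record splits use per-class sizes
`round(0.15·n)` for validation and test with train taking the remainder
(20 records/class → 14/3/3); k-fold remainders spread over leading folds;
sequential selection uses LDA as its wrapper classifier by default — it
searches ~10³ candidate subsets per dataset and LDA is the same linear
decision family as a linear SVM at a fraction of the fitting cost
(`base_classifier = "svm_linear"` restores the SVM); gestational-age
bounds are inclusive ("between the 27th and 33rd week" read inclusively);
manual artifact exclusions are an explicit id → reason list, never an
automatic detector; filter edge transients are kept by default
(`trim_s` discards them when wanted); and all ties — feature rankings,
sector boundaries, fold remainders — break by canonical order so that
every run is bit-reproducible from its seed.

## Known limitations

FuzzEn's absolute tolerance makes it sensitive to the record-level
z-scoring convention; records normalized differently upstream would shift
it. The window-level k-fold pool can place windows of one record in both
a training and a validation fold — validation scores are therefore
optimistic; only the fixed record-disjoint test set measures
generalization, which is why the recovery criterion reads test accuracy.
Classifier presets are fixed rather than tuned; no hyperparameter search
is performed. The WFDB layer covers format 16 with the metadata comments
this pipeline writes and reads; it is not a general-purpose WFDB
implementation.
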