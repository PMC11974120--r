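---
title: "Interictal SEEG biomarkers and RF-TC outcome prediction: methods"
author: "seegrftc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interictal SEEG biomarkers and RF-TC outcome prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis

Stereo-electroencephalography (SEEG)-guided radiofrequency
thermocoagulation (RF-TC) ablates epileptogenic tissue through the same
depth-electrode contacts used for recording. Whether a patient will become
seizure-free is not observable at surgery time, but short interictal
recordings taken before and shortly after the procedure are. This package
implements a contact-level electrophysiological analysis of such paired
recordings:

1. two windowed biomarkers — line length (LL) and approximate entropy
   (ApEn) — in four frequency bands,
2. directional nonparametric group comparisons (thermocoagulated vs
   spared contacts pre-operatively; pre vs post on spared contacts), and
3. a two-level outcome predictor: an RBF-kernel support vector machine on
   per-contact pre-minus-post feature changes, aggregated into a
   per-patient *response possibility*.

Because clinical SEEG of this kind is not publicly shareable, the package
also contains a first-class synthetic cohort generator whose defaults
encode the cohort structure and effect directions the analysis is designed
to detect, so that every stage can be validated end to end.

## Biomarkers

**Line length** of a window $x_1,\dots,x_N$ is
$\mathrm{LL}(x)=\sum_{i=2}^{N}|x_i-x_{i-1}|$, an amplitude- and
frequency-weighted activity measure. It is reported as the raw sum, not
divided by $N-1$: every window in an analysis shares one $N$, and the
within-subject normalization below removes constant factors anyway.

**Approximate entropy** follows the classic Pincus construction with
self-matches included:
$\mathrm{ApEn}(m,r)=\Phi^m(r)-\Phi^{m+1}(r)$, where
$\Phi^m(r)=\frac{1}{N-m+1}\sum_i \log C_i^m(r)$ and $C_i^m(r)$ is the
fraction of length-$m$ templates within Chebyshev distance $r$ of template
$i$. We use the field-standard $m=2$ and $r=0.2\,\mathrm{sd}(x)$ per
window; with an SD-proportional tolerance the statistic is invariant to
adding a constant and to positive rescaling, which matters because the
montage and the normalization both rescale amplitudes. A flat window
(zero SD) is defined to have $\mathrm{ApEn}=0$ (and $\mathrm{LL}=0$): a
constant signal generates no patterns.

The implementation sorts template start positions by their first
coordinate so that only pairs with $|x_t-x_u|\le r$ (a necessary match
condition) are visited; counts for dimensions $m$ and $m+1$ accumulate in
one sweep. This is an exact algorithm — the test suite pins it against an
independent $O(N^2)$ brute-force implementation at $10^{-10}$ — not an
approximation.

## Preprocessing

The chain is fixed and deterministic: TC-channel removal (post-operative
recordings only, since ablated contacts record only noise) → average
reference → artifact masking → resampling → power-line notches →
band-pass decomposition → 10 s non-overlapping windows (20 windows from
200 s by default, taken from the start of usable signal).

Choices worth recording:

* **Resampling before filtering.** Recordings arrive at 512, 1000 or
  2000 Hz; 1000/2000 Hz data are decimated to 500 Hz first so a single
  filter design serves all patients. Decimation uses cascaded factor-2
  linear-phase FIR stages (30th order, cutoff 0.8× the target Nyquist),
  which keep passband gain errors well under 1%. 512 Hz input is left at
  its native rate: it is already below the target and resampling it would
  only degrade it.
* **Band edges vs Nyquist.** The bands are filtered 0.5–250, low 0.5–50,
  high-gamma 50–80 and ripple 80–250 Hz. At a 500 Hz rate a 250 Hz upper
  edge sits exactly at Nyquist and is unrealizable; any upper edge at or
  above 0.99× Nyquist degrades the design to a high-pass at the lower
  edge, which is the same response in practice since no content exists
  above Nyquist.
* **Filter family.** Zero-phase forward–backward 4th-order Butterworth
  band-passes (unit gain at the geometric band centre), applied by a
  compiled forward–backward kernel with odd-reflection edge padding.
  Zero-phase filtering matters because LL is sensitive to phase
  distortion of sharp transients.
* **Notches.** Second-order IIR notches (quality 30) at 50 Hz and odd
  harmonics strictly below Nyquist (50, 150 at 500 Hz; 250 Hz only above
  500 Hz), applied zero-phase, which squares the stopband attenuation.
* **Artifact handling** is an input, not a detector: the clinical
  workflow this models rejects contaminated spans manually. A window
  overlapping a masked span on a channel is dropped for that channel, and
  windowing then takes the first 20 clean windows.

## Within-subject normalization

Features are z-scored per (patient, band, feature) using the pooled mean
and SD over *all* of that patient's rows — both periods, all contacts,
all windows. Pooling the periods is essential: normalizing each period
separately would zero out exactly the pre/post contrasts the paired
statistics and the delta features measure. Normalizing per band and
feature (rather than pooling them) is an assumption; it puts every
(band, feature) pair on a comparable scale for the classifier.

## Group statistics

Two designs are run separately for responders and non-responders, per
band and feature, on contact means (the average of a contact's 20
windows):

* **TC vs non-TC (pre-operative)**: one-tailed Mann–Whitney U, testing
  that thermocoagulated contacts have *higher* values — the direction in
  which epileptogenic tissue is expected to differ.
* **Pre vs post (non-TC contacts)**: Wilcoxon signed-rank on paired
  contact means. Both one-tailed directions are evaluated and the smaller
  p is reported with its direction label. This mirrors the clinical
  reporting rule; its price is that under the null the effective per-test
  level doubles, so the strict family-wise guarantee applies to the
  TC-vs-non-TC family (the validation suite measures both).

Small tie-free samples use exact enumeration (both arms ≤ 8 for the rank
sum; ≤ 20 pairs for the signed rank); otherwise the tie-corrected normal
approximation with continuity correction is used. Bonferroni correction
is applied within each group × design family of 8 tests (2 features × 4
bands), the most conservative reading of the multiple-comparison family;
significance is adjusted p < 0.05.

## Outcome prediction

Each non-TC contact contributes one 8-dimensional sample: pre minus post
contact means of LL and ApEn in the four bands (canonical order:
LL-filtered, LL-low, LL-high-gamma, LL-ripple, then ApEn likewise), with
the patient's outcome as its label (responder = positive). Samples are
split class-stratified 1/6 into test and training sets — with 834
positives and 163 negatives this reproduces 695/139 and 136/27. The split
is contact-level: contacts of one patient can land on both sides, a
leakage risk the report output states explicitly (it is forced by the
printed counts, which are incompatible with patient-level splitting).

Class imbalance is handled by partitioning the training positives into 5
random subsets of near-equal size (~139 each, comparable to the 136
training negatives). Each subset ∪ negatives is evaluated over a grid of
RBF-SVM hyperparameters (cost {0.1, 1, 10, 100} × kernel scale
{1/8, 0.01, 0.1, 1}) by stratified 25-fold cross-validation (folds are
reduced with a warning when the smaller class has fewer samples), scored
by mean validation AUC computed from decision values by the rank
statistic. The winning cell is retrained on its subset ∪ negatives.

Ties in mean AUC are real, not hypothetical: on separable data the whole
grid reaches AUC 1.0, and the most-regularized cells can do so while
degenerating to one-class prediction (AUC is rank-based and ignores the
decision threshold). Ties therefore break first to the highest mean CV
*accuracy*, then deterministically to the smallest subset index, cost and
kernel scale.

At the individual level, a patient's *response possibility* is the
fraction of all their non-TC contacts (training and test alike — the
statistic is defined over the patient's montage, not over a partition)
classified positive; the patient is predicted a responder iff it strictly
exceeds 0.5.

## The synthetic cohort generator

Each channel is the sum of three sub-band components (low 0.5–50,
high-gamma 50–80, ripple 80–250 Hz), plus 50 Hz mains with odd harmonics.
A component mixes:

* a **regular** part: $1/f^a$-coloured in-band Gaussian noise,
  amplitude-modulated by a slow (0.2–3 Hz) non-negative burst envelope —
  waxing/waning oscillatory background, the dominant character of
  interictal intracranial EEG; and
* an **irregular** part: stationary white in-band Gaussian noise,

weighted $\sqrt{1-\mathrm{irr}}$ and $\sqrt{\mathrm{irr}}$ and scaled to
the component RMS. The two levers map cleanly onto the two biomarkers:
component RMS drives LL, while the irregular fraction raises ApEn — in
wide bands by flattening the in-band spectrum, in narrow bands by
replacing burst structure with stationary noise. The burst mechanism is
essential: for stationary Gaussian signals the ApEn of a narrow band is
almost fully determined by the measurement filter, so no stationary
spectral manipulation can move high-gamma ApEn appreciably.

Synthesis is performed in the frequency domain (one FFT per part from its
power spectral density), which is statistically equivalent to time-domain
filtering of white noise and an order of magnitude faster. Per-contact
log-normal amplitude jitter (SD 0.08) and Gaussian irregularity jitter
(SD 0.05) create realistic between-contact variability; identical seed
and configuration give a bit-identical cohort.

Default conditions encode the study design the analysis targets: 10
patients (8 responders), contact counts whose seed-1 non-TC totals are
834 responder and 165 non-responder contacts (non-responders get smaller
montages, consistent with the observed cohort where only totals constrain
the generator), ~26% of contacts thermocoagulated (per-patient TC counts
within the observed 7–76 span). Effect defaults were chosen once so that
the configured direction pattern is realized: responder TC contacts get
1.6× amplitude in high-gamma/ripple and +0.25 irregularity in low/ripple
pre-operatively (higher LL in filtered/high-gamma/ripple, higher ApEn in
filtered/low/ripple); post-operatively, responder non-TC contacts lose
25% amplitude in all sub-bands and 0.15 irregularity in
high-gamma/ripple (LL falls in all four bands, ApEn falls in
high-gamma/ripple), while non-responder non-TC contacts gain 35%
amplitude in low/ripple and lose 0.15 irregularity in low/ripple (LL
rises in filtered/low/ripple, ApEn falls in filtered/low/ripple).

What the generator does **not** emulate: interictal spikes and
high-frequency-oscillation events, seizures, nonstationary state changes
(sleep/wake), electrode geometry, and volume conduction between channels
(channels are independent). Filter skirts couple neighbouring bands
slightly (a high-gamma effect leaks weakly into the low and ripple
measurements), which is also true of the real measurement chain.
Passing the validation suite therefore demonstrates that the pipeline
recovers the effects its generative model encodes — it is not evidence
about any particular clinical recording.

## Validation design and problem sizes

The suite validates at scaled-down sizes chosen for a single-CPU run:

* *Reference cohort* (seed-fixed recovery, prediction checks): 10
  patients, 12–14 contacts per responder, 10–12 per non-responder, 30%
  TC, 100 s analysed per period.
* *End-to-end label recovery*: 20 independently seeded cohorts with 5–7
  contacts per patient and 50 s analysed; the two-level predictor must
  recover all 10 outcome labels in ≥ 90% of seeds.
* *Null calibration*: the 200-replicate family-wise error study draws
  exchangeable contact means directly (the property under test concerns
  the comparison machinery), and a smaller full-pipeline null check runs
  zero-effect cohorts through the entire signal path. The
  label-permutation null re-labels patients (excluding the identity
  assignment) and re-runs the predictor on a reduced grid.

## Numerical choices and degenerate inputs

* ApEn boundary counting uses $d \le r$ (inclusive), matching the brute
  force oracle bit-for-bit; tolerance is computed from the sample SD
  (n−1 denominator).
* Mann–Whitney ties get midranks with the variance correction; exact
  enumeration is only used for tie-free small samples. All-zero paired
  differences are an error (no information), fewer than 5 non-zero pairs
  a warning.
* A Wilcoxon "reversed tail" on an extreme sample yields p = 1 under the
  standard inclusive convention ($P(W \le w_{obs})$), which is what the
  package returns.
* Zero pooled SD in normalization is an error naming the offending
  (patient, band, feature) group; an artifact mask covering a whole
  channel drops the channel with a warning; a recording left with a
  single channel makes the average reference (a contrast) undefined and
  errors.
* The decision rule is strict: a response possibility of exactly 0.5
  predicts non-responder.

## Known limitations

* The contact-level split leaks patient identity between training and
  test sets at the sensor level (forced by the reference partition
  sizes); sensor-level metrics should be read accordingly. The leakage
  is measurable: on cohorts with many contacts per patient, a
  patient-label permutation null retains above-chance test AUC, because
  within-patient normalization gives each patient's delta vectors a
  shared offset the classifier can memorize. With few contacts per
  patient the effect is small and permutation AUC sits at chance.
* The paired design's better-tail reporting doubles its effective
  per-test level under the null; family-wise guarantees are stated for
  the one-tailed TC-vs-non-TC family.
* The fast-ripple band (250–500 Hz) is out of scope (it requires
  ≥ 1000 Hz acquisition everywhere), as are automatic artifact detection,
  bipolar montages, and event (spike/HFO) features.
* EDF import/export is not provided; recordings enter as in-memory
  matrices or the package's text+RDS cohort bundles.
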