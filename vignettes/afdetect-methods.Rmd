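---
title: "Methods: ensemble AF detection in ICU telemetry ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble AF detection in ICU telemetry ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afdetect)
```

## The detection problem

Atrial fibrillation in stored ICU telemetry must be found against two
confounders that dominate in critical illness: noise (motion artifact,
electrode dropout, muscle activity) and premature atrial/ventricular beats,
whose short coupling interval plus compensatory pause produces RR
variability that entropy-style AF detectors happily mistake for
fibrillation. The ensemble therefore works by *elimination*: a segment is
called AF only after it has survived a noise gate, exceeded an
irregularity screen, and failed to be explained as ectopy by two
independent evidence streams. Patient-level calls additionally require six
continuous minutes of AF evidence.

All processing operates on 2-minute segments (`segment_length_s = 120`),
half-open windows `[iL, (i+1)L)` with 0-based indices; trailing partial
windows are discarded because every statistic is calibrated for complete
windows. Record-level inclusion uses a closed duration interval of
[6 h, 55 h]; the bounds are configurable and the boundary is taken as
inclusive since a 6-hour recording supports exactly the minimum number of
analyzable segments the episode rule needs.

## Signal quality

The quality stage is a transparent rule-based index, chosen over any
published black-box noise classifier so that every decision in the audit
trail can be traced to a threshold in `af_config()`. A 5-second sub-window
is noisy if any of:

* flat-line — variance below `flatline_var_floor` (1e-4 mV²), more than
  50% identical consecutive samples, or any NaN (dropout);
* clipping — more than 5% of samples pinned at the window extremes;
* spectral distortion — less than 15% of power in the 5–40 Hz ECG band
  (wander/low-frequency artifact dominance) or more than 20% above 40 Hz
  (EMG/broadband noise);
* amplitude outliers — the largest local peak more than 8 robust SDs above
  the other peak amplitudes (motion spikes). Peaks are compared against
  peaks, not against baseline, so tall-but-regular QRS complexes do not
  trip the check.

"Majority noise-free" is implemented as a *strict* majority (> 0.5) of
clean sub-windows. A record is analyzable only if some lead has ≥ 3
consecutive usable segments — the minimum run the episode rule could ever
convert into an AF call. On the synthetic generator the verdict is monotone
in SNR, and white noise flips a clean sinus segment to unusable between 0
and −6 dB.

## Beat detection

R-peaks are detected on a VFCDM reconstruction: the signal is complex
demodulated at a bank of center frequencies spaced `fs/64` apart, each
component extracted by an ideal low-pass of half the spacing (FFT
implementation; segments are long enough that edge periodicity is
immaterial), and only components with centers in the QRS band are summed.
The band default is **5–25 Hz**: the lower edge was set below the more
common 8 Hz because wide ectopic QRS complexes (~120 ms) concentrate their
energy near 5–8 Hz, and with an 8 Hz edge the detector missed PVC
templates on the generator while T- and P-waves still live below 5 Hz.
Peak picking runs on the lightly smoothed squared reconstruction with a
running threshold of 0.3 × an exponentially updated recent-peak estimate, a
0.25 s refractory period (240 bpm ceiling), and final refinement to the raw
signal's local maximum within ±50 ms. Segments with fewer than 10 beats
are flagged insufficient and excluded from rhythm analysis. A band-pass +
analytic-envelope fallback detector is available via
`af_config(detector = "envelope")`.

On clean synthetic records from 40–160 bpm the detector's sensitivity and
positive predictivity are 1.00 within a ±50 ms matching window (the
acceptance suite asserts ≥ 0.98).

## Rhythm screen

Sample entropy uses the template convention with starts `1..N−m` for both
lengths, self-matches excluded. Defaults m = 1 and absolute r = 30 ms: a
2-minute segment yields only 100–200 RR intervals, too few for stable m ≥ 2
estimates, and an absolute tolerance keeps the screen anchored to
physiological RR resolution (an `sd_fraction` mode exists for
normalized-tolerance workflows). Degenerate cases are explicit: A = 0 with
B > 0 returns `Inf` ("maximally irregular", screened as possible AF);
B = 0 is undefined and the segment is flagged INSUFFICIENT (treated as
non-AF by episode logic but logged distinctly).

The screening threshold (SampEn ≥ 1.0) was calibrated once on the
generator and frozen: sinus rhythm at 60–90 bpm scores ≤ 0.70, atrial
bigeminy ≥ 1.07, AF ≥ 1.8. The screen is intentionally non-specific —
ectopy passes it by design and is resolved downstream.

## Ectopy discrimination

Only possible-AF segments reach this stage, so it can demote but never
promote: specificity is monotone non-decreasing as evidence streams are
added, which is exactly the stepwise behaviour the ablation experiment
measures.

**Poincaré stream.** In the plot of successive heart-rate differences, a
premature beat writes a stereotyped signature: a large ΔHR jump of one
sign followed by an opposite jump of nearly equal magnitude (compensatory
closure). A point is an ectopy-lobe point if either coordinate exceeds
`d_min_bpm = 15`, the signs oppose, and
|ΔHR_i + ΔHR_{i+1}| < 0.25 · max(|ΔHR_i|, |ΔHR_{i+1}|). The triangular
score is the ectopy-lobe fraction among large-deflection points. On the
generator, continuous bigeminy scores ≥ 0.6 (1.0 when deterministic) and
AF ≤ 0.3; the decision threshold is 0.5. The pair-closure rule captures
*continuous* bigeminy, whose heart rate alternates between exactly two
levels; sporadic ectopy closes only over three differences and is left to
the P-wave stream — a deliberate division of labour.

**P-wave stream.** The segment is QRS-blanked (±60 ms) and T-blanked
([R+0.14, R+0.44] s); without T blanking the preceding T-wave enters the
pre-R search window whenever RR < ~0.65 s — i.e. in most AF — and
masquerades as a P-wave. The blanked signal is low-passed at 20 Hz (EMD
otherwise spends its first mode on broadband noise and mixes the P-wave
across modes), decomposed by standard sifting EMD with cubic-spline
envelopes, and the intrinsic mode functions whose zero-crossing dominant
frequencies fall in 1.5–15 Hz are summed into a P-band signal. Each window
[R−280 ms, R−80 ms] (standard PR physiology) is searched for a positive
deflection ≥ 10% of the median R amplitude. P-to-R counts, not amplitudes,
form the ratio. On the generator: sinus ≈ 1.0, AF ≤ 0.05 (fibrillatory
waves stay under threshold), sporadic PVC ≈ 0.95. A known limitation: at
sinus rates ≥ 90 bpm the T-blank begins to clip the following P-wave and
the ratio can fall to ~0.5; such segments never reach adjudication (their
entropy is far below the screen), so the pipeline is unaffected.

**Combination.** ECTOPY if triangular score ≥ 0.5 *or* P-to-R ≥ 0.6 — an
OR rule, because each stream certifies a different ectopy mechanism and
either is sufficient to explain away the irregularity; AF requires
irregularity that neither stream explains *and* absent P-waves. Modes
`none` / `poincare_only` / `poincare_plus_pwave` reproduce the stepwise
development configurations.

## Episode logic and lead fusion

Maximal runs of ≥ 3 consecutive AF segments become episodes; onset is the
run's first segment start, offset the last segment end (offsets are a
package convention — only onsets are externally comparable). NOISE and
INSUFFICIENT labels *break* runs: the rule demands continuous AF, and
bridging gaps would manufacture six-minute evidence that was never
observed. Default fusion takes, per segment, the label of the lead with
the highest clean fraction (ties to record order); `any_lead` calls AF if
any usable lead does, and its AF set therefore contains every single
lead's — sensitivity can only rise, which the ablation asserts.

## Comparators

The three-statistic rule (normalized RMSSD ≥ 0.1, normalized Shannon
entropy ≥ 0.7 over 16 equal-width bins after 5% tail trimming, turning
point ratio within [0.81, 1.155] — the published bounds divided by the
random-series expectation 2(n−2)/3 so the ratio is centred at 1) and the
COSEn rule (threshold −1.2, m = 1, r = 30 ms) run on the raw RR series of
usable segments, with the same episode logic. Neither has an ectopy stage —
the deficit the ensemble exists to fix. Note that strict alternation gives
a turning point ratio ≈ 1.5, *outside* the randomness band, so continuous
bigeminy is actually rejected by the three-statistic rule; on the
synthetic corpus its failure modes are smaller, while COSEn false-positives
on bigeminy (COSEn ≈ −1.2 straddles its threshold there).

## The synthetic generator

The generator emulates what the detector measures, nothing more: RR
structure, P-wave presence, QRS-band morphology, and ICU noise. Beats are
Gaussian-bump templates (P 0.15 mV at R−200 ms, QRS ~1 mV, T 0.35 mV;
PVCs widened, taller, P-less, with discordant T). Rhythms: sinus with
0.25 Hz respiratory modulation (CV ≈ 3%); AF as serially independent
draws from a two-component lognormal mixture (short/long clusters at
0.85×/1.25× the base interval; CV ≈ 20–25%) with P-waves removed and a
4–9 Hz fibrillatory baseline added; bigeminy as coupling 0.6×base
(SD 0.12×base) with compensatory pause 2×base − coupling plus independent
post-ectopic variability (SD 0.05×base — without it the pause
anti-correlates perfectly with the coupling and caps the rhythm's sample
entropy below what real multifocal ectopy shows); sporadic PAC/PVC at a
configurable per-minute rate. Noise: baseline wander (0.1 mV at
0.05/0.3 Hz), white EMG (0.02 mV), powerline, and random 5–30 s dropout
spans per segment. Default lead set is two leads at relative gains
1.0/0.6. All draws are reproducible from a single seed; a fixed seed gives
byte-identical output.

The validation corpus mirrors a 50-patient validation design: 25 records
with an AF onset uniform in the first 40% of the record and AF to the end,
25 AF-free records of which 40% are ectopy-rich (alternating continuous
bigeminy and 8/min sporadic PAC). Tests and the acceptance script use
10-minute records at 125 Hz (5 segments/record, ~45 s of computation for
the corpus and ~90 s for the full ablation on one CPU); the generator's
default record length is 6 h, matching the inclusion minimum.

What passing on this corpus shows: the stage logic, thresholds and episode
machinery behave as designed against a ground truth with the right
statistical structure. What it does not show: performance on real
telemetry — template-rendered beats have no morphology drift, no atrial
flutter, no paced rhythms, and noise processes are stationary. The
published operating points of the original clinical study (e.g. 94%
validation accuracy on real sepsis telemetry) are not reproducible without
access to the restricted waveform archive, and the package does not claim
them; it claims the *orderings* (ectopy discrimination strictly improves
entropy-only accuracy; all-leads fusion cannot lower sensitivity; the
ensemble is at least as accurate as both RR-only comparators), which are
asserted by the acceptance suite.

## Numerical and statistical choices

* Exact (Clopper–Pearson) binomial 95% CIs by default — on a 47/50
  accuracy the exact interval reproduces the conventional printed 83%–99%
  where Wilson gives 84%–98%; Wilson is available by option.
* Paired accuracy comparisons use the exact McNemar test on discordant
  pairs (binomial p = 0.5); with no pairing, Fisher's exact test on the
  correct/incorrect counts. No discordant pairs ⇒ p = 1.
* Quantiles use linear interpolation between order statistics
  (`stats::quantile` type 7), stated in the output metadata because
  quartile conventions differ.
* Undefined metrics (zero denominators) are `NA`, never 0.
* Ties in the turning point ratio are not turning points (strict
  inequalities); ties are measure-zero under the generator.
* Segment-level features are deterministic given the waveform; the only
  randomness anywhere is the generator's, governed by explicit seeds.

## Limitations

Single-channel quality gating cannot distinguish lead failure from global
noise; atrial flutter is out of scope (its regular irregularity defeats
entropy screens by design); the P-wave stream assumes upright P in the
analyzed lead; and all thresholds, while exposed in `af_config()`, were
calibrated on the synthetic corpus — deployment on a real archive should
re-examine the screen threshold and P-amplitude fraction against a locally
adjudicated sample.
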