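---
title: "Methods: STN conflict-control LFP analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: STN conflict-control LFP analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and design decisions
behind `stnlfp`, in the spirit of a statistical-methods appendix. The
package reimplements, as tested and reusable code, the analysis of
intraoperative subthalamic nucleus (STN) local field potentials recorded
during the Simon task: signal conditioning, Morlet band power, trial-wise
baseline normalization and QC, response-locked binning, distributional
behavioral analyses, mixed-model contrasts, and baseline-power/behavior
correlations. Because the underlying patient recordings are not publicly
deposited, the package is exercised end to end on a synthetic-data
generator that emulates the study design; what the synthetic results do and
do not establish is discussed at the end.

## The task and the data model

Each trial of the Simon task presents a lateralized coloured circle; the
colour rule maps to a left or right button. On corresponding (Cs) trials
the stimulus side matches the required response side; on non-corresponding
(NC) trials it conflicts with it. A trial table records, per trial, the
stimulus onset (seconds from the recording start), stimulus side, correct
side, response side, reaction time (ms, capped by the 1000 ms deadline),
correspondence, accuracy (`correct`, `error`, `omission`, `too_early`) and
the preceding intertrial interval (750–1250 ms uniform). Correspondence is
defined, and validated on every read, as `Cs` iff stimulus side equals
correct side.

A recording holds exactly three parallel microelectrode voltage traces per
hemisphere and depth (dorsal or ventral STN), with its sampling rate. The
acquisition-scale rate is 44 kHz; the package treats the rate as metadata
and the simulator defaults to 11 kHz (2 kHz in most tests) purely for
compute economy — every rate above twice the 100 Hz analysis band limit is
valid, and the decimation contract is verified explicitly at 44 kHz.
Containers are plain text (JSON metadata plus full-precision CSV channels;
CSV trial tables with a schema-version tag) so that round trips are exact
and the format is self-describing.

Hemisphere is analyzed *relative to the responding hand*: a recording is
ipsilateral to a response from the same-side hand. The relabelling is per
trial, since the responding hand changes trial to trial.

## Signal conditioning

Per recording, the channel with the largest variance over the concatenated
trial periods (stimulus onset to response) is selected for analysis, and
all three channels are used for common-average demeaning (subtracting the
instantaneous cross-channel mean), which cancels common-mode pickup such as
line noise. The selected, demeaned trace is then decimated to 1000 Hz with
anti-aliasing (staged integer decimation, stages ≤ 13; polyphase rational
resampling for non-integer ratios), linearly detrended, band-passed 1–100 Hz
and band-stop filtered 59–61 Hz.

Two reading decisions are config-exposed because the source description is
terse: "second ordered" is read as 2nd-order Butterworth for both the
band-pass and the notch, and filters are applied forward–backward
(zero-phase), since response-locked timing must not be skewed by group
delay. The chain's contracts are tested against oracles: ≥ 20 dB
attenuation at 60 Hz, < 5% passband amplitude error, zero cross-correlation
lag, near-idempotence, and < 5% band-power change across the 44 kHz → 1 kHz
step.

## Time–frequency analysis and normalization

Band power comes from an FFT-based complex Morlet decomposition. The
number of wavelet cycles ramps linearly from 4 at the lowest analyzed
frequency to 12 at the highest, anchored to the analyzed frequency vector
(default 2–100 Hz in 1 Hz steps; the pipeline examples use 2–30 Hz, which
fully contains both analysis bands, to keep the frequency loop short). The
wavelet spectrum is peak-normalized (one-sided, factor 2), so a unit
sinusoid at an analyzed frequency has power 1. Samples within half a
wavelet length (3.5 Gaussian SDs) of the trace ends are counted as
edge-contaminated per frequency. Theta is 4–7 Hz and low beta 12–22 Hz,
averaged across band rows inclusive of bounds.

The response-locked analysis window is the half-open `[-380, 0)` ms before
the timestamped button press, on correct trials only. The 380 ms baseline
window is config-exposed because its placement is genuinely ambiguous in
the source description, which anchors it both to the intertrial period and
to 500–100 ms before the response:

* `intertrial` (default): 380 ms ending 100 ms before stimulus onset,
  inside the preceding intertrial interval. It never overlaps the analysis
  window and is the statistically cleaner choice.
* `literal_preresponse`: `[-480, -100)` ms before the response, the literal
  pre-response reading, which can overlap the analysis window on fast
  trials. Provided for fidelity.

Three normalizations serve three purposes. Decibel,
`10·log10(P/mean(P_base))`, is used for baseline-power summaries; z-scoring
uses baseline moments pooled over *all* of a subject's baseline windows
within subregion × band (both hemispheres) and feeds the condition
time-course plots; and the mixed model's response is the natural log of the
trial-ratio power `P/mean(P_base)` averaged per cell. The last choice
resolves a real ambiguity: z-scores can be negative and cannot be logged,
so the modelled quantity must be the ratio-scale normalization. Non-positive
ratios are dropped with a logged count, and more than 5% of them aborts the
run as a sign of an upstream normalization problem.

The per-trial inclusion test ("QC") compares the analysis window against
the trial's baseline window with a two-sided paired *t*-test on the
samplewise differences (380 pairs at 1000 Hz), including the trial iff
p < 0.05. "Full spectrum" QC is read as broadband — the mean power across
all analyzed frequencies — with a per-band option. On i.i.d. null windows
the inclusion rate is ≈ α by construction (verified by simulation); on
structured data the autocorrelation of power makes genuine responses
overwhelmingly significant, so exclusions stay in the low single digits,
matching the < 6.7% exclusion regime of the study. Binning averages the
normalized series over `[-380,-285)`, `[-285,-190)`, `[-190,-95)`,
`[-95,0)` ms (bin 1 earliest), then averages bins across a subject's
included trials within subregion × relative hemisphere × correspondence.

## Behavioral battery

Reaction times below 150 ms are removed as anticipatory; then, within each
subject × depth × correspondence cell, times above the cell mean + 3 SD
(computed once on the post-150 ms set, no re-iteration) are removed.
Accuracy uses responded trials as its denominator (omissions and too-early
trials excluded), since the analysis concerns commission accuracy. Rank
binning sorts trials fastest to slowest into four bins, giving the first
`r` bins one extra trial when the count is not divisible (ties keep input
order). Delta plots are computed on correct trials within subject × depth:
interference `d_b = RT_NC,b − RT_Cs,b` against `x_b = (RT_NC,b + RT_Cs,b)/2`,
with the final suppression slope `(d₄ − d₃)/(x₄ − x₃)`; conditional
accuracy functions are computed on responded trials including errors, per
the activation–suppression literature. Group inference is subject-level
first: per-subject cells are formed before paired *t*-tests with
`d = mean(diff)/sd(diff)`.

One reference-table note: in the shipped reference results, the dorsal
Simon RT effect equals the table's NC − Cs difference exactly (42.1 ms),
while the printed ventral effect (34.8 ms) differs from its table
difference (31.0 ms), implying subject-weighted means somewhere upstream;
the package reports subject-level means and leaves the discrepancy
documented rather than reconciled. Similarly, the contralateral beta
cell averages are consistent with the printed contralateral pair only with
the Cs/NC labels exchanged; that pair is therefore excluded from the
cross-footing checks.

## The mixed model

Per band, log cell power is modelled with fixed effects for subregion,
correspondence, relative hemisphere, the subregion × correspondence and
correspondence × hemisphere interactions, and the three-way interaction —
deliberately *without* the subregion × hemisphere two-way, which gives the
three-way term 2 numerator df and makes the 8 fixed parameters a complete
cell-mean parameterization. Time bin enters the random part only: the
random structure is an intercept per subject, an (uncorrelated) random
slope for correspondence per subject, and a random time-bin slope per
subject × subregion × correspondence — one defensible reading of a nested
random-slope description whose exact covariance structure is ambiguous in
the source; the structure is config-exposed. Fits are REML with
Satterthwaite F tests; estimated marginal means are reported on the log
scale with SEs; contrasts are differences of cell means (or averages of
cells) with SEs from the fixed-effect covariance.

Convergence handling is pre-registered as a fallback ladder: a
non-convergent or singular fit drops the nested time slope, then the
correspondence slope, leaving the subject intercept; the step actually used
is recorded in the result and in the report provenance. A singular fit at
the last step is an error (with the degenerate exception of a constant
response, which is returned with all fixed effects zero). On null
simulations the fixed-term type-I error of the full ladder is 4.8–5.9%
per term (2000 replicates), i.e. nominal.

Baseline-power/behavior association uses Spearman rank correlations across
subjects between per-subject mean baseline-window band power — in dB on an
absolute (arbitrary-unit) scale, averaged across hemispheres, per
subregion — and the Simon effects (RT and percent accuracy) from the
behavior of the matching depth. The dB reference deserves a note: a
baseline normalized *within* subject would erase exactly the
between-subject differences the correlation measures, so the absolute-scale
dB is the only self-consistent choice; Spearman correlation is invariant
to it anyway.

## The synthetic cohort generator

The generator is first-class, tested code, and its defaults are the study
conditions: 10 subjects, 144 trials per block (the study range is 144–190),
two blocks per depth, bilateral recordings, 1000 ms deadline, 750–1250 ms
intertrial intervals. Signals are 1/f background noise (exponent 1) per
channel plus a shared common-mode component and a common 60 Hz line (so
demeaning has real work to do), ongoing narrowband theta/beta background,
and response-locked Hann-windowed theta and beta bursts of 300–400 ms
centred 150 ± 50 ms before the response — inside the analysis window.
Burst amplitude is `base × condition gains × subject gain` with a
dorsal-NC theta gain, an ipsilateral-NC beta gain and a dorsal beta gain;
burst phase is independent per channel (so common-average referencing
attenuates by a third rather than cancelling) with fixed channel gains
emulating unequal electrode proximity. No effect-size magnitudes in
physical units are available for the modelled phenomena, so the gains
(1.5, 1.4, 1.2) are calibrated to make pipeline recovery testable at desk
scale, not to match patient physiology.

Behavior uses ex-Gaussian reaction times (μ = 450 ms, σ = 60 ms,
τ = 120 ms, matching the observed ~570 ms means) with a 40 ms NC shift.
Impulse-capture errors are a race: an automatic response toward the
stimulus side with its own, faster ex-Gaussian latency wins when it beats
the goal response and suppression fails (probability ~0.08 per NC trial,
log-normally heterogeneous across subjects). Captured trials are fast
errors, which produces the depressed fastest-bin NC accuracy that the
conditional accuracy function must detect; an optional late-suppression
parameter shrinks the NC cost on slow trials to produce negative-going
final delta slopes. A condition-independent 10% lapse rate yields realistic
Cs accuracy (~88%).

Subjects' ongoing beta levels and impulse-capture probabilities are coupled
through a Gaussian copula. The coupling knob targets the *measured*
subject-level Spearman correlation between ventral baseline beta and the
accuracy Simon effect at study scale; since binomial noise in a
144–288-trial accuracy effect attenuates rank correlations, the latent
copula correlation is boosted by a calibrated gain (knob 0.8 maps to full
rank-matching of beta intercepts to capture probabilities — the simplest
monotone coupling). With the knob at its default 0.8, the measured
correlation reaches ≥ 0.5 in ~90% of 10-subject replicate cohorts, and the
knob at 0 gives replicate-averaged correlations within ±0.05 of zero.

For statistical calibration at scale the package also provides
`simulate_powercells()`, a generative model of the mixed model's unit of
analysis (one log-power value per subject × subregion × hemisphere ×
correspondence × bin) with fixed effects mapped from the same configuration
gains: a multiplicative amplitude gain `g` appears on the log-power scale
as `κ·2·log(g)` with an occupancy factor κ = 0.6 reflecting that bursts
fill most but not all of the analysis window. Type-I-error and power
studies over hundreds of replicate cohorts run through this generator (the
full signal chain costs minutes per cohort, which would make such studies
hours long); agreement between the two routes is verified end to end on
seeded full-signal cohorts, which reproduce the same qualitative
fingerprint: a significant dorsal — but not ventral — theta conflict
contrast, a significant ipsilateral — but not contralateral — beta conflict
contrast, and a positive ventral-beta/accuracy correlation.

## Problem sizes and numerical choices

The shipped tests and the acceptance script choose problem sizes as a
deliberate compromise between statistical resolution and desk-scale
runtime: full-signal runs use 2 kHz raw sampling, a 2–30 Hz analysis grid,
one 144-trial block per depth and 10 subjects (the acceptance run) or 24–32
trials and 3–4 subjects (unit tests); replicate studies use 100–800
power-cell cohorts and 500 behavior-only cohorts. Noise generation and
wavelet convolution pad to power-of-two FFT lengths. Tie-breaks are
deterministic everywhere (lowest channel index; input order within tied
RTs). Degenerate inputs are labelled errors rather than silent results:
zero-variance QC differences, zero baseline SD, non-positive baseline
means, constant vectors in rank correlations, fewer trials than bins, and a
singular last-step mixed fit.

## Limitations

The synthetic generator emulates the statistical structure the analysis
assumes — it is not a biophysical model of STN activity, does not simulate
spiking, Parkinsonian pathophysiology beyond an elevated dorsal beta gain,
or electrode drift, and its effect sizes are self-chosen. Passing
recovery tests therefore demonstrates that the pipeline detects the
structure it targets at realistic SNR and scale, not that the original
biological findings are reproduced; the arithmetic cross-foots of the
reference tables are the only checks anchored to the published numbers.
Real-data use enters through the plain-text containers and the same
pipeline entry points, with the vendor acquisition format out of scope.
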