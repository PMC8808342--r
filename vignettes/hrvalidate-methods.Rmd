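---
title: "Methods: nocturnal HR/HRV device validation with hrvalidate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nocturnal HR/HRV device validation with hrvalidate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hrvalidate` implements a complete pipeline for validating wearable
(PPG/interbeat-interval) nocturnal heart rate and heart-rate-variability
measurements against a single-lead reference ECG, together with a synthetic
paired-recording generator so that every stage can be verified against known
ground truth. This vignette documents the models, the tunable parameters and
their defaults, the numerical choices, and the design decisions taken where
the underlying methodology left the design open.

## 1. The synthetic world

### Tachogram model

Beat-to-beat (NN) intervals are generated as

$$NN_k = \mu + A_{LF}\sin(2\pi f_{LF} t_k) + A_{HF}\sin(2\pi f_{HF} t_k) + \varepsilon_k,
\qquad \varepsilon_k \sim N(0, \sigma^2),$$

with $t_k$ the cumulative beat time. The two sinusoids emulate autonomic
modulation in the standard low-frequency (0.04–0.15 Hz) and high-frequency
(0.15–0.4 Hz) HRV bands; the white jitter term emulates residual short-term
variability. Parameters, with defaults used throughout the test-bed world:

| parameter | meaning | default | why |
|---|---|---|---|
| `mean_nn_ms` ($\mu$) | mean NN interval | 1000 ms (60 bpm) | typical sleeping heart rate; constrained to 300–1200 ms, the 50–200 bpm normal range |
| `lf_amp_ms`, `lf_freq_hz` | LF modulation | 40 ms at 0.10 Hz | mid-band LF rhythm of realistic nocturnal amplitude |
| `hf_amp_ms`, `hf_freq_hz` | HF modulation | 30 ms at 0.25 Hz | respiratory-frequency modulation (~15 breaths/min) |
| `jitter_sd_ms` ($\sigma$) | white beat noise | 15 ms | gives RMSSD values in the tens of ms, as observed in sleeping adults |
| `duration_s` | night length | 29700 s (8.25 h) | a typical full night of sleep; study-sized runs use 4800 s (16 windows) |

A sinusoid of amplitude $A$ has variance $A^2/2$; this gives the generator
analytically known spectral ground truth (LF $= A_{LF}^2/2$, HF
$= A_{HF}^2/2$), and a sampled sinusoid's SD of $A/\sqrt 2$ is used as a
closed-form oracle in the tests.

### ECG morphology

The waveform is a template per beat — a narrow Gaussian R spike (SD 12 ms)
flanked by smaller P and T bumps (15 % and 30 % of the R amplitude; the P/T
offsets shrink proportionally at short intervals) — plus optional sinusoidal
baseline wander, white noise, high-energy artifact bursts and flat
electrode-dropout gaps. This is deliberately *not* a physiological PQRST
simulator: the detector under test only needs a dominant R deflection with
exactly known timing, and a parameter-free template keeps the ground truth
exact and reproducible. Beats whose spike would fall outside the sampled
record (e.g. at exactly `duration_s`) are excluded from the ground-truth
beat list; beats inside dropout gaps stay listed but are flagged.

### Device-error model

The wearable channel is generated **at window level** as
truth + bias + noise, independently per parameter, rather than re-derived
from a corrupted IBI stream. This is a deliberate design choice: it gives
the agreement-statistic recovery tests analytically known targets (the
injected bias and SD are exactly what Bland–Altman must recover). Defaults
are parameterized from a published window-level ring-vs-ECG validation:
bias = the reported mean bias per parameter, noise SD = (upper − lower
limit of agreement)/(2·1.96). Values are intentionally not clamped to
physical ranges (a noisy pNN50 may leave [0, 1]); clamping would bias the
recovery targets. The wearable IBI stream itself carries the validity
structure: one contiguous invalid run per 5-minute window covering
`invalid_fraction` of its samples, mimicking motion-artifact episodes
(i.i.d. flags would be unrealistically easy to gate).

What the generator does **not** emulate: between-subject variance in the
true parameters (all nights share one tachogram spec, so only jitter
differentiates windows), respiration-coupled HF dynamics, sleep-stage
transitions, and the vendor's proprietary PPG processing. Consequently the
synthetic world's Pearson correlations between the channels are near zero —
the high correlations in real validation studies are driven by
between-subject spread — and a green recovery test establishes correct
*estimation* of bias and limits, not realistic correlation structure.

## 2. ECG processing chain

1. **Band-pass filtering.** Butterworth band-pass, 0.5–100 Hz, order 4,
   applied zero-phase. The filter is realized in the frequency domain as
   the squared analog Butterworth magnitude response — exactly the
   magnitude of a forward–backward (filtfilt) pass — with ~10 s reflection
   padding against wrap-around, and zero-padding to a 2-3-5-smooth FFT
   length. Zero phase matters because any group delay would shift R-peak
   latencies and corrupt interval statistics. (No signal-processing package
   with a Butterworth designer is available in the target environment, so
   the filter is implemented here; its response is verified against the
   closed-form Butterworth magnitude in the tests.)
2. **Windowing.** Non-overlapping 5-minute windows aligned to the record
   start (clock alignment is not assumed); a trailing partial window is
   dropped.
3. **Round-1 peak detection.** All strict local maxima above the window
   mean amplitude. By construction this over-detects: P/T waves and noise
   peaks above the mean are included.
4. **Round-2 refinement.** Three rules derived from the 50–200 bpm normal
   heart-rate range, iterated to a fixed point:
   * amplitude: retain peaks ≥ θ (default 0.5) times the mean peak
     amplitude. The mean is seeded from the round-1 candidates and then
     **iterated over the retained set**. This departs from a single-pass
     reading of "the average value of the peaks detected in the first
     round": with P/T candidates present that average sits far below the
     R amplitude, and a T wave whose R spike fell just outside the window
     boundary would survive as a false beat. Iterating converges the
     threshold to a fraction of the R amplitude and sheds such stragglers;
     it also makes the operator idempotent, which single-pass thresholding
     is not.
   * refractory: of two retained peaks closer than 300 ms (= 60/200 bpm),
     keep the larger; equal amplitudes keep the earlier (deterministic
     tie-break). Peaks rejected here are barred from re-admission, which
     guarantees loop termination.
   * search-back: a gap longer than 1200 ms (= 60/50 bpm) between retained
     peaks is re-scanned and the largest round-1 candidate above θ′
     (default 0.3) of the mean round-1 amplitude is re-admitted.
     Re-admissions are exempt from the iterated amplitude rule — they
     passed the lowered threshold deliberately.
   θ and θ′ are not dictated by the underlying method description; the
   defaults were chosen so clean synthetic ECG is detected perfectly and
   both are exposed in the configuration. Detection operates on the signed
   filtered signal (not its absolute value) and all thresholds are
   relative, so detection is invariant to uniform amplitude scaling.
5. **Window validation.** RR intervals outside 300–1200 ms are flagged
   invalid; a window is rejected when its mean HR leaves 50–200 bpm or the
   valid-RR fraction falls below φ = 0.8. φ quantifies an otherwise
   qualitative "signal quality" criterion and is configuration-exposed;
   the HR rule is checked first, so a window failing both reports
   "HR out of range".

## 3. HRV parameters

Per retained window, from the valid (normal-to-normal) intervals:

* AVNN = mean; SDNN = sample SD (n−1 denominator; unstated in the source
  methodology, chosen as the statistical default);
* RMSSD = $\sqrt{\mathrm{mean}(\Delta NN^2)}$ over *adjacent valid pairs*
  — an invalid interval breaks adjacency on both sides;
* pNN50 = (# adjacent pairs with |ΔNN| > 50 ms) / (**total number of NN
  intervals**), reported as a proportion. Most references divide by the
  number of successive pairs; the printed definition this package follows
  divides by the interval count, and that definition is kept deliberately;
* HR = 60000/AVNN for the ECG channel; the wearable channel reports its
  own HR and RMSSD, which are taken as-is rather than recomputed.

**Spectral estimation** uses the Lomb–Scargle periodogram on the unevenly
sampled NN series (abscissa = cumulative beat time, values in ms). This
avoids the interpolation bias that resample-then-Welch estimators introduce
on gapped wearable IBI data. The periodogram (classic Scargle form, verified
against an independent reference implementation to 14 digits) is evaluated
on a grid from $1/(4T)$ to the pseudo-Nyquist frequency $1/(2\,\overline{NN})$
with spacing $1/(4T)$, then scaled so its integral over the grid equals the
sample variance of the NN values. Band powers are the integrals over
LF = [0.04, 0.15) Hz and HF = [0.15, 0.4] Hz — half-open at 0.15 Hz so the
boundary is counted once. Under this normalization a pure sinusoidal
modulation of amplitude $A$ recovers band power $A^2/2$, which is the
package's spectral acceptance oracle. LF:HF is reported as missing (never
infinite) when HF = 0. Frequency-domain values require ≥ 30 valid intervals
spanning ≥ 120 s (a pragmatic floor below which band integrals are
meaningless); windows below the floor carry NA and still contribute their
time-domain values to nightly means.

**Wearable gate.** A wearable window is used only if at least 30 % of its
IBI samples are valid — boundary inclusive, so exactly 30 % is kept. Gated
windows carry no HRV values and are excluded from pairing and nightly
averages.

**Nightly averages** are unweighted means over non-gated windows with
per-parameter missingness handled independently (a window missing LF:HF
still contributes its HR).

## 4. Agreement statistics

For each parameter, matched wearable/reference pairs (inner join on window
start time or night id; units missing on either side are dropped and
counted) feed three analyses:

* **Pearson correlation** with two-sided p-value (p-values are reported,
  never used for gating);
* **Regression**: OLS of wearable on reference (reference on the abscissa,
  matching the plotting convention of published validation figures;
  the opposite orientation is available behind a flag),
  $r^2 = 1 - SS_{res}/SS_{tot}$, plotted against the identity line;
* **Bland–Altman**: differences d = wearable − reference (so an
  underestimating device shows negative bias), mean bias, sample SD of d,
  and 95 % limits of agreement bias ± 1.96·SD. The "95 % CI" column of the
  source study's tables is interpreted as these limits: its HR row equals
  −0.44 ± 1.96·1.21, which is inconsistent with a CI of the mean at
  n ≈ 3000 windows.

The identity $r^2 = r_{Pearson}^2$ for simple linear regression is asserted
to 1e−9 wherever both sides are defined. Note one degenerate case by
design: the analytic spectral ground truth is constant across windows, so
frequency-domain reference columns of the recovery study have zero variance
and correlation/regression are undefined there (Bland–Altman is not).

Interpretive correlation labels (≥ 0.7 high, 0.5–0.7 moderate, < 0.5 low)
are attached to reports as a convenience and carry no analytic weight.

## 5. Pipeline, reproducibility and performance

`study_config()` collects every parameter above; `run_study()` simulates
(or would ingest) the nights, runs both channels, pairs windows and nights,
and emits agreement tables, an exclusion table (one row per excluded unit
with stage and reason; used + excluded always reconciles to the total) and,
with an output directory, delimited-text tables whose headers carry the
MD5 hash of the scientific configuration. The hash excludes the output path
and plot toggle, so reruns into different directories are byte-identical —
this is tested literally, file by file. All randomness flows from explicit
seeds in the specs (per-night streams are derived deterministically); no
function perturbs the caller's RNG state.

Scale: the statistical recovery study (35 nights × 16 windows, reference
from ground truth) runs in seconds. The full ECG-waveform chain costs
roughly 30 s per 8.25 h night in pure R (waveform synthesis and FFT
filtering dominate); nights are processed sequentially so memory stays
bounded. Tests and the acceptance script therefore exercise the ECG chain
on shortened nights — the chain is identical, only the duration differs.

## 6. Known limitations

* The synthetic wearable channel bypasses the vendor's actual IBI
  processing; recovery results validate the *statistics*, not any real
  device.
* Pooled window-level agreement ignores within-participant correlation, as
  in the replicated analysis; repeated-measures Bland–Altman corrections
  and CIs on the limits of agreement are out of scope.
* 24-hour HRV metrics (SDANN, triangular index), nonlinear indices and
  normalized-unit LF/HF are out of scope.
* The two-round detector assumes R-dominant, positive-deflection
  morphology (as in a Lead II-style signal); inverted or multi-lead
  recordings are not handled.
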