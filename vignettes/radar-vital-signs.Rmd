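---
title: "Extracting vital signs from laterally positioned FMCW radar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting vital signs from laterally positioned FMCW radar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radarvitals)
```

## The measurement problem

A frequency-modulated continuous-wave (FMCW) radar sweeping a bandwidth
$B$ partitions space into spherical shells ("range bins") of depth
$c/(2B)$ — about 5 cm for a 60–63 GHz sweep. Within one bin, sub-millimetre
motion of a reflecting surface appears in the phase of the returned wave:

$$\varphi = \frac{4\pi f_{\min} R}{c},$$

so a 1 mm displacement at 60 GHz is a comfortable ~2.5 rad. Breathing moves
the torso surface by 1–5 mm at 0.1–0.4 Hz; the heartbeat pulse moves the
skin by only 0.29–0.57 mm at 0.8–1.7 Hz. Because breathing is an order of
magnitude larger and its harmonics reach into the heart band, the pulse is
easily *masked* wherever both motions fall into the same bin.

The package is built around one physiological observation: a radar placed
*laterally* (at the foot end of the bed, or on a nightstand) maps distinct
body zones onto distinct range bins. Legs and feet carry a (damped, delayed)
heartbeat pulse but no breathing, so a lateral view supplies bins in which
the pulse is unmasked by construction. A ceiling radar looking top-down sees
the whole body in a handful of bins and every bin mixes both motions. All
signal containers in the package carry displacement in metres per bin
(unwrapped phase already converted through the relation above), so the 1 mm
artifact threshold below applies directly.

## The extraction pipeline

Rates are computed on a sliding 60 s window with 40 s overlap (20 s hop),
giving a frequency resolution of 1 BPM and one estimate per window per mode.

**Range-bin selection** (`select_bins()`):

1. *Spatial gate* — keep bins with centre range in the closed interval
   [0.45 m, 3 m]; closer bins are corrupted by antenna cross-talk, farther
   ones lie beyond the bed. The bin centre convention is
   $(i + \tfrac12)\,c/(2B)$ for 0-based index $i$.
2. *Artifact gate* — a bin is dropped for the window when any
   sample-to-sample displacement step exceeds 1 mm: no vital motion moves
   the body by a whole breath's amplitude in 50 ms. The test is per bin, so
   a moving limb does not discard a calm torso; if every bin fails, the
   window is marked as containing no radar vital signs.
3. *Magnitude screen* (breathing only) — a human body modulates the
   reflected energy, static clutter does not. The `k_top = 3` bins with the
   highest temporal magnitude SD are kept with `halo = 2` neighbours on
   each side (3 ± 2 bins ≈ 25 cm, a torso depth at 5 cm bins). Pulse-only
   bins do not stand out in magnitude, so the heartbeat search skips this
   screen.
4. *Temporal phase coherency (TPC)* — each surviving bin is bandpass
   filtered (zero-phase second-order Butterworth; 0.1–0.4 Hz or
   0.8–1.7 Hz), normalised by its Hilbert envelope to lie in (−1, 1), and
   its average period $T$ is estimated from the zero crossings. The TPC is
   the correlation of the normalised signal $\hat P$ with itself shifted by
   $T$:

   $$\mathrm{TPC} = \frac{\sum_{s} \hat P(s)\,\hat P(s-T)}
     {\sigma_{\hat P(t)}\;\sigma_{\hat P(t-T)}},$$

   evaluated over the two aligned segments of length $t_0 - T$ and divided
   by the overlap sample count so that scores are comparable across bins
   with different periods and bounded by 1. The five bins with the highest
   TPC proceed; ties break towards the radar, where SNR is higher.

**Breathing rate** (`breathing_rate_from_signal()`): the *raw* windowed
signal is autocorrelated with per-lag normalisation,

$$\rho(k) = \frac{\mathrm{Cov}(X_t, X_{t-k})}{\sigma(X_t)\,\sigma(X_{t-k})},$$

so every lag is a genuine Pearson correlation. The width of the middle peak
— twice the first trough lag — must lie inside the breathing cycle range
(2.5–10 s, from the 0.1–0.4 Hz band) or the computation stops: broadband
artifacts collapse the middle peak, drifts and body-movement bumps widen
it. The input is deliberately *not* bandpass filtered first: filtering folds
any artifact into the breathing band and blunts exactly this test (an
in-band signal can only ever produce widths of 2.5–10 s). The rate is
$60/\ell$ BPM for the first autocorrelation peak lag $\ell$ inside 2.5–10 s.
The belt reference uses this same function — one implementation, two
sensors.

**Heart rate** (`heart_rate_from_bin()`): peaks of the envelope-normalised
heart-band signal (the TPC intermediate) are detected with a refractory
separation adapted to the signal's own periodicity — the candidate beat
period is the smallest autocorrelation-peak lag in the physiological range
whose correlation comes within 0.05 of the in-range maximum, and peaks
closer than 0.6 of that period are suppressed. The adaptive window matters
near the 0.8 Hz band edge, where the filter attenuates the pulse
fundamental ~4× but passes its second harmonic: with a fixed band-based
separation the intervals come out at double rate. The hint abstains
whenever a *sub*-range lag correlates equally well, so genuinely
out-of-band pulse trains still fail the physiological check. Peak times are
refined by parabolic interpolation, peak-to-peak intervals are median
filtered (kernel 3) to repair isolated missed beats, the bin is discarded
if the mean filtered interval leaves the 48–102 BPM band, and the rate is
the inverse mean filtered interval.

**ECG reference** (`ecg_heart_rate()`): a stationary (undecimated) wavelet
decomposition with the Symlet-4 wavelet, whose shape resembles the QRS
complex. At 256 Hz, detail levels 4–5 (≈4–16 Hz) carry the QRS energy; the
summed details are enveloped and peak-detected, and the rate is the inverse
mean peak-to-peak interval. The level choice is configurable; QRS energy is
classically quoted at 8–25 Hz, and the synthetic QRS used in the tests
(Mexican-hat, σ = 20 ms) peaks near 11 Hz.

## Parameters that matter

| Parameter | Default | Unit | Rationale |
|---|---|---|---|
| window / overlap | 60 / 40 | s | 1 BPM resolution; 20 s hop |
| artifact threshold | 1 | mm/sample | a breath-sized step in 50 ms is never physiological |
| spatial gate | 0.45–3.0 | m | cross-talk floor, bed length |
| `k_top`, `halo` | 3, 2 | bins | torso ≈ 25 cm at 5 cm bins |
| TPC bands | 0.1–0.4, 0.8–1.7 | Hz | breathing / heart physiological bands |
| peak prominence | 0.1 | normalised | permissive floor on (−1,1) signals |
| heart peak separation | 0.6 × period hint | s | adaptive refractory; falls back to 0.5/1.7 s |
| median filter kernel | 3 | intervals | smallest kernel repairing isolated missed beats |
| ECG SWT levels | 4–5 of 5 | – | ≈4–16 Hz at 256 Hz |
| envelope floor | 1e−9 | m | avoids division blow-ups in dead bins |

## The synthetic sleeping body

Overnight recordings of sleeping subjects generally cannot be
redistributed, so the package ships a seeded simulator
(`make_scenario()`, `simulate_recording()`) that generates the range-time
displacement and magnitude matrices together with matched reference
channels (32 Hz belt, 256 Hz ECG-like QRS train) and per-window truth.

What it emulates:

* five body zones (feet, legs, abdomen, thorax, head) with position-specific
  range spans: foot-end view from ~0.6 m (feet) to ~2.2 m (head);
  nightstand view with the torso nearest and attenuated leg reflections;
  ceiling view with all zones superimposed in a ~15 cm span;
* breathing as a raised-cosine cycle (inhale faster than exhale, 0.4 : 0.6)
  scaled 1–5 mm, with a `"sharp"` variant (brisk inhale, passive exhale,
  end-expiratory pause) whose harmonics genuinely reach the heart band —
  the masking regime;
* the heartbeat as a smooth unipolar pulse train (0.29–0.57 mm at the
  thorax, gain 0.3 and ~0.15–0.2 s pulse delay at the legs/feet: the distal
  pulse is attenuated but detectable);
* rate tracks wandering slowly inside 6–24 BPM and 48–102 BPM;
* per-sample Gaussian phase-displacement noise (default 0.03 mm — the
  phase accuracy of a 60 GHz bin is well below 1 mm; at this level the
  distal pulse is detectable but not trivially clean);
* magnitude as static clutter plus body-bin fluctuation proportional to
  motion; injected large-motion artifacts; optional out-of-bed intervals.

What it does not emulate: electromagnetic scattering, multipath, antenna
patterns, angle estimation, raw chirp processing, and the full morphology
of real ECG or belt signals. Passing tests therefore demonstrate that the
pipeline recovers what this body model encodes — spatially separated
vital-sign motion under noise, harmonics and artifacts — not performance on
any particular hardware.

Ceiling zone gains are tempered (breathing 0.7/0.5 for thorax/abdomen
instead of 1.0/0.9) because summing co-located zones at full amplitude
would overstate the motion of a shared shell — a bin containing two
surfaces does not move twice as far.

## Numerical and design choices

* **Zero-phase filtering** keeps all bins and both sensors time-aligned;
  the filter direction is otherwise arbitrary.
* **TPC normalisation**: the raw statistic is an unnormalised product sum;
  dividing by the overlap count makes scores comparable across periods,
  which the top-5 ranking requires.
* **Width-test pad**: trough lags are quantised to the frame period, so the
  2.5–10 s bounds are applied inclusively with a one-lag pad — a 6 BPM
  breath sits exactly on the 10 s bound.
* **Best-bin choice, breathing**: both stated quality criteria (inter-peak
  SD, first-peak ρ) are used, with ρ quantised to 0.02 ranked first and SD
  breaking ties. Bandpass-filtered noise in an empty bin is quasi-periodic
  and can show deceptively regular peak spacing (low SD) but never a high
  peak correlation, so ρ must dominate. Inter-peak SD uses all
  autocorrelogram peaks up to a 30 s lag horizon so at least two peak
  distances exist for slow breathing.
* **Best-bin choice, heart**: lowest interval SD, ties to the higher TPC.
* **Sub-sample peak timing**: peak positions are refined by parabolic
  interpolation; at a 20 Hz frame rate the raw 50 ms quantisation would
  otherwise bias the median-filtered mean interval by over 1 BPM.
* **Degenerate inputs**: constant bins, zero-variance windows and dead
  envelopes all fail soft (explicit `fail_reason` / `empty_reason`), never
  with an exception; an all-artifact window is marked as having no radar
  vital signs.

## Problem sizes used in the checks

The test-suite checks run at desk scale, chosen to finish in minutes on one
CPU while keeping the Monte-Carlo margins interpretable: 200 independent
60 s clean windows for parameter recovery (breathing and heart rates drawn
uniformly in-band), ten seeded 30-minute harmonic-rich scenarios per radar
position for the positional comparison, ten seeds for the
thoracic/abdominal localisation, and 15–40 seeds for the smaller
property checks. `scripts/acceptance.R` re-runs the same computations from
scratch and writes the resulting numbers as JSON.

## Known limitations

* Heart rates just above 48 BPM put the pulse's second harmonic inside the
  0.8–1.7 Hz band while the fundamental sits on the filter edge. The
  adaptive refractory window resolves most of these windows, but a residual
  minority of rate draws in this corner still miss by more than 1 BPM —
  intrinsic to peak-interval estimation on a band that spans one octave.
* The width test cannot reject artifacts whose autocorrelation structure
  mimics a breathing cycle length; it targets broadband noise and
  drift-like motion.
* Bins are selected per window with no tracking across windows; a subject
  moving between windows simply re-selects.
* The simulator's truth is the mean instantaneous rate per window; with
  strongly wandering rates the windowed estimate and the truth differ by
  design at the 0.1–0.3 BPM level.
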