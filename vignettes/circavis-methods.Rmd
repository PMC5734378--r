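---
title: "Models and methods behind circavis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind circavis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circavis)
```

## What the package models

`circavis` studies a simple question with a layered measurement chain: does
the responsiveness of the fly visual system change with circadian time, and
with what period?  The package provides both the analysis chain and a
synthetic-data generator with known ground truth, so every stage can be
exercised and validated end to end without access to raw recordings.

The measurement chain mirrors standard fly electrophysiology:

1. **Flash ERG.**  A 750 ms light pulse evokes a field potential with a
   sustained corneal-negative *receptor potential* (photoreceptors), fast
   on/off *transients* (synaptic, lamina), and a return to baseline.
   Features extracted: peak-to-peak height, receptor-potential magnitude,
   off-transient magnitude, and latency.
2. **Two-frequency SSVEP.**  The light is the sum of two square waves, 12 Hz
   (contrast $c_1$) and 15 Hz ($c_2$).  Because the retina-to-medulla
   pathway is nonlinear, the recorded steady-state response carries energy
   not only at the stimulus fundamentals but at harmonics and
   intermodulation frequencies.  The anatomical attribution used throughout
   is: 1F1 (12 Hz) — photoreceptors; 2F1 (24 Hz) — lamina; intermodulation
   terms, reported as 2F1+2F2 (54 Hz) — medulla.  Frequency-domain analysis
   at exact stimulus bins makes these components essentially immune to
   broadband noise.
3. **Cosinor-style period estimation.**  Per-fly component amplitudes
   sampled over circadian time are fit with
   $$SS(t) = C + \alpha\,\sin(2\pi t/\Omega) + \beta\,\cos(2\pi t/\Omega),$$
   with $t$ in days and the period $\Omega$ a free parameter.
4. **Locomotor rhythmicity.**  Activity counts in 2-min bins from a
   Trikinetics-style monitor are rebinned, displayed as daily profiles, and
   classified as rhythmic/arrhythmic per fly with a Lomb-Scargle
   periodogram over a circadian band.

## The synthetic cascade and why it is filtered

The SSVEP generator drives three stages with
$s(t) = c_1\,\mathrm{sq}_{12}(t) + c_2\,\mathrm{sq}_{15}(t)$:

* photoreceptor: $y_1 = g_1 s$ (linear, broadband);
* lamina: $y_2 = g_2\,[\mathrm{LP}(y_1)]^2$;
* medulla: $y_3 = g_3\,[\mathrm{LP}(y_2)]^2$;
* trace $= w_1 y_1 + w_2 y_2 + w_3 y_3 +$ white Gaussian noise.

Squaring is the minimal smooth nonlinearity that generates exactly the
observed frequency taxonomy: stage 2 produces $2F_1$ (24 Hz), $2F_2$
(30 Hz), $F_2\!-\!F_1$ (3 Hz) and $F_1\!+\!F_2$ (27 Hz); stage 3 produces
$2F_1\!+\!2F_2$ (54 Hz).  One subtlety forces the low-pass step: an ideal
$\pm 1$ square wave squares to the constant 1, because the products of its
odd harmonics cancel exactly.  A first-order "synaptic" low-pass (default
cutoff 50 Hz) applied to each squaring stage's input perturbs the harmonic
weights, breaking that cancellation, so the second-order terms survive —
while the *linear* photoreceptor stage stays unfiltered, keeping the
analytic square-wave identity (fundamental amplitude $4/\pi \cdot c_1 g_1
w_1$) available as an exact spectral oracle.  The cascade is a frequency
taxonomy generator, not a biophysical phototransduction model; eye-color
screening-pigment effects are represented only as gain scalars.

Circadian modulation multiplies each stage gain by a `gain_profile`:
mesor plus one or two cosines in circadian time.  The default experiment
contrasts a control-like genotype (single 14.6 h component — two peaks per
day, peak CT6) with a clock-mutant-like genotype (single 25.2 h component,
peak CT4).  Both use relative amplitude 0.3 around mesor 1, and downstream
recovery tests use response noise at 20% of that amplitude — a
signal-to-noise regime in which 12-timepoint designs still identify the
period to about half an hour.

## Exact-bin spectral protocol

Trial durations are restricted to integer seconds so that every analyzed
frequency (3, 12, 24, 27, 54 Hz) falls on an exact DFT bin; the amplitude
spectrum uses a rectangular window and is normalized so a sinusoid of
amplitude $a$ reads $a$ at its bin.  Non-integer durations are rejected
rather than windowed, because bin leakage would contaminate the
intermodulation terms that the method depends on.  The per-component noise
floor is the mean amplitude over the two flanking bins on each side,
skipping any flanking bin that is itself a harmonic or intermodulation
frequency ($|a f_1 + b f_2|$, $|a|,|b| \le 4$); both the flank count and the
exclusion set are configurable.

The simulated protocol presents 18 trials with contrasts drawn uniformly
from $\{0.1, \dots, 0.9\}$ per channel; only trials 10–18 enter summaries,
discarding the adaptation phase.  The per-fly value carried into period
fitting is the **maximum** component amplitude over the analyzed trials
(a mean-based summary is available).  Contrast-response steepness is
summarized as the slope of an origin-anchored least-squares line; the
driving contrast is $c_1$ for 1F1/2F1 and the product $c_1 c_2$ for
intermodulation terms, whose drive requires both inputs.  No saturating
contrast-response model is fit.

## Period estimation: separable grid search plus refinement

For fixed $\Omega$ the model is linear in $(C, \alpha, \beta)$, so the fit
at each candidate period is an exact ordinary-least-squares solve.  The
default grid spans 0.4–1.6 days in 0.01-day steps; the residual sum of
squares plotted against $\Omega$ is the *residual profile*, and all local
minima are reported because half-day and full-day rhythms both produce
dips.  The global minimum (ties broken toward the smaller period,
deterministically) seeds a refinement step.

Refinement uses variable projection: the profiled residual — with the
linear parameters solved exactly at each trial period — is minimized over
$\Omega$ within one grid step of the start (Brent search, tolerance
$10^{-10}$ days).  This is the same estimator as a full four-parameter
nonlinear least squares but remains stable on zero-residual (noiseless)
data, where generic Gauss–Newton iterations stall; the test suite verifies
agreement with `stats::nls` to five decimals, including standard errors, on
noisy data.  Uncertainties are linearized (Jacobian-based) standard errors
from the full four-parameter model, scaled by residual variance, and are
labelled as SEs.  Fits run on cohort data (all flies' values at each
timepoint) by default, producing one fitted line per genotype; per-fly
series can be fit by constructing per-fly `circadian_series` objects.
Degenerate designs (fewer than 4 samples, or all sampling times equal)
error out at the linear-fit level rather than returning silent garbage.

## Locomotor analysis

The activity generator draws Poisson counts per 2-min bin.  In LD, the
expected rate is baseline × Gaussian peak shaping (morning/evening peaks,
SD 1.5 h) × $(1 + \text{step})$ after ZT12 — the step models the nocturnal
phenotype in which activity rises ~60% after lights-off and stays elevated.
In DD, a seed-deterministic subset of $\lfloor \text{fraction} \cdot n
\rfloor$ flies (first $k$ of a seeded shuffle, recorded in metadata) gets
sinusoidal rate modulation at the free-running period (default depth 0.5);
the rest are Poisson-constant.

The Lomb-Scargle periodogram is the classical normalized form, computed on
30-min rebinned DD counts (the rebinning is configurable; it speeds cohort
scans ~15-fold and is transparent at circadian periods).  The band is
16–32 h in 0.1 h steps; significance uses the M-independent-frequencies
approximation $z = -\ln(1 - (1-\alpha)^{1/M})$ with $M$ the number of
scanned periods and $\alpha = 0.05$.  Because the scanned frequencies are
correlated, this threshold is conservative: the realized false-positive
rate on Poisson-constant cohorts is measured at ~2–4%, comfortably below
$\alpha$.  A fly is rhythmic iff its peak in-band power exceeds the
threshold; the period estimate is the peak period.  The daily-profile
lights-off step is estimated as (first 30-min bin after lights-off − mean
ZT0–12 rate) / mean ZT0–12 rate, and is exactly scale-invariant.  DD
profiles are aligned to projected CT assuming 24-h cycles from the last
lights-on.  No chi-square periodogram, autocorrelation, or sleep-bout
analysis is provided.

## fERG template and feature conventions

The template is baseline + gain × (exponential-rise sustained negativity
during the pulse; alpha-function on/off transients peaking
`tau_transient` after each light transition; exponential return after
offset).  Feature windows are fixed, documented defaults: 100 ms baseline
before onset, last 50 ms of the pulse for the plateau (the receptor
potential is read at plateau, not at peak negativity), 100 ms after offset
for the off-transient extremum, and onset→offset+300 ms for peak-to-peak.
Latency is the time to half the sustained deflection; it is reported as
missing, not zero, when the receptor potential is zero.  Amplitudes are
magnitudes.  Two consequences worth knowing: the off-transient window reads
the deviation from the plateau level, so templates whose sustained
potential decays quickly within that window bias the off-transient upward —
validation templates therefore use a slow post-offset decay; and
peak-to-peak is computed strictly inside the response window, so it can
fall below the receptor potential for waveforms with large negative
on-transients.

## Determinism and problem sizes

Every stochastic step takes an explicit integer seed, isolated with
`withr::with_seed` so the global RNG stream is never consumed; one global
seed expands into per-stage and per-fly sub-seeds via a seeded
`sample.int` draw.  Reruns with identical configuration and seed are
bit-identical, and stage CSVs are serialized at 17 significant digits so a
resumed run regenerates deleted downstream outputs byte for byte.

Defaults were chosen as a realistic desk-scale study: 12 circadian
timepoints (every 4 h over two DD days), 4 flies per timepoint, 18 trials
of 2 s at 1 kHz per fly, locomotor cohorts of tens of flies over 3 LD + 9
DD days.  Validation simulations in the test suite use 50–500 replicates
per property.  What passing these tests shows is that the chain recovers
the structure *it assumes*: sinusoidal (or two-component cosine) gain
rhythms, white Gaussian recording noise, Poisson counts, stationary
periods.  Real recordings add drift, non-Gaussian artifacts, inter-fly
amplitude heterogeneity, and waveform idiosyncrasies that the generator
deliberately does not model, so the synthetic results bound method error,
not biological variability.
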