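---
title: "Two-stage LSTM detection of apnea and hypopnea episodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage LSTM detection of apnea and hypopnea episodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdbdetect)
```

## The problem

Sleep-disordered breathing is scored from overnight recordings as discrete
episodes: an *apnea* is a near-complete cessation of airflow (at least a
90% amplitude drop), a *hypopnea* a partial reduction (at least 30%), and
both must last at least 10 s to be clinically relevant. Per-patient
severity is summarized by events per hour: the apnea index (AI), hypopnea
index (HI) and their sum. When no sleep staging is available — the normal
situation for at-home polygraphy — total recording time is used as the
denominator, giving the respiratory event index (REI), a surrogate for
the AHI. Severity classes follow the standard boundaries REI &lt; 5
(Normal), 5–15 (Mild), 15–30 (Moderate), ≥ 30 (Severe), with left-closed
intervals, so REI = 5 is Mild and REI = 30 is Severe.

`sdbdetect` detects and classifies these episodes from three respiratory
channels that every polygraph records: oronasal airflow (thermal sensor)
and thoracic and abdominal respiratory effort, working at a 10 Hz sample
rate. Obstructive, central and mixed events are not distinguished; SpO2
is not used.

## The model

The detector is a cascade of two sequence classifiers around dedicated
pre- and postprocessing.

**Preprocessing.** Each channel has its mean removed and is multiplied by
a scaling factor $SF = A \cdot N / \sum_{n=1}^{N} |x(n)|^2$, which evens
out sensor and patient amplitude differences; with the default $A = 0.5$
a unit-amplitude sine maps to unit amplitude, so signals land roughly in
$(-1, 1)$. The airflow channel is inverted (thermal airflow sensors read
opposite in sign to effort belts; toggleable per dataset). All channels
pass through an order-8 Butterworth low-pass at 1.25 Hz applied forward
and backward (`signal::filtfilt`), preserving phase. Finally, airflow and
abdominal effort are shifted by the integer-sample lag (within ±5 s) that
maximizes their normalized cross-correlation with the thoracic channel;
the thoracic channel — the time base of the annotations — is never moved.
Sub-sample alignment is not attempted because all downstream products
live on a 0.5 s grid. A record-quality screen computes each channel's
energy divided by recording length and rejects records with any channel
below a threshold (default 0.05, calibrated to reject channels that are
indistinguishable from the simulator's noise floor).

**Stage 1 — onset-aware window labelling.** The record is cut into 16 s
windows with 0.5 s stride (160 × 3 samples; each window's per-channel
mean is removed). Labels are *N* (every 0.5 s grid point in the window
unannotated), *A* (every point inside an apnea) and *Hb* — a hypopnea
*onset* lies 4–12 s after the window start. The Hb class exists because
the ≥ 30% amplitude drop that defines a hypopnea is only visible at its
onset; later parts of a hypopnea can resemble normal breathing, and
normal amplitude itself drifts over the night. Windows matching no rule
are discarded; both endpoint bounds of the onset range are treated as
inclusive (the convention is stated nowhere authoritative, and the choice
only moves one 0.5 s window at each end). If a window satisfies the Hb
rule and simultaneously full apnea coverage (possible only through a
sub-0.5 s annotation gap), Hb wins: onset detection is the class's
purpose. Classes are balanced by seeded uniform undersampling to the
minority count. The window classifier is an LSTM (150 units at full
scale), dropout 0.5, a 30-unit ReLU dense layer, dropout 0.5 and a
3-class softmax, trained with Adam for 50 epochs. Class probabilities of
consecutive windows are lined up at the window starts (2 Hz) and smoothed
with a trailing 32-sample moving average with shrinking support at the
edges — the unique placement for which each smoothed sample is the mean
probability of every window containing that instant.

**Stage 2 — episode boundaries.** A fourth input series summarizes breath
strength: airflow zero crossings (exact zeros attach to the preceding
segment) partition the record into inspirations/expirations; per segment
and channel the scaled energy $E = \sum |x(n)|^2 / N^2$ is computed, the
segment is filled with the *minimum* of the three channel energies, and
the 10 Hz piecewise-constant series is decimated to 2 Hz (every 5th
sample — it is constant within breaths, so no anti-alias filter is
needed) and divided by its maximum. Decimation-then-normalization makes
the signal invariant to any common rescaling of the channels. The three
smoothed stage-1 probabilities (extended to the full-record grid by
repeating the final row, since the last window starts 16 s before the
record ends) and the minimal-energy series are windowed at 32 s / 0.5 s
stride (64 × 4). Each window is labelled by the class at its *ending
point* (N/A/H, half-open lookup), trained with the same topology for 100
epochs, and probabilities are stamped at window ends so that argmax
transitions translate directly into episode borders. No per-window mean
removal is applied here: probabilities and the normalized energy are
already bounded.

**Postprocessing.** Episode borders are placed where the argmax label
switches between N and {A, H}; A↔H switches never split an episode. Each
episode takes the class holding the argmax at the majority of its grid
points; its *certainty* is the arithmetic mean of the assigned class's
probability over **all** the episode's grid points (not only the points
it wins — the alternative reading; the all-points mean is kept because it
is what the per-episode mean of a probability series naturally is, and it
makes certainty comparable between fragmented and clean episodes).
Majority ties break to the higher mean class probability, then to apnea.
Class-specific certainty thresholds are chosen by exhaustive grid search
(default 0–1 in steps of 0.02) minimizing the RMSE of AI and HI across
validation records never used for network training; episodes shorter than
10 s are excluded from both threshold determination and index
calculation, and grid ties resolve to the smallest threshold (keeping
more events). Finally, *additional marking*: with
$N_{thr} = 1 - \max(A_{thr}, H_{thr})$, any episode removed by its class
threshold whose mean N probability is below $N_{thr}$ is reinstated with
its majority class — these are events the model is confident exist but
cannot cleanly type. Because the extra events push the optimal class
thresholds upward, the threshold search is re-run once with reinstatement
active. Since thresholding operates on whole episodes via their mean
score, raising a threshold removes events but never fragments them.

## The synthetic data generator

No suitable public recordings ship with the package, so a seeded
simulator provides ground-truthed input for every stage. Breathing is a
0.25 Hz sinusoid whose amplitude envelope wanders slowly (a discretized
Ornstein–Uhlenbeck process, SD 0.1, correlation time 60 s), emulating
overnight amplitude drift. The three channels observe the same waveform
with per-channel gain and sensor lag (defaults +0.8 s airflow, 0 s
thoracic, −0.5 s abdominal, exercising phase alignment; the airflow
channel is generated with inverted polarity, which preprocessing undoes).
Episodes multiply the envelope by a *fraction remaining*: ≤ 0.10 for
apnea (≥ 90% drop; default 0.05) and 0.30–0.70 for hypopnea (≥ 30% drop;
default 0.5), for random non-overlapping durations of 15–45 s, with 2 s
raised-cosine ramps so that onsets are visible but not discontinuous.
White Gaussian noise (SD 0.05) is added per channel, and optional wake
intervals superimpose broadband movement-artifact bursts. All randomness
derives from one seed; corpora derive per-record seeds from a master
seed.

What the simulator does *not* model: real breath morphology (flow
limitation plateaus, snoring oscillations), cardiorespiratory coupling,
desaturation physiology, paradoxical thoraco-abdominal motion, sleep
stages beyond binary wake, and scorer disagreement. Tests passing on this
generator therefore demonstrate that the pipeline's machinery — labelling
rules, both networks, thresholding, index arithmetic — is implemented
correctly and can learn amplitude-defined events end to end; they do not
certify clinical accuracy on real polygraphy.

## Scaled study conditions

The packaged end-to-end study (also what `scripts/acceptance.R` runs)
uses 40 records of 30 min split 28/4/8, per-record apnea and hypopnea
counts cycling deterministically over 1–5 each so REI spans all severity
classes, and both networks at reduced size: 32 LSTM units, 30 dense
units, dropout 0.5, batch 128, Adam at 3·10⁻³, 10 epochs for stage 1 and
15 for stage 2, with per-class training windows capped at 3000. These
sizes were chosen as the smallest configuration that exercises every
pipeline component on a single CPU; the learning rate is raised from the
usual 10⁻³ because only a few hundred optimizer steps are taken.

## Numerical and degenerate-input choices

* Times are seconds; intervals are half-open `[start, end)`; sample `n`
  (1-based) covers `[(n-1)/fs, n/fs)`.
* Linear resampling (8 → 10 Hz support for other recorders) preserves
  duration and continues the final segment's slope for grid points past
  the last input sample.
* Scaling a constant (zero-energy after offset removal) signal is an
  error; an all-zero record gives a zero minimal-energy signal with a
  warning rather than 0/0.
* The Butterworth filter refuses series shorter than its warm-up length;
  the alignment search reports when it clamped at the ±5 s bound.
* Records shorter than one window produce an empty window set with a
  warning.
* Training is single-threaded and fully seeded (weight init, dropout
  masks, shuffling), so every model in the test suite is bit-reproducible.

## Limitations

Hypopnea scoring without SpO2 is intrinsically incomplete: clinical rules
require a desaturation or arousal that no respiratory channel carries.
The wake-exclusion analysis uses the episode midpoint to decide
containment (configurable), and the epoch-level evaluation counts every
0.5 s point, so long recordings dominated by normal breathing yield high
total accuracy even when event classes disagree — per-class accuracies
are the informative numbers. The LSTM implementation is deliberately
minimal (no CuDNN, no bidirectionality, no attention) and mirrors the
fixed printed topology.
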