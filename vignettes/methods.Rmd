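---
title: "Methods: beat-to-beat interval extraction from cardiac vibration signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beat-to-beat interval extraction from cardiac vibration signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cvsbeat` extracts beat-to-beat intervals (IBIs) from multichannel cardiac
vibration signals (CVS): ballistocardiograms from piezoelectric or
electromechanical films and load cells, and radar Doppler cardiograms. This
vignette explains the model behind each stage, the parameters that matter,
the numerical choices, what the simulator does and does not emulate, and
the known limitations.

## The signal model

A CVS is quasi-periodic: each heartbeat stamps a waveform whose shape
depends on the sensor, its placement, the subject and the respiratory
phase. Two components matter for timing:

* a **low-frequency body-motion wave** (roughly 1–8 Hz), strong but broad,
  whose peak position wobbles from beat to beat because it reflects
  downstream vascular mechanics;
* a **high-frequency valve component** (roughly 15–25 Hz), weaker but
  sharply localized and tightly locked to the cardiac trigger.

This dissociation is the rationale for optimal band selection: when a
channel carries usable valve energy, timing should be read from the high
band. All filtering is zero-phase (forward–backward Butterworth), because
any phase distortion would move peaks and directly corrupt intervals.

## Window-level heart rate and quality: harmonic summation

The mean heart rate anchors everything downstream (template length, search
windows), so it must be robust to harmonic-dominant spectra. On each 8 s
window (1 s hop) the signal is z-scored, squared — which folds beat energy
onto the envelope's low-order harmonics — and band-passed to 1–10 Hz. The
amplitude spectrum of the Hamming-windowed, 8x zero-padded window is then
scored over a candidate fundamental grid by the summation kernel: weight
$1/i$ at the $i$-th harmonic and $-1/(2i)$ at the flanking half-integer
valleys, for $i \in \{1, 2, 3, 5, 7\}$. The decreasing weights keep higher
harmonics from outscoring the fundamental; the restriction to prime
multipliers (with 1) reduces aliasing between candidates; the valley terms
make a flat spectrum score exactly zero. The candidate grid spans
42–180 bpm in 0.005 Hz steps (0.3 bpm, below the padded-FFT bin width).

Two numerical choices deserve a note:

* **Aperture integration.** The kernel does not read single spectral bins.
  Each harmonic/valley position contributes the spectral mass integrated
  over a 0.25 Hz aperture (an exact integral of the piecewise-linear
  density). Point values are fragile: respiratory frequency modulation
  smears the $k$-th harmonic by $\pm k \cdot \Delta f_{\mathrm{RSA}}$, and a
  padded FFT's peak bin height depends on the padding density. The aperture
  is half the minimum peak-to-valley spacing at the lowest candidate
  fundamental, so apertures never overlap.
* **Quality-index normalization.** The published thresholds
  $Q_1 = 0.52,\ Q_2 = 0.26$ act on a bounded energy-ratio-like index, but
  the normalization that produces that scale is not fully determined by the
  formulas alone; this package defines
  $\mathrm{SQI} = \mathrm{HS}(\hat f_0) / (\sqrt{2}\,\mathrm{sd}(z^2)\, M_1)$,
  where $M_1$ is the aperture mass an ideal unit-amplitude tone would
  produce under identical windowing. A perfectly periodic tone carrying all
  of the squared signal's power scores exactly 1; broadband noise scores
  near 0 (measured: clean synthetic renders 0.45–0.79, white-noise windows
  95th percentile ~0.10, 20x-noise artifact epochs ~0.09). The printed
  thresholds are therefore meaningful on this scale, but transferring them
  to very different hardware should be preceded by the same calibration
  exercise on representative data.

## Band and channel selection

Per channel and window, each band of the bank ($f_L \in \{1,3,5,7\}$ Hz,
$f_H = 40$ Hz, third-order Butterworth, bidirectional) gets an SQI. The
rules, in order: (1) if any band clears $Q_1$, keep the *highest* cutoff
that does; (2) else if any clears $Q_2$, keep the best-scoring band (ties
toward the higher cutoff, consistent with the preference for valve bands);
(3) else discard the channel for this window. The clause-2 condition is
implemented as $Q_2 < \mathrm{SQI} \le Q_1$. Bands carry weight
$\beta = 1 + K (f_L - 1)$ with $K = 0.05$, i.e. 1.0–1.3 across the default
bank, used later to bias per-beat quality toward high-band channels.

## Template groups by sequential clustering

From the first admissible window, peak-centered segments of length
$L = \mathrm{round}(60 / \mathrm{HR} \cdot \mathrm{SR})$ (round-half-even;
window $[p - \lfloor L/2 \rfloor, p + \lceil L/2 \rceil)$ so even and odd
$L$ both yield exactly $L$ samples) are clustered with the basic sequential
algorithmic scheme: a segment joins the cluster maximizing its *minimum*
correlation to the members, or opens a new cluster below $\theta = 0.75$.
Averaging within clusters is deliberately avoided — it would smooth away
morphology — so templates are actual observed segments.

The primary cluster is chosen by the highest mean **center-sample
amplitude** of its members; the package also offers the mean member
L2-norm as `cluster_rank = "l2norm"`. The center-amplitude reading is the
default because with period-length segments, a window centered *anywhere*
inside a beat captures essentially the whole beat's energy: member norms
are nearly position-invariant and cannot distinguish beat-centered
clusters from ones centered on oscillation sidelobes, while the center
amplitude peaks exactly at the beat fiducial. Within the winning cluster
the template is the member with the highest correlation sum to the others;
ties break to the earliest cluster/segment for determinism. Local maxima
are strict (plateaus count once, at their first sample).

If consecutive member centers of the primary cluster leave a gap wider
than $1.5 L$, the beats inside the gaps belong to a different morphology —
typically the opposite respiratory phase. Clusters owning segments inside
those gaps compete by the same ranking for a second template. Two
templates suffice because respiration has two phases; the group never
grows beyond two.

## Beat tracking and updates

Correlation is evaluated **only at local maxima** of the band-filtered
signal (the work per window is peaks x templates, not samples x
templates). The first beat is the best-correlating peak within the first
2 s; each subsequent search is restricted to $[(1-v)L, (1+v)L]$ after the
previous beat with $v = 0.3$, so every emitted interval is physiologically
bounded by construction. Template choice is gated by reliability: only
templates whose correlation at the *previous* beat exceeded
$\theta = 0.75$ compete at the current beat (all compete at cold start —
the gate would otherwise deadlock on the first beat, where no previous
correlation exists). Per-beat quality is
$\mathrm{SQI}_{beat} = \beta \cdot \max(\mathrm{ccf}_1, \mathrm{ccf}_2)$.

An empty search window is a missed beat: the anchor advances by one
expected period, no interval is emitted across the gap, and three
consecutive misses force a template update. Likewise five consecutive
beats below $\theta$, or a window in which *no* channel passes the
spectral screen, trigger an update: band selection and the template group
are recomputed on the most recent full window and tracking resumes from
the last confirmed beat. Between updates the band choice is frozen — the
update rule, not the sliding window, is the re-decision point. The first
and last 0.5 s of the filtered recording are excluded from peak candidates
(forward–backward IIR edge transients). Beat times are reported at sample
resolution; sub-sample refinement is intentionally absent — the
sampling-rate experiment below addresses resolution by resampling instead.

## Fusion

Beats from different channels are aligned greedily in time order into
slots (tolerance 150 ms — below $(1-v)L$ for heart rates up to ~140 bpm,
so adjacent beats cannot merge; configurable). Per slot, channels present
in both this slot and the previous one with a previous-beat quality above
$\theta$ are eligible, and the eligible channel with the highest current
quality supplies the beat; when none is eligible (including the very first
slot) the best present channel is used and the beat is flagged
low-confidence. Fused intervals are differences of consecutive *fused*
beat times, not the source channel's internal intervals, so switching
channels between beats cannot double-count fixed inter-sensor offsets; the
channel-internal interval is carried alongside for audit. Constant
inter-sensor lags are not corrected: interval-level evaluation cancels
them.

## Metrics

Windowed HR errors (MAE, MRAE, SDAE) are computed against the reference
HR $60 / \overline{\mathrm{IBI}}$ of beats inside each window; coverage is
the fraction of windows with at least one admitted channel. For intervals,
each estimated beat is matched to its nearest reference beat within half
the local reference interval (one estimate per reference beat); an
estimated interval is scored only when its endpoints match *consecutive*
reference beats, is correct when $|RR - JJ| \le 30$ ms (inclusive, with a
nanosecond slack against float rounding), precision divides correct by
scored, and the detection rate divides correct by **all** reference
heartbeats — including those inside windows the pipeline discarded, which
is what makes detection rate the fusion-sensitive metric. Bland–Altman
limits are $\mathrm{bias} \pm 1.96\,\mathrm{sd}$ of the paired differences.

## The simulator: what it emulates, and what it does not

`cvs_scenario()` fixes the study conditions; the defaults are the
package's reference conditions: 3 heterogeneous channels (piezo, radar,
load cell), 120 s at 250 Hz, mean HR 72 bpm, respiratory sinus arrhythmia
of ±40 ms at 0.25 Hz, 5 ms white interval jitter (consecutive-interval
ratios clipped to ±30%, matching the detector's search window), 15 dB
in-band SNR, 0.02 mains amplitude at 50 Hz and 0.3 baseline wander at
0.3 Hz. Beats stamp archetype waveshapes — a Gabor-like body-motion wave
plus a Gaussian-enveloped valve burst (constants per archetype in
`archetype_params()`); the burst is locked to the beat fiducial while the
body wave wobbles by 8 ms (sd) around it, reproducing the high-band
precision advantage. Morphology alternation, when on, switches two
waveshape variants with the respiratory phase and modulates amplitude
±20%. Artifact epochs multiply the channel's noise by a gain over a time
span. SNR is defined on beat-waveform power versus additive-noise power
within 1–40 Hz. All randomness flows from one integer seed;
identical scenarios are bit-reproducible.

Not emulated: hemodynamic forward physics, radar front-end processing
(beamforming, phase unwrapping), waveform drift within a recording,
arrhythmic or ectopic beats, and sensor-specific nonlinearities. Passing
tests on these renders therefore demonstrates the algorithm's mechanics —
band preference, two-template recovery, fusion dominance, octave
robustness — not clinical performance on recorded data.

## Problem sizes and design margins

The test-suite and acceptance-script problem sizes are the package's
reference conditions: five 120 s three-channel recordings for end-to-end
recovery; ten 90 s recordings with disjoint 20 s artifact epochs per
channel for fusion dominance; ten paired 60 s single-channel runs for the
band-selection effect (burst gain 1.2, 12 ms body-wave wobble, 20 dB SNR —
conditions under which the low band is wobble-limited while the high band
is quantization-limited); 200 eight-second harmonic-series windows with
the second harmonic amplified up to 3x for octave robustness; and 60 s
recordings at 1000 Hz decimated to 100 Hz for the sampling-rate
experiment, where plain 100 Hz processing loses accuracy to the 10 ms
sample grid while quadratic-spline restoration to 1000 Hz recovers it.
Quadratic (order-2) spline interpolation is used deliberately — not
cubic — implemented as B-spline interpolation with midpoint knots and
phantom boundary points; decimation is plain subsampling without an
anti-alias stage, so any aliasing of out-of-band interference is part of
the modeled experiment.

## Known limitations

* The SQI thresholds' absolute scale rests on this package's
  normalization; other normalizations would need recalibrated thresholds.
* The detector has no arrhythmia model: an ectopic beat outside
  $[(1-v)L, (1+v)L]$ is treated as a miss.
* Beat times are sample-resolution; at 50–100 Hz use the spline
  restoration path.
* The BSAS result is order-dependent by design (it is a single-pass
  scheme); templates therefore depend on the segment order within the
  extraction window.
* Fusion assumes inter-channel lags well below the alignment tolerance;
  sensors with transport delays beyond ~100 ms would need explicit lag
  compensation.
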