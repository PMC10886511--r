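---
title: "Simulating a biohybrid hand: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a biohybrid hand: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`neurotactile` is a closed-loop simulator and analysis pipeline for a
biohybrid neuroprosthetic hand: a cultured cortical network on a
multielectrode array (MEA) controls a robotic finger through spike-rate
decoding, while fingertip forces are encoded into slowly adapting (SA) or
rapidly adapting (RA) mechanoreceptor firing patterns that stimulate the
network back. This vignette explains the models, the tunable parameters and
the choices made where the design was genuinely open. It states no result
that the package's tests and acceptance script do not themselves compute.

## The loop

One control tick is 1 ms. Within a tick:

1. **Culture surrogate.** A recurrent network of 400 Izhikevich neurons
   (80% regular-spiking excitatory with the usual parameter heterogeneity,
   20% fast-spiking inhibitory) is advanced with two 0.5 ms forward-Euler
   substeps. Synapses are current pulses decaying with `tau_syn` = 20 ms;
   excitatory synapses depress (release fraction 0.15, recovery 1.2 s);
   every spike increments a slow adaptation current (decay 4 s). Each
   neuron receives Gaussian background current (SD 4.5 excitatory / 1.8
   inhibitory per substep). This produces irregular population bursts
   separated by roughly one to a few seconds -- the qualitative regime of
   dissociated cortical cultures -- without claiming biophysical fidelity.
2. **Efferent decoding.** Spikes of the neurons captured by the recording
   electrode are summed over tumbling 50 ms bins; a bin with at least 3
   spikes emits a 100 ms TTL pulse, and no new pulse can start while one is
   active. The TTL level commands the finger: contact angle (45 deg) while
   high, open hand (0 deg) otherwise.
3. **Plant.** The tendon-driven finger and its PID controller are
   surrogated by first-order tracking: approach time constant 30 ms,
   release 1000 ms (tendon-driven fingers flex faster than they extend).
   Contact above 15 deg produces a steady force `F_DC` proportional to
   penetration (0.006 contact units/deg) through a viscoelastic backlash of
   4 deg, plus sensor noise (SD 5e-4). The dynamic channel `F_AC` is the
   3-sample centered difference of a 25-sample moving average of `F_DC`.
4. **Afferent encoding.** The Izhikevich encoder neuron (a = 0.1, b = 0.2,
   c = -65 mV, d = 8, membrane polynomial 0.04/5/140, dt = 0.5 ms)
   receives `beta + k_SA*F_DC + k_RA*|F_AC|` (SA) or `alpha + k_RA*|F_AC|`
   (RA) and each threshold crossing raises the 4.5 V stimulation trigger,
   delivered to the afferent electrode on the next tick (the measured
   0.8-1.0 ms loop latency is modeled as this one-tick delay).

The three embodiment configurations differ only in two switches: CL closes
both loop arms; AD runs the encoder but does not transmit stimulation; ES
replaces the decoded command with a 0.25 Hz square wave (2 s contact, 2 s
open, starting out of contact) while still delivering stimulation.

## Parameter choices that were genuinely open

* **Encoder gains.** The source model's gain constants are qualitative
  ("chosen to produce physiologically meaningful patterns"). With the
  Table-of-parameters encoder, the rheobase is exactly I = 4 (the
  discriminant of `0.04 v^2 + 4.8 v + 140 + I` vanishes there), so a
  baseline of 4 fires at zero force. We therefore use `beta = 3`,
  `alpha = 2`, `k_SA = 20`, `k_RA = 8`: the SA baseline is clearly
  subthreshold, a held tap (`F_DC` about 0.18) drives roughly 40 Hz tonic
  firing (measured f-I curve: I = 6 gives 42 Hz), and contact edges drive
  RA bursts of a handful of spikes.
* **Rectified dynamic channel.** The literal affine encoder maps carry a
  signed `F_AC`; a release transient would then be purely suppressive and
  RA would never respond to contact offset. The fingertip sensor's dynamic
  channel is AC-coupled vibration magnitude, so the loop feeds the encoder
  `|dF_DC/dt|`. `compute_input_current()` itself remains the literal
  affine map of whatever dynamic value it is given.
* **Slow release and backlash.** With a fast symmetric servo, the 50 ms
  command dropouts inside a TTL chain put flutter on the force derivative
  that drives spurious RA firing and latches the loop. The slow release
  keeps `|F_AC|` below the RA rheobase during release and the 4 deg
  backlash absorbs residual flutter, so RA stays phasic in the closed loop.
  A consequence worth knowing: smooth servo releases attenuate contact-
  offset transients, so RA offset bursts appear for sharp force profiles
  (rectangular test signals, ES command steps) but are weak for decoded
  taps.
* **Stimulation pathway and electrode selection.** The recording protocol
  selects a recording site with healthy activity and a stimulation site
  that responds to pulses; the surrogate seeds about ten units at the
  recording (efferent) electrode and gives delivered pulses a direct drive
  onto them (`pathway_gain` = 0.2 of the stimulation amplitude). The
  pathway shares a short-term depression resource (release 0.15, recovery
  150 ms), so sustained SA trains deliver charge in proportion to their
  active duration rather than their pulse count. The stimulation site
  itself is kept free of units (no neurons within 185 um, beyond the
  audibility radius of the amplitude model): its recorded signal is
  exactly noise plus stimulation artifacts, as expected of a site chosen
  for stimulating rather than recording, while pulses recruit the ~20
  units in the surrounding annulus (stimulation radius 250 um). Without
  this, the afferent electrode's spontaneous units track every network
  burst: the whole-session coherence of an afferent-deprived session then
  rivals the closed loop's, and faint sub-noise spike residue seeds the
  envelope normalization with session-specific structure that a classifier
  can exploit where chance-level accuracy is expected.
* **Stimulation-driven suppression.** Delivered charge feeds, through a
  600 ms cascade, a slow network-wide suppression current (4 s decay).
  Because SA stimulates throughout a tap while RA stimulates only at its
  edges, SA accrues several times more suppression per tap, which delays
  the next spontaneous burst. This is the surrogate's explicit, documented
  mechanism for the encoding effect on inter-tap intervals (ITIs); it is a
  modeling choice, not a biological claim.

## Event detection

The efferent trace is transformed with a complex Morlet CWT (center
frequencies log-spaced over 100-4000 Hz), the squared magnitude is scaled
by its global maximum, clipped to (0.05, 0.4), averaged across frequency,
smoothed with a 50 ms moving mean and renormalized; peaks above 0.5 with at
least 0.5 s separation are neurotactile events, and ITIs are their
successive differences.

Two numerical notes. First, the clip (`clip_mode = "band"`) zeroes
sub-floor cells (noise power) and saturates super-ceiling cells
(coincident spikes, artifacts). Saturating the floor as well raises the
quiet baseline to about three quarters of the envelope maximum and floods
the 0.5 peak threshold with false peaks, while zeroing the ceiling makes
the envelope non-monotone in spike density and destabilizes burst heights;
the band semantics recover ground-truth tap times with high precision and
recall (the test suite measures this). Both alternatives remain available
via `cwt_config(clip_mode=)`. The envelope height of a burst scales with
the multiunit spike density until the in-band duty saturates, so the
surrogate records about ten units at the efferent site; electrodes with
few, slow units would yield envelope peaks spread too widely for a fixed
0.5-of-maximum threshold. Second, the CWT kernel is given a
cosine taper to zero at Nyquist: an abruptly clipped response rings with
slowly decaying time tails, which would defeat the overlap-save chunking
used for long traces.

## Coherence TFIs

For each event, one second of the efferent and afferent MASP envelopes
(300 ms before to 700 ms after the peak) is compared with analytic Morlet
wavelet coherence: scale-proportional Gaussian smoothing in time, a
0.6-octave boxcar across scales, dyadic scales from two samples up to a
quarter window. The cone of influence (Morlet e-folding time `sqrt(2) s`)
is masked to zero, and the matrix is resized (nearest neighbor, high
frequencies on top) to a 227 x 227 image with a fixed 0-1 color scale.
Whole-session (macro) coherence first decimates both envelopes to 2 kHz
with an 8th-order Butterworth anti-alias filter at 80% of the target
Nyquist. Coherence operates on the smoothed envelopes; because they carry
no content above a few tens of Hz, event windows are analyzed at a reduced
rate (500 Hz in the tests and acceptance script) without loss.

## Classification

No deep-learning framework is among the package's dependencies, so the
classifier is a compact network trained from scratch: TFI pixels are
center-cropped and mean-pooled to 16 x 16, standardized, and fed to a
tanh hidden layer (8 units) with a logistic output, trained with
minibatch Adam (learning rate 5e-3, batch 16, weight decay 1e-2) for 10
epochs on a stratified 70/30 train/validation split. Training images are
augmented with random mirroring about the vertical axis and random
translations up to 30 px. The reported accuracy is the mean of the
validation accuracy over the final 10 minibatch iterations; identical
data, configuration and seed give identical results.

## Statistics

The encoding effect on behavior is the unbalanced one-way fixed-effects
ANOVA (via `stats::lm`/`anova`) between the RA and SA ITI samples of each
simulated day, at alpha = 0.05; the same machinery compares classifier
accuracies across embodiment configurations. The test suite checks the F
statistic against hand-worked and permutation oracles and its type-I error
rate under a null simulation.

## What the synthetic data does and does not emulate

The generator reproduces the study's *structure*: 60-electrode geometry
(8 x 8 minus corners, 200 um pitch), 20 kHz extracellular traces with a
10-20 uV noise floor, spontaneous bursting, stimulation artifacts with
sub-half-amplitude neighbor crosstalk, the 3-DIV x 3-configuration x
2-encoding protocol of 5-minute sessions, and the qualitative SA/RA
firing phenotypes. It does not emulate development across DIV (replicates
differ only by seed), multi-unit waveform diversity, plasticity beyond
depression and adaptation, or the true dynamics of a living culture; passing
tests therefore show that the pipeline recovers the effects this surrogate
embeds, not that a living culture would produce them.

## Problem sizes

Simulated studies in the tests and the acceptance script use 5-minute
sessions sampled at 10 kHz (the analysis band of 100-4000 Hz sits below
Nyquist), 16 CWT voices for event detection, 500 Hz event windows and
8 coherence voices per octave. At the default tap rates this yields
roughly 70 (closed-loop SA) to 170 (afferent-deprived) events per session,
comparable to the 80-150 images per session of a full-scale study; the
classifier protocol is unchanged.

## Known limitations

* The surrogate's ITI effect direction (SA slower than RA) is built in via
  the suppression mechanism; its magnitude is a calibration, not a
  prediction.
* Event timestamps are envelope peaks, so they lag tap onsets by a few
  tens of milliseconds; the micro-window (300 ms pre) absorbs this.
* The ES configuration delivers encoder-driven stimulation locked to the
  fixed waveform; no attempt is made to reproduce day-to-day sign flips of
  the ES ITI contrast reported for living cultures.
* `run_plant()` and the in-loop plant are numerically identical, but the
  in-loop dynamic channel uses a trailing (causal) moving average while
  `sense_forces()` uses the centered one; the difference is one tick of
  group delay.
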