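---
title: "The cisim model: from sound to simulated psychoacoustics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cisim model: from sound to simulated psychoacoustics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`cisim` simulates how a cochlear implant (CI) user performs in two
psychoacoustic tasks - spectral modulation detection and speech reception
in noise - by chaining five model stages:

1. **Sound coding.** Audio is converted to an electrodogram by a
   current-steering strategy with 15 virtual channels on 16 electrodes,
   in three scheduling variants: sequential (S, one channel at a time),
   paired (P, two simultaneous channels) and triplet (T, three).
2. **Electrode-nerve interface.** A parametric 3D cochlea holds 9001
   auditory nerve fibers (ANFs) over 900 degrees of insertion angle and
   16 point-source electrode contacts; per-fiber degeneration removes
   peripheral segments.
3. **Excitation.** A homogeneous-medium potential (inverse distance), the
   activation function (second spatial difference along each fiber), and
   a calibrated scalar `M_C` turn electrode currents into a per-fiber
   induced current.
4. **ANF population.** Each fiber is a pair of adaptive
   integrate-and-fire circuits (cathodic- and anodic-excitatory) coupled
   by a logical OR, with an absolute refractory period of 500 us.
5. **Internal representation (IR) and recognizer.** Spikes are grouped
   into auditory filters, low-pass filtered, forward-masked and
   downsampled to 100 Hz; whole-stimulus hidden Markov models with
   single-Gaussian emissions are trained on these features and their
   recognition scores are fitted with a psychometric function.

# The model stages and their parameters

## Sound coding

Every virtual channel k steers current between adjacent electrodes
(k, k+1) at one of 8 positions; a pulse is a cathodic-leading biphasic
pulse of 18 us phase. All variants stimulate each channel exactly once
per 540 us cycle (about 1852 pulses per second). The published
description of the strategy leaves its internals open, so this package
uses a 15-band log-spaced filterbank (350-5600 Hz) with Hilbert
envelopes, picks the steering position from the within-band spectral
centroid, and maps the envelope logarithmically from T to MCL over a
30 dB input dynamic range with the saturation point at the calibrated
presentation level of -49 dBFS - the knee point of the processor's gain
control, so conversational input drives the upper part of the electrical
dynamic range (`coder_config()` exposes all of these). Clinical units convert to
current as `cu/6000 * 2040 uA * 229/phase_us`.

One scheduling subtlety: eight paired groups plus their gaps cannot fill
exactly 540 us if the gap must equal one full biphasic pulse. The
per-channel 540 us period is treated as the hard constraint; groups are
spaced at 540/8 = 67.5 us, making the paired-variant gap 31.5 us rather
than 36. The triplet variant is exact (108 = 36 + 2 x 36).

## Geometry

The cochlea is a logarithmic spiral (42 mm basilar membrane, 2.5 turns,
basal-to-apical radius ratio 2.8). Fibers start on the BM spiral and run
as straight 31-node chains (200 um internodes) toward a point 5 mm below
the modiolar axis, approximating the oblique course toward the spiral
ganglion. The electrode template holds 22 contacts at 0.75 mm pitch
inserted 20 mm along a lateral-wall path (0.8 mm radially outward of the
BM spiral, 2.4 mm below it); contacts 21, 19, 17, 15, 13 and 11 are
removed to yield the 16-electrode array. These offsets were chosen once
so that (a) the node of maximum activation sits beyond the fifth node
for fibers facing the array, (b) induced currents at comfortable levels
are of order 1 mA, and (c) the spatial excitation profile is contiguous
in insertion angle. They are stand-ins for an unpublished patient
geometry and are exposed in `geometry_config()`.

## Excitation and degeneration

The activation function is evaluated only at interior nodes (both
neighbours present). End nodes - including the new most-peripheral node
after degeneration - are excluded rather than given a one-sided
difference: a one-sided end node reduces to a first difference, which
can *increase* as segments are removed and would make a degenerating
fiber easier to excite. With the interior-only rule, truncation can only
shrink the candidate set, so the peak activation is non-increasing in
the degeneration index by construction.

Degeneration indices are drawn per fiber as `round(N(mean, 3))` clipped
to [0, 20]; the presets are healthy (mean 5), moderate (10) and severe
(15), with ideal (0) and total (20) as reference extremes.

## Neuron model

The two circuits share the induced current I but split its phases with
an inhibitory compression beta = 0.75: the cathodic-excitatory circuit
receives `-(I- + 0.75 I+)`, the anodic-excitatory `I+ + 0.75 I-`.
Capacitances are 856.96 nF (cathodic) and 1772.4 nF (anodic). The
internals of the passive filter, adaptation and noise processes are not
published for this configuration, so they are first-order processes with
exposed parameters (`neuron_params()`): a leak with a 300 us membrane
time constant, a subthreshold tracker of V (gain 0.5 mS, 50 ms), a
suprathreshold current incremented by 0.5 uA per spike (10 ms decay),
and an Ornstein-Uhlenbeck noise current (100 us correlation, 1.75 uA
sd). During the 500 us refractory period both circuits are held at
reset; adaptation and noise keep evolving.

**Calibration.** The activation-to-current factor is fixed at the
published value `M_C = 89.525e6`. The two free scalars of the neuron -
threshold and noise amplitude - were then set once (2.5 mV and 1.75 uA)
so that the virtual fitting produces most-comfortable levels below
250 CU in every health condition, the explicit criterion of the original
calibration. The resulting desk-scale MCLs run from ~70 CU (healthy,
apical) to ~245 CU (severe, basal), with the ideal-to-healthy difference
near zero and differences growing with degeneration, reproducing the
qualitative fitting pattern of the modeled study. These defaults were
not revisited afterwards.

## Integration scheme

The membrane equation is linear with piecewise-constant drive, so the
exponential-Euler update is exact between grid points, and V is monotone
within a constant-drive span; threshold *detection* therefore loses
nothing when the grid is one step per 18 us phase - only the reported
spike time is quantized. The default step (2 us in pulses) keeps spike
times within 2 us of a 0.1 us reference integrator; the desk and micro
profiles use one step per phase (18 us) for speed. Noise is refreshed
on its own subgrid (36 us at most) with the exact discrete OU update;
its 100 us correlation time makes the coarser refresh statistically
neutral. Fibers whose voltage bound (max drive over leak conductance
plus a 6-sigma noise excursion) stays below threshold are skipped as
provably silent.

## Internal representation

Fibers are labeled by their best-coupled electrode (peak |activation|),
majority-smoothed over 5 fibers, and contiguous runs become auditory
filters; runs shorter than 1.1 mm of BM merge toward the apex, runs
longer than 2.6 mm split basal-first. The filter count lands between 16
and 39 for all health presets. Spikes are binned at 10 kHz per filter,
convolved with a Gaussian kernel (the printed form of the low-pass
kernel is typographically ambiguous; it is implemented as a Gaussian in
normalized time `k/(fs*tau)` with `tau` = 1 ms, truncated at 4 sigma and
area-normalized), passed through forward masking (masker attack 5 ms,
release 50 ms, output = max(masker, signal); the source model for these
constants gives attack << release, exact values are exposed), and
averaged down to 100 Hz in 10 ms blocks.

## Recognizer and psychometrics

Each label (ripple/reference, or each of 50 matrix words) gets an
8-state left-to-right HMM with diagonal single-Gaussian emissions,
trained by segmental k-means with Viterbi re-alignment (variances
floored at 1e-4 of the pooled variance; Viterbi ties break to the lowest
state). Training pools all condition levels into one corpus, following
the stated corpus design rather than a per-condition model matrix.
Sentences are decoded through the closed 5-slot x 10-word grammar.
Scores per condition are fitted with the logistic
`Ps(x) = p_chance + p_range / (1 + exp(-s (x - x_o)))` by bounded
Levenberg-Marquardt with multi-start (slope inits 0.2/0.5/1/2, offset at
the empirical half-range crossing). Thresholds invert the fit in closed
form: 79.4% for the spectral task (chance 50%), 50% for the word task
(chance 10%).

# Experiments and the synthetic corpus

The spectral ripple generator realizes the sinusoidal-in-log-frequency
magnitude spectrum directly in the discrete spectrum (hard band 350 to
5600 Hz, 0.5 ripples/octave, 0.4 s at 17.4 kHz); the ripple phase and
all component phases are randomized per stimulus - component-phase
randomization is the standard reading for a noise carrier. Loudness
roving draws the level from -49 +/- 5 dBFS on a 0.5 dB grid.

The speech material replaces a licensed matrix-sentence corpus with a
synthetic one that preserves the experimental structure exactly: 5
categories x 10 words, balanced corpora in which every word appears
n/10 times, speech fixed at -49 dBFS, training at SNRs 0 to 18 dB in
3 dB steps plus clean, testing from -9 to 18 dB. Words are rendered as
formant tokens (glottal pulse train, two gliding resonators, 250-390 ms)
that are deterministic per word id; the masking noise is white noise
shaped to the inventory's long-term spectrum, as matrix-test noise is.
What passing tests on this corpus show is that the *model chain*
transmits spectro-temporal differences the recognizer can exploit; they
do not certify performance on natural speech, whose phonetic variability
the generator does not emulate.

# Scale profiles

Three profiles set the problem sizes. "paper" is the full-scale
configuration (9001 fibers, 1000+1000 spectral training stimuli, 100
sentences; cluster-scale). "desk" decimates the population to 301
fibers and the corpora to 30+30 training ripples, 5+5 test stimuli per
contrast and 10 sentences, so a complete experiment runs in minutes on
one CPU; "micro" (101 fibers, reduced SNR grid, 5 test sentences per
SNR) is used for smoke tests and the bundled acceptance runs. The
decimation preserves structure: grids, balance, criteria, and the
proportional 858-of-9001 fitting-group rule. At these scales the
recognizer sees far less training data than the full study, so absolute
thresholds are noisier and upper asymptotes lower; the full-scale
threshold values additionally depend on an unpublished cochlear mesh
and proprietary coder internals and are not reproduction targets.

One directional trend deserves an explicit caveat. Neural degeneration
acts on speech reception through two opposing mechanisms: re-fitting
the degenerated map raises stimulation levels, which *broadens
recruitment* (more fibers active, more total spikes - the same effect
that raises the induced current toward the apex in worse health
conditions), while the flatter, more central activation profiles
*smear* the spatial excitation pattern. At the full population size
neither condition is information-starved, so smearing wins and severe
loss costs speech reception. At 1/30 to 1/90 of the population the
count advantage of the broadly recruited severe condition can outweigh
the smearing penalty, and the net health effect on the speech reception
threshold can vanish or invert; the corresponding directional check in
the test suite documents this rather than hiding it. The MCL-versus-
health trend, by contrast, is robust at every scale.

# Known limitations

* The inverse-distance potential decays faster than measured intracochlear
  spreads, understating channel interaction between simultaneous groups.
* The IR features are highly correlated across filters and carry no
  relative-spectral-shape information, which caps spectral-ripple
  discrimination well below human performance - an effect the original
  study reports for the same feature/back-end pairing.
* One neuron parameter set serves the whole population; no per-fiber
  diameter or latency variation.
* The synthetic corpus has exact word boundaries, which the word-model
  training uses directly; natural corpora would need forced alignment.
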