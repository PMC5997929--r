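---
title: "The syllable sequencing model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The syllable sequencing model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(syllseq)
```

This vignette documents the model that `syllseq` simulates, the constants it
uses and why, the numerical choices in the simulator, and what the package's
tests do and do not establish. Code chunks are illustrative and not
evaluated when the package is built; every number quoted here is computed by
the test suite or by `scripts/acceptance.R`.

## The task and the circuit

The model performs a rapid syllable repetition task: after a brief visual
cue `BA`, it must produce the fixed cycle `BA, DA, GA, PA, TA, KA, BA, …`
until the trial ends (5.5 s, with a 0.5 s silent lead-in and the cue shown
from 0.5 to 0.7 s; the last 5 s are the scored task window). Syllables and
their execution states are 32-dimensional unit *semantic pointers*; a
cortical *buffer* is an array of 32 one-dimensional ensembles of 50 leaky
integrate-and-fire neurons (1600 neurons) that jointly hold one
pointer-valued state. Six buffers represent the visual, phonemic,
somatosensory, premotor, auditory-expectation and motor states.

Behaviour is organised as 14 condition–effect rules evaluated by a basal
ganglia / thalamus action-selection loop:

* **start** — visual `BA` loads the phonemic buffer with `BA`;
* **idle** — a blank screen (visual `ZERO`) maps to `NEUTRAL`;
* **speak(S)** ×6 — a phonemic syllable `S` sets premotor and auditory
  expectation to `S` and the motor buffer to `S_EXEC`;
* **advance(S)** ×6 — somatosensory `S_EXEC` sets the phonemic buffer to
  the next syllable of the cycle.

Each rule's *utility* is a weighted dot product between buffer contents and
condition pointers. Utilities drive one action channel each through the
selection circuit: cortex excites striatum D1 (gain `ws(1+lg)`), striatum
D2 (gain `ws(1−le)`) and STN (gain `wt`); D1 inhibits the two output
nuclei, GPi and SNr (implemented as separate populations); D2 inhibits GPe;
STN broadcasts excitation to GPe and SNr at the fixed weight 0.9 and to GPi
at the tunable weight `wp`; GPe inhibits STN, GPi and SNr at 0.3. Each
population's rate response is a rectified line (`ramp()`), thresholds
0.2 (striatum), −0.25 (STN), −0.2 (GPe, GPi, SNr), slope 1. The output
nuclei tonically inhibit per-channel thalamic ensembles; when a channel's
combined GPi + SNr output collapses, its thalamic gate opens and the rule's
effects are injected into the target buffers.

A peripheral motor-execution module watches the motor buffer. When the
similarity to some `S_EXEC` crosses 0.7 (releasing below 0.45 before it can
re-trigger) the module schedules the same pointer into the somatosensory
buffer 200 ms later — the articulation delay — as a 45 ms, amplitude-1
pulse. That feedback is what advances the cycle, so at healthy parameters
one syllable occupies the 200 ms delay plus an ≈ 80 ms selection-and-routing
loop: ≈ 278 ms.

## Tunable parameters

| parameter | default | range | role |
|---|---|---|---|
| `lg`, `le` | 0.2 | 0–0.2 | tonic striatal dopamine (D1 selection / D2 control pathways); 0.2 is the typical level, 0 complete depletion |
| `wt` | 1.0 | 0–1 | cortical afferent gain of the STN; reduced values model STN inhibition |
| `wp` | 0.9 | 0–0.9 | STN→GPi broadcast weight; 0.9 gives maximal GPi activity, reduced values model GPi inhibition |

All remaining circuit constants (`ws = wm = wg = 1`, `we = 0.3`,
`w_stn = 0.9`, the ramp thresholds above, AMPA 2 ms / GABA 8 ms synapses)
are the conventional values of the action-selection circuit this model
extends, exposed through `bg_params()` rather than hard-coded.

## What had to be decided, and why

The circuit's published description leaves several constants open. They
were fixed once, against the healthy-regime description (18 syllables in
5 s, ≈ 278 ms period, ≈ 80 ms loop, slim ≤ 100 ms single-peak motor pulses,
first selection after the cue ends), and then frozen before any degraded
condition was evaluated:

* **Thalamic gating weight −1.5 per output nucleus.** The unsplit circuit
  inhibits the thalamus at weight −3 from its single merged output nucleus.
  After splitting GPi and SNr, giving *each* nucleus −3 doubles the tonic
  suppression and the fixed-point analysis (`steady_state_selection()`)
  shows no channel is ever disinhibited, even at full dopamine. −1.5 per
  nucleus preserves the original combined total. With this choice the rate
  oracle places the feedback action's selection boundary at `lg = le ≈ 0.16`
  for `wt = 1` and ≈ 0.08 for `wt = 0.8`, and produces co-selection at
  `wt ≤ 0.2` — the qualitative structure of the degradation tables.
* **Gate nonlinearity.** Thalamic channels decode a saturating go-signal:
  0 below disinhibition drive 0.02, 1 above 0.22 (drive =
  `1 − 1.5·(GPi+SNr)`). Selection in this circuit is *relative* — a winner
  with competitors retains a small nonzero output — so a gate that
  saturates early in the disinhibition range turns a modest margin into a
  full go-signal while leaving suppressed channels at exactly zero.
* **Idle-rule weight 0.35.** The screen shows `ZERO` for nearly the whole
  trial; at full weight the idle rule would be a permanent equal competitor
  of every sequencing rule. Down-weighted, it contributes background
  utility without ever out-competing an active rule.
* **Phonemic memory: leaky, τ ≈ 77 ms** (recurrent gain 0.35, 50 ms
  synapse). The phonemic trace must outlive its cause long enough to drive
  the speak rule (and set the ≈ 100 ms motor pulse width via its decay) but
  must be gone before the next feedback arrives, or stale and fresh
  syllables compete. The identity of the *next* syllable is carried by the
  delayed somatosensory feedback, not by phonemic persistence.
* **Effect gains above 1** (3.5 into the phonemic integrator, 1.8
  elsewhere). Gates fluctuate with spiking noise; strong injection makes
  buffer states saturate near full pointer similarity even under a
  partially open gate, keeping utilities well-separated.
* **Somatosensory feedback pulse 45 ms.** The feedback marks an event (the
  end of articulation). It must outlast the advance rule's selection time
  (≈ 35 ms) but fade before the following speak rule needs the circuit:
  while both the advance and the speak utilities are high, their broad STN
  excitation blocks *both* channels, and with a long (e.g. 100 ms) pulse
  the loop can only complete after the pulse fades, stretching it to
  ≈ 130 ms and the syllable period to ≈ 330 ms.
* **BG population radius 1.5.** During rule hand-offs two channels carry
  utility ≈ 1 simultaneously and the summed broad excitation exceeds 1. At
  radius 1 the GPe saturates exactly then, disabling the control loop that
  is supposed to clamp the STN; radius 1.5 keeps the populations in the
  range where the rate equations are linear.
* **Trigger arming at task onset.** Before any input there is no
  competitive floor (all utilities ≈ 0), and decoder noise occasionally
  cascades into a transient selection. The motor-execution module arms at
  0.5 s — there is no articulation before the task — and the thalamic bias
  ramps in over the first 200 ms so tonic inhibition is established before
  the gates can open.
* **Vocabulary similarity bound 0.5.** Random 32-D unit vectors have
  pairwise dot products with σ ≈ 0.18. A rare execution-pointer pair at
  similarity ≈ 0.6, combined with motor activity overdriven to ≈ 1.3,
  crosses the 0.7 trigger threshold by cross-talk and launches a second
  syllable. Resampling above 0.5 (≈ 0.5 % of draws) removes exactly the
  confusable pairs a bound is meant to remove.

## Numerical choices

* Time step 1 ms; LIF membrane 20 ms, refractory 2 ms, maximum rates
  uniform 200–400 Hz, intercepts uniform over the represented range.
  Membrane integration uses the exact exponential update with sub-step
  refractory carry-over, so rates match the analytic LIF curve.
* Decoders solve regularised least squares over 250 evaluation points per
  ensemble (regularisation 0.1 × peak rate). The normal-equations solve is
  implemented in plain C++ (Cholesky) so a seeded build is bit-for-bit
  reproducible regardless of BLAS threading; the spiking trajectories are
  chaotic, and last-bit decoder differences would otherwise make trial
  outcomes machine-dependent.
* All randomness (pointers, tuning curves, initial voltages) flows from two
  integer seeds per trial (vocabulary, network) through an isolated RNG
  stream; `simulate()` is deterministic given the built network. The five
  replicate trials of every condition use seeds 1–5 applied to both.
* The rate oracle iterates the ramp fixed point with damping 0.5 to
  tolerance 1e-9 and then applies one exact update, so outputs that the
  fixed point places below threshold are exactly zero; non-convergence
  within the iteration budget is reported (oscillating equilibria).
* Pulse extraction uses hysteresis (onset 0.7 / offset 0.45) and merges
  same-syllable peaks closer than 120 ms; a single peak wider than 150 ms
  is *broad*, multiple merged peaks are *oscillatory*. A trial with no
  pulses classifies as halting. Degenerate statistics (two zero-variance
  samples with equal means) are reported as such rather than returning a
  number.

## Problem sizes

The study conditions use the full-scale model: ~13,900 neurons
(6 × 1600 buffer neurons, 4200 in the basal ganglia, 700 thalamic) at 1 ms
steps for 5.5 s, five seeded exemplars per parameter setting. One trial
builds and runs in a few seconds, so the test suite exercises full trials
directly and the sweep tests use a reduced grid; the complete 88-cell and
77-cell sweep grids are reproducible with `run_sweep()` in a few hours of
single-CPU time.

## What the simulations do and do not show

The model generates all of its own data; nothing is fit to recordings. The
synthetic vocabulary emulates well-separated learned representations —
near-orthogonal unit pointers — and the trial protocol emulates the cued
task; neither captures articulatory dynamics, auditory feedback (the
auditory-expectation buffer is written but never compared against
reafference), dopamine effects outside the striatum, or any
electrical-stimulation waveform: reduced `wt`/`wp` stand in for the *net*
inhibitory effect a stimulation protocol may have on a nucleus.

Known quantitative limitations, measured honestly by the acceptance suite:
the collapse at moderate depletion (`lg = le = 0.16`, full `wt`) is milder
here (mean ≈ 14 correct per trial) than the ≈ 5 the acceptance checks
expect, because
failures in this implementation are independent per-cycle chances rather
than a systematic death after ~5 syllables; and the slow broad-pulse regime
under deep GPi inhibition overshoots (≈ 72 correct over five trials versus
≈ 55), because with the −1.5-per-nucleus gating, silencing the GPi lowers
total thalamic inhibition and so *speeds* selection, where a full slowdown
would require the remaining SNr path alone to carry near-complete
suppression. At near-zero dopamine even the cue-driven first syllable
frequently fails here, since a lone full-utility channel reaches only a
marginal disinhibition drive under the faithful rate equations. These are
properties of the frozen design, documented rather than tuned away.
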