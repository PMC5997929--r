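# syllseq

A spiking neural model of syllable sequencing through the
cortico-basal-ganglia-thalamus-cortex loop, with tunable striatal dopamine
and tunable subthalamic (STN) / pallidal (GPi) afferent weights, plus the
full analysis pipeline needed to quantify how sequencing degrades under
dopamine depletion — and recovers when the STN or GPi is inhibited, as one
hypothesis for how deep brain stimulation restores speech fluency in
Parkinson's disease.

## The model

The package targets the diadochokinesia (rapid syllable repetition) task:
after a visual cue `BA`, the model must produce the cycle
`BA, DA, GA, PA, TA, KA, BA, …` for the rest of a 5.5 s trial.

Everything is built with the Neural Engineering Framework (NEF): leaky
integrate-and-fire (LIF) neurons grouped into ensembles represent scalar or
vector states; connection weights are obtained by regularised least-squares
so that each connection decodes a chosen function of the represented value.
Discrete states (syllables, their execution states `BA_EXEC…`, `NEUTRAL`,
`ZERO`) are 32-dimensional unit *semantic pointers* held in six cortical
buffers (visual, phonemic, somatosensory, premotor, auditory expectation,
motor), each buffer an array of 32 one-dimensional 50-neuron ensembles
(1600 neurons).

Action selection uses a Gurney-style basal ganglia circuit — striatum D1/D2,
STN, GPe, and *separately implemented* GPi and SNr output nuclei — over 14
action channels (one per condition→effect rule), with a disinhibition-gated
thalamus routing the winning rule's effects into the buffers. The swept
parameters:

| parameter | range | meaning |
|---|---|---|
| `lg` | 0–0.2 | tonic dopamine on the D1 (selection) pathway; cortex→striatum gain `ws·(1+lg)` |
| `le` | 0–0.2 | tonic dopamine on the D2 (control) pathway; gain `ws·(1−le)` |
| `wt` | 0–1  | cortical afferent weight of the STN (1 = standard) |
| `wp` | 0–0.9 | STN→GPi broadcast weight (0.9 = maximum GPi activity) |

A motor execution module watches the motor buffer; when a syllable's
execution pointer crosses threshold it feeds that pointer back into the
somatosensory buffer after a 200 ms articulation delay, which triggers the
advance to the next syllable. At healthy parameters each syllable therefore
occupies ≈ 278 ms: the 200 ms delay plus an ≈ 80 ms
cortex→BG→thalamus→cortex loop.

Analysis converts motor-buffer similarity traces into pulse events
(hysteresis thresholds 0.7/0.45, 120 ms same-syllable merge window), counts
correctly sequenced syllables (cyclic-successor rule), classifies error
trials (repetition, skipping, restart, halting) and pulse shapes (normal,
oscillatory, broad), aggregates parameter sweeps into region-coded tables,
and runs the one-sided pooled-variance t tests.

## A worked example

One healthy trial (≈ 5 s of wall time: ~14,000 LIF neurons for 5.5 s of
simulated time at 1 ms steps):

```r
library(syllseq)
cfg   <- trial_config()            # lg = le = 0.2, wt = 1.0, wp = 0.9
trace <- run_trial(cfg)            # vocabulary seed 1, network seed 1
res   <- analyze_trial(trace)
res
#> <trial_result> 18 correct / 18 pulses; no errors

head(res$pulses, 3)
#>   syllable onset offset n_peaks width  span  shape
#> 1       BA 0.722  0.775       1 0.053 0.053 normal
#> 2       DA 1.009  1.058       1 0.049 0.049 normal
#> 3       GA 1.298  1.344       1 0.046 0.046 normal

mean(onset_intervals(res))         # syllable period (s)
#> 0.278
mean(loop_times(trace, res))       # BG-thalamus loop time (s)
#> 0.078
```

18 correctly sequenced syllables in the 5 s task window, ~278 ms per
syllable, pulses that are tall slim single peaks — the healthy regime.
`plot_trace(trace)` draws the similarity panels (one per buffer, one line
per pointer).

The rate-based fixed-point oracle predicts what the spiking circuit should
settle to; for a dominant action its output-nucleus signal is driven
exactly to zero, releasing the thalamus:

```r
or <- steady_state_selection(c(1.2, rep(0.1, 13)))
or$gpi[1] + or$snr[1]   # winner: fully disinhibited
#> 0
min(or$gpi[-1] + or$snr[-1])  # losers keep suppressing their channels
#> 1.89
```

Degraded conditions are one argument away —
`trial_config(params = bg_params(lg = 0.16, le = 0.16))` — and full sweep
grids with per-cell seeding, resume support and table-style reports come
from `sweep_spec()` / `run_sweep()` / `sweep_grid()`. A thin command-line
wrapper is installed at `inst/scripts/syllseq-cli.R`
(`trial`, `sweep`, `report`, `dump-config` subcommands).

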