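---
title: "Methods: synthetic motor-imagery EEG, temporal ICA, OVR-CSP and shared control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic motor-imagery EEG, temporal ICA, OVR-CSP and shared control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mibci implements a complete hybrid motor-imagery brain-computer interface
(BCI) pipeline — from raw multichannel EEG/EOG to the shared control of a
falling-blocks game — and, because no public recording of the original
experiment exists, a synthetic-data generator that reproduces the
statistical structure every stage assumes. This vignette documents the
models, the tunable parameters, the numerical decisions, and what the
synthetic experiments can and cannot demonstrate.

## The synthetic recording model

Cortical activity is modelled as `M` independent autoregressive (AR)
sources,

$$ s_i(t) = \sum_{k=1}^{P} a_{ik}\, s_i(t-k) + \sigma_i\, g_i(c_t)\,\varepsilon_i(t), $$

mixed onto the scalp by a forward matrix with Gaussian spatial profiles
centred on each source's electrode. The innovation gain $g_i(c)$ encodes
event-related (de)synchronisation: during an imagery epoch of class $c$ the
innovation scale of a class-linked source is multiplied by a gain below one
(ERD — band power shrinks by the squared gain) or above one (ERS). Between
trials all gains are one; those inter-trial stretches are the *idle*
baseline, which matters because the original protocol never recorded
explicit idle trials.

The default source set mimics a well-performing participant: mu/beta
resonators at Cz (8–12 Hz, foot ERD, gain 0.5), C3 and C4 (12–16 Hz,
contralateral hand ERD, gain 0.5), an Fz source with tongue ERS (gain 1.5),
two unmodulated narrowband sources (F4, T7) and two broadband 1/f
background sources (P3, P4) with larger amplitude. Resonators are AR(2)
pole pairs (`ar_resonator()`), zero-padded to order 6; gains of 0.5 on the
innovation SD give the commonly reported 50–80% band-power suppression.

On top of the mixed sources the renderer adds a 50 Hz mains sinusoid,
blink artifacts (a 300 ms biphasic pulse, 150 µV on the vertical EOG pair
with 30%/15% leakage onto prefrontal/frontal channels; doubles are two
pulses 400 ms apart, events at 6/min), white sensor noise, and finally
subtracts a simulated reference channel so the stored data is
ear-referenced, as an amplifier referenced to the left ear would deliver.
The trial scheduler reproduces the training protocol exactly: 2 sessions ×
2 runs × 15 cues per class, 2 s blank + 4 s imagery per trial, randomised
within runs — 240 trials, 60 per class.

What the generator does *not* emulate: volume-conduction head geometry,
non-stationary background (drowsiness, drift), myogenic artifacts, or
inter-participant variability beyond the source profile. Results on this
data therefore validate the pipeline's statistical machinery, not its
performance on real EEG.

## Preprocessing

Preprocessing follows the acquisition chain: a constrained biquad notch at
50 Hz (zeros on the unit circle, 1 Hz bandwidth, applied forward–backward
so attenuation at the centre is complete and the response stays within
1 dB outside ±2 Hz); ocular correction by ordinary least squares — each
EEG channel's projection on the four EOG channels is removed, the EOG
channels themselves kept for blink detection; per-epoch baseline
correction over the 0.5 s before the cue; common average reference over
the EEG channels only; and a filterbank of Chebyshev type-I band-pass
filters of order 10, 2 Hz wide, tiling 0–60 Hz.

The filterbank is designed in zero-pole-gain form and applied as cascaded
second-order sections. This is not cosmetic: a 2 Hz band at 1 kHz puts
poles within $10^{-3}$ of the unit circle, where a degree-20 transfer
function has no usable precision, while biquads are exact to double
precision. Ripple is fixed at 0.5 dB; the lowest band's lower edge is
clamped to 0.5 Hz to keep the bilinear design realisable; forward–backward
application doubles attenuation and cancels group delay. Epochs are
filtered after extraction (matching the order of the original processing
description), with odd-reflection padding proportional to the inverse
bandwidth to contain edge transients.

## Characteristic components

Every (electrode, band) component is scored by the mean, over the six
class pairs, of the squared point-biserial correlation between per-epoch
band power and the pair's binary label — the standard $r^2$ feature
measure in sensorimotor BCI work. The top ten components are then screened
for physiological plausibility against the idle baseline: a component
survives if at least one class moves its power in the expected direction
(a decrease for hand or foot imagery, an increase for tongue). Ties break
deterministically by lower band edge, then electrode name. Pairwise
averaging (rather than one-versus-rest contrasts) is the default reading;
both the aggregation and the screen are configurable.

## Temporal-structure-preserving ICA

The separation stage models each *estimated* source as a stationary AR
process and applies the independence criterion to the prediction-error
residuals rather than to raw samples. Estimation alternates: (a) project
the whitened data through the current unmixing matrix; (b) fit each
source's AR polynomial by least squares; (c) take a natural-gradient step
that pairs the score function $\varphi(e)=\tanh(e)$ of source $i$'s
residual with *all* sources filtered by source $i$'s own prediction-error
polynomial. Step (c) is the exact quasi-maximum-likelihood gradient of the
model "independent AR sources with $1/\cosh$ innovations"; the objective
that the line search monotonically decreases is the corresponding negative
log-likelihood (prediction-error log-scales plus marginal log-cosh terms
minus the log-determinant volume term).

Two design points deserve emphasis:

* **The source model is per-source (diagonal), not a joint multivariate
  AR.** A joint MVAR fit of *any* invertible mixture of AR sources is
  exact, and its residuals are the mixed innovations — for Gaussian
  sources these are jointly Gaussian and white, so *no* independence
  criterion applied to joint-MVAR residuals can identify the unmixing
  matrix. With per-source AR models the temporal structure itself becomes
  identifying: Gaussian AR sources with distinct spectra are separated,
  which is precisely the regime where sample-wise ICA provably fails.
  `fit_unmixing(order = 0)` gives that temporal-structure-blind baseline
  (an Infomax-style ICA), and `source_model = "full"` retains the joint
  variant for comparison. The acceptance script quantifies all three.
* **Indeterminacies are fixed for reproducibility**: rows of the unmixing
  matrix are scaled to unit residual variance, ordered by component power,
  and signed so the largest-magnitude entry of each estimated forward
  column is positive. The same data and seed give bitwise-identical
  models.

Defaults: AR order 6 (the generator's order; configurable), initial step
0.05 with backtracking halving and mild growth on acceptance, relative
tolerance $10^{-6}$, at most 500 evaluations, identity-plus-jitter
initialisation under the caller's seed. Whitening is full-rank PCA;
numerically singular inputs (duplicated components) are refused rather
than silently truncated.

## One-versus-rest CSP and its features

For each class the trace-normalised epoch covariances are averaged and the
class covariance is simultaneously diagonalised with the composite
$\Sigma_c + \Sigma_{\text{rest}}$ ("rest" = unweighted mean of the other
three classes), so each filter's class and rest eigenvalues sum to one
exactly. Two filters from each end are kept per class — 16 log-variance
features in total, each the log of a projection variance normalised within
its class model. Filters carry a positive-largest-entry sign convention;
singular composites fall back to a $10^{-6}$ shrinkage with a warning.

The first-minus-last filter variance gap — the summary used to compare the
direct pathway (cspW_Data) with the ICA pathway (cspW_IC) — is computed on
trace-normalised epochs. In raw units the comparison would only measure
the physical scale of the two representations (microvolts squared against
unit-variance components), which differs by many orders of magnitude for
reasons unrelated to separability.

### What the pathway comparison shows on linear synthetic data

A square ICA transform is an invertible linear map, and OVR-CSP with
log-variance features is invariant to invertible linear maps up to three
weak effects (per-epoch trace normalisation, finite-sample filter
estimation, the singularity fallback). On data that is *exactly* a linear
mixture — which the generator produces by construction — the two pathways
therefore carry nearly identical information, and their cross-validated
accuracies differ only through those weak, sign-symmetric effects. The
package's benchmark measures this honestly: across seeds the IC pathway
wins roughly as often as it loses. An observed IC advantage on real
recordings must consequently come from properties the linear synthetic
world lacks — residual nonlinear artifacts, non-stationarity, or the
denoising effect of discarding components — and the benchmark should be
read as a calibration of the machinery, not as a reproduction of that
advantage. The benchmark's conditions (six components, 60 trials per
class, component noise of the same order as the sources) were fixed once
so that single-pathway accuracies land in the 60–75% band typical of
four-class single-trial motor imagery.

## The small-world network classifier

The classifier is a feedforward perceptron with ten hidden layers of eight
sigmoid neurons whose connection topology is perturbed: at construction
each edge is rewired with probability 0.1 to a random forward neuron
(possibly skipping layers), and during training every 50 epochs the 5% of
active connections with the smallest absolute weight are cut and rewired
— shortcut edges that shorten the characteristic path while the layered
graph stays effectively triangle-free. A degree floor guarantees no neuron
is ever stranded. Training is full-batch backpropagation with momentum on
a cross-entropy loss against the four 4-bit class codes (right hand 0001,
left hand 0010, foot 0100, tongue 1000 — one-hot patterns, kept verbatim
from the original code map despite its "gray code" name).

The output layer's hard-limit (threshold) transfer function has zero
gradient, so it is used at inference only; training goes through the
sigmoid surrogate. Thresholding yields a 4-bit pattern; the twelve
patterns that name no class decode as *idle* — the no-command state that
was never collected during training but occurs constantly during play.
For accuracy benchmarking (where every trial has a true class and printed
accuracy tables assume a forced decision), `swnn_predict(rule =
"force_choice")` instead reports the most active output neuron's class;
cross-validation uses this rule, online control uses the hard limit.

## Shared control and the game

Decoded labels feed a finite-state automaton with eight states (`Start`,
new-block `N_B`, four speed adjustments, stop `V_zero`, `Reset`) and
eleven inputs: the four class symbols, three command-count comparisons,
the game events `Touch`/`Fallen`/`Cross`, and `Null`. The transition
function is total — pairs absent from the control table keep the state.
Speed semantics: a class symbol adds one increment (1 cell/s) along its
axis; `P_plus` (the 1-second command count rose) adds another along the
active direction, `P_minus` while moving removes one, `P_eq` holds; wall
contact stops the block; landing returns to `N_B`; overflow resets.
Notably, direction symbols are ignored in `N_B` — only `Null` (an idle
decode) releases the new block for control, a quirk preserved from the
control table.

The headless engine is a 6×6×20 cuboid by default (only the 20 layers are
fixed by the original game; footprint, fall rate 0.5 layers/s, speed
increment and the polycube shape set are configuration). Filling a layer
clears it for one score unit. The layer-forfeit rule is ambiguous in its
source ("blocks stacked over a layer with gaps"); the strict reading —
lose a layer whenever the topmost occupied layer has gaps after a landing
— makes every run end within ~20 landings with score 0 regardless of
control quality, so the default is the overhang reading (a landing that
seals empty cells beneath it forfeits one layer), with the strict rule
available as `layer_rule = "topgap"`. Blink EOG commands rotate the
block: a double blink advances the rotation axis in the X–Y–Z loop, a
single blink rotates 90° about the current axis; blocked rotations are
no-ops. Blink detection thresholds the vertical EOG at 4 median absolute
deviations with a 0.1 s refractory window, a 20 ms minimum width (which
rejects single-sample noise exceedances) and a 0.6 s double-blink window.

Sessions decode one label per 0.25 s hop from 1 s windows and log every
window, state, speed and event. Control quality is validated by ordering:
a greedy placement decoder (steer toward the drop position that seals the
fewest cells, then lands lowest) must outscore a uniform-random decoder on
average — on a 2×2 board with single/domino shapes, where layer completion
is attainable within a session. The 2-D screen game scorer is the
population standard deviation of the four class percentages among non-idle
decodes; balanced production scores 0.

## Problem sizes and determinism

All statistical claims are exercised at desk scale, chosen once: ICA
separation on 3 AR(4) sources at $T = 2\times10^4$ over 20 seeds; MVAR
recovery at $T = 10^4$; the pathway benchmark at 60 trials per class of
150-sample component epochs, 5-fold cross-validation, 20 seeds; ERD/ERS
recovery on 160 Hz recordings of 20 trials, 20 seeds; end-to-end pipeline
tests on 160 Hz recordings with a 0–24 Hz filterbank. Every stochastic
stage takes an explicit seed and restores the caller's RNG state, so the
full pipeline is a deterministic function of (data, configuration, seed).

## Known limitations

* The synthetic world is linear and stationary; see the pathway
  discussion above for what that implies.
* The exact rewiring rule of the original small-world classifier is not
  recoverable from its description; rewiring period, cut fraction and
  rewire probability are package defaults, all exposed.
* The per-player component tables and accuracy figures of the original
  study depend on its unreleased recordings and are out of scope; the
  package reproduces procedures and their qualitative orderings.
* Recordings are stored as quantised 16-bit CSV with a JSON sidecar, not
  EDF; the quantisation step is recorded and round-trips are exact to it.
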