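# mibci

A complete, testable implementation of a hybrid motor-imagery
brain-computer interface (BCI): four-class motor imagery decoded from EEG
drives the movement of block groups in a headless 3-D falling-blocks game,
while eye blinks detected on the EOG issue rotation commands. Because no
public recording of such an experiment exists, the package ships a
synthetic EEG/EOG generator with the statistical structure every stage
assumes, so the entire pipeline can be exercised, validated and benchmarked
offline.

It is aimed at BCI methods researchers who want a self-contained reference
implementation of this processing chain, and at anyone who needs a
controllable synthetic test bed for motor-imagery decoding pipelines.

## What is implemented

* **Synthetic recordings** — class-modulated autoregressive cortical
  sources (`s_t = Σ_k a_k s_{t-k} + σ g(c) ε_t`, ERD/ERS as innovation-gain
  changes), forward-mixed onto a 25-channel 10-20 montage at 1000 Hz, plus
  50 Hz mains, biphasic blink artifacts and sensor noise, under the exact
  training protocol (2 sessions × 2 runs × 15 cues/class; 240 trials, 60
  per class).
* **Preprocessing** — zero-phase 50 Hz notch, least-squares ocular
  regression, baseline correction, common average reference, and a
  Chebyshev type-I filterbank (order 10, 2 Hz bands over 0–60 Hz) built as
  cascaded second-order sections.
* **Characteristic components** — per-(electrode, band) scoring by mean
  pairwise squared point-biserial correlation (r²) of band power, top-10
  selection, ERD/ERS plausibility screening against the idle baseline.
* **Temporal-structure-preserving ICA** — each estimated source is
  modelled by its own autoregression and the independence criterion is
  applied to the prediction-error residuals via an exact quasi-ML natural
  gradient with tanh score. Gaussian AR sources with distinct spectra are
  separated — the regime where ordinary sample-wise ICA
  (`fit_unmixing(order = 0)`) provably fails.
* **One-versus-rest CSP** — per class, simultaneous diagonalisation of the
  class covariance against class + rest, paired eigenvalues summing to one
  exactly; log-variance features; both the direct (`cspW_Data`) and the
  ICA-preprocessed (`cspW_IC`) pathway.
* **Small-world network classifier** — 10 hidden layers × 8 neurons with
  cut-and-rewire topology adaptation, hard-limit 4-bit output codes
  (0001/0010/0100/1000), all 12 non-class codes decoding as *idle*.
* **Shared control** — the 8-state/11-input finite-state automaton mapping
  decoded classes and per-second command counts to speed adjustments, blink
  rotations (double blink cycles the axis X→Y→Z), and a headless 3-D
  engine with 20 vertical layers, layer clearing, layer forfeits and
  session logging.
* **Evaluation** — stratified repeated k-fold cross-validation of pathway ×
  classifier (SWNN, MLP, RBF-SVM, LS-SVM), ERD/ERS indices against the
  idle baseline, and the 2-D screen-game balance scorer.

## Worked example

```r
library(mibci)

## 1. simulate a training recording (scaled to 160 Hz for the example)
montage <- montage_spec(fs = 160)
schedule <- build_schedule(n_sessions = 1, runs_per_session = 1,
                           reps_per_class = 10, seed = 1)
model <- default_source_model(montage)
rec <- render_recording(model, schedule, montage, seed = 1)
print(rec)
#> <recording> 29 channels x 38720 samples (242.0 s at 160 Hz), 40 trials, 22 blink events

## 2. event-related desynchronisation at the planted site
eps <- extract_epochs(rec, idle = TRUE)
labs <- vapply(eps, `[[`, character(1), "mi_class")
idle <- eps[labs == "idle"]
round(erds_index(eps[labs == "right_hand"], idle, "C3", c(12, 16)), 3)
#> [1] -0.726

## 3. blink commands recovered from the vertical EOG
head(detect_blinks(rec), 3)
#>     time_s   kind
#> 1  3.66875 double
#> 2 15.09375 double
#> 3 18.40625 single

## 4. temporal ICA separates an AR mixture that defeats sample-wise ICA
set.seed(2)
S <- rbind(stats::filter(rnorm(20000), c(1.6, -0.8), method = "recursive"),
           stats::filter(rnorm(20000), c(-1.2, -0.6), method = "recursive"))
A <- matrix(rnorm(4), 2)
fit <- fit_unmixing(A %*% S, order = 4, seed = 1)
round(amari_index(fit$unmixing %*% fit$whitener %*% A), 4)
#> [1] 3e-04
fit0 <- fit_unmixing(A %*% S, order = 0, seed = 1)   # structure-blind baseline
round(amari_index(fit0$unmixing %*% fit0$whitener %*% A), 4)
#> [1] 0.2616

## 5. shared control: one decoded command through the automaton
fsa_step("Start", "left")
#> [1] "VX_plus"

## 6. a headless game session under the scripted placement decoder
g <- game_new(width = 2, depth = 2, layers = 10, fall_rate = 0.5, seed = 3,
              shapes = c("single", "domino"))
s <- run_session(decoder_oracle(), duration_s = 600, game = g)
print(s)
#> <session_log> 571 windows, 142.5 s, final score 1 (run ended)
```

The ERD index of −0.73 at C3 in 12–16 Hz reflects the planted contralateral
mu/beta suppression during right-hand imagery (a gain of 0.5 on the
innovation SD suppresses band power by ~75%, attenuated by mixing with
unmodulated sources). The Amari index near 0 says the temporal ICA
recovered the mixing matrix almost exactly where the sample-wise baseline
(0.26) stayed far from a permutation. The session log records every decode
window, automaton state and score on the way to a cleared layer.

End-to-end training — recording in, selection + ICA + CSP filters + trained
classifier out — is one call:

```r
art <- train_pipeline(rec, seed = 1)
predict_pipeline(art, eps[[1]])
```

A thin command-line front end over the same functions is installed at
`inst/scripts/mibci` (`simulate`, `benchmark`, `play` subcommands).

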