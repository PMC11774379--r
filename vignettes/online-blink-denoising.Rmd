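---
title: "Online wavelet-based adaptive denoising of EEG blink artefacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online wavelet-based adaptive denoising of EEG blink artefacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Scalp EEG is contaminated by physiological artefacts — eye blinks above all —
that are often an order of magnitude larger than the neural signal. Offline
pipelines remove them with multi-channel decompositions and human review; an
*online* system sees only the data recorded so far, must return each segment
within its own duration, and, in the minimal setting this package targets,
has a single channel and no reference electrode.

The observed signal is modelled additively: `x(n) = s(n) + v(n)`, a neural
background `s` plus sparse artefact transients `v`. The pipeline never
estimates `v` explicitly; it looks for moments whose time–frequency content
is *anomalous* relative to the recent past and attenuates them:

1. **Windowing.** The stream is cut into consecutive non-overlapping windows
   of `window_ms` milliseconds (default 1000 ms at 1024 Hz = 1024 samples).
2. **Decomposition.** Each window is decomposed with an orthogonal discrete
   wavelet transform (Mallat's pyramid, `sym4` by default — its near-symmetric
   positive lobe resembles a blink). To shield the window's left edge from the
   cone of influence, the transform runs on the concatenation of the previous
   and current windows and keeps only the coefficients attributable to the
   current one (`n/2^m` at level `m`).
3. **Scaleogram.** Per-level coefficients are replicated `2^(m-1)` times into
   a rows-by-columns matrix (one row per scale plus the final approximation,
   one column per pair of samples), then each row `m` is divided by `2^m` so
   that no scale dominates the next stage.
4. **Detection.** Each column is a point in scale space. An extended
   isolation forest — `if_trees` random oblique-partition trees, each grown on
   `if_subsample` columns drawn from a sliding buffer of the last
   `buffer_capacity` windows — scores every column of the current window:
   `s = 2^(-E(h)/c(psi))`, where `E(h)` is the mean isolation depth and
   `c(psi)` the average unsuccessful binary-search path among `psi` points.
   Columns with `s > anomaly_threshold` are flagged.
5. **Mitigation.** Flagged columns, expanded by `expansion_step` neighbours to
   each side, are attenuated towards the buffer medoid: each entry is
   multiplied by `1 - |a_j - medoid_j| / maxdist_j` (clamped to [0, 1]),
   computed row-wise on the raw (de-normalised) coefficients, so scales far
   from typical behaviour shrink aggressively while typical scales are barely
   touched. The window is then rebuilt with the inverse transform. Windows
   with no flagged column are returned bit-identical.

The first `buffer_capacity` windows are a cold start: they pass through
unmodified and only fill the buffer. The forest is retrained after every
window, which is what makes the detector adaptive to slow drifts.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `window_ms` | 1000 | ms | latency/frequency-resolution trade-off; must give a dyadic sample count |
| `sampling_rate` | 1024 | Hz | acquisition rate |
| `mother_wavelet` | `"sym4"` | — | analysis template; should resemble the artefact |
| `buffer_capacity` | 20 | windows | memory of "recent normal behaviour" |
| `if_subsample` | 512 | vectors | per-tree sample; 5–10% of the buffer fights swamping/masking |
| `if_trees` | 100 | trees | ensemble size |
| `anomaly_threshold` | 0.55 | — | score above which a column is artefactual |
| `expansion_step` | 35 | columns | neighbourhood mitigated around each flag (~68 ms each side) |
| `extension_level` | rows − 1 | — | oblique-split dimensionality; 0 = axis-parallel |
| `boundary_mode` | `"symmetric"` | — | pyramid edge extension (see below) |
| `seed` | 0 | — | all randomness of a run |

Two defaults deserve their own explanation.

**Decomposition depth.** The pyramid could in principle run to
`log2(samples_per_window)` levels (10 for 1024 samples). We default instead to
the standard rule `floor(log2(n_context / (L - 1)))` evaluated on the
two-window context the transform actually sees — 8 levels for `sym4` at
1024 samples. The deeper levels of a one-second window are not meaningfully
estimable: the analysing wavelet's support exceeds the available context, so
those coefficients are boundary artefacts, and carrying them into the anomaly
vectors drowns the real scales. The full pyramid remains available via
`max_level`.

**Boundary extension.** The right edge of the current window (and both edges
of the first one) must be extended at every pyramid level. A straight-line
(first-derivative) continuation is attractive on paper, but at coarse levels
the per-level extension spans the equivalent of seconds of signal, and the
extrapolated values compound level over level: on pure synthetic background
we measured coarse-row standard deviations 3–6 times larger than the
signal's energy permits, large enough to bury a blink signature entirely.
The default is therefore a symmetric mirror reflection, which is bounded by
the data range at every level; the straight-line mode is kept as
`boundary_mode = "smooth"` for comparison. Reconstruction is exact under
both modes because the boundary-influenced coefficients are retained
internally and restored at inversion.

## What the synthetic generator emulates — and what it does not

`simulate_blink_eeg()` produces a frontal-channel caricature with exact
ground truth:

* background: Gaussian 1/f-weighted noise (flat below 1 Hz), band-limited by
  an anti-aliasing low-pass with half-power at `sampling_rate / 5` (the
  front-end of the active-electrode system this instantiation targets), plus
  a 10 Hz alpha oscillation at 20% of the total RMS; scaled to 15 µV RMS;
* blinks: positive squared-cosine pulses, widths uniform in 100–400 ms,
  amplitudes 80 µV ± 20%, Poisson-like arrivals at 12/min with a 500 ms
  refractory gap (mean inter-blink interval is exactly `60 / rate`); a
  `double_blink` flag emits pulse pairs 300 ms apart to reproduce the known
  hard case. The template is deliberately *not* a sampled wavelet atom, so
  detection does not trivially favour the analysing wavelet;
* the contaminated trace is the exact sum, so the oracle SNR
  `10 log10(sum(clean^2) / sum((observed - clean)^2))` is available per window.

The generator is stationary apart from the blinks: it has no electrode
drifts, no movement or muscle artefacts, no saccades, and its blink shape is
stereotyped. Passing tests on it demonstrates that the machinery does what
it claims under the stated conditions — not that real recordings, with their
non-stationarity and richer artefact mixture, will behave as cleanly.

## Numerical choices and edge cases

* Coefficient trimming is *centre-aligned*: the kept `n/2^m` coefficients at
  level `m` are the ones whose support centres fall inside the current
  window (level-`m` coefficient `j` is centred on sample
  `2^m j - (L-3)/2 (2^m - 1)`), which keeps them maximally clear of the
  padded edges of the full arrays.
* Reconstruction of a decomposed window writes the (possibly mitigated)
  trimmed coefficients back over the retained full arrays and inverts the
  exact synthesis chain; untouched windows reconstruct to ~1e−12 relative
  error. Dyadic coefficient sets constructed without decomposition context
  invert through periodised synthesis filters, which keeps the inverse
  linear and exact for algebraic tests.
* The approximation row is carried through the scaleogram, the anomaly
  vectors and the mitigation, normalised by `2^M` (mirroring its replication
  factor).
* Mitigator guards: rows with zero spread (`maxdist = 0`) attenuate nothing;
  the factor is clamped into [0, 1] so a column beyond every buffer member
  is zeroed rather than sign-flipped. Overlapping expansions merge, so each
  column is mitigated at most once per window.
* Medoid ties break to the earliest (window, column); distance sums are
  maintained incrementally across the FIFO turnover (exactly — verified
  against recomputation from scratch) so the O(N²) pass happens once per
  stream, not once per window.
* Scores exactly at the threshold are *not* flagged (strict `>`).
* The buffer stores pre-denoising vectors only; mitigation never feeds back
  into its own reference.
* Blink-free ground-truthing: `tune_k()` accepts a peak as a plausible blink
  if its topographic prominence exceeds 6 and its height 3.5 robust standard
  deviations of the 1–10 Hz band-passed trace. The pair was fixed once from
  a pilot of 20 background-only and 20 blink simulations: background
  prominences are valley-driven (peak ~3σ plus valley ~3σ) while the
  narrowest admissible blinks still clear both floors. This single-channel
  filter stands in for the multi-channel topography check that needs more
  electrodes than this package assumes.

## Known limitations

* At the default threshold of 0.55, roughly 0.1–1% of perfectly ordinary
  columns exceed the score threshold (the upper tail of the isolation-score
  distribution of a homogeneous cloud — the same rate is observed with an
  independent isolation-forest implementation). Across 512 columns per
  window this means most windows have at least one flagged column, so
  classifying a window as artefactual because of a single flag (the default
  `min_anomalies_for_positive = 1`) is permissive; the mitigation of such
  isolated false flags is mild by construction (columns near the medoid are
  barely attenuated), but strictly untouched windows are a minority.
* The right edge of each window remains the weak spot: no future context
  exists, so blinks at a window's end are detected less reliably — an
  intrinsic cost of the online setting.
* Double blinks (pulse pairs closer than the refractory assumption) deviate
  from the single-pulse template and are the generator's built-in hard case.
* Per-window latency is logged against the `window_ms` budget and a run
  warns when it is exceeded; with the defaults on current commodity hardware
  the mean is well under the budget, but this is hardware-dependent and
  never enforced.

## Problem sizes used by the test suite

The packaged tests exercise the full pipeline on 60-second synthetic
recordings (60 windows, 40 screened after the 20-window warm-up) across 10
seeds, with smaller 64-sample-window instantiations for the unit-level
algebra. `scripts/acceptance.R` reruns the sizing checks, a 50-window
reconstruction sweep, one full 60-second pipeline run and its evaluation for
an arbitrary seed.
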