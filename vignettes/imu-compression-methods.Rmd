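---
title: "Lossless predictive compression of IMU signals: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lossless predictive compression of IMU signals: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imucodec)
```

## The problem

Body-worn inertial measurement units (IMUs) emit six co-located channels —
three accelerometer and three gyroscope axes — of 16-bit signed samples at a
fixed rate (60 Hz in the gait corpora this package targets). Uncompressed,
full-body motion capture quickly outruns wireless links:
`raw_stream_bandwidth(500, 15, 9, 32)` = `r raw_stream_bandwidth(500, 15, 9, 32)`
Mbps, comparable to an HD video stream. Movement applications often cannot
tolerate distortion (no single distortion criterion fits all of them), so
the package implements *lossless* compression only.

Every codec here follows the classic two-stage decomposition: a **model**
predicts the current sample from past samples, and a **coder** entropy-codes
the prediction residual `e[n] = x[n] - xhat[n]`. Slowly varying signals give
small residuals, which Golomb–Rice codes represent in few bits. The decoder
runs the identical model on the samples it has already reconstructed, so the
pipeline is exactly invertible.

## Predictors as fixed linear filters

All seven predictive models reduce to a fixed filter over the `p` most
recent samples, `xhat[n] = sum_{i=1..p} w_i x[n-i]`:

* **delta** (`d = 0, p = 1`): `w = (1)`; residual is the first difference.
* **linear extrapolation** (`d = 1, p = 2`): `w = (2, -1)`.
* **polynomial regression** of order `d` over `p > d` points: fit by least
  squares at unit-spaced past positions `-1..-p` and extrapolate to
  position 0. The weight vector is the row `e_d (C'C)^{-1} C'` of the
  normal equations and is data-independent, so high-order extrapolation
  costs one dot product per sample. With the default exact fit `p = d + 1`
  the weights are the signed binomial coefficients
  `(-1)^(i+1) choose(d+1, i)` — exact integers, hence exactly
  representable in fixed point. `p` is configurable for the overdetermined
  case; weights always sum to 1, so every polynomial predictor reproduces
  constants.
* **natural cubic spline** through the `p` most recent samples (default
  `p = 5`, configurable 3–16), with the last cubic piece evaluated one step
  beyond its interval.

### The spline collapses to the linear filter

A fact we did not expect when implementing `derive_spline_coeffs()`: write
`M_i` for the spline's second derivatives at the knots. On unit-spaced
knots, evaluating the last piece one full step past the end knot gives

```
f_{p-1}(p + 1) = 2 x[p] - x[p-1] + M_p ,
```

(the `M_{p-1}` terms cancel exactly), and the natural boundary condition
*is* `M_p = 0`. So the natural-spline one-step extrapolator equals linear
extrapolation, `w = (2, -1, 0, ..., 0)`, for every `p`. The implementation
still solves the tridiagonal system generically (that is the method's
definition, and any other boundary condition would give non-trivial
weights); the tests pin the collapsed form as a hand-algebra oracle. The
practical consequence: the spline codec's output is bit-identical to the
linear codec's, and observed rank differences between the two in other
implementations can only come from numerical details of an in-loop spline
solve, not from the mathematics.

## Fixed-point evaluation

IEEE-754 floating point does not guarantee bit-identical results across
platforms or compilers, which is fatal for lossless coding: one rounding
difference on the decoder desynchronizes every later sample. Predictions
are therefore evaluated in signed Q16.16 fixed point: coefficients are
quantized to `round(w * 2^16)` (half away from zero, symmetric in sign),
and `q16_fma_dot()` computes an exact wide-integer multiply-accumulate
followed by an arithmetic right shift of 16 bits, i.e. floor toward
negative infinity. Floor was chosen over round-to-nearest because the only
requirement is that encoder and decoder agree, and floor is what a
two's-complement shift gives for free. The accumulator is exact for
`p <= 64` (|acc| < 2^53 in R's doubles, the analogue of a 64-bit integer
accumulator). For the default exact-fit predictors the coefficients are
integers, so quantization introduces no error at all.

## Residual coding

Signed residuals are mapped to non-negative integers with the zigzag
bijection (`0, -1, 1, -2, ... -> 0, 1, 2, 3, ...`), which keeps small
magnitudes small regardless of sign — the right property for the roughly
symmetric, roughly geometric residual distributions prediction produces.
Each value `u` is Rice-coded with order `m`: a unary quotient
`floor(u / 2^m)` (ones terminated by a zero), then the `m`-bit remainder,
MSB first — `m + floor(u / 2^m) + 1` bits per codeword. The per-channel
`m` is chosen by exhaustively minimizing the closed-form total over
`m = 0..15`, ties to the smaller order; a one-pass streaming heuristic
(`m = floor(log2(mean u))`) is available behind a flag. Two guards matter
in practice:

* an **escape** replaces any codeword whose quotient exceeds 47 with 48
  ones plus the raw 32-bit value (80 bits), bounding the damage an
  adversarial sample can do to the stream;
* bitstreams are packed MSB-first and zero-padded to a byte per channel,
  and that layout is part of the container contract.

The container (`kc_compress()` / `kc_decompress()`) frames method id,
`d`, `p`, channel count, sample count, per-channel Rice order, the first
`p` samples verbatim (warm-up, so the decoder has history; signals shorter
than `p` are stored entirely as warm-up) and the payloads. Filter
coefficients are *not* stored — the decoder re-derives and re-quantizes
them from `(method, p)`, which keeps the fixed header at
`16 + s(5 + 2p)` bytes. Channels are compressed independently, matching
the node- and stream-independence restriction of the codec family.

## Baselines and the compression ratio

The reference representation is a constant-width CSV: every sample is an
explicit sign plus five zero-padded digits, so a row of `s` values is
exactly `7s` bytes and the baseline size is data-independent. Compression
ratio is `CR = CSV bytes / compressed bytes`; the raw int16 binary format
is then a data-independent `CR = 3.5`, and DEFLATE (zlib level 6, via
`memCompress`) provides the general-purpose reference. Absolute CRs scale
linearly with the bytes-per-sample of the chosen CSV dialect, which is why
cross-study CR comparisons need the dialect pinned.

## The L1-optimal reference models

To bound what any fixed linear predictor could achieve on a given signal,
`fit_l1_ar()` solves

```
minimize_a  || x - X a ||_1  +  lambda || a ||_1
```

offline, with full knowledge of the signal. The L1 residual norm is the
right objective because the Rice codeword length is affine in the residual
magnitude (the relaxed size model `l + l m + 2^-m sum(u)` implemented by
`approx_encoded_size()`, within `l` bits of the exact stream when no
escape fires); the L1 penalty promotes sparse coefficients, which lose
less to Q16.16 quantization. `fit_l1_mvar()` expands the design to the
past `p` samples of all `s` co-located streams.

The solver is cyclic coordinate descent in which each one-dimensional
subproblem is solved *exactly* by a weighted median of breakpoints (the
penalty contributes a breakpoint at zero with weight `lambda`). Because
the piecewise-linear objective can stall coordinate descent at a
non-global corner, a second candidate is produced by iteratively
reweighted least squares (smoothing floor shrinking geometrically to
1e-9) and polished by the same descent; the better of the two is
returned. Two structural guarantees follow from warm starts rather than
from solver accuracy: the AR fit starts at the delta filter, so its
objective never exceeds delta's total absolute residual; each MVAR target
starts at its fitted AR solution, so MVAR never does worse than AR.
Defaults: `lambda = 0` (the penalty is exploratory; a `{0, 0.1, 1, 10}`
grid is the suggested sweep), order `p = 8` for corpus experiments,
relative objective tolerance 1e-8, 200-sweep cap. All steps are
deterministic.

Degenerate inputs are worth knowing about: on a ±1-step random walk the
empirical L1 objective is flat in whole regions of coefficient space (any
mixing coefficient in [-1, 1] has identical *expected* cost), so the
in-sample optimum can sit several percent below delta with coefficients
far from `(1, 0, ..., 0)`. With steps drawn from a spread distribution
(e.g. rounded Gaussian, sd 20) the optimum is essentially unique, the
fitted coefficients approach the delta filter and the in-sample gap falls
below 0.2% at `n = 3000` — this is the configuration the tests and the
acceptance script use to quantify "delta approaches the optimum".

`quantize_model()` turns a fitted AR model into a Q16.16 predictor usable
with the codec primitives and reports the real-vs-fixed-point size cost.
Since the container stores no coefficients, quantized custom models run
through `predict_encode()`/`predict_decode()` directly rather than through
the seven named container methods.

## What the synthetic corpus emulates — and what it does not

`synth_corpus()` generates labeled test cases of six co-located channels,
16-bit at 60 Hz, in two regimes:

* **stationary** (sitting/standing-like): constant offset (within ±500
  LSB) plus Gaussian sensor noise, sd 3 LSB;
* **active** (walking/running-like): a quasi-periodic harmonic series at
  a 1.8 Hz stride frequency — amplitudes `2000/h` LSB over 4 harmonics,
  random phases — plus a wide-band Gaussian term, sd 400 LSB.

The wide-band term deserves its justification. It models everything a
one-step predictor cannot anticipate: sensor noise *plus* the broadband
movement content (heel-strike transients, soft-tissue vibration) that real
gait spectra carry all the way to Nyquist at 60 Hz. A band-limited
harmonic signal with only instrument-grade noise would be the wrong
emulation: on such a signal higher-order extrapolators beat delta coding,
whereas on real gait corpora the unpredictable band dominates the
sample-to-sample change and delta wins — the ordering the generator must
(and with sd = 400 ≈ a fifth of the fundamental, does) reproduce,
including the monotone degradation from 1st- to 5th-order polynomials
whose noise-amplification factors `1 + sum(w^2)` grow from 6 to 924.

What the generator does **not** emulate: real stride-to-stride
variability, inter-channel phase structure (channels are independent given
the regime), sensor bias drift, clipping at high dynamics, or any
particular database's amplitude scale. Passing benchmarks on synthetic
data therefore demonstrate the codec's ordering and regime separation, not
the absolute compression ratios of any real corpus: absolute CRs depend on
the corpus's residual scale and the CSV dialect, and reproducing published
corpus values requires the corpus itself.

## Statistical comparison machinery

`run_benchmark()` compresses every case with every method and applies the
standard comparing-classifiers-over-datasets protocol: per-case ranks
(rank 1 = highest CR, average on ties — near-ties are structural here:
spline and linear produce identical payloads and differ only in warm-up
overhead), the classic Friedman statistic
`12/(Nk(k+1)) sum(Rj^2) - 3N(k+1)` against chi-squared with `k-1` df, and
the Nemenyi critical difference `q_alpha(k) sqrt(k(k+1)/(6N))` with
`q_alpha(k) = qtukey(0.95, k, Inf)/sqrt(2)`. Across data classes (the
per-activity CR distributions are near normal) a one-way ANOVA with
Tukey's HSD locates the separated pairs; both delegate to the standard
`stats` routines. Alpha is fixed at 0.05. The per-method "overall CR" is
the unweighted mean over test cases (the pooled byte ratio is available
from the per-case table if wanted).

## Problem sizes and reproducibility

The shipped test-and-report configuration uses sizes chosen to keep a
desk run in seconds-to-minutes while leaving the conclusions stable
across seeds: 24 synthetic cases of 8 s × 60 Hz × 6 channels for the
benchmark (the activity ANOVA rejects at p < 1e-30 there), 250–1000
randomized signals for the losslessness property, walks of `n = 3000` for
the optimality gap, and `n = 5000` for AR support recovery.
`scripts/acceptance.R --seed S --out f.json` recomputes all headline
quantities from scratch; every random draw derives from the one seed.

## Known limitations

* Rice order is static per channel block; dynamic order adaptation and
  dropped-packet recovery are out of scope.
* No inter-channel prediction in the shipped codecs (the MVAR reference
  exists precisely to measure what that independence costs — little, on
  corpora like these).
* The L1 solver is exact only up to its descent tolerance; the structural
  bounds (≤ delta, MVAR ≤ AR) hold regardless, but reported objectives
  carry ~1e-8 relative slack.
* Coefficient re-derivation at decode time assumes encoder and decoder
  run the same package version; the container's version byte exists to
  gate format changes.
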