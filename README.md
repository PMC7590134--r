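# imucodec

Lossless compression of multi-channel human-movement IMU signals —
body-worn 6-axis accelerometer + gyroscope streams of 16-bit samples at a
fixed rate (60 Hz in gait corpora). Raw full-body motion capture is heavy:
500 Hz × 15 segments × 9 axes × 32 bits = 2.16 Mbps, about an HD video
stream, more than Bluetooth or Zigbee carry. Movement applications rarely
agree on an acceptable distortion, so compression here is strictly
lossless.

Every codec is a causal, zero-delay autoregressive predictor followed by
Golomb–Rice coding of the prediction residual `e[n] = x[n] - x̂[n]`:

* **delta** — `x̂[n] = x[n-1]` (0th-order polynomial);
* **linear** — `x̂[n] = 2x[n-1] - x[n-2]`;
* **poly2..poly5** — order-*d* least-squares polynomial regression over the
  *p* most recent samples, extrapolated one step; the weight vector
  `e_d (CᵀC)⁻¹Cᵀ` is data-independent, and with the exact fit `p = d+1` it
  is the signed binomial vector;
* **spline** — natural cubic spline through the *p* most recent samples,
  last piece evaluated one step ahead (which provably collapses to the
  linear filter — see the methods vignette).

Predictions are evaluated in deterministic Q16.16 fixed point (exact
64-bit accumulate, arithmetic shift), so encoder and decoder are
bit-identical on any platform. Residuals are zigzag-mapped and Rice-coded
with a per-channel order chosen by exhaustive search; codewords are
`m + ⌊u/2^m⌋ + 1` bits. Alongside the codecs the package ships the
constant-width CSV / raw-binary / DEFLATE baselines, a-posteriori
L1-optimal AR and multivariate AR reference models
(`min ‖x − Xa‖₁ + λ‖a‖₁`, solved by exact weighted-median coordinate
descent), a synthetic 60 Hz corpus generator with active and stationary
regimes, and a benchmarking harness (compression ratios, Friedman/Nemenyi
rank comparison, ANOVA/Tukey activity comparison).

## Worked example

```r
library(imucodec)

corpus   <- synth_corpus(24, seed = 42)       # 12 active + 12 stationary cases
channels <- corpus[[1]]$channels              # six 480-sample int16 channels

kc  <- kc_compress(channels, method = "delta")
csv <- write_fixed_csv(channels)
length(csv); length(kc)
#> [1] 20160
#> [1] 4281
identical(kc_decompress(kc), lapply(channels, as.integer))
#> [1] TRUE

run_benchmark(corpus)
#> IMU compression benchmark over 24 test cases
#>
#> Mean compression ratio per method (CSV baseline = 1):
#>  delta linear  poly2  poly3  poly4  poly5 spline
#>  8.706  7.666  6.736  5.991  5.390  4.902  7.591
#>
#> Friedman chi^2 = 144.00 (p = 1.43e-28); mean ranks:
#>  delta linear  poly2  poly3  poly4  poly5 spline
#>      1      2      4      5      6      7      3
#>
#> Mean CR of delta by activity:
#> sitting walking
#>   12.71    4.71
```

The 480-sample walking-like case costs 20 160 bytes as constant-width CSV
and 4 281 bytes delta-compressed (CR 4.7); stationary cases compress to
CR ≈ 12.7. Delta coding ranks first on every case and each higher
polynomial order ranks worse — high-order extrapolation amplifies the
wide-band component of movement signals (Runge-type behaviour), it does
not cancel it. The spline codec's payload is bit-identical to linear's
(its rank differs only through warm-up overhead).

How close is delta to the best any fixed linear model could do?

```r
x   <- corpus[[1]]$channels[[1]]
fit <- fit_l1_ar(x, p = 4)        # offline L1-optimal AR reference
fit
#> L1-optimal AR model (p = 4, lambda = 0)
#>   objective (sum |e| + lambda sum |a|): 260175.1809 over 476 samples
#>   coefficients (lag 1..p):  0.9968  0.1479 -0.1639 -0.1660
#>   delta-filter objective on same data: 294885.0000
```

On random-walk-like channels the gap shrinks below 0.2%; `quantize_model()`
turns such a fit into a Q16.16 predictor and prices the quantization.

A thin command-line interface wraps the same functions
(`inst/cli/imucodec.R`): `compress`, `decompress`, `cr`, `synth`, `bench`,
`fit-optimal`.

## Container format

`kc_compress()` emits a self-describing `.kc` image: magic `KC01`,
version, method id, `d`, `p`, channel count `s`, sample count `l`
(16-byte header), then per channel the Rice order, the first `p` samples
verbatim (warm-up), payload byte count and the MSB-first, byte-padded
bitstream — `16 + s(5 + 2p)` bytes of fixed overhead. Filter coefficients
are never stored; the decoder re-derives them from `(method, p)`.

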