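---
title: "Methods: mapping subthreshold oscillations in voltage imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping subthreshold oscillations in voltage imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stomap)
```

## The measurement problem

Inferior-olive neurons express subthreshold oscillations (STOs): regular,
near-sinusoidal fluctuations of the membrane voltage in the 3–12 Hz band
with peak-to-peak amplitudes of a few millivolts. Because the oscillation is
a *network* phenomenon in a gap-junction-coupled nucleus, single-cell
patch-clamp recordings cannot reveal its spatial organization. Wide-field
voltage imaging with a purely electrochromic dye converts membrane voltage
linearly into fluorescence, at roughly 0.5 %ΔF/F per mV of depolarization,
so a 6 mV peak-to-peak STO appears as a ~3 % fluorescence modulation on top
of the resting intensity, photobleaching, and camera noise. `stomap`
implements the analysis chain that turns such movies into maps of
oscillating clusters and quantifies their temporal relationships, plus the
radial-profile analyses used to characterize dye spread and internalization
in fixed tissue.

## Generative model of the synthetic fixtures

Every stage of the package is testable against ground truth produced by
`generate_sto_movie()`. The model for a pixel covered by clusters $c$ is

$$ F(t) = B\, e^{-t/\tau}\bigl(1 + s \sum_c V_c(t)\bigr) + \varepsilon(t), $$

with baseline $B$ (counts), photobleaching time constant $\tau$,
sensitivity $s$ (fractional ΔF/F per mV) and per-frame Gaussian sensor
noise $\varepsilon$. Each cluster contributes
$V_c(t) = \tfrac{A_c}{2}\sin(2\pi f_c t + \varphi_c)$ in mV within a filled
circular footprint; overlapping clusters superpose. An optional stimulation
train (default 10 pulses at 10 Hz) re-renders all clusters after the train
at a common entrained frequency with per-cluster phases and an amplitude
gain, and adds brief negative deflections at the pulse times, emulating
afferent-stimulation experiments.

Stated-world defaults: 256 × 256 px frames at 17.86 µm/px (5× objective;
1.22 µm/px at 60×), 40–120 fps, 10 s duration, cluster footprints of
110 µm diameter (≈ 29 px at 5×), frequencies in 3–12 Hz, amplitudes around
6 mV peak-to-peak (the 2–10 mV range), sensitivity 0.005/mV.

Two values the emulated experiments do not pin down were chosen once:

* **Sensor noise `noise_sd = 5` counts** on a 1000-count baseline (0.5 %
  rms per pixel-frame). No SNR figure for raw single-pixel traces is
  published for this preparation; 0.5 % gives a per-pixel, per-frame
  oscillation SNR near 2 for a 6 mV STO — oscillations are visible but
  single pixels remain noisy, which is the regime the averaging and
  thresholding steps exist for. Tests sweep noise where it matters.
* **Bleaching `bleach_tau_s = 100` s**, i.e. ~10 % intensity loss over a
  10 s trial — mild, realistic bleaching that the correction step must
  genuinely remove (the shared decay otherwise correlates every pixel with
  every other).

What the generator does **not** emulate: optical point-spread, 3-D
scattering, movement, inhomogeneous staining within a footprint, non-
sinusoidal STO waveforms, and biophysical network dynamics. A green test
therefore establishes that an operator recovers what its contract promises
on data satisfying its assumptions — not that those assumptions hold in any
particular slice.

## Pipeline choices and their rationale

**Bleach correction.** The decay model is mono-exponential plus offset. The
time constant is estimated once from the frame-mean trace (nonlinear least
squares); per-pixel amplitude and offset are then linear least squares on
the basis $\{e^{-t/\tau}, 1\}$. This keeps the correction per-pixel (local
staining differs) while avoiding 65k nonlinear fits; pixels with a
non-positive fitted trend fall back to the global trend. Output is
dimensionless with mean ≈ 1, so a second pass finds a flat trend
(idempotence, tested).

**ΔF/F.** Baseline is the per-pixel temporal mean by default, or a stated
pre-stimulus window. Zero-baseline pixels are masked with a warning, not an
error, because single dead pixels must not abort a mapping run. Intensity
histogram normalization is provided for display only — it is nonlinear and
would corrupt PSD amplitudes.

**Welch PSD.** Defaults: 1 s segments (1 Hz resolution resolves the
3–12 Hz band at all supported frame rates), 50 % overlap, periodic Hann
window, linear detrend per segment, one-sided density scaling so the
integrated PSD matches trace variance (Parseval, tested at 10 %). Band
integration is half-open $[f_{lo}, f_{hi})$, making sub-band additivity
exact: power[3,12) = power[3,7) + power[7,12).

**Thresholding.** The band-power image is normalized to its maximal pixel,
then masked at the 0.90 linear-interpolation sample quantile (strictly
above), optionally intersected with a z-score mask (default z ≥ 2; the
z-threshold is not pinned by the emulated protocol and is exposed in
config). Masks intersect, so quantile and z-score filters commute.

**Clustering.** OPTICS runs on the (row, col) coordinates of masked pixels
only — the mask already encodes oscillation strength, and density-based
clustering lets clusters be spatially discontinuous. Parameters:
max reachability 5 px, ξ = 0.05 steepness extraction, minimum cluster size
5 px, derived as a "significant portion" (5/29) of the per-neuron footprint
`neuron_footprint_pixels(110, 18) = 29`. Processing order ties break on
ascending (row, col); the partition is invariant to input order (tested).
The implementation was validated during development against an independent
OPTICS implementation to 1e-16 on reachabilities with identical labels; the
frozen case lives in `test-optics.R`. Cluster ids are assigned from 0 in
descending mean band power.

**Correlograms.** Sliding windows (default 1 s, half-window step) with
*overlap-normalized* correlation, i.e. `cor()` of the overlapping segments
at each lag rather than the taper-biased ACF estimator — a pure tone then
keeps peak height ≈ 1 at its period, matching how correlogram peak heights
are reported in this field. Periodic signals tie across whole periods;
the reported peak lag is the smallest |lag| among ties. Zero-variance
windows are skipped with a warning and excluded from averages, never
zero-filled.

**Pre/post stimulation ratio.** Matched windows (default 2 s) before and
after the train, spectrum per window at the window's own resolution (single
periodogram) with a **rectangular** taper. This deviates from the package's
Hann default deliberately: a per-bin *ratio* amplifies taper leakage — with
a Hann taper the entrained tone leaks ±1 bin into bins whose denominator is
a bare noise draw, which moves the ratio peak off the true frequency about
20 % of the time regardless of noise level. With matched rectangular
windows an on-bin oscillation's power stays in its bin and the ratio peak
sits at the entrained frequency. Hann remains available via `window=`.

**Covariance / coherence.** Covariance matrices are computed on
running-median-detrended ΔF/F traces (window 0.25 s — the detrending used
for displayed traces in this workflow; it removes the stimulus transient
and residual drift). Display normalization to [0, 1] is joint across
windows by default (per-window optional, both emitted), since the figure
being emulated compares windows on a common scale. The coherence image is
each pixel's maximal across-window mean absolute off-diagonal covariance.

**Downsampling.** 50 kHz electrophysiology is bin-averaged (not decimated)
into frame-length windows — anti-aliasing for free at the cost of a
half-frame group delay, which is below the one-frame tolerance used in all
lag comparisons.

**Radial profiles.** Annulus membership by pixel-centre distance, bin width
one pixel pitch by default, empty annuli recorded as missing. The half-max
radius subtracts a baseline (mean of the outermost 10 % of bins) before
halving, and interpolates linearly between bins; profiles that never fall
below half-max are censored at the field edge. Consequence: the field of
view must extend to ~2.5 σ of the spread being measured, or the baseline
term inflates and the estimate biases low — the fixtures use confocal-like
geometry (≥ 450 µm fields) for this reason.

**Per-cell profiles.** 20 µm discs, 18 segments of 20° starting at the
image row axis (counterclockwise). All profiles (average and segments) are
min–max normalized with the *average* profile's range: the averaged profile
then peaks at exactly 1 while segment profiles remain mutually comparable,
which is what the across-segment peak-variability statistic requires.
Compartment bounds are fixed at nucleus 0–3.5 µm, cytosol 3.5–10 µm,
neuropil > 10 µm.

**Coordinates.** Everywhere: 0-based (row, col), half-open ranges, time on
axis 1. Movies are multi-page TIFF (16-bit unsigned for counts, 32-bit
float for dimensionless data) with a flat key-value metadata sidecar; a
missing frame rate is an explicit error, never a silent default.

## Degenerate inputs and numerical edges

* All-equal PSD images threshold to an empty mask with a warning (there is
  no 90 % quantile of one value); all-zero images cannot be max-normalized
  and error.
* Fewer masked pixels than the minimum cluster size yields an *empty
  cluster set*, logged, not an exception — a quiet slice is a result.
* `dff` on a constant movie returns zeros; `bleach_correct` on a constant
  movie returns ones (flat trend).
* Cross-correlation and CSD operators require equal-length inputs and
  direct the caller to `downsample_ephys()` instead of resampling
  implicitly.
* Censored half-max estimates carry a `censored` attribute rather than
  fabricating a radius.

## Command-line interface

`simulate`, `preprocess`, `map`, `cluster`, `coherence`, `anatomy`, driven
by flat `key: value` config files with a strict schema (unknown keys are
rejected) and `--key=value` overrides. Exit codes: 0 success, 2
configuration error, 3 data-format error, 4 numerical failure. Every
product is a new file with a JSON provenance sidecar (parameters, input
MD5s, package version); inputs are never mutated. Seeds are explicit
everywhere randomness exists; identical seeds give byte-identical movie
files (tested).

## Known limitations

* OPTICS is O(n²) in masked pixel count in this pure-R implementation;
  fine up to the ~6.5k pixels a 90 % threshold leaves on a 256² frame,
  slow far beyond that.
* The TIFF layer reads/writes uncompressed single-sample baseline TIFF
  only (8/16-bit unsigned, 32-bit float) — sufficient for this pipeline's
  products, not a general TIFF library.
* Phase relationships are taken from cross-correlogram lags and CSD phases;
  no Hilbert/wavelet instantaneous phase is provided.
* The half-frame group delay of bin-average downsampling is uncorrected
  (below every stated tolerance here, but a consideration at higher
  oscillation frequencies).
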