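---
title: "Methods: multiparametric QPI drug screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiparametric QPI drug screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpiscreen)
```

This vignette documents the models, parameter choices, and numerical
decisions behind the package, and what the synthetic-data tests do and do
not establish about real microscope data.

## The DPC imaging model

Differential phase contrast encodes a transparent sample's phase in
intensity asymmetries between complementary half-circle illuminations. For
a weak object, each half-circle frame is linear in the sample phase, and
the normalized difference of an opposing pair,
$g = (I_1 - I_2)/(I_1 + I_2)$, has the frequency-domain form
$\tilde g(u) = H(u)\,\tilde\phi(u)$ with a purely imaginary, antisymmetric
phase transfer function $H$.

`build_phase_transfer_function()` evaluates $H$ numerically as the
pupil/source overlap sum over the discrete LED positions of the
illuminator: an 8 × 8 grid of 18 mm extent, 24 mm above the sample, giving
an illumination NA of 0.39 against a 0.25 objective
(coherence parameter $\sigma = 1.56$ from the apertures). Only brightfield
LEDs (individual NA ≤ NA~obj~) contribute to the linear phase response, so
$H$ vanishes at DC, in a small neighbourhood of it, and beyond the
partially coherent cutoff. Two consequences matter downstream:

* a global phase offset is never recoverable, so all quantitative uses of
  reconstructed phase are referenced to a background level;
* compact objects sit in a shallow smooth depression (the attenuated
  low-frequency content), which the bead calibration and the background
  correction both have to handle.

`tikhonov_reconstruct()` inverts one or more gradient/transfer-function
pairs by ridge-regularized least squares. The transfer functions are scaled
to unit maximum magnitude so that the regularization constant
$\beta = 10^{-3}$ has the same meaning at every image size; $\beta$
suppresses frequencies where $|H|^2 \lesssim \beta$, trading noise
amplification against low-frequency fidelity. The imaginary residue after
the inverse FFT is checked against $10^{-6}$ of the output amplitude and a
warning raised beyond that. `simulate_dpc_frames()` applies the same
linearized model forward (the two frames of a pair use $\pm H$, so their
sum is exactly twice the background and the normalized difference is
exactly linear in $\phi$), with optional seeded multiplicative noise.

Round-trip accuracy is only meaningful for phantoms supported where the
system responds; `bandlimit_phantom()` projects a phantom onto the region
where the combined two-axis response exceeds a threshold (default 0.05),
and reconstruction then agrees with the phantom to ~1% L2 at zero noise.

## Bead calibration

Polystyrene beads (n = 1.583 at 624 nm) in NOA73 optical adhesive
(n = 1.56) give a refractive-index step comparable to cells in medium.
`calibrate_with_beads()` recovers each bead's index from the integrated
reconstructed phase over its known disk and the analytic sphere volume,

$$ n = n_\text{medium} + \frac{\lambda}{2\pi}\,
   \frac{\sum_\text{disk}\phi \cdot A_\text{pixel}}{V_\text{bead}}. $$

Because of the low-frequency deficit, each bead's local background — the
median phase in an annulus between 2 and 3 bead radii, as in aperture
photometry — is subtracted before integration; a global median would leave
the neighbouring beads' depressions uncompensated. With 4 µm beads this
recovers the index to better than 0.1%; the residual ~0.06% deficit is the
unrecoverable low-frequency content of the bead itself and shrinks with
bead size. The temporal coefficient of variation over repeated frames
reports measurement precision.

## Segmentation, background, mass

`segment_cells()` finds edges with a Sobel gradient magnitude (threshold at
a quantile of the non-zero gradients, default 0.9), closes and fills them
into solid candidates, and then trims each candidate to pixels above half
its peak phase. The refinement step makes the reported area approximately
the half-maximum support of the object, robust to the edge-threshold
choice; for single-cell lines an intensity watershed splits touching
objects. Objects below `min_object_area_px` are discarded.

`correct_background()` fits a 2D polynomial of total degree 8 to non-cell
pixels only (reduced automatically, with a warning, when background pixels
cannot constrain 45 coefficients) and subtracts it everywhere, then applies
rolling-ball background removal as a grayscale opening with a 100 px disk.
The rolling ball is a background (low-frequency) operator; it is applied to
the polynomial-corrected image in that standard role. Finally the
background median is zeroed, which pins the arbitrary DPC offset.

Mass conversion uses the cell-average specific refractive increment
$\alpha$ = 1.8 × 10⁻⁴ m³/kg (0.18 µm³/pg), making mass additive over
disjoint regions; negative totals (debris) are flagged, not censored.
Tracking is greedy nearest-neighbour in a combined position/mass cost,
$(\Delta r/s_\text{pos})^2 + (\Delta m/s_\text{mass})^2$, with
$s_\text{pos}$ twice the median nearest-neighbour spacing per frame and
$s_\text{mass}$ the median object mass; assignments are made in increasing
cost order with deterministic tie-breaks, so tracking is reproducible.

## SGR estimation and filters

Each track is median filtered (5-frame kernel), required to span at least
20 frames and 110 pg mean mass (debris floor), time-shifted to start at
zero, and fit by ordinary least squares; SGR = slope / intercept. Records
deviating more than 3 MAD from the per-condition median in SGR or in the
standard error of the estimate are removed (scaled MAD, factor 1.4826, so
3 MAD ≈ 3σ for normal populations; the raw MAD would cut at ~2σ and
visibly truncate the population spread). The filter runs once per
condition, not iterated, and degenerates safely when the MAD is zero.

The slope/intercept estimator is exact when within-track mass accumulation
is linear in time, $m(t) = m_0(1 + k t)$, and carries an upward bias of
order $0.6\,k T$ on strictly exponential tracks of length $T$ (about +30%
for k = 0.02 h⁻¹ over 24 h). The synthetic generator therefore defaults to
linear within-track accumulation at rate $k m_0$ — the small-$kT$ limit of
exponential growth, under which the estimator is unbiased and recovery
tests are sharp — and offers `growth_model = "exponential"` where the
compounding matters (e.g., the stability of windowed estimates across
time). Real tracks fall between the two regimes; recovery tests on the
linear model demonstrate the estimator and filters, not the absence of
linearization bias in arbitrarily long exponential tracks.

## Temporal dynamics: windows, bins, Hellinger distance, ToR

With frames every 20 min over 72 h the acquisition grid is
$N = 216$ frames at $t = 0, \dots, (N-1)\Delta t$. Overlapping 24 h windows
centred on each frame and fully contained in the acquisition give exactly
144 intervals, grouped 8 per bin into 18 bins. Within each window the
minimum-length, minimum-mass and 3-MAD (on $s_{y.x}$) filters are
reapplied and each track's SGR is recomputed from the window's own
time-shifted regression. Bin summaries use the per-track mean SGR in the
bin; kernel densities use Silverman's bandwidth.

Treated-versus-control divergence is quantified by the Hellinger distance
between discretized SGR distributions,
$H^2(S,T) = \tfrac12\sum_i(\sqrt{s_i} - \sqrt{t_i})^2$, on fixed bins of
width 10⁻⁴ h⁻¹ spanning \[−0.3, 0.3\] h⁻¹ (wide enough for death rates
near −0.22 h⁻¹; out-of-range values are clipped into edge bins with a
warning). $H$ is symmetric, in \[0, 1\], and sensitive to both mean and
variance changes. At fine binning the empirical distance between two
same-distribution samples grows as the per-bin counts drop, so absolute
values are only comparable at matched sample sizes — which is exactly how
the response threshold is defined: $H^*$ is the maximum over time of the
solvent-control versus untreated-control distance at the same scale.

The time of response fits $H(t) = a - b e^{ct}$ (nonlinear least squares;
initial values $a = \max H$, $b = a - H(t_1)$, $c = -0.05$ h⁻¹, natural
logarithm throughout) and inverts analytically,
$t = \tfrac1c \ln\frac{a - H^*}{b}$. No response is reported when the fit
degenerates (constant series), the plateau sits at or below the threshold,
$b \le 0$, or the inverted time falls outside the experiment. Per drug, the
ToR at the tested concentration strictly above the EC50 stands in for the
ToR at the EC50 itself (the concentration below typically elicits none).

## Dose response

Condition-level response is the mean over per-location mean SGRs (27
locations for a triplicate condition); the solvent control is mapped to a
pseudo-concentration of (lowest tested)/100 so all points sit on a log
axis. The 4-parameter Hill model
$\mathrm{SGR}(C) = E_\text{max} + (E_0 - E_\text{max})/(1 + (C/EC_{50})^{HS})$
is fit by Levenberg–Marquardt least squares in log₁₀ concentration with a
multi-start over EC50 (7 log-spaced starts across the tested range × 3
Hill slopes), HS bounded to \[0.1, 10\] and EC50 to \[min/100, max×100\].
The response call compares the Hill fit against a fitted constant with an
F-test on (3, n − 4) degrees of freedom at p < 0.01; the fitted-constant
null is used rather than pinning the line at the control level. For
responders, DoR = (E₀ − E_max)/E₀, with DoR > 1 (E_max < 0) cytotoxic.
The same machinery fit to per-condition SGR standard deviations yields the
heterogeneity EC50.

## Heterogeneity and in-silico mixing

SD at EC50 takes the single-cell SGR standard deviation at the tested
concentration nearest the EC50 in log distance. The mixing analysis pools
all treated cells with control cells sampled to a target prevalence
(rounded count, minimum one, sampled without replacement when possible),
sweeps resistance thresholds over −0.1 to 0.15 h⁻¹ in 0.005 h⁻¹ steps
(51 thresholds; the grid step is a package choice), and predicts
"resistant" for SGR strictly above the threshold. Precision–recall points
are integrated along the threshold sweep (trapezoid over recall, anchored
at zero recall; empty prediction sets take precision 1, i.e. no false
positives — the convention under which a perfect separator scores 1).
AUPRC is normalized as (AUPRC − prevalence)/(1 − prevalence), mapping
no-skill to 0 and perfection to 1 at every mixing ratio. Each ratio is
repeated 100 times with derived seeds; the median normalized AUPRC and the
curve of the median repeat are reported.

## Concordance statistics

Pearson correlation (two-sided t-transform p), Lin's concordance
coefficient
$\rho_c = 2\,\mathrm{cov}(x,y) / (\mathrm{var}\,x + \mathrm{var}\,y + (\bar x - \bar y)^2)$,
and a percentile bootstrap CI (10,000 paired resamples, middle 95%,
degenerate resamples skipped and counted) compare assays. EC50 agreement is
computed on log₁₀ EC50 — dose responses span decades — and restricted to
pairs responding in both assays; the response/no-response confusion matrix
uses all pairs.

## What the synthetic generators emulate — and what they do not

`generate_cell_tracks()` reproduces the study's acquisition grid (72 h,
20 min frames), normal SGR populations, lognormal initial masses around
350 pg, a dying subpopulation switching to exponential mass loss at
−0.217 h⁻¹, and multiplicative measurement noise (2% default), all
deterministic per seed. `plate_layout()` encodes the 96-well design: five
drugs × six concentrations in triplicate plus two solvent controls, nine
imaging locations per well (864 locations, 27 per condition), and the
1:1 serial-dilution arithmetic. The generators do not emulate cell
division and track fragmentation, segmentation errors, identity switches,
spatial crowding, focus drift, or non-stationary drug kinetics — so green
tests demonstrate the correctness of the estimators, filters and fits
under the stated models, not robustness to every failure mode of real
microscopy data.

## Numerical choices and problem sizes

Tests and the acceptance script run at deliberately modest sizes chosen to
exercise every code path with stable statistics: 256²–320² phase images
with eight 4 µm beads, populations of 40–500 tracks, 1000-replicate null
simulations for the F-test calibration, 120 outer repeats at 400 bootstrap
resamples for CI coverage, and 20–40 mixing repeats where medians are
compared. Fitting tolerances: Levenberg–Marquardt `ftol` 10⁻¹⁵ for the
Hill fit (so zero-noise recovery reaches 4 significant figures), histogram
probability sums checked to 10⁻¹², antisymmetry of transfer functions to
machine precision. Known limitations: the discrete-LED transfer function
is a staircase rather than the smooth half-circle-source limit, low
frequencies below the response floor are unrecoverable by design, and
EC50s outside the tested concentration range are extrapolations bounded by
the fit box rather than measurements.
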