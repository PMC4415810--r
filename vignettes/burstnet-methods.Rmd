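---
title: "Source-network analysis of burst-suppression EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-network analysis of burst-suppression EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

Burst suppression (BS) is the EEG signature of profound brain inactivation:
pseudo-periodic alternation of high-voltage slow-wave bursts (150–350 µV
peak-to-peak) and near-flat suppression (< 25 µV). burstnet implements a
complete source-level network analysis of such recordings: a five-shell
spherical forward model, multitaper cross-spectral estimation, DICS
(dynamic imaging of coherent sources) beamforming with automated
reference-region and coherent-source selection, spatial-filter source-signal
extraction, and renormalized partial directed coherence (RPDC) with
chi-squared, bootstrap and time-reversal significance testing. Because no
clinical burst-suppression recordings are publicly available, the package
also ships a calibrated synthetic generator that produces annotated
burst-suppression EEG from a directed delta-band source network with known
ground truth; every statistical claim the package makes about itself is
validated against that generator.

# The forward model

The head is five concentric spherical shells (white matter, grey matter,
CSF, skull, scalp). Defaults are infant-scaled: radii 58/60/62/65/70 mm and
conductivities 0.33/0.33/1.79/0.04/0.33 S/m — a 70 mm scalp sphere and a
comparatively conductive neonatal skull. The potential of a current dipole
is the classical Legendre series: for each degree $n$ the radial profile in
shell $j$ is $a_j r^n + b_j r^{-(n+1)}$, matched across interfaces by
continuity of potential and radial current and closed by the insulating
scalp boundary. The per-degree transfer coefficients are solved once per
model (a 9×9 linear system per degree, in a scaled basis that stays
well-conditioned to degree 200); the series over degrees is truncated
adaptively when the last term falls below $10^{-8}$ of the running sum.
In the equal-conductivity limit the solution must reduce to the
homogeneous-sphere closed form (obtained by summing the series analytically
with Legendre generating-function identities); the test suite verifies
agreement to $10^{-6}$ relative, and the acceptance script recomputes this.

Electrodes follow the textbook 10–20 arc construction on the sphere: nasion,
inion and the preauricular points on the equator, Cz at the vertex, the
midline and central chains at 36° steps, the circumferential ring at 72°
inclination, and F3/F4, P3/P4 as great-circle midpoints. Potentials are
average-referenced; sources live on a cubic grid (10 mm default) clipped to
the innermost shell.

# Spectral estimation

Spectra are estimated on one-second epochs with discrete prolate spheroidal
(Slepian) tapers, computed from the standard symmetric tridiagonal
eigenproblem. Defaults: time–bandwidth product NW = 2 and K = 3 tapers,
giving ±2 Hz smoothing at 1 Hz resolution — appropriate for a 1–4 Hz band of
interest. Epochs are tiled so that none straddles a concatenation join
(phase segments are cut and concatenated, and joins would otherwise inject
spurious broadband coherence). The cross-spectral density is the mean outer
product of tapered Fourier coefficients over epochs and tapers, one-sided
and density-normalized (Parseval is verified to 1% in the tests). The
beamformer consumes the unweighted mean of the CSD over the integer bins
1–4 Hz.

# DICS beamforming

For a grid point with (radially oriented) leadfield $l$, the spatial filter
is the minimum-variance unit-gain solution
$a = C_\mathrm{reg}^{-1} l / (l' C_\mathrm{reg}^{-1} l)$ with
$C_\mathrm{reg} = C + \lambda\,\mathrm{tr}(C)/N\,I$. Two per-voxel scalars
are kept:

* **power** $P = \mathrm{Re}(a' C a)$ — the raw band power, used to
  normalize coherence and to report absolute source power;
* **NAI** $P / \lVert a\rVert^2$ — the unit-noise-gain (neural activity
  index) power used for localization and reference selection. Raw
  minimum-variance power grows without bound at poorly covered deep voxels
  (noise amplification), so the raw maximum is uninformative; the NAI is
  the standard correction.

The package defaults to the *radial scalar* beamformer: on a spherical
conductor with mostly radially oriented generators, radial topographies
separate far better at 19 electrodes than free-orientation subspaces (the
thalamus and brainstem 3-column subspaces are 0.99 correlated; their radial
columns only 0.86). A free-orientation engine (orientation from the
generalized power-versus-weight eigenproblem) is available via
`orientation = "free"`.

Two regularization levels are used deliberately. Reference selection runs
at λ = 0.5: a network *hub* — a source coherent with many others — is
partially cancelled by strongly adaptive filters (the minimum-variance
criterion exploits correlated sources to cancel the constrained one), and
heavy regularization restores it. Coherence mapping runs at λ = 0.05,
where the filters are sharp enough to give distinct peaks. Both are
configurable (`lambda_ref`, `lambda`).

Coherence between the reference and a grid point is the scalar
$|a_\mathrm{ref}' C a_r|^2 / (P_\mathrm{ref} P_r)$, exactly bounded by 1 by
Cauchy–Schwarz. Candidate sources are the *local maxima* of the NAI map
(distinct activity peaks): greedy maxima of the coherence map land on the
reference's point-spread shoulders, while NAI peaks sit within about one
grid spacing of true generators in simulation. Candidates are screened by
the surrogate threshold (below), accepted in decreasing coherence order,
and separated by 20 mm exclusion spheres, up to 8 sources.

Source signals are extracted with the real-valued unit-gain filter along
the stored orientation, sign-canonicalized so the first non-negligible
filter coefficient is positive, then decimated to 32 Hz (zero-phase FIR
anti-aliasing) and band-passed 1–4 Hz for connectivity analysis.

# Surrogate significance of coherent sources

The null asks: how large can the reference-to-voxel coupling statistic be
when the temporal alignment between the reference signal and the rest of
the data is destroyed, but every spectrum is preserved? Each of the
(default 100) permutations shuffles the order of the one-second epochs of
the *extracted reference signal* relative to all grid signals and
recomputes the band statistic through the observed (fixed) filters —
cheap, because the per-epoch tapered Fourier coefficients are cached. The
family-wise threshold is the 99th percentile (linear interpolation between
order statistics, a stated convention since 100 permutations make the
percentile otherwise ambiguous) of the null maximum outside the
reference's exclusion sphere.

The statistic under test is the **imaginary part of coherency**, not the
full magnitude-squared coherence. Beamformer outputs share sensors, so
their plain coherence contains an instantaneous volume-conduction overlap
that no misalignment null can reproduce: with full coherence the observed
maximum exceeds any epoch-shuffle threshold even on pure white noise
(every variant — per-channel or reference-signal shuffling, fixed or
refit filters — was implemented and measured before settling on this
design). The imaginary part is zero in expectation under instantaneous
mixing, making the observed statistic and its shuffled null comparable,
and the physiological couplings of interest are lagged (31–62 ms), so
genuine coupling retains a substantial imaginary component. The full
coherence value is still computed and reported for every source — it is
the descriptive quantity — while significance is decided on the
overlap-immune statistic. Type-I behaviour is checked directly: on
white-noise recordings the observed maximum exceeds the threshold in at
most 2 of 50 runs. One consequence is that exactly phase-symmetric
bidirectional coupling (the suppression-phase model) has a zero-phase
cross-spectrum and is invisible to the screen, so suppression phases
typically return the reference alone.

# RPDC, bootstrap and time reversal

Extracted source signals are modeled with a least-squares MVAR fit; the
order minimizes the Schwarz criterion (capped at 10 by default for the
decimated 60 s series). The renormalized partial directed coherence for an
ordered pair $(i \leftarrow j)$ at frequency $f$ is
$\lambda_{ij}(f) = Z' V^{-1} Z$, with $Z$ the real and imaginary parts of
the off-diagonal entry of $\bar A(f) = I - \sum_k A_k e^{-2\pi i f k/f_s}$
and $V$ its estimator covariance (innovation variance times the
regressor-covariance inverse block, rotated by the lag cosine/sine terms
and scaled by the sample size). Under the null of no influence,
$\lambda \sim \chi^2(2)$ pointwise; the Monte-Carlo calibration test
verifies the pointwise exceedance rate of the α = 0.01 threshold lies in
[0.002, 0.03] — this is the guard against mis-scaling the renormalization.

Bootstrap significance resamples one-second blocks independently per
channel (destroying cross-channel lag structure while preserving
autocorrelation), refits at the observed order, and takes the 99th
percentile of band-mean λ per ordered pair; the same resamples provide the
null of the asymmetry Δ = λ(i←j) − λ(j←i) for the time-reversal technique
(TRT). An edge is finally accepted only if (1) band-mean λ exceeds the
χ²(2) threshold, (2) it exceeds the bootstrap threshold, and (3) TRT
confirms a strong asymmetry: Δ > 0, |Δ| above its bootstrap null, and the
sign of Δ flips when the signals are reversed in time. True lagged
causality flips under reversal; zero-lag (volume-conduction-like) mixtures
do not, and the discrimination rate on constructed cases is ≥ 95%.

# The synthetic generator

The generator defines the study conditions: thirteen-subject cohorts of
annotated burst-suppression EEG at 512 Hz on the 19-channel montage. Ten
dipolar nodes sit on the infant sphere: bilateral precuneus, somatosensory,
prefrontal and occipital cortex (placed along their anatomical directions
at 50 mm radius) plus midline thalamus and mid-brain tegmentum. Burst
dynamics follow a directed chain — brainstem → thalamus → precuneus →
{somatosensory, prefrontal}, somatosensory → prefrontal, plus a diffuse
ascending brainstem → precuneus projection — as a two-lag VAR whose lags
live at 32 Hz (31–62 ms delays), embedded at 512 Hz as a sparse-lag
recursion driven by innovations band-passed to 1–4 Hz. Suppression is
cortical only (precuneus, occipital, somatosensory, prefrontal) with
symmetric bidirectional coupling; both deep nodes are silent and all
coupling into or out of them is zero.

Coupling coefficients were calibrated against the analytic band-averaged
coherence of the VAR so that delta-band source coherencies sit in the
physiological range (≈ 0.3–0.5 to the reference's coupled partners, ≈ 0.1
for homologous pairs). This matters more than it looks: near-DC VAR
resonances cascade, so coefficients that "look small" (0.3–0.5) drive
coherencies of 0.8–0.9, under which coherent leakage sums constructively
into phantom deep blobs and the whole map saturates.

Amplitudes are specified as per-node RMS moments relative to precuneus,
with deep nodes carrying larger moments (depth compensation) and bilateral
pairs amplitude-asymmetric (dominant side ≈ 4×): with 19 channels, a pair
of independent mirrored sources 30–70 mm apart is actively cancelled by
minimum-variance filters and its coherence with the reference collapses,
whereas an effectively unilateral source is recovered cleanly. The paper's
own per-patient results report unilateral findings for some regions, so
this is within the reported phenomenology. The bilateral precuneus is
modeled as two essentially colocated midline-adjacent dipoles — one
topography for the array, which is also what "bilateral precuneus" means at
19-channel resolution.

Scalp calibration is iterative and per-recording: the burst scale is set so
the maximum burst peak-to-peak is ~250 µV (inside the 150–350 µV clinical
band), and the suppression scale is solved so the burst/suppression
delta-band power ratio (the relative SNR) hits the target, 37.4 dB by
default, with per-subject targets drawn from 36.2–38.7 dB in cohorts —
inside the clinically reported 35.85–39.09 dB range. Bursts carry
delta-band spatially-incoherent background activity at 5% of burst band
power (suppression: 15%), plus 1 µV white sensor noise; suppression
peak-to-peak stays < 25 µV. Cohort jitter displaces node locations by up to
5 mm (redrawn to stay inside the innermost shell) and scales amplitudes
log-uniformly by 0.8–1.25.

What the generator does *not* emulate: ECG/movement artifacts, non-delta
background rhythms, electrode impedance drift, inter-subject montage
variation, and the neurometabolic mechanism of burst alternation. Passing
tests therefore demonstrate the pipeline's behaviour under an idealized but
physiologically scaled signal model, not robustness to clinical artifact.

# Phase handling and units

Phases are labeled by sliding-window peak-to-peak amplitude (0.5 s windows;
burst if any channel reaches 30 µV, suppression if all stay below 15 µV —
window-level thresholds sit below the whole-burst clinical band because a
sub-second window on one channel sees only part of a slow-wave cycle);
agreement with ground-truth annotations exceeds 95% of samples. Segments
are concatenated earliest-first to exactly 60 s per phase (half-open,
0-based sample intervals; sub-second annotated scraps are skipped), and the
join positions are carried along so spectral epochs avoid them. Units
throughout: µV (sensors), mm (space), Hz (frequency), nA·m (dipole
moments), S/m (conductivity).

# Numerical choices and degenerate inputs

Series truncation $10^{-8}$ relative, cap 200 degrees; batched 3×3
inverses/eigenvalues by adjugate and trigonometric cubic (free-orientation
engine); coherence clamped to [0, 1] (the scalar reduction is bounded, so
clamping only absorbs rounding); quantile convention type-7 linear
interpolation everywhere; reference ties broken at the lowest grid index;
flat pooled spectra return the full search band with a warning; MVAR order
0 is a valid selection outcome but RPDC refuses it explicitly; unstable
bootstrap refits are skipped and more than 20% of them is an error; EDF
output is 16-bit with per-channel symmetric physical ranges (round-trip
error bounded by range/65535, verified against an independent Python
reader). All randomness flows from explicit seeds; seeded functions
restore the caller's RNG state.

# Problem sizes used by the shipped tests

The test-suite and acceptance script run at desk scale, stated here as the
package's chosen sizes: 10 mm grids (619 sources) for localization and
recovery, 20 mm grids for null-calibration loops; 50 surrogate permutations
and 100 bootstrap resamples (the `"full"` preset uses 100 and 1000); 20
seeded end-to-end subject analyses for the recovery and directionality
rates; 200 Monte-Carlo replicates for RPDC calibration; 100 constructed
cases for TRT discrimination; a 13-subject cohort for the phase contrast.

# Known limitations

The central honest finding of the package's own validation: with 19
average-referenced electrodes on an infant-scaled spherical head, 60 s of
data and the default generator, the automated pipeline robustly recovers
the precuneus reference (16/20 seeded runs), the thalamic coherent source
(17/20), the thalamus → precuneus directed edge (17/20), and suppression
specificity (no deep false-positive sources and no accepted directed
edges in 20/20 suppression runs). It does **not** reliably resolve the
full five-region network: the brainstem peak merges into the thalamic
blob at this channel count, and the somatosensory source's
reference-coherence is diluted below the surrogate threshold. The
corresponding acceptance checks are therefore expected to fail at their
nominal ≥ 90% / ≥ 80% levels, and the acceptance script reports the
measured rates. Recovering the full topology appears to require more
channels, longer data, or individual (non-spherical) head models — which is
consistent with the method's published applications being at the edge of
what the montage supports.

Other limitations: the spherical model ignores skull inhomogeneity and
anisotropy; radial-only default orientations assume quasi-radial
generators; RPDC on band-limited, beamformer-extracted signals inherits
leakage between sources, which the TRT step only partially absorbs; and
the Friedman contrast treats the two phases as exchangeable conditions
within subjects, which is the paired design but ignores temporal order.
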