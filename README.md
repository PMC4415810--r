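# burstnet

Source-level network analysis of burst-suppression EEG in R.

Burst suppression is the EEG pattern of profound brain inactivation —
pseudo-periodic alternation of high-voltage slow-wave bursts (150–350 µV
peak-to-peak) and near-flat suppression (< 25 µV) — seen in deep coma,
anesthesia and severe infantile encephalopathies. The scientific question
behind this package is *which* brain network generates each phase: whether
deep structures (brainstem, thalamus) drive the cortex during bursts, and
whether that drive disappears during suppression ("cortical
deafferentation"). burstnet is written for EEG methods researchers who want
a self-contained, fully tested implementation of the frequency-domain
source-network pipeline that addresses this question, together with a
ground-truth simulator to probe what a 19-channel montage can and cannot
resolve.

## What it computes

Given a multichannel EEG recording with burst/suppression annotations (or
an amplitude-based labeler standing in for visual review), the pipeline:

1. concatenates 60 s of burst-only and suppression-only data;
2. estimates multitaper cross-spectra on 1-s epochs (DPSS tapers, NW = 2,
   K = 3) and averages the CSD over the 1–4 Hz delta band;
3. solves the forward problem analytically on a five-shell spherical head
   (Legendre series, adaptively truncated; verified against the
   homogeneous-sphere closed form to 1e-6);
4. beamforms with DICS: for each grid point `r` the minimum-variance
   unit-gain filter `a(r) = C⁻¹reg l(r) / (l'(r) C⁻¹reg l(r))`; the
   reference region is the maximum of the unit-noise-gain power
   (neural activity index), and coherent sources are significant local
   power maxima ranked by their coherence with the reference
   `|a'ref C a(r)|² / (P_ref P_r)`;
5. tests source coherence against a Monte-Carlo surrogate null (epoch
   shuffling of the reference signal; significance on the
   volume-conduction-immune imaginary part of coherency);
6. extracts source time series with the spatial filters, decimates to
   32 Hz, and fits an MVAR model; directed influence is the renormalized
   partial directed coherence `λ(f) = Z' V⁻¹ Z ~ χ²(2)` under the null,
   screened additionally by a per-channel block bootstrap and the
   time-reversal technique (true lagged causality flips its asymmetry when
   the data are reversed; volume-conducted mixtures do not);
7. contrasts burst against suppression across subjects (source power and
   interaction strength, Friedman test).

A calibrated synthetic generator produces annotated burst-suppression
recordings from a directed delta-band source network (brainstem → thalamus
→ precuneus → somatosensory/prefrontal during bursts; cortical-only
symmetric coupling during suppression) projected through the same forward
model, with scalp amplitudes and burst/suppression SNR matched to the
clinical definition. It is the ground truth for every statistical claim in
the test suite.

## Worked example

```r
library(burstnet)

# simulate one subject (ground truth attached), then analyze it
sim <- assemble_burst_suppression(seed = 5)
print(sim$ground_truth)
#> Ground truth: burst-active nodes: precuneus_L, precuneus_R, somatosensory_L,
#>   somatosensory_R, prefrontal_L, prefrontal_R, thalamus, brainstem
#>   suppression-active: precuneus_L, precuneus_R, somatosensory_L,
#>   somatosensory_R, prefrontal_L, prefrontal_R, occipital_L, occipital_R
#>   directed burst edges: brainstem -> thalamus; thalamus -> precuneus;
#>   precuneus -> somatosensory; precuneus -> prefrontal; somatosensory -> prefrontal
#>   measured: burst pp 253 uV, suppression pp 5.2 uV, SNR 37.33 dB

res <- run_subject(sim$recording, bs_config("desk"))
print(res)
#> burstnet subject 1
#>   relative burst/suppression SNR: 36.29 dB
#>   burst: 3 sources (threshold 0.044), band peak 1-4 Hz
#>     accepted directed edges: 1
#>   suppression: 2 sources (threshold 0.026), band peak 1-4 Hz
#>     accepted directed edges: 0

# which regions were found, and which directed edges were accepted?
m <- match_sources_to_regions(res$phases$burst$sources, sim$ground_truth)
m[, c("role", "region", "coherence")]
#>        role    region coherence
#>   reference precuneus      1.00
#>    coherent  thalamus      0.46
#>    coherent unmatched      0.24
edges_to_regions(res$phases$burst$rpdc$edges, m)
#>   from_region to_region
#> 1    thalamus precuneus
```

The printed numbers mean: the burst phase carries a strong delta-band
source network (reference at the precuneus, a thalamic source coherent with
it at 0.46, and an accepted thalamus → precuneus directed edge — the upward
flow), while the suppression phase retains only cortical activity with
no directed coupling, at a burst/suppression band-power ratio of
~36 dB. A cohort run aggregates this over 13 simulated subjects:

```r
cohort <- run_cohort(n_subjects = 13, config = bs_config("desk"))
print(cohort)
#> burstnet cohort: 13 subjects analyzed
#>   relative SNR range: 34.99-38.39 dB
#> Phase contrast over 13 subjects
#>   source power:    burst > suppression (Friedman Q = 13.00, p = 0.00031)
#>   mean coherence:  burst > suppression (Friedman Q = 9.31, p = 0.0023)
```

Recordings round-trip through EDF with TSV annotation sidecars
(`write_recording()` / `read_recording()`).

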