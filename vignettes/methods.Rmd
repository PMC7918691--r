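---
title: "Models and methods behind axotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind axotrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the models it implements,
the parameters that matter, and the design choices made where more than
one defensible option existed. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The two-state motility model

Axonal mitochondria and lysosomes imaged over two minutes behave, to a
good approximation, as a mixture of two discrete trafficking states: a
*mobile* state dominated by processive runs and an *immobile* state
dominated by pausing and non-processive jitter. `simulate_tracks()`
realizes each state as a run-and-pause walk along the channel axis. Per
time step `dt` (default 0.3 s, one frame at 3.3 fps):

- with probability `pause_fraction` the organelle pauses;
- otherwise it advances `v * dt` in its current direction, with `v` drawn
  from a normal law (`run_speed_mean`, `run_speed_sd`) truncated at zero;
- the direction reverses with probability `reversal_prob_per_step`;
- isotropic Gaussian jitter (`jitter_sd`, per axis, per step) is added.

Direction persistence with rare reversals makes the walk a telegraph
process: over 400 steps the net displacement grows like
`v_eff * dt * sqrt(N * (1 - p) / p)` rather than ballistically, which is
what lets a state combine a ~0.7 μm/s mean speed with only ~9 μm of net
displacement.

The observable contract of each preset is the pair of state-level grand
means (per-track mean speed; per-track net displacement) published for
the four (state × organelle) combinations: mobile 0.7/1.1 μm/s and
9/14 μm (mito/lyso), immobile 0.4/0.4 μm/s and 5/5 μm. The remaining
kinetic parameters are not separately identifiable from those summary
statistics, so they were fixed once by a coarse grid search against the
four targets and frozen in `inst/extdata/motility_presets.yaml`; the
calibration is verified by the test suite at n = 1,000 tracks (±15% on
speed, ±20% on displacement, the tolerances matching the spread of the
published box plots).

**Track lifetimes.** Real trackers lose organelles to focus drift,
crossing and bleaching, so observed track durations vary widely. The
generator emulates this with a per-track observation window drawn
uniformly between 50% and 100% of the movie, placed uniformly in time.
Besides realism, this matters structurally: the `duration` master
parameter needs a non-degenerate control distribution for its Z-score to
be defined.

**Diameters.** Simulated tracks carry a per-track apparent diameter
drawn from a log-normal law (median 0.8 μm for mitochondria, 0.6 μm for
lysosomes, σ~log~ = 0.2) so that signatures built purely from simulated
tracks have all 44 components defined. When tracks come from the
detection path instead, the diameter is the LoG scale estimate
`2σ√2 × pixel size`.

## Decline schedules

A `motility_schedule` maps genotype → (compartment, day) → mobile
fraction. Before a compartment's onset day every track is mobile. From
the onset day (the onset is closed on the left: "already at D21" means
declined *at* D21) the mobile fraction drops to `mobile_fraction_onset`
(default 0.35) and then ramps linearly down to `mobile_fraction_after`
(default 0.10) at the last sampled day, D80. Each track's state is an
independent Bernoulli draw from that fraction.

Two points in this design were genuinely open:

- *Progression versus step.* A single post-onset level would reproduce
  the onsets but would plateau the phenotypic-strength curves, whereas
  the observed phenotype deteriorates with ageing — strength keeps
  rising after onset. The linear ramp is the simplest schedule shape
  that yields both a sharp onset (Z far below −5 at the onset day) and
  a strictly increasing post-onset strength curve.
- *Residual mobility.* How much trafficking survives in a declined
  compartment is not quantified state-by-state in the source data; 0.10
  at D80 is a choice, exposed in the schedule table rather than buried.
  Likewise the milder TDP43-like phenotype is modelled as a larger
  mobile fraction (0.65 → 0.50) rather than as slower run speeds; with
  only state-level summary statistics available the two are not
  distinguishable, and the mixture keeps the two-state structure exact.

The canonical onset table (Ctrl distal D40; C9 distal+proximal D40;
C9-GC distal D40 only; C9-KO both D21; WT-KO distal D21, proximal D50;
FUS-like distal D14; TDP43-like distal D14, milder) is hard-coded in
`make_schedule()` and is what `run_study()` must re-detect from the
simulated data alone.

## Rendering and tracking

`render_movie()` draws each organelle as an isotropic Gaussian of width
`psf_sigma_px` (default 1.3 px ≈ 300 nm at 229.55 nm/px, a plausible
near-diffraction PSF) with peak amplitude `snr × sqrt(background)` on a
constant background (default 100 counts). Noise is additive normal with
variance matched to the expected signal — a Poisson-like model that
avoids speculating about camera gain; at the SNRs used (≥ 5) the normal
approximation is indistinguishable from true shot noise.

`detect_spots()` is single-scale Laplacian-of-Gaussian detection:
convolution with a zero-sum, scale-normalized LoG kernel (window
±4σ), 8-neighbour local maxima above a quality threshold (default
`5 × mad(response)`, a robust noise floor), then sub-pixel refinement by
intensity-weighted centroid in a `(2⌈2σ⌉+1)²` window of the
background-subtracted frame. Two spots within about one σ merge into a
single detection; this is documented behaviour, not an error.

`link_tracks()` uses greedy nearest-neighbour assignment: candidate
(track end, spot) pairs are accepted in order of increasing distance,
gated at `max_link_dist_um` per bridged frame. The default gate of
2 μm/frame is the maximal plausible inter-frame step (≈ 6 μm/s at
0.3 s/frame); gap closing bridges up to 2 missing frames with a
proportionally enlarged gate. Greedy rather than globally optimal (LAP)
assignment is an explicit approximation: at the organelle densities
simulated here the test suite shows the greedy total link cost within
10% of a brute-force optimal assignment oracle, and end-to-end track
recovery above 90% at SNR 10.

## Signatures, strength, clustering

`zscore()` uses mean and sample SD (divisor n − 1) of the pooled-control
baseline; a median/MAD variant is available behind the same function
(`robust = TRUE`) because the estimator choice is a convention, not a
derivation. The nine per-track parameters are scored on per-track
distributions; the two per-batch parameters on per-batch (movie
surrogate) distributions — batches exist precisely so that control
variability of those derived parameters is estimable. Whether to pool
per-track or per-movie values for the nine master parameters was an open
choice; per-track pooling was chosen as it matches how the raw result
files are assembled.

The baseline is always the pooled control condition at D21 proximal, per
channel, so every signature is interpretable as deviation from healthy
young proximal axons. Signature order is fixed (mito-distal,
mito-proximal, lyso-distal, lyso-proximal × 11 parameters = 44) and
serialized labels always accompany values.

Significance uses the strict convention |Z| > 5. Onset detection in
`run_study()` instead uses Z ≤ −5 (closed), matching the wording that a
decline is present "already" at the onset day; both conventions are
implemented exactly where each applies.

Hierarchical clustering defaults to Ward linkage on Euclidean distances
(`hclust(method = "ward.D2")`), with linkage and metric exposed because
the original tool's settings are unrecorded. Merge heights are verified
against an independent Lance-Williams recursion in the tests; *topology*
(cluster membership), not heights, is what the acceptance properties
assert, since absolute dendrogram scales are tool-specific.

## Foci quantification

`triangle_threshold()` bins intensities into 256 uniform bins over the
observed range (bit-exact thresholds depend on binning, so the binning
is declared), orients the triangle toward the longer tail, and returns
the bin-centre intensity at maximal perpendicular distance from the
peak-to-tail line. With integer histograms the threshold shifts exactly
with a constant intensity offset.

`count_foci()` binarizes above the threshold, labels 8-connected
components, discards components under `min_size_px` (default 4 px;
particle-analysis settings are conventions, so they are config, not
constants), and assigns each focus to the nucleus containing its
centroid. Perinuclear foci — centroids outside every nucleus — are
assigned to the nearest nucleus within 5 μm, else left unassigned,
because perinuclear aggregates are counted per neuron without a stated
assignment rule anywhere; 5 μm is roughly one nucleus radius.

The GA/DSB co-occurrence rule is read literally: category A requires at
least one aggregate focus and *zero* DSB foci; category B at least one
aggregate and ≥ 3 DSB foci; GA-positive cells with 1–2 DSB foci fall in
the gap and are unclassified. The alternative reading ("without" = fewer
than 3) is available as `dsb_free_max`.

The foci-field generator places foci inside a nucleus with a minimum
mutual separation of six focus radii. This is a deliberate generator
constraint: two Gaussian blobs closer than ~4σ merge into one
thresholded component, so without a separation floor the ground truth
would be systematically uncountable by *any* connected-component
counter. Crowded nuclei that cannot fit another focus after bounded
retries record exactly what was rendered.

## Statistics

`one_way_anova_bonferroni()` delegates the decomposition to
`stats::aov()` and the pooled-variance pairwise t-tests to
`stats::pairwise.t.test()`, with Bonferroni over *all* k(k−1)/2 pairs
(stated explicitly because some tools adjust only versus control); the
test suite re-derives both from textbook formulas. `deg_overlap()` is
exact set arithmetic with unrounded percentages retained alongside the
rounded ones used for reporting.

## Problem sizes and determinism

Every stochastic operation takes an explicit seed and is bit-reproducible
for fixed arguments. The sizes used by the shipped tests and acceptance
script are the package's chosen study scale: 1,000 tracks per preset for
calibration checks; the full in-silico study at 7 genotypes × 7 days ×
2 compartments × 2 channels with 300 tracks in 10 batches per condition;
imaging tests on 128 px fields with 60 frames; foci tests on fields of
up to 512 px with 30–200 nuclei. These run in a few minutes on one CPU
while leaving the statistical margins (pre-onset |Z| noise ≲ 1 versus
the ±5 significance band) comfortable.

## What the generator does and does not emulate

It emulates: two-state kinetics calibrated to the published state
statistics, genotype- and compartment-specific decline schedules,
detection-limited track lifetimes, PSF-blurred noisy movies, and
IF fields with Poisson foci counts. It does not emulate: axon
morphology or bundling (tracks are independent), organelle-organelle
interactions, splitting/merging events, drift, 3-D effects, or the
biology linking genotype to phenotype (schedules are imposed, not
emergent). Passing tests therefore demonstrate that the *analysis
pipeline* correctly recovers known structure from data of realistic
geometry and noise — not that the simulator is a faithful biophysical
model of axonal transport.
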