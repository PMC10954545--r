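---
title: "Methods: edge-polarity quantification, interactome ranking and root morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: edge-polarity quantification, interactome ranking and root morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgesense)
```

`edgesense` implements the quantitative workflow used to study
edge-polarized membrane proteins in plant lateral roots: ranking candidate
interactors of an edge-directed Rab GTPase from comparative
co-immunoprecipitation proteomics, quantifying confocal images (background
removal, colocalization, distance-from-edge intensity profiles, laser-ablation
responses), and measuring root swelling from traced outlines. Every stage has
a seeded synthetic-data generator with known ground truth, so the whole
pipeline is testable without the original raw data. This vignette explains
each method, its assumptions, the tunable parameters, and the design choices
made where the underlying procedures left genuine freedom.

## 1. Comparative interactome ranking

### Model and procedure

The input is a label-free quantification (LFQ) matrix of protein intensities
for four sample groups: the bait pull-down (a YFP-tagged Rab GTPase), two
related Rab GTPases used as comparators to subtract generic Rab interactors,
and an untagged negative control, each with (typically three) biological
replicates. Zero means "not detected"; LFQ non-detection is left-censoring,
not evidence of absence.

The pipeline is:

1. **Bait-completeness filter** (`filter_complete_in_bait()`): keep only
   proteins detected in *every* bait replicate. Sporadically detected
   proteins carry no reliable quantitative signal.
2. **Half-minimum imputation** (`impute_half_minimum()`): remaining zeros
   are replaced by half the smallest nonzero intensity of the whole matrix —
   a single global pseudo-detection floor. The alternative readings
   (per-protein or per-sample minima) were rejected because a global floor
   is the common convention and the phrase "across all detected proteins"
   describes the whole matrix.
3. **Moderated volcano test** (`volcano_enrich()`): for each protein,

   $$d_i = \frac{\bar{x}_{\text{bait}} - \bar{x}_{\text{comp}}}
   {s_{\text{pooled SE}} + s_0}, \qquad s_0 = 2,$$

   computed on $\log_2$ intensities. The fudge constant $s_0$ (the SAM
   convention) damps the significance of low-variance, low-effect proteins;
   $s_0 = 2$ is only meaningful on a log scale, which is why log transform
   is the default (`log2_transform = FALSE` is available for data already on
   a log-like scale). Significance is assessed by permutation: group labels
   are relabelled (exhaustively when the number of distinct relabellings is
   at most `n_perm`, which for 3 vs 3 replicates means all 20), the null
   statistics are pooled across proteins (the usual exchangeability
   assumption of SAM-type tests), per-protein permutation p-values are
   converted to q-values by Benjamini–Hochberg, and a protein is *enriched*
   when $q \le$ `fdr` (default 0.2) **and** its effect is positive. The
   original analysis used a proprietary implementation whose internals are
   not published; this permutation scheme is the standard reconstruction and
   may differ in detail.
4. **Intersection** (`intersect_significant()`): candidates must be enriched
   against *both* comparators.
5. **Super rank** (`super_rank()`): candidates are ranked by
   (1) bait abundance (descending), (2) enrichment over comparator A
   (descending), (3) enrichment over comparator B (descending) and
   (4) negative-control abundance (ascending). *Abundance* is the mean
   intensity over a group's replicates (robust to unequal replicate counts;
   equivalent to the sum for ranking when counts are equal). *Enrichment* is
   the ratio of bait to comparator mean intensity on the raw scale; because
   ranks are invariant under strictly monotone transforms, a log-ratio
   would give identical ranks. Ties get average ranks, which preserves the
   column-sum invariant $\sum r = n(n+1)/2$. The super rank is the
   ascending rank of the sum of the four ranks; ties in the sum are broken
   by bait-abundance rank, then protein id, so output is deterministic.

### Synthetic matrices

`make_quant_matrix()` draws baseline $\log_2$ abundances from
$\mathcal{N}(20, 2^2)$ with replicate noise of 0.5 (≈ 40% CV, typical of
affinity-purification LFQ), multiplies a planted interactor set by `fold`
(default 8) in the bait only, and censors values with a logistic
intensity-dependent dropout reaching at most 0.5 for vanishing intensities,
with half-maximal dropout 2.5 abundance-s.d. below the median. The curve
concentrates non-detection in the low-abundance tail, so that an 8-fold
enriched protein is rarely lost from the bait channel itself; with these
conditions the full pipeline recovers essentially all planted interactors
(see `tests/testthat/test-acceptance.R` and `scripts/acceptance.R`).

What these simulations do **not** model: shared-peptide effects, batch
drift, correlated contaminant blocks (ribosomes, chaperones), or
compositional distortion of LFQ between pull-downs. Passing recovery tests
shows the pipeline's statistics behave as designed under left-censored
log-normal data, not that real co-IP data meet those assumptions.

## 2. Image quantification

All physical quantities are in micrometres; a voxel's physical position is
its 0-based index times the voxel size (`image_stack()`).

### Hysteresis background removal

`derive_thresholds()` maps a sample of (typically ten) compartment
intensities to a high threshold (their mean) and a low threshold (their
minimum minus two sample standard deviations, floored at 0). The phrase
defining these thresholds in the source workflow is ambiguous about which
statistic receives the "− 2 s.d."; we read the mean as the seed ("surely a
compartment") and min − 2 s.d. as the support boundary, and expose
`high_fun` / `low_fun` so either convention can be swapped in.
`hysteresis_filter()` then keeps exactly the voxels at or above the low
threshold that are connected to a voxel at or above the high threshold
(8-connectivity in 2D, 26 in 3D), implemented as geodesic dilation of the
high seeds inside the low mask and verified against an independent
flood-fill oracle.

### Manders colocalization per region

`subdivide_regions()` tiles the imaging plane into non-overlapping
25 µm × 25 µm regions (full depth; border remainders dropped), the scale at
which tissue-level differences in localization were assessed.
`manders()` computes $M_1 = \sum_{A \cap B} A / \sum_A A$ (and symmetrically
$M_2$) over hysteresis foreground masks; a zero masked total is an error,
never silently 0. `colocalize_regions()` chains thresholds → masks → tiles →
coefficients.

### Edge-distance intensity profiles

`edge_profile()` walks a manually traced wall path (a `wall_trace`, anchored
at the cell edge — the junction where walls meet) at pixel pitch, averaging
`width_px = 7` pixels perpendicular to the local trace direction at unit
pixel spacing with nearest-pixel lookup (no sub-pixel interpolation, as in a
fixed-width plot profile). Distance is **arc length** from the anchor — the
profile was generated along the traced outline, so the path metric, not the
Euclidean distance to the anchor, is the faithful reading. Samples fall into
half-open bins $[k w, (k+1) w)$ with $w = 0.5$ µm; boundary samples go to
the right bin deterministically.

`aggregate_profiles()` pools per-trace bin means per wall class, reports
mean ± s.d. per bin, and computes the **significance distance**: one-way
ANOVA across bins followed by Tukey HSD of every bin against bin 0; the
significance distance is the left edge of the nearest bin significantly
*lower* than the edge bin at `alpha = 0.05`, or none. Because Tukey HSD
controls the family-wise error, flat profiles yield "none" in ≥ 95% of
cases by construction. Bins are reported contiguously from the edge;
trailing bins covered by fewer than two traces are dropped.

One geometric property deserves emphasis: at the anchor the perpendicular
7-pixel window runs *along* the crossing wall, so even a protein with no
edge enrichment shows an elevated first bin wherever two labelled walls
meet. This is a real feature of junction-anchored fixed-width profiles, not
a bug; it is why the null condition in our calibration is a spatially
uniform phantom rather than a wall lattice without edge enrichment.

### Ablation ratios

`ablation_ratio()` matches pre- and post-ablation profiles per wall,
computes the per-bin ratio of mean intensities (bins with zero pre-ablation
mean are excluded with a warning), and aggregates mean ± s.d. across walls.
`compare_ablation_channels()` contrasts two channels per bin with the
one-way ANOVA + Tukey contract. Note that the ratio estimates the
depletion of *total* signal; it equals the edge-class depletion only where
edge signal dominates the profile, and a ratio of low photon counts is
upward-biased (≈ $1 + 1/\lambda$ for Poisson counts), which matters in the
trailing, partially covered bin of a trace — recovery fixtures therefore
profile complete bins only.

## 3. Confocal phantoms

`make_phantom()` renders a lattice of rectangular cells (2D mid-plane or 3D)
with three signal classes on known geometry: a uniform **face** signal on a
wall band of 0.7 µm (two adjacent plasma membranes plus the wall — of the
order of the profile width once blurred), an **edge** signal decaying as
$\exp(-d/\lambda)$ with distance from the nearest junction, and Gaussian
**punctae**, over a uniform cytoplasmic background. The ideal image is
convolved with a Gaussian PSF (FFT-based, circular boundary, kernel
normalized — total intensity is conserved to machine precision, which the
tests assert at 10⁻⁶ relative) and corrupted with Poisson shot noise then
Gaussian read noise, the standard confocal approximation. Generation is a
pure function of the spec and its seed.

Each edge carries its own log-normal brightness multiplier
(`edge_sdlog = 0.7`, CV ≈ 80%). This inter-edge biological variability —
not shot noise — dominates the variance of edge profiles, matching the wide
±1 s.d. ribbons of measured profiles, and it is what gives the
significance-distance assay a finite, realistic sensitivity: with
near-noiseless profiles *any* decay length collapses to a significance
distance of one bin, because the geometric first-bin elevation alone is
detectable. The default calibration (12 traces of 3 µm per replicate) was
chosen, once, so that planted decay lengths λ ∈ {0.5, 1, 2} µm map to
increasing mean significance distances over 20-replicate batches; flat
(uniform) phantoms stay at "none". Phantoms do not model optical
aberrations, depth-dependent attenuation, or cell-shape irregularity.

`make_ablation_pair()` renders one geometry twice, scaling the edge class by
$1 - \text{depletion}(d_\text{wound})$ and zeroing a circular wound in the
post image; geometry, punctae and edge multipliers are shared (so the
multiplier cancels in the ratio) while noise is independent. Tissue
deformation is deliberately not simulated.

## 4. Root morphometry

`max_diameter()` implements the outline-based diameter: for every point on
side 1, the Euclidean distance to its nearest neighbour on side 2; points
within 100 µm of the tip — measured as **arc length along side 1** from the
point nearest the tip landmark, a reading robust to curved roots (the
original convention is not recorded; a Euclidean-radius reading would
differ only for strongly curved tips) — are excluded, and the maximum
diameter is the mean of the 10 largest retained distances. Roots with fewer
retained points use all of them with a warning. The one-directional
side 1 → side 2 convention follows the described computation; a symmetric
variant is available (`symmetric = TRUE`). The implementation is exact
(verified against an all-pairs oracle), rotation/translation invariant and
scale-equivariant.

A caveat the synthetic truth makes explicit: the nearest-neighbour distance
reads slightly *below* the vertical width wherever the outline slope is
steep (shortcut across a bulge flank, a factor ≈ cos(arctan w′)). Root
swelling is broad relative to the width, so `root_spec()` defaults to a
gentle bulge (σ = 60 µm) where measurement and analytic truth agree within
twice the outline point spacing.

`relative_increase()` is $100(\bar{d}_\text{treated} -
\bar{d}_\text{control})/\bar{d}_\text{control}$; `growth_compare()` wraps
the genotype × treatment two-way ANOVA with Tukey HSD on cell means and an
optional length-matching pre-flight check (Welch test, warning below
p = 0.05 — a warning, not an automatic exclusion, because length matching
is a design property of the experiment, not of single roots). The
simulated swelling experiment (n = 35 roots per genotype × treatment,
between-root s.d. 12 µm on an 80 µm base, planted increases of 50% and 77%)
recovers the planted percentages within a few points and detects the
genotype × treatment interaction essentially always at these effect sizes.

## 5. Shared statistics

`anova_oneway()` / `anova_twoway_tukey()` delegate to `stats::aov()` and
`stats::TukeyHSD()` — the same functions the original analysis used. The
two-way table uses Type II sums of squares by default (via `car::Anova()`):
group sizes in the swelling experiments are mildly unequal, Type II is
invariant to that imbalance for main effects, and it coincides with Type I
for balanced designs; Types I/III remain selectable. Exactly constant data
return F = 0, p = 1 rather than an indeterminate ratio; zero within-group
variance with a real effect reports a p-value at machine minimum rather
than NaN. Empty cells and single-observation-per-cell two-way designs are
errors (the interaction is not estimable), not silent refits.

## 6. Numerical and interface conventions

* Distances are µm end to end; voxel sizes are converted at ingest.
* Pixel indices are 0-based in physical coordinates (position = index ×
  voxel size); R arrays remain 1-based internally.
* s.d. is always the sample (n−1) standard deviation.
* CSV outputs are UTF-8, comma-separated, '.' decimal, headered, doubles at
  9 significant digits; every artifact written by the command-line layer is
  accompanied by a `.provenance.json` (inputs, parameters, seed, package
  version).
* All stochastic stages take an explicit seed; generators restore the
  caller's RNG state (`with_seed()`).
* Problem sizes in the test-suite and in `scripts/acceptance.R` (500-protein
  matrices, 20 seeds; ~280-pixel-square phantoms, 20 replicates per decay
  length; 35 roots per group, 10 runs) are the package's chosen desk-scale
  study conditions: large enough for the recovery properties to be sharp,
  small enough to re-run routinely.

## Known limitations

* The volcano reconstruction (pooled permutation null + BH) is a standard
  SAM-type scheme, but the original proprietary implementation may compute
  its FDR differently; candidate *sets* at FDR 0.2 can differ at the margin.
* Whether the original ranking's "relative enrichment" was a fold change or
  a test statistic is unrecorded; the ratio-of-means default is monotone in
  fold change, so ranks are unaffected by that subset of readings.
* Profiles assume traces stay inside the image and walls are locally
  straight at the 7-pixel scale; strongly curved walls bias the
  perpendicular average.
* The phantom's polyhedral geometry is idealized; significance-distance
  calibration transfers to real data only insofar as inter-edge variability
  and wall-band width are comparable.
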