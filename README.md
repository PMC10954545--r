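# edgesense

Quantitative tools for studying **edge-polarized membrane proteins in plant
lateral roots** — proteins that accumulate at cell edges, the 1D junctions
where two cell faces meet, delivered there by Rab-GTPase-dependent
trafficking. The package is aimed at plant cell biologists who have (a) a
comparative co-immunoprecipitation LFQ matrix and want a ranked interactor
list, (b) confocal stacks with manual wall traces and want edge-polarity and
colocalization numbers, or (c) traced root outlines and want swelling
statistics.

Three analysis pipelines, plus ground-truth generators for all of them:

* **Interactome ranking.** Filter a proteins × samples LFQ matrix to
  proteins detected in every bait replicate, impute non-detections with the
  global half-minimum, test bait enrichment against two comparator
  pull-downs with a SAM-type moderated statistic
  `d = (x̄_bait − x̄_comp) / (SE_pooled + s0)` on log2 intensities
  (`s0 = 2`), call significance by group-relabelling permutation FDR
  (`q ≤ 0.2`, positive effect), intersect the two significant sets, and
  assign each candidate a **super rank**: the ascending rank of the sum of
  its ranks by bait abundance (↓), enrichment vs comparator A (↓),
  enrichment vs comparator B (↓) and negative-control abundance (↑).
* **Image quantification.** Hysteresis background removal (high = mean of
  ten sampled compartments, low = min − 2 s.d., connectivity-based
  rescue), Manders colocalization coefficients per non-overlapping
  25 µm × 25 µm region, 7-pixel-wide intensity profiles along wall traces
  binned in 0.5 µm distance-from-edge intervals with a Tukey-based
  **significance distance**, and per-wall post/pre ablation intensity
  ratios.
* **Root morphometry.** Maximum root diameter as the mean of the ten
  largest side-to-side nearest-neighbour distances, excluding the tip-most
  100 µm; percent diameter increase between treatments with a
  genotype × treatment two-way ANOVA + Tukey test.

Synthetic generators (`make_quant_matrix()`, `make_phantom()`,
`make_ablation_pair()`, `make_root_outline()`) produce seeded, fully
reproducible inputs with known truth: log-normal LFQ matrices with planted
interactors and intensity-dependent dropout, polyhedral-cell confocal
phantoms with face/edge/punctae signal, Gaussian PSF and Poisson + read
noise, ablation pairs with a planted depletion profile, and tapering root
outlines with optional swelling.

## Worked example

Simulate a 500-protein co-IP experiment with 25 planted 8-fold interactors
and rank candidates:

```r
library(edgesense)

sim <- make_quant_matrix(matrix_spec(seed = 42))
sim$matrix
#> quant_matrix: 500 proteins x 12 samples
#> groups: bait (n=3), comparatorA (n=3), comparatorB (n=3), negative (n=3)
#> zeros (not detected): 141 (2.4%)

res <- rank_interactome(sim$matrix, seed = 42)
res
#> interactome ranking: 468 bait-complete proteins, 25 candidates
#> top candidates:
#>   protein_id rank_sum super_rank
#> 1      P0179       29          1
#> 2      P0298       30          2
#> 3      P0292       33          3
#> ...

sum(res$candidates %in% sim$interactors)
#> [1] 25   # every planted interactor recovered, no false positives
```

468 proteins survive the bait-completeness filter; 25 are significantly
enriched against both comparators at S0 = 2 / FDR = 0.2, and all 25 are the
planted interactors, ordered by super rank.

Edge-polarity profile on a confocal phantom with a 1 µm edge decay length:

```r
ph  <- make_phantom(phantom_spec(edge_decay_um = 1, seed = 42))
trs <- phantom_wall_traces(ph$spec, length_um = 3, max_traces = 12)
profs <- lapply(trs, function(tr)
  edge_profile(drop(ph$stack$channels$signal), tr, ph$spec$voxel_size_um))
aggregate_profiles(profs)[[1]]   # traces are aggregated per wall class
#> edge profile (longitudinal-anticlinal): 7 bins, n = 6 traces
#> significance distance: 1.0 um
```

The signal becomes significantly lower than at the edge 1 µm out — the
profile is edge-peaked with a decay on the scale planted (λ = 1 µm).

Root diameter with a 30 µm swelling bulge:

```r
simr <- make_root_outline(root_spec(bulge_amplitude_um = 30, seed = 42))
max_diameter(simr$outline)
#> max diameter: 109.41 um (204 distances, 47 tip points excluded)
simr$true_diameter
#> [1] 109.86   # analytic truth from the width function
```

A command-line front end over the same functions lives at
`inst/cli/edgesense.R`
(subcommands `rank-interactome`, `colocalize`, `edge-profile`, `ablation`,
`root-diameter`, `growth-compare`, `simulate`, `stats`); every output CSV is
accompanied by a `.provenance.json` recording inputs, parameters and seed.

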