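# axotrace

High-content phenotypic profiling of axonal organelle trafficking, as an
R package.

## The problem

In compartmentalized motor-neuron cultures, axons grow through 900 μm
microchannels, so mitochondria and lysosomes can be live-imaged at two
standardized readout windows — *proximal* (soma side) and *distal* (axon
exits) — over weeks in culture. Organelle motility in such movies falls
into two essentially discrete trafficking states: a **mobile** state
(net track displacement ≈ 9/14 μm and mean speed ≈ 0.7/1.1 μm/s for
mitochondria/lysosomes over a 2-min movie) and an **immobile** state
(≈ 5/5 μm and ≈ 0.4/0.4 μm/s). ALS-related genotypes differ in *when* and
*where* trafficking collapses from the mobile into the immobile regime:
controls decline only distally late in culture, C9ORF72
repeat-expansion lines decline at both sites simultaneously, knockouts
decline earlier, and gene-corrected lines are rescued proximally.

`axotrace` implements the full analysis chain needed to quantify such
phenotypes — and a calibrated synthetic-data generator that emulates
them, so every stage of the pipeline is testable without any raw movies:

1. **Simulation** (`make_schedule()`, `simulate_tracks()`,
   `render_movie()`, `simulate_foci_field()`) — a two-state run-and-pause
   trajectory model with genotype × compartment × day decline schedules,
   rendered into noisy movies, plus nuclei-with-foci IF fields with known
   ground truth.
2. **Tracking** (`detect_spots()`, `link_tracks()`) —
   Laplacian-of-Gaussian spot detection with sub-pixel centroids and
   greedy nearest-neighbour linking with gap closing.
3. **Master parameters** (`compute_master_parameters()`) — 9 per-track
   descriptors (net displacement, path length, duration, mean/max/min
   speed, speed SD, straightness, diameter) plus 2 per-batch descriptors
   (anterograde/retrograde ratio; % moving tracks at the 1.2 μm cut).
4. **Signatures** (`assemble_signature()`, `significant_parameters()`,
   `phenotypic_strength()`, `cluster_signatures()`) — each parameter is
   expressed as a Z-score against pooled controls at D21 proximal,

   Z = (mean(condition) − mean(baseline)) / SD(baseline),

   and the 11 parameters × {mito, lyso} × {distal, proximal} assemble
   into a 44-component signature. |Z| > 5 flags significant deviations;
   the sum of |Z| over a site is its *phenotypic strength*; signatures
   are compared by Ward hierarchical clustering.
5. **Fixed-cell quantification** (`triangle_threshold()`, `count_foci()`,
   `classify_ga_dsb()`, `pearson_colocalization()`,
   `foci_per_100_cells()`) — triangle-threshold foci segmentation,
   per-nucleus counting, co-occurrence classification and pixel
   colocalization.
6. **Statistics** (`one_way_anova_bonferroni()`, `deg_overlap()`) —
   one-way ANOVA with Bonferroni post hoc pairwise tests, and exact
   Venn-overlap arithmetic for gene lists.

`run_study()` drives the whole in-silico ageing study (7 genotypes ×
7 days × 2 compartments × 2 channels) end to end and reports signatures,
strength curves, dendrograms, significant parameters and detected onset
days.

## Worked example

```r
library(axotrace)

# calibrated mobile mitochondrial preset: 1,000 two-minute tracks
ts <- simulate_tracks("mobile", "mito", n_tracks = 1000, seed = 1)
mp <- compute_master_parameters(ts)
mean(mp$per_track$mean_speed_um_s)      # 0.701  (um/s)
mean(mp$per_track$net_displacement_um)  # 9.05   (um)

# a reduced ageing study
cfg <- study_config(genotypes = c("Ctrl", "C9", "C9-KO"),
                    days = c(14, 21, 40, 80),
                    n_tracks = 150, n_batches = 6, seed = 1)
report <- run_study(cfg)
report
#> <study_report> 3 genotype(s) x 4 day(s), 150 tracks/condition (seed 1)
#>   Ctrl       distal   onset: D40
#>   Ctrl       proximal onset: none
#>   C9         distal   onset: D40
#>   C9         proximal onset: D40
#>   C9-KO      distal   onset: D21
#>   C9-KO      proximal onset: D21
```

The onset table is the study's headline readout: the first sampled day at
which any parameter at a site drops below Z = −5. Control axons decline
only distally from D40; the C9 repeat-expansion line declines globally at
D40; the knockout brings the global decline forward to D21. Strength
curves make the progression explicit — for C9, proximal strength stays at
baseline (≈ 3) through D21 and then climbs from 43 (D40) to 60 (D80):

```r
report$strengths[report$strengths$line == "C9", ]
#>   line    day total distal proximal
#>   C9       14   7.1    4.0      3.1
#>   C9       21   7.2    3.9      3.2
#>   C9       40  83.5   40.4     43.2
#>   C9       80 118.9   58.4     60.5

round(sort(significant_parameters(report$signatures[["C9_D80"]]))[1:3], 2)
#> lyso.proximal.mean_speed_um_s lyso.proximal.speed_sd_um_s lyso.distal.mean_speed_um_s
#>                        -14.75                      -14.55                      -14.49
```

All speed-family parameters collapse at both sites, the expected
signature of a global trafficking breakdown.

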