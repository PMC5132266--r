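# cholmap

Mapping specific lipid (cholesterol) interaction sites on membrane
proteins from coarse-grained molecular dynamics trajectories.

Bulk lipids patter against a membrane protein on the nanosecond scale;
a specific binding site holds *one* cholesterol molecule for
microseconds.  `cholmap` turns that contrast into a systematic,
statistically controlled mapping protocol:

1. **Maximum occupancy times.**  For every membrane-facing residue,
   the longest continuous time in contact (any bead pair ≤ 6 Å,
   minimum image) with a single lipid molecule, t_max.
2. **Replicate merging.**  Per-system Kruskal–Wallis tests at
   α = 0.01 (H vs the tabulated χ², e.g. 9.21 at df = 2) with
   iterative leave-one-out to discard divergent replicas, then
   cross-system merging into one pooled t_max population.
3. **Outliers.**  Residues above the box-plot fence
   T = Q3 + 1.5·(Q3 − Q1) of the pooled distribution.
4. **Spatial density.**  A voxelized density of lipid beads around the
   Kabsch-superposed protein, g = N/(ρ·ΔV·N_frames) on a 1 Å³ lattice
   (bulk ≡ 1), contoured into connected hotspots at 40/60 hits per
   voxel.
5. **Sites.**  Outliers matched to hotspots reproducible in *all*
   systems, ranked, classified linear vs non-linear.
6. **Kinetics & selectivity.**  Residence events from a dual-RMSD
   hysteresis machine (bound < 6 Å, unbound > 10.8 Å vs a reference
   bound pose), binding-mode clustering, per-species selectivity
   (non-annular = closed to phospholipids), and CRAC/CARC
   cholesterol-recognition motif scanning.

A synthetic trajectory generator (static helix-bundle dimer, 2-D
lipid diffusion, planted sites with exponential dwells, full ground
truth) underpins the validation suite.

## Worked example

Generate a small three-system study (15/20/25 mol% cholesterol, two
replicas, two monomers each, 5 µs per replica) with three planted
sites of 2/1/0.5 µs mean dwell, and run the whole protocol:

```r
library(cholmap)
study  <- generateStudy(replicas = 2L, seed = 8L, nFrames = 500L)
report <- runProtocol(study, runConfig(), outDir = "report")

report$outliers$threshold_ns
#> [1] 405
report$outliers$common_ids
#> [1]  5 11 23 29 41 47
for (s in report$sites) show(s)
#> InteractionSite S1 [non-linear]: 2 residues, 2 outliers, peak 358
#> InteractionSite S2 [non-linear]: 2 residues, 2 outliers, peak 326
#> InteractionSite S3 [non-linear]: 2 residues, 2 outliers, peak 320
```

The pooled t_max population (288 contacting-residue values across the
merged data-sets) has its Tukey fence at 405 ns; the twelve residues
of the six planted site copies all exceed it, and the three
reproducible density hotspots assemble into exactly three ranked
sites.  Per-site kinetics mirror the planted contrast between busy,
shallow sites and long-dwell sites:

```r
report$siteSummaries[, c("site", "max_residence_us", "n_events_total",
                         "n_events_gt_threshold")]
#>   site max_residence_us n_events_total n_events_gt_threshold
#> 1   S1              2.6            500                    12
#> 2   S2              4.5            320                    22
#> 3   S3              4.5            406                    21
```

`runProtocol()` writes `tmax.csv`, `dataset_summary.csv`,
`merged_summary.csv`, `outliers.csv`, `hotspots.csv`, `sites.json`,
`events.csv`, `site_summary.csv`, `selectivity.csv`, `tests.json` and
a `manifest.json` recording every convention used.  Motif scanning is
available standalone:

```r
scanMotifs("AGSTKAGSTYAGSTAVGATS", kinds = "CARC", offset = 486)$motif
#> [1] "K490-Y495-V501"
```

A thin command-line front end lives in `inst/scripts/cholmap`
(`simulate`, `contacts`, `motifs`, `run` subcommands).

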