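---
title: "Mapping lipid interaction sites from coarse-grained trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping lipid interaction sites from coarse-grained trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cholmap)
```

## The problem

Membrane proteins such as the neurotransmitter sodium symporters sit in
cholesterol-rich bilayers, and specific, long-lived cholesterol contacts
at defined surface pockets are thought to modulate their conformational
cycle.  Coarse-grained molecular dynamics can sample the tens of
microseconds needed to watch lipids exchange at the protein surface, but
telling a *specific* interaction site apart from the constant pattering
of bulk lipids requires a statistical protocol, not visual inspection.
`cholmap` implements such a protocol end to end and ships a synthetic
trajectory generator with planted ground truth so that every stage can
be validated quantitatively.

## The protocol

**1. Maximum occupancy times.**  A residue and a lipid molecule are in
contact at a frame when any bead pair sits within 6 Å (minimum-image
convention; the value approximates the first minimum of the
coarse-grained bead radial distribution function).  The maximum
occupancy time $t_\mathrm{max}$ of a residue is the longest run of
consecutive frames in contact with one *single* lipid molecule — never
pooled across molecules, because specific binding means one molecule
staying, not many molecules visiting.  Specific sites produce
microsecond $t_\mathrm{max}$; bulk contacts live on the nanosecond
scale.  Contact detection runs on a cell-list neighbor search (cell
edge ≥ cutoff) implemented in C++, with an all-pairs R engine retained
as an independent cross-check.

**2. Merging replicate data-sets.**  Each replica/monomer contributes
one $t_\mathrm{max}$ distribution over the membrane-facing residues that
made at least one contact.  Distributions are heavy-tailed (the
D'Agostino–Pearson omnibus test, implemented from the classical
skewness and kurtosis z-approximations, rejects normality), so
replicate agreement is tested with Kruskal–Wallis at $\alpha = 0.01$
against the $\chi^2$ critical value.  When the full set of replicates
fails, the test is repeated leaving each data-set out in turn; among
passing subsets the one with the smallest $H$ is merged and the
excluded data-set reported.  We chose minimal $H$ as the selection rule
because it is parameter-free and reproducible; when several subsets
pass, any of them is statistically defensible, and the choice is
recorded in the output.  Merged macro-samples are then tested against
each other the same way before pooling into the single population from
which outliers are called.

**3. Outliers.**  The outlier threshold is the box-plot (Tukey) upper
fence $T = Q_3 + 1.5\,(Q_3 - Q_1)$ on the pooled distribution of
contacting residues, with strictly-greater comparison.  Quartiles use
linear interpolation between order statistics (R `quantile` type 7 by
default); the convention is configurable because published thresholds
are typically only reproducible to printed precision.

**4. Spatial density probability function.**  Every frame is
superposed on a reference structure by a Kabsch least-squares fit over
the membrane-facing residue beads (with a reflection guard), and the
chosen species' beads are binned on a 1 Å³ voxel lattice.  The count
lattice $N(x,y,z)$ is normalized by the bulk density $\rho$ (species
beads per box volume), the voxel volume and the frame count,

$$ g(x,y,z) = \frac{N(x,y,z)}{\rho\,\Delta V\,N_\mathrm{frames}}, $$

so that bulk regions average to 1.  Grids from data-sets of one system
merge by summing counts and frames; merging two half-trajectories is
identical to binning the concatenation.  Hotspots are 26-connected
components of voxels whose **raw hit counts** exceed a contour level
(40 and 60 hits per voxel are reported; the lower level seeds sites
because it is the more inclusive of the two published display levels),
with a 5-voxel minimum to suppress single-voxel noise.

**5. Site assembly.**  Hotspots are grouped across systems by centroid
proximity (6 Å); only groups present in *every* system — entirely
reproducible hotspots — seed sites.  An outlier belongs to a site when
any of its beads lies within 6 Å (the contact cutoff, reused for
coherence) of a super-contour voxel center.  Sites are ranked by
matched-outlier count, then peak density.  Reproducible hotspots
without any overlapping outlier are not discarded: they are emitted as
unranked density-only candidates, the situation that arises for linear
sites whose occupancy is spread along a sequence stretch.  Sites whose
residues fall in one structural segment within a 10-residue window are
classified linear; everything else is a three-dimensional, multi-helix
pocket.

**6. Residence kinetics.**  For each site, every cholesterol that ever
contacts it is mapped onto a reference bound pose — its fitted-frame
coordinates at the frame of maximal summed site density, earliest
frame on ties — and its per-frame RMSD from that pose drives a
three-state hysteresis machine: binding below 6 Å, bound while ≤
10.8 Å (1.8 × the binding cutoff; the tolerance prevents partial,
transient unbinding from fragmenting events), unbinding above 10.8 Å.
An event's duration is its number of bound frames times the frame
interval; with the series `3, 5, 8, 9, 12, 4, 11` Å at 1 ns/frame this
yields two events of 4 ns and 1 ns.  Bound poses are clustered
greedily at 4 Å to count distinct binding modes (clusters holding ≥ 5 %
of bound frames), with a low-confidence flag when the qualifying modes
cover under half of the poses.

**7. Selectivity and motifs.**  Per-species $t_\mathrm{max}$ profiles
and density grids classify a site as non-annular when every
phospholipid species shows less than 10 % of cholesterol's mean site
density — a pocket effectively closed to other lipids.  Finally, the
sequence is scanned for CRAC motifs (N→C: apolar V/L, 1–5 spacer
residues, aromatic Y/F, 1–5 spacers, basic R/K) and CARC motifs (same
reading direction, anchors in reverse order).  Spacers count the
residues strictly between anchors, the convention under which the
canonical worked examples (K490-Y495-V501 on TM10; V265…K272 on TM4)
carry spacers within 1–5.  Tryptophan does not qualify as the aromatic
anchor, and the membrane-facing filter is applied to the three anchors
(full-span filtering is available but demands per-residue exposure
data that is rarely known).

## The synthetic generator

`generateSystem()` emulates the *structure* of the data the protocol
consumes, not membrane physics: a static, jittered transmembrane helix
bundle (two monomers per box, mirroring dimeric simulation setups that
double the statistics per run); two independent leaflets of lipids
performing two-dimensional lateral Brownian motion with per-species
diffusion coefficients (4 Å²/ns for cholesterol, 2 Å²/ns for the
phospholipids, plausible coarse-grained magnitudes), slowed mildly with
cholesterol enrichment; and planted surface sites where a cholesterol
entering an 8 Å capture radius binds with probability 0.5 and dwells
for an exponentially distributed time before being released outside the
hysteresis band.  A short refractory period after release prevents
instant recapture from artificially fusing consecutive dwells.

The default study conditions used throughout validation are three
systems at 15/20/25 mol% cholesterol (remainder split between PC and
PE species), two replicas each, 30 µs per replica sampled at 10 ns
with the first 500 ns discarded as equilibration, and three planted
sites per monomer with mean dwells of 2, 1 and 0.5 µs against ~10 ns
diffusive background contacts.  Composition is realized to within one
molecule of the requested mole fraction.  All randomness flows from a
single seed, so equal seeds give bitwise-identical trajectories.

What the generator does *not* emulate — excluded volume, binding
competition beyond one lipid per site, protein conformational change,
leaflet exchange, realistic lipid shapes (one bead per lipid by
default) — bounds what passing tests can claim: they demonstrate that
the statistical machinery recovers known ground truth planted in data
with realistic dimensions and noise structure, not that the protocol is
robust to every artifact of real force fields.

## Numerical choices and degenerate inputs

* Coordinates are Ångström internally; GRO input (nm) is converted on
  read.  Boxes must be orthorhombic — triclinic input is rejected so
  the minimum-image convention stays exact.
* Superposition requires ≥ 3 non-collinear selection beads and refuses
  reflections; fitting an already-fitted frame moves coordinates by
  < 1e-6 Å.
* Dimer trajectories are split into per-monomer data-sets at analysis
  time; monomer B is superposed onto monomer A's reference through the
  parallel bead ordering of a homomeric topology, and residues are
  pooled across monomers by their position in the monomer sequence.
* The t_max gap tolerance defaults to 0 (strict runs); bridging is
  exposed for robustness studies and is monotone by construction.
* Beads drifting outside the density grid are tallied, not silently
  dropped; grid extent defaults to the protein bounding box + 15 Å.
* With a single data-set the merging stage degrades to a pass-through
  and the fence is computed on that set alone.
* Empty results are legal everywhere: no contacts, no outliers, no
  reproducible hotspot and no event list abort nothing downstream.

## Validation scale

The bundled validation suite runs the full pipeline on the reference
study conditions above (12 monomer data-sets of 3 000 analyzed frames,
~300 lipids each; a few minutes on one core), checks the contact engine
against all-pairs enumeration on 50 random toy systems, the density
normalization against its closed form and bulk limit at 10⁵
bead-frame observations, the merging stage's operating characteristics
over 100 seeded replicates (n = 300 per data-set), and the motif
scanner against an exhaustive enumerator.  `scripts/acceptance.R`
recomputes all headline numbers from scratch for any seed.

## Known limitations

Residence analysis assumes the bound pose is well represented by a
single frame per lipid per site; slow multi-modal sites are summarized
by the binding-mode count instead.  Site-hopping frames are assigned to
one site at a time: the first event closes at its hysteresis exit
before the next opens.  The Wilcoxon and Kruskal–Wallis decisions use
the normal/χ² approximations with tie corrections, adequate for the
sample sizes the protocol targets (hundreds of contacting residues) but
not for very small masks.  The generator's planted kinetics are
memoryless by design; real lipid exchange need not be.
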