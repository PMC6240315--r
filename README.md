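# nmlineage

Lineage analysis of zebrafish neuromesodermal progenitors (NMps): do spinal
cord and paraxial mesoderm descend from shared progenitors, and are those
progenitors bi-fated single cells or a mixture of mono-fated ones? This
package re-implements, as tested R components, the three computational
procedures such a study needs, each paired with a synthetic-data generator so
the whole analysis runs and is validated without any external data:

1. **ScarTrace clonal analysis** — CRISPR/Cas9 scars in a tandem GFP
   transgene array are heritable clone marks. Starting from per-organ scar
   read-count tables, the pipeline applies a four-stage filter
   (sequencing-error fraction filter, per-fish QC, cross-fish rare-scar
   filter, binarization), computes an information-weighted sparse-sample
   (IWSS-like) dissimilarity between body structures, and summarizes it as
   average-linkage clustered log-distance heatmaps and neighbor-joining trees
   with 100× bootstrap clade support.
2. **In-silico fate mapping** — on cell-tracking lineage forests (TGMM-style
   XML or flat tables), select a clone at a timepoint, follow all
   descendants, classify each terminal cell from its reporter traces
   (mezzo⁺ → mesoderm, sox17⁺ → endoderm excluded, reporter-negative
   survivors → neural), and score every *terminal division* as N/N, M/M or
   bi-fated N/M.
3. **Online stage tracking** — the 3D phase-correlation loop that keeps a
   fast-moving tailbud in the light-sheet field of view: downsample to 1 µm
   isotropic voxels, every 5th timepoint estimate the shift against a
   reference stack, move the stage by the negated shift, replace the
   reference; plus offline consecutive-stack registration with the same
   estimator.

## The statistics at the core

**Scar filtering.** Within each fish, a scar observation is kept only when its
within-sample read fraction is at least 10× the minimum detected scar
fraction (boundary inclusive). A fish passes QC when its mean unscarred-GFP
percentage across organs is < 50 and it carries > 100 distinct surviving
scars (both strict). Scars detected in more than one fish, or on a
user-supplied blacklist, are removed everywhere; surviving counts are
binarized.

**IWSS-like distance.** With presence frequency
`p_s = (k_s + α) / (n + 2α)` (Jeffreys pseudocount α = 0.5), presence weight
`w_s = −log₂ p_s` and absence weight `v_s = −log₂(1 − p_s)`, the distance
between binary profiles x, y is

    D(x,y) = Σ_{x≠y} w_s / ( Σ_{x=y=1} w_s + Σ_{x=y=0} v_s + Σ_{x≠y} w_s )

so shared rare scars pull samples strongly together, shared absences weakly,
and mismatches push apart — all positions of a sparse profile contribute.
The published method names this distance but prints no formula; the form
above is this package's documented stand-in, isolated behind `iwss()` /
`scar_weights()` so an alternative can be swapped in.

**Terminal-division scoring.** A terminal division is a division none of
whose descendants divide again within the observation window; it is N/M
(bi-fated) when one daughter ends mesodermal (sustained mezzo ≥ threshold on
≥ k consecutive frames) and the other neural (reporter-negative but tracked
to the end of the movie). Undivided tracks are mono-fated directly.

**Phase correlation.** The translation between stacks is the argmax of the
inverse transform of the normalized cross-power spectrum
`F(mov)·conj(F(ref)) / |·|`, restricted to a ±max_shift window with
wrap-around unfolding; ties break to the smallest-norm shift.

## Worked example

The analysis is organised as numbered drivers under `analysis/` over the
package functions; each writes its tables under `results/` with a manifest
(seed, parameters, md5 per output).

```sh
Rscript analysis/01_scar_clonal_analysis.R --seed 1
```

simulates three scarred fish, filters and binarizes their organ scar tables
and prints, per fish, the organ×organ IWSS matrix, e.g. for fish3:

```
spinal cord - muscle: 0.658 | spinal cord - brain: 0.839 -> spinal cord groups with muscle
bootstrap supports on internal nodes:  100 / 100
```

Spinal cord sits closer to muscle than to brain — the clonal signature of a
shared neuromesodermal origin — while brain/skin and the endoderm organs
(intestine/liver, distance 0.067) form their own groups, each with full
bootstrap support.

```sh
Rscript analysis/02_fate_mapping.R --seed 1
```

simulates a tracked gastrula with a true bi-fated progenitor fraction of 0.3
and prints

```
terminal divisions scored: 218
incomplete   M/M   N/M   N/N
        10    79    63    66
bi-fated fraction: estimated 0.303 vs true 0.299 (95% CI 0.241-0.370, n = 208)
```

```sh
Rscript analysis/03_stage_tracking.R --seed 1   # online loop holds the object:
# max centroid excursion: 26.2 voxels uncorrected vs 10.8 with the loop
Rscript analysis/04_window_contrast.R --seed 1  # short scarring window is weaker:
# mean scars/fish: rna 221 vs protein 19; support 0.999 vs 0.857, weaker in 20/20 fish
```

## Formats

* **Scar tables**: TSV, metadata columns `sample_id fish_id organ
  axis_position replicate_id` before scar columns; scar ids are opaque
  `position:indel-signature` strings; one reserved `GFP_unscarred` column.
* **Lineage forests**: TGMM-style per-timepoint XML (elements with `id`,
  `parent`, `lineage`, `m="x y z"` attributes; extra numeric attributes
  become intensity channels) or a flat CSV `cell_id,parent_id,t,x,y,z,...`.
* **Trees**: Newick with bootstrap counts as internal node labels.
* **Volumes**: in-memory 3D arrays; optional multi-page TIFF `t####.tif`
  with JSON sidecars (needs the `tiff` package).
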