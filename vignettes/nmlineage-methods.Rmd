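---
title: "Models and methods behind nmlineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nmlineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmlineage)
```

This vignette is the package's own account of the three methods it
implements, the assumptions behind them, the tunable parameters that matter,
what the synthetic-data generators do and do not emulate, and the numerical
choices made where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself compute.

## 1. ScarTrace clonal analysis

### The measurement

CRISPR/Cas9 injected into a zygote carrying a tandem array of eight GFP
transgenes introduces indels ("scars") at the target sites. A scar created in
a cell is inherited by all of that cell's descendants, so two adult body
structures that share recently created scars share clonal ancestry. The data
are per-organ bulk read counts over scar identities, with a reserved
`GFP_unscarred` column counting reads from unedited target copies.

### Filtering model and its assumptions

The filter chain assumes three noise sources: sequencing errors (spurious
low-fraction scar calls), inefficiently scarred fish (little lineage
information), and recurrent scars created independently in several embryos
(not clone-specific, since informative scars should have creation
probabilities on the order of 10⁻⁵).

1. **Fraction filter** — within each fish, an entry is kept iff its
   within-sample fraction is ≥ `factor` (default 10) times the minimum
   detected scar fraction. The boundary is inclusive ("at least"). The floor
   is computed *per fish* by default because sequencing depth, and hence the
   error floor, varies by fish; `fmin_scope` also offers `"sample"` and
   `"global"`. The floor can be passed explicitly (`f_min`), which makes the
   censoring map idempotent; re-estimating it from already-filtered data
   would raise it, because the error reads that defined the floor are gone.
   The `GFP_unscarred` column is exempt: it is a QC quantity, not a scar.
2. **Fish QC** — keep a fish iff mean unscarred-GFP percentage over organs
   < 50 *and* distinct surviving scars > 100, both strict, as the thresholds
   are stated.
3. **Cross-fish filter** — a scar detected (count > 0) in ≥ 2 fish of the
   cohort is removed everywhere; an optional blacklist handles scars known
   from external experiments. This generalizes the original exclusion list,
   whose underlying data are not available, into a user-supplied input.
4. **Binarization** — presence/absence per merged sample; technical
   replicates of the same dissected structure are summed (after the scar
   filters, before binarization, following the original order of operations).

### The IWSS-like distance

The published distance is named and described as incorporating "both the
matches and mismatches in an information-weighted manner", but no formula is
printed. The package therefore implements a documented stand-in with exactly
that property and keeps it isolated behind `scar_weights()` and `iwss()`:

* presence frequency with a Jeffreys pseudocount,
  $p_s = (k_s + \alpha)/(n + 2\alpha)$, $\alpha = 0.5$, so both weights are
  finite even for scars present in all or no samples;
* presence information $w_s = -\log_2 p_s$, absence information
  $v_s = -\log_2(1 - p_s)$;
* $D(x,y) = \frac{\sum_{x_s \ne y_s} w_s}{\sum_{x_s = y_s = 1} w_s +
  \sum_{x_s = y_s = 0} v_s + \sum_{x_s \ne y_s} w_s} \in [0, 1]$.

A match on a rare scar (large $w_s$) is strong evidence of relatedness; a
match on absence of a common scar is weak but non-zero evidence, which is
what makes the measure usable on sparse profiles. $D$ is a dissimilarity,
not a metric; triangle-inequality violations are permitted. Results should
be reported as "IWSS-like" since the original definition may differ.

Heatmap ordering follows the original convention: rows of
$\log_{10}(D + \varepsilon)$ ($\varepsilon = 10^{-6}$, display only) are
clustered by average linkage on euclidean distances.

### Trees and support

The original workflow bootstrapped distance trees 100× and reported clade
proportions. The tree constructor itself is not stated; neighbor joining
(Saitou–Nei) is used here as the standard distance-based choice, with the
average-linkage dendrogram available as an alternative via
`cluster_log_distance()`. The bootstrap resamples scar *columns* (the
characters) with replacement, recomputes weights → distances → NJ per
replicate, and counts, for every internal edge of the reference tree, the
replicates containing the same unrooted bipartition. Matching is by split,
not rooted clade, because the trees are unrooted; the counting is
cross-checked against `ape::prop.clades` in the test suite. Negative NJ
branch lengths (possible on non-additive dissimilarities) are clamped to 0
with a warning.

### What the scar simulator emulates

`simulate_embryo()` grows a synchronous binary division tree (default 11
rounds → 2048 leaves). Each cell carries 8 independent target copies; inside
the scarring window each still-unscarred copy scars with probability 0.25
per division, drawing its identity from a truncated power law (50 000
identities, exponent 0.8), whose rare tail reaches creation probabilities of
order 10⁻⁵ — the regime in which scars are usable as clone marks. Window
presets map the two injection chemistries onto rounds: `"rna"` (long,
scarring throughout gastrulation) = rounds 1–9, `"protein"` (short, early
cleavage only) = rounds 1–3; a first round of 0 scars the zygote itself.
These are coarse mappings of hours post fertilization onto synchronous
rounds — the real cleavage clock is neither synchronous nor uniform — and
are exposed as plain parameters.

Organs draw `cells_per_organ` (default 100) leaves from configurable
progenitor subtrees at generation 4. The default `tissue_map` interleaves
organ pools across the early-cleavage quadrants — spinal cord
{1,2,5,6,9,10} overlapping muscle {2,3,6,7,10,11}, brain = skin = {4,8,12},
endoderm organs {13–16} — because zebrafish early cleavage is indeterminate:
organ primordia must not align with the first division planes. With this
geometry, scars from the first two rounds are uninformative about organ
grouping and the informative signal arises near the progenitor allocation,
which is what makes the short "protein" window genuinely weaker.

Sequencing is a multinomial draw at fixed depth (20 000 reads/sample) over
copy abundances, with per-scar dropout (5%) and ~40 spurious error
identities per sample at ~1-read abundance. The error reads are what the
10× fraction filter exists to remove: without them the minimum detected
fraction is a genuine single-copy scar and the rule would censor real
signal. Not modelled: PCR amplification bias, indel sequence content,
lane/batch effects, single-cell protocols. Passing tests therefore
demonstrate correctness of the pipeline's logic and its behaviour under
multinomial + dropout + error-floor noise, not performance on any real
library preparation.

Recovery is scored two ways: the distance ordering (IWSS(spinal cord,
muscle) < IWSS(spinal cord, brain)) and bootstrap clade support for the true
organ groupings. The window contrast is asserted on support (and on scar
counts), because binarized organ profiles saturate with 100 sampled cells
and raw distance margins do not separate the two chemistries — trees and
their support are also how the original analysis displayed the contrast.

## 2. In-silico fate mapping on lineage forests

### Data model

A forest row is one cell observation: globally unique `cell_id`, the
`parent_id` it continues from, integer timepoint, micron position, reporter
intensities. A node with two children is a division; a *track* is a root and
all its progeny. TGMM-style per-timepoint XML is imported with orphan
parents demoted to new roots (and reported), since a tracker can lose a
link; duplicated ids within a timepoint or more than two children are hard
errors.

### Clone selection

`select_clone()` takes the cells inside a sphere or box at `t0`, optionally
intersected with a viewer half-space (eliminating cells on the far side of
the embryo, which interactive selection tends to catch by accident), and
closes over descendants exactly. The closure is checked against an
independent graph-reachability oracle in the tests.

### Fate classification

Reporter scoring in the original study was by eye; here it is an explicit
rule with three parameters: channel thresholds, and `k_frames` (default 3)
consecutive frames required above threshold, which rejects single-frame
tracking flicker (a nucleus passing a bright neighbour). Priority: sustained
sox17 → endoderm (excluded from the neural/mesodermal question); else
sustained mezzo → mesoderm; else a track observed to the end of the window →
neural; else unassigned (lost early — the analogue of discarded tracks).
Unassigned daughters make a division `incomplete`, excluded from bi-fated
denominators.

A terminal division has no dividing descendants; its class is the pair of
daughter fates. Undivided tracks are mono-fated directly. The bi-fated
fraction β is estimated as N/M divisions over complete terminal divisions.

### What the track simulator emulates

Starting cells carry latent fates (N, M, bi-fated NM, endo) with configurable
probabilities and divide after exponential waiting times; an NM cell's
division yields one N and one M daughter; daughters divide at
`child_division_rate` (default 0, so every observed division is terminal —
set it positive for multi-division tracks). Committed cells switch their
reporter from baseline 10 to 100 after a 5-minute delay, with Gaussian
observation noise (σ = 3) and commitment inherited across divisions of
already committed cells. Motion is uniform drift plus Brownian jitter;
tracks are lost (censored, with their whole subtree) at 0.002 per frame,
exercising the unassigned pathway. Divisions are quantized to the 2.5-minute
frame grid, so a division within ~12.5 minutes of the movie end cannot show
the 3 sustained post-onset frames the classifier demands — a realistic,
quantified source of missed late commitments. Not modelled: convergence-
extension mechanics, reporter bleaching, segmentation errors other than
whole-track loss.

At the study scale used in the tests (260 starting cells, ~200 complete
terminal divisions, β = 0.3), the estimator is within ±0.10 of truth in
≥95% of seeds, and with β = 0 and noise-free reporters it makes zero N/M
calls — the logic behind concluding an absence of bi-fated progenitors when
no division produces mixed daughters.

### Label summaries

`classify_label()` applies the strict over-90% rule (a 90/10 label is
"both"); `label_polar_position()` reports a label's great-circle arc from
the animal pole and its azimuth about the animal–vegetal axis measured from
the shield (dorsal) meridian, with the azimuth undefined (NA) at the poles;
`ap_contribution()` gives per-somite neural/somite histograms and occupied
spans; `clone_fold_change()` is the guarded ratio of labelled cell counts;
`zone_assign()` assigns track fates from the anatomical zone of the terminal
position (with the sox2⁺/tbxta⁺ co-expression zone mapping to "unassigned")
and summarizes spatial sorting as the mean fraction of k-nearest
start-position neighbours sharing a track's fate — an invented statistic,
reported as such, equal to 1 for a fully sorted layout. 2D fate-map
projections collapse an axis and can fabricate apparent mixing; the mixing
summary is computed in 3D for that reason.

## 3. Online stage tracking and registration

### The loop

The tailbud displaces quickly relative to the field of view, so the
microscope must follow it. The implemented loop mirrors the acquisition
design: stacks are block-mean downsampled to 1 µm isotropic voxels (cheap,
anti-aliased, mean-conserving); at every 5th timepoint the current stack is
phase-correlated against the reference, the stage moves by the negated
estimated shift, and the reference is replaced by the current stack so the
loop tolerates gradual growth and shape change. Events whose correlation
confidence (peak over the top-5 peak sum) falls below a floor are logged
with the correction withheld.

### Numerical choices

* Integer-voxel shifts by default: stage feedback needs micron-scale, not
  subpixel, accuracy.
* The argmax is restricted to ±`max_shift` per axis (default a quarter of
  each dimension) after unfolding the FFT's wrap-around; this encodes the
  loop's core assumption that inter-event drift is small. A drift of d per
  frame with interval k needs `max_shift ≥ k·|d|`.
* Ties break to the smallest-norm shift; zero-variance inputs are an error
  ("no signal") rather than a spurious zero shift.
* A Hann window is available (off by default) for non-circular real data
  with strong edge structure.
* Offline registration aligns each frame to frame 0 by the prefix sums of
  consecutive pairwise shifts — removing the sudden stage-move displacements
  — with zero-fill and a validity mask in non-circular mode so downstream
  statistics can exclude padded voxels.

### What the volume simulator emulates

Gaussian blobs (optionally growing, a cartoon of the extending tailbud)
under a known drift path — constant, piecewise, or random walk — with
additive Gaussian noise, at the study cadence of 2.5 min/frame. Circular
boundary mode makes integer drifts exactly recoverable (used for exactness
tests); crop mode lets content leave the field (used for the
field-of-view-keeping property). Not modelled: optical PSF, bleaching,
anisotropic resolution, non-rigid tissue deformation — so passing tests
bound estimator correctness, not microscope performance.

## Problem sizes and budgets

The test and acceptance runs use deliberately modest sizes chosen once as
the package's study conditions: 2048-leaf embryos with 6 organs × 2
replicates at 20 000 reads; 100 grouping seeds and 20 window-contrast seeds;
260-cell forests over 40 frames (≈200 terminal divisions) × 50 seeds; 64³
volumes with 50 random shifts. At these sizes the full suite runs in a few
minutes on one CPU.

## Known limitations

* The IWSS formula is a stand-in; absolute distances are not comparable to
  the original publication's, only orderings and groupings are meaningful.
* The fraction filter's floor estimation depends on an error-read floor
  existing in the data; on error-free data it censors real single-copy scars
  (see the idempotence discussion above).
* The fate classifier's neural call is "survived unlabelled to movie end";
  it cannot distinguish a neural cell from a mesodermal cell whose
  commitment falls within the reporter delay of the movie end.
* hpf-to-division-round mapping in the scar simulator is linear and
  synchronous; real cleavage slows after the midblastula transition.
* The NJ/bootstrap machinery targets organ-level trees (tens of leaves), not
  single-cell-scale reconstruction.
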