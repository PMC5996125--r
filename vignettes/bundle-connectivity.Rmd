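---
title: "Quantitative bundle tractography with fascicle: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative bundle tractography with fascicle: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fascicle` implements a quantitative tractography analysis of white-matter
fiber bundles — the kind of analysis applied to the inferior longitudinal
fasciculus (ILF), a ventral association tract connecting anterior temporal
to occipital cortex. The pipeline runs from per-voxel fiber-orientation
fields to deterministic streamline bundles, geometric bundle extraction,
dorsal/ventral subdivision, region-pair connection indices, volumetry with
lateralization statistics, and CIRCOS-ready connectogram export. Because
real multi-shell diffusion data cannot ship with a package, a synthetic
phantom generator provides orientation fields with known ground truth; the
published connection-index tables of a 30-subject ILF study are packaged as
plain-CSV fixtures so their summary statistics can be recomputed exactly.

This vignette documents the model, the tunable parameters, the synthetic
data, and the design decisions taken where the method description left
choices open.

## The tracking model

The tracker is a deterministic generalized-streamline method over
multi-peak orientation fields. Each voxel holds up to $K = 3$ unit peak
directions $v_k$ (sign-ambiguous axes) with a per-peak quantitative
anisotropy (QA) scalar. From a seed, two half-tracks are advanced along the
positive and negative sense of the seed voxel's best admissible peak and
joined. At each step, with incoming unit direction $d$:

1. the peaks of the voxel containing the current position are looked up
   (nearest-voxel; no directional interpolation across voxels);
2. peaks with QA below `qa_threshold` are discarded;
3. among the survivors, considered in both signs, the direction $v^\*$
   maximizing $d \cdot v$ is selected; if the best turning angle is not
   below `angle_threshold`, the track terminates;
4. the next moving direction is the renormalized blend
   $\mathrm{normalize}(w_{\mathrm{in}}\, d + (1 - w_{\mathrm{in}})\, v^\*)$
   with $w_{\mathrm{in}} = 0.2$ — 20% incoming direction, 80% nearest
   fiber orientation;
5. the position advances by `step_size` along the blended direction.

Tracks also terminate on leaving the grid, in zero-peak voxels, or at
`max_steps`; tracks shorter than `min_length` are rejected.

Defaults (all user-settable through `tracking_params()`):

| parameter         | default | unit    | rationale                                        |
|-------------------|---------|---------|--------------------------------------------------|
| `step_size`       | 0.2     | mm      | sub-voxel stepping at ~1 mm voxels               |
| `angle_threshold` | 60      | degrees | standard deterministic turning limit             |
| `qa_threshold`    | 0.05    | —       | midpoint of the commonly tuned 0.02–0.08 range   |
| `w_incoming`      | 0.2     | —       | 20/80 incoming/peak directional blend            |
| `min_length`      | 20      | mm      | suppress spurious short tracts                   |
| `max_streamlines` | 100000  | count   | generation cap per bundle                        |
| `max_steps`       | 10000   | count   | termination guard, not a scientific parameter    |

Notes on open choices. Descriptions of this family of trackers sometimes
quote both a 20%/80% directional weighting and a separate "50% smoothing"
setting; these cannot both describe the same blend. This implementation
realizes the 20/80 rule exactly and treats the 50% figure as a vendor
surface over the same mechanism. QA is thresholded per peak (the selected
peak's QA), not per voxel, consistent with peak-wise orientation data.
Nearest-voxel peak lookup (rather than interpolation) keeps oracle
comparisons exact and is standard for peak-based deterministic tracking;
the voxel of a point is `floor(mm / voxel_size)`, so boundary points belong
to the higher-index voxel. Ties in the congruence argmax are broken by the
lowest peak index, making every run order-deterministic. Per-dataset
tuning of the QA threshold by visual inspection of false continuities is
replaced by an explicit config value.

## The synthetic phantom

`generate_phantom()` builds, from a `phantom_config()`:

* **bundles** as tubes of constant radius around smooth centerlines
  (natural cubic splines through control points, chord-length
  parameterized, so tangents vary continuously and the 60° test is never
  tripped by discretization corners);
* an optional **posterior bifurcation**: at a fractional arc-length
  `branch_point` the centerline forks into dorsal and ventral branch
  centerlines sharing the fork point;
* an optional **crossing bundle**: voxels inside several tubes carry one
  peak per bundle (up to $K = 3$; more is a configuration error);
* **angular jitter**: each in-tube peak is rotated by an angle drawn from
  $N(0, \sigma^2)$ about a random axis perpendicular to it — a simple
  isotropic noise model;
* **labels** as disjoint axis-aligned boxes rasterized to an integer
  atlas;
* **ground truth**: per-bundle voxel masks and volumes, centerline-following
  truth streamlines (with random in-tube radial offsets), and the
  region-pair table they imply under the same endpoint-assignment rule the
  analysis uses.

World coordinates are millimeters with the voxel-center convention
(`mm = (index0 + 0.5) * voxel_size`); axes are x = left–right,
y = anterior–posterior, z = inferior–superior.

Three stock configurations are exported. `tube_phantom_config()` is a
single straight 40 mm tube of radius 2 mm — the analytic cylinder used for
volumetry checks. `crossing_phantom_config()` crosses two orthogonal tubes
(radius 3 mm) at 90°. `ilf_phantom_config()` emulates the target anatomy:
one curved tube per hemisphere (radius 3 mm, ~75 mm long) running anterior
to posterior and forking at 75% of its length into a dorsal and a ventral
branch ~21 mm apart, with an anterior temporal label and dorsal/ventral
occipital labels per hemisphere. `asymmetric_tube_pair_config()` is a
left/right pair of straight tubes for lateralization recovery.

**Asymmetry.** `asymmetry` is the left:right tube radius ratio: right-
hemisphere radii are divided by it, so the left/right volume ratio scales
as `asymmetry`² and the lateralization index
$\mathrm{LI} = 2(V_L - V_R)/(V_L + V_R)$ has the sign of
`asymmetry` − 1. The default 1.17 yields an analytic LI of ≈ 0.31, a
realistic leftward dominance for ventral association tracts, and is used
as the standard simulated condition throughout.

**Per-subject variability.** No subject-level variability model is
available to estimate from data; the pipeline emulates inter-subject
variation with independent 5° angular jitter per simulated subject. This
is a free knob, not an estimate.

**What the phantom does not emulate** — and hence what passing tests do
not show about real data: no raw diffusion signal, b-values, or q-space
reconstruction (the phantom starts at the orientation-field level); no
partial-volume or Rician noise structure; no cortical folding, gyral bias,
or bottleneck regions; no per-subject anatomical variability beyond
angular jitter and radius scaling; label regions are convex boxes rather
than cortical parcels. Tests against the phantom validate the algorithmic
pipeline, not its fidelity on clinical data.

**Voxelization bias.** Ground-truth volumes are voxel counts at the
configured grid. At 1 mm voxels, a radius-3 mm tube voxelizes ~2.6% above
its analytic cross-section and a radius-2.56 mm tube ~1.6% above, so the
voxelized L/R volume ratio of the default ILF phantom is ≈ 1.417 against
the analytic 1.369, shifting the truth LI by ≈ +0.03. Deterministic
tracking additionally cuts corners on curved thin tubes. For this reason
the analytic LI-recovery check runs on the straight-tube pair (where the
measured LI lands within 0.02 of analytic), while the curved phantom is
held to agreement with its own voxelized ground truth; both appear in the
acceptance suite.

## Bundle extraction and subdivision

Selection reproduces a two-ROI approach: streamlines must pass through a
sphere in the anterior temporal white matter *and* a coronal box at the
temporo-occipital junction, and must avoid a sagittal midline plane (a
region of avoidance). Manual removal of spurious fibers belonging to
neighboring systems is reproduced non-interactively as exclusion-mask
predicates declared in configuration — a deliberate mechanization for
testability and determinism. Membership is tested at streamline points
plus segment midpoints (half the 0.2 mm step), and zero-thickness planes
use an exact segment-crossing test, so thin regions cannot slip between
samples. Selection is a pure filter: idempotent, order-invariant, never
mutating streamlines.

Subdivision mechanizes the dorsal/ventral separation of a bundle with a
bifurcated posterior termination pattern. For each streamline the
posterior endpoint (the endpoint beyond a posterior coronal plane) is
taken; endpoints are clustered by a 1-D 2-means on the superior–inferior
coordinate, initialized at the coordinate extremes — the smallest faithful
and fully deterministic mechanization of a visual split. The cluster with
the greater mean z is dorsal. If the between-center gap is below two
voxels the split is declared degenerate and the whole bundle is returned
as ventral (a single-branch bundle has no dorsal component). The ventral
branch is not subdivided further, and no anterior subdivision is
attempted (anterior morphology is the more variable end).

## Connection indices

Each streamline contributes once to the unordered pair of its endpoint
regions. An endpoint in background is assigned to the nearest nonzero
label within 2 voxels (nearest wins, lowest label on ties) — streamlines
terminate at anisotropy boundaries slightly short of labeled regions, and
the radius is an explicit, unglamorous default. Streamlines with an
unassignable endpoint are counted in an explicit `unassigned` bin, never
dropped, so `sum(counts) + unassigned = total_fibers` is an invariant.
Self-pairs (both endpoints in one region) are retained in matrices but
excluded from connectogram links.

Counts are normalized per subject by the fascicle's **total** fiber count,
then aggregated across subjects by the arithmetic mean per pair, divided
by the global maximum mean and scaled to 0–100:

$$\mathrm{CI}_{ab} = 100 \cdot
  \frac{\overline{c_{ab}/N}}{\max_{a'b'} \overline{c_{a'b'}/N}}$$

"Scaled over the range of subjects" admits several readings (per-pair
min–max, global max, …); mean-then-global-max is the simplest one that
yields 0 for no connectivity and exactly 100 for the strongest relative
connection, and it is the implemented and documented choice. It makes the
CI invariant under uniform count scaling and under subject permutation.
Hemispheres are merged per fascicle before counting, so left and right
pairs share one scaling — which is why only one hemisphere's strongest
pair reaches 100 in the packaged tables.

## Volumetry and statistics

Bundle volume is the count of distinct voxels containing at least one
streamline point (segments sub-sampled at half the smallest voxel
dimension), times the voxel volume, in ml — set semantics, so duplicated
streamlines add nothing and volume is monotone under union. The
lateralization index is $2(V_L - V_R)/(V_L + V_R) \in [-2, 2]$, positive
leftward.

CI summary statistics (mean, sample n−1 SD, median, nonzero count) are
computed over an **explicit cell mask**, because the packaged tables'
published summaries use inconsistent cell sets: the left-dorsal mean
matches all 16 left cells of table 1, the left-whole mean matches the 28
cells of table 3 excluding the all-zero amygdala column, the right-whole
mean matches all 35 right cells — while the published right-dorsal mean
(10.45) matches no subset of table 1's right half, and the published
dorsal medians duplicate the whole-bundle medians (the whole-bundle
medians do reproduce under their masks; the dorsal ones do not, consistent
with a transcription duplication). No unifying rule is guessed: every
statistic in `reproduce_tables()` states its mask, and statistics that no
mask reproduces are reported without a reference comparison.

Hemispheric comparisons use Welch's unequal-variance t-test with
Welch–Satterthwaite degrees of freedom — the pooled-variance form does
not reproduce the published t = 3.07 / t = 1.64 on the table cells, the
Welch form does. One-sided p-values are taken in the direction of the
observed effect. Because the fixture cells are themselves printed rounded
to 2 decimals, recomputed statistics are compared to published ones at
one unit in the last printed digit.

## Numerical choices and determinism

* Voxel membership: floor rule; boundary points belong to the
  higher-index voxel (documented once, used everywhere).
* Tie-breaks: lowest peak index (tracking), lowest label (endpoint
  assignment), lower cluster center (2-means distance ties).
* Degenerate inputs: empty bundles select/volumetrize to empty/0; a
  zero-peak seed propagates to nothing; `total_fibers = 0` refuses to
  normalize; both-zero volumes refuse an LI; an empty selection issues a
  warning and skips downstream stages for that subject.
* All randomness (jitter, truth-streamline offsets, random seeding) flows
  from explicit integer seeds through a local RNG that saves and restores
  the caller's RNG state; subject s of a pipeline run uses
  `seed * 1000 + s`. Two runs with equal configuration are bit-identical,
  including CSV/JSON outputs (verified by checksum in the tests).
* Problem sizes: the test and acceptance suites track a few hundred to a
  few thousand seeds on 20–90-voxel grids and simulate 2 subjects in the
  pipeline checks — sizes chosen so the full suite runs in a couple of
  minutes while every rate they estimate (connection rates, misassignment
  rates) is computed from several hundred streamlines.

## Known limitations

* Pure-R tracking is comfortable at phantom scale (thousands of seeds);
  whole-brain seeding at 100,000 accepted tracts would want a compiled
  inner loop.
* Nearest-voxel lookup makes streamline shape mildly grid-dependent;
  trilinear peak interpolation is a possible extension but would decouple
  the tracker from the exact-oracle tests.
* The connectogram export writes CIRCOS karyotype/links text; it does not
  render diagrams.
* The subdivision rule assumes a single dorsal/ventral bifurcation; more
  than two posterior prongs would need a different clustering.
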