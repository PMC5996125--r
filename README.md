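# fascicle

Quantitative tractography analysis of white-matter fiber bundles, built
around the kind of study applied to the inferior longitudinal fasciculus
(ILF) — a ventral association tract connecting anterior temporal to
occipital cortex whose subdivision, lateralization and connectivity are
quantified from deterministic streamline tractography over multi-fiber
orientation fields.

The package implements the full pipeline:

* **Tracking** — deterministic generalized-streamline propagation over
  per-voxel multi-peak orientation fields with quantitative-anisotropy
  (QA) termination. At each 0.2 mm step the fiber orientation most
  congruent with the incoming direction `d` (both signs considered, QA ≥
  threshold, turning angle < 60°) is selected, and the next direction is
  `normalize(0.2 d + 0.8 v*)`; tracks run bidirectionally from each seed
  and must reach 20 mm.
* **Selection** — two-ROI extraction (anterior sphere ∧ posterior coronal
  box) with a sagittal midline region of avoidance and mask-based
  exclusion predicates.
* **Subdivision** — a deterministic dorsal/ventral split of the bundle's
  bifurcated posterior terminations (1-D 2-means on the superior–inferior
  endpoint coordinate, initialized at the extremes).
* **Connectivity** — endpoint-to-region count matrices and the connection
  index `CI_ab = 100 · mean_s(c_ab/N) / max_ab mean_s(c_ab/N)` ∈ [0, 100],
  scaled across subjects, plus CIRCOS-ready karyotype/links export.
* **Quantification** — bundle volumetry by voxel occupancy (ml), the
  lateralization index `LI = 2(V_L − V_R)/(V_L + V_R)`, masked CI summary
  statistics, and Welch t-tests.
* **Phantoms** — a synthetic orientation-field generator (curved tubes,
  posterior bifurcation, orthogonal crossings, hemispheric asymmetry,
  angular jitter, labeled terminations) with analytic ground truth, since
  real multi-shell diffusion data cannot ship with a package.
* **Fixtures** — the published 30-subject ILF connection-index tables
  (dorsal / ventral / whole, left and right) as checksum-pinned CSVs,
  with `reproduce_tables()` recomputing every summary statistic they
  support.

I/O: NIfTI (`.nii.gz`) orientation fields and label atlases, TrackVis
`.trk` and MRtrix `.tck` streamlines (world-mm coordinates), CSV/JSON
tables and reports, JSON/YAML pipeline configs. A thin command-line
wrapper lives at `inst/cli/fascicle.R` (subcommands `phantom`, `track`,
`subdivide`, `reproduce-tables`, `run`).

## Worked example

Generate the two-hemisphere phantom (leftward asymmetry 1.17, noise-free),
track the left bundle, split it, and quantify:

```r
library(fascicle)

ds <- generate_phantom(ilf_phantom_config(asymmetry = 1.17, jitter_sd = 0,
                                          seed = 1))
ds$field
#> <orientation_field> 56 x 90 x 50 voxels @ 1 x 1 x 1 mm, K = 3
#>   voxels with >= 1 peak: 4819; with >= 2 peaks: 0

seeds <- seeds_from_mask(ds$bundle_masks$ILF_L, ds$field$voxel_size,
                         every = 2)
ilf_L <- track_bundle(ds$field, seeds, hemisphere = "L", name = "ILF_L")
ilf_L
#> <bundle> 'ILF_L': 1063 streamlines (s1, L, whole)
#>   length [mm]: min 20, median 74.2, max 76.8

split_dorsal_ventral(ilf_L, plane_roa(axis = 2, position = 62),
                     voxel_size = 1)
#> <subdivision_result> dorsal: 474, ventral: 589, gap: 22.52 mm

count_matrix(ilf_L, ds$atlas)$counts
#>   region_a region_b count
#> 1    ATL_L    OCd_L   413
#> 2    ATL_L    OCv_L   470
```

The tracked bundle connects the anterior temporal label to both posterior
occipital labels, and the subdivision separates the two branches (their
posterior endpoints sit 22.5 mm apart in z). Tracking the right bundle the
same way and comparing voxel-occupancy volumes gives 2.773 ml (left) vs
1.918 ml (right), i.e. `laterality_index(2.773, 1.918) = 0.365` — the
leftward dominance configured into the phantom (analytic LI for radius
ratio 1.17 is 0.31; the small excess is voxelization and curvature bias,
quantified in the vignette).

Recomputing the packaged tables' published statistics:

```r
head(reproduce_tables()[, c("statistic", "computed", "printed", "pass")])
#>                   statistic computed printed pass
#>         left_dorsal_mean_ci 14.76750   14.77 TRUE
#>           left_dorsal_sd_ci 26.13598   26.13 TRUE
#>   left_dorsal_n_connections  9.00000    9.00 TRUE
#>  right_dorsal_n_connections  7.00000    7.00 TRUE
#>        left_ventral_mean_ci 16.75929   16.76 TRUE
#>          left_ventral_sd_ci 25.79869   25.80 TRUE
```

All 20 statistics (means, SDs, medians, nonzero-connection counts, Welch
t = 3.07 / p = 0.004 and t = 1.64 / one-sided p = 0.053) reproduce at the
precision the rounded table cells support.

The end-to-end multi-subject simulation:

```r
res <- run_pipeline(pipeline_config(n_subjects = 3, seed = 1), "out/")
```

writes per-fascicle CI tables and connectograms, volume and lateralization
CSVs, a JSON quantification report, and provenance (config checksum +
seed); a rerun with the same configuration is byte-identical.

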