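# boundaryprofile

Surface-based analysis of diffusion metrics and T1 tissue contrast at the
cortical gray–white matter (GWM) boundary, for neuroimaging researchers
studying conditions — such as autism spectrum disorder — in which the GWM
transition zone is suspected to be "blurred".

## What it computes

Given per-subject white and pial surface meshes (FreeSurfer binary format)
and coregistered scalar volumes (MGH/MGZ or NIfTI) of fractional anisotropy
(FA), mean diffusivity (MD) and normalized T1 intensity, the package:

1. **Samples each metric at fixed cortical depths** at every vertex *i*:
   at the boundary, at projection fractions of 30% and 60% cortical
   thickness (CT) along the white→pial axis into the gray matter, and at
   absolute depths of −1 and −2 mm along the inward surface normal into
   the superficial white matter (trilinear interpolation in each volume's
   own voxel space).
2. **Computes the gray–white tissue contrast**
   `GWC_i = 100 (WMI_i − GMI_i) / (0.5 (WMI_i + GMI_i))`,
   with WMI the T1 intensity at −1 mm and GMI at 30% CT; lower GWC means
   a less distinct boundary.
3. **Smooths every analysis map on the mesh** with a heat-diffusion kernel
   calibrated to a target FWHM (default 15 mm).
4. **Fits a vertex-wise GLM**
   `Y_i = β0 + β1 Group + β2 Sex + β3 Group×Sex + β4 Site + β5 Age +
   β6 Age² + β7 FSIQ + ε_i`
   with effect-coded factors and mean-centered covariates, giving group
   and group-by-sex t-maps plus step-up nested-model F-tests.
5. **Corrects cluster-wise at p < .05 (two-tailed)** using random-field
   theory for nonisotropic images (cluster extents measured in resels from
   residual-based local FWHM), with a Freedman–Lane permutation test as a
   nonparametric cross-check.
6. **Quantifies spatial overlap** between the thresholded difference maps
   of GWC, FA and MD: vertex counts, overlap percentages, pairwise
   continuity-corrected χ² prevalence tests, and an empirical null from
   5,000 random difference maps thresholded at two-tailed p < 0.05.
7. **Cohort statistics**: Welch t and Yates-corrected χ² demographics
   tests, and Pearson correlations between cluster means and clinical
   questionnaire scores.

A synthetic-cohort generator (`synthetic_spec()`, `simulate_cohort()`,
`simulate_to_dir()`) produces template geometry, per-subject volumes with
sigmoidal tissue profiles, planted regional effects, spatially correlated
noise, and cohort tables with the full group × sex × site structure — so
the entire pipeline is testable without any imaging data.

## Worked example

```r
library(boundaryprofile)

spec <- synthetic_spec(n_per_cell = 3, mesh_extent_mm = 20, seed = 42)
cfg  <- pipeline_config(spec = spec, out = "bp_run", fwhm_mm = 8,
                        n_sims = 200, seed = 42)
run  <- run_pipeline(cfg)
cat(make_report("bp_run"))
```

The report for this 24-subject run prints (abridged):

```
Significant clusters (corrected p < alpha):
  significant:
    FA@-2mm        group        #1 negative n=3 peak t=-4.09 p=0.0197
    FA@boundary    group        #1 negative n=6 peak t=-4.14 p=0.0154
    FA@30%CT       group        #1 negative n=15 peak t=-4.32 p=0.0075
    GWC@boundary   group        #1 negative n=95 peak t=-6.58 p=0.0001

Overlap of significant between-group differences:
  GWC_vs_FA: |A|=95 |B|=6 inter=4 -> 66.67% ; chi2=86.6 p=1.34e-20 ; sim p=0.004975
```

The generator plants an FA reduction and a T1 gray-matter intensity
increase (hence a GWC reduction) in partly overlapping discs for the ASD
group: the pipeline recovers both as negative clusters, and the overlap
section shows that 66.67% of the FA-altered vertices also carry a GWC
alteration — far beyond the ~5% expected under spatial independence
(simulation p = 1/201 at 200 simulated map pairs).

Single stages are available directly: `build_depth_profile()`,
`compute_gwc()`, `smooth_vertex_map()`, `fit_vertex_glm()` /
`contrast_t()` / `nested_f_test()`, `estimate_smoothness()` /
`define_clusters()` / `rft_cluster_p()` / `permutation_cluster_test()`,
`overlap_analysis()`, `demographics_tests()`,
`cluster_clinical_correlations()`. A thin CLI wraps the common paths:

```sh
Rscript exec/boundaryprofile simulate --out data/ --seed 1
Rscript exec/boundaryprofile run --data data/ --out run/ --seed 1
Rscript exec/boundaryprofile report --out run/
```

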