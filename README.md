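# osmech

Optical-stretcher mechanophenotyping of single cells in R.

A dual-beam optical stretcher applies a contact-free step stress of order
1 Pa to a cell held in suspension and records its creep and relaxation by
phase-contrast imaging. Because circulating tumor cells (CTCs) adapt
mechanically to the blood stream, such low-force creep curves — rather than
surface markers — are a candidate, label-free way to tell CTC candidates
(CD45-negative, non-hematopoietic cells from patient blood) apart from
peripheral blood mononuclear cells (PBMCs). osmech implements the complete
analysis chain for this kind of experiment, for researchers in cell
rheology and biophysical cytometry:

* **Synthetic cohorts** with known viscoelastic ground truth
  (`synth_preset()`, `generate_cohort()`), including rendered frame stacks
  (`render_frames()`), so every stage is testable without instrument data;
* **Tracking**: sub-pixel contour detection and direct least-squares
  ellipse fits per frame (`detect_contour()`, `fit_ellipse()`,
  `trace_axes()`, `compute_morphology()`);
* **Rheology**: relative and elliptic deformation curves and
  passive/active Kelvin–Voigt fits. The cell is a spring `E` in parallel
  with a dashpot `eta` (`tau = eta/E`); the active model lets a
  contraction erode the applied stress at rate `a` (Pa/s):

  `gamma(t) = (sigma0/E) (1 - exp(-t/tau)) - (a/E) [t - tau (1 - exp(-t/tau))]`

  plus shape restoration `R = d(T) - d(T + 1.5 s)` and the active /
  non-active label at the 0.001 Pa/s threshold (`fit_kv()`,
  `shape_restoration()`, `classify_activity()`);
* **Features + classification**: a 46-feature per-cell matrix
  (`featurize_cohort()`), cross-validated random-forest discrimination
  with held-out permutation importances (`train_and_evaluate()`,
  `progressive_input()`);
* **Statistics and reporting**: two-sample Kolmogorov–Smirnov comparisons,
  median curves, fold enrichment, and a one-call pipeline
  (`run_pipeline()`).

See `vignettes/osmech-methods.Rmd` for the models, parameter defaults and
numerical choices.

## Worked example

Simulate a two-class cohort under the three-power clinical protocol
(400/800/1200 mW, 10 s stretch + 2 s relaxation), run the full pipeline and
inspect the result:

```r
library(osmech)
cfg <- synth_preset("clinical_like", n_per_class = 250)
rep <- run_pipeline(cfg, rf = rf_config(n_trees = 200, cv_repeats = 1, seed = 5),
                    seed = 5)
rep$summary$medians
#>     class_label rel_def_end ell_def_end    activity shape_restoration radius_um
#> 1 CTC_candidate 0.009486541  0.01155408 0.003816938       0.007759851  7.451825
#> 2          PBMC 0.014542598  0.02024405 0.016263106       0.005493176  4.739980
rep$ks[rep$ks$subset == "pooled", c("metric", "D", "p_value", "stars")]
#>              metric     D      p_value stars
#> 1       rel_def_end 0.168 1.724440e-03    **
#> 5       ell_def_end 0.260 9.150678e-08   ***
#> 9 shape_restoration 0.116 6.919033e-02
rep$classification$accuracy
#> [1] 0.948
head(rep$classification$importance$feature, 3)
#> [1] "area_um2"                          "radius_um"
#> [3] "fit_error_relative_first2s_active"
```

Reading this output: the PBMC-like class ends the stretch with roughly
twice the elliptic deformation of the CTC-like class (median 0.0202 vs
0.0116) while its relative deformation differs less — the Poisson effect
is the sharper discriminator. The CTC-like class restores more of its
shape within 1.5 s of relaxation (0.0078 vs 0.0055), and the pooled KS
tests flag both deformation contrasts as significant. The forest separates
the classes well, led by the cell-size features (area and radius are two
readings of the same measurement, so single-feature permutation
importances split the credit between them — see the vignette).

A thin CLI wrapper is included: `Rscript inst/scripts/osmech.R run --out
out/ --seed 1`.

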