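# fetalT2star

Quantitative T2* relaxometry of the fetal brain from multi-echo
gradient-echo MRI, for researchers studying functional brain development
in utero — in particular, cohort comparisons between fetuses that later
deliver very preterm (< 32 weeks) and term controls, where mean brain T2*
acts as an indirect proxy for tissue oxygenation and perfusion.

The package implements the full analysis chain as tested, reusable
components, together with a digital-phantom simulator so every stage can
be exercised and validated without clinical data:

1. **I/O** — multi-echo NIfTI-1 volumes with BIDS-style JSON sidecars
   (`EchoTime` in seconds, converted once to the internal millisecond
   unit), binary masks, fitted map sets, and per-subject cohort CSVs with
   validated invariants (e.g. funisitis ⇒ chorioamnionitis ⇒ histology
   available).
2. **Relaxometry** — voxel-wise fitting of the mono-exponential decay

   *S*(TE) = *S*₀ · exp(−TE / T2\*)

   by bounded nonlinear least squares in linear signal space, repeated
   from 10 random initialisations per voxel with the voxel-wise median of
   the converged estimates reported (T2\* and *S*₀ medianed
   independently). A closed-form log-linear fit (OLS of ln *S* on TE) is
   provided as an independent oracle.
3. **ROI statistics** — conservative margin via 6-connected morphological
   erosion, CSF exclusion by thresholding the fitted T2\* (default
   250 ms), then mean T2\*, adjusted Fisher–Pearson skewness
   *G*₁ = [√(n(n−1))/(n−2)] · *m*₃/*m*₂^{3/2}, and supratentorial volume.
4. **Cohort analysis** — quadratic regression of mean T2\* on gestational
   age (GA, GA²) with a preterm-group contrast and ethnicity adjustment;
   linear regression for volume and skewness; pooled *t* / chi-squared
   demographic comparisons; and outcome/histology percentage tables with
   the correct per-block denominators.
5. **Phantom & cohort simulator** — ellipsoidal brain/CSF phantoms with
   Rician noise (magnitude of complex Gaussian), a gestation-dependent
   tissue T2\* trajectory peaking near 22 weeks, a configurable preterm
   group offset, and two-group cohorts of 25 preterm vs 67 control
   subjects matching the reference study design.

## Worked example

```r
library(fetalT2star)

# a default 32^3 digital phantom at 3 mm isotropic, tissue T2* 160 ms,
# CSF 400 ms, Rician noise at first-echo SNR ~ 50
ph  <- makePhantom(phantomSpec(), seed = 1)
map <- fitMap(ph$series, ph$brainMask, fitConfig(seed = 1))
map
#> T2StarMap: 32 x 32 x 32 grid, 7568 fitted voxels
#>   T2* range: 136 - 497.4 ms (median 160.5)

roi <- applyCsfThreshold(map, erodeMask(ph$brainMask, 1), 250)
summarizeROI(map, roi, subjectId = "phantom-01", gaMri = 24.5)
#>  subject_id ga_mri mean_t2star  skewness  volume n_voxels ...
#>  phantom-01   24.5    160.6789 0.2742773 159.192     5896 ...
```

The ROI mean lands on the ground-truth tissue value (160 ms) after the
erosion margin and the CSF threshold have removed boundary and CSF
voxels; the volume is the voxel count times 27 mm³ in mL.

At cohort level, on a simulated summary table with the default −8 ms
preterm offset:

```r
tab <- simulateSummaryTable(cohortSimSpec(), seed = 1)
fitQuadraticGroupModel(tab)
#> Group model for mean_t2star: n = 92
#>   .y ~ ga_mri + I(ga_mri^2) + group + .eth
#>   group (preterm - control): -7.651 (SE 2.5), p = 0.003
```

The group coefficient estimates the simulated preterm–control difference
in mean T2\* (ms) after adjusting for gestation and ethnicity; its sign
and significance mirror the lower-T2\*-in-preterm direction the method is
designed to detect.

The packaged example cohort table reproduces a clinical outcome table's
percentages with their block denominators:

```r
tab <- readCohortTable(system.file("extdata", "preterm_outcomes.csv",
                                   package = "fetalT2star"))
summarizeOutcomes(tab)
#>             label            numerator denominator percent
#>  Chorioamnionitis                   17          21      81
#>  Funisitis                          15          17      88
#>  Respiratory distress syndrome      16          19      84   ...
```

A full simulate → fit → summarize → analyze run (file-based stages, YAML
config, provenance record) is one call — `runPipeline()` — or one shell
command via the thin CLI:

```sh
Rscript inst/scripts/t2star_pipeline.R run-all --seed 1 --out my_run
```

## Notes

- `inst/extdata/preterm_outcomes.csv` is **synthetic**: subject-level
  rows are fabricated so that the flag counts match a published outcome
  summary; it exists to exercise the table machinery, not to release
  data.
- The methods vignette (`vignettes/fetalT2star-methods.Rmd`) documents
  the model, the simulator's assumptions (and what passing tests do and
  do not show about real data), all tunable parameters, and the numerical
  choices in the fitter.
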