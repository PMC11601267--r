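# fwetract

Free-water-eliminated (FWE) tractometry for aging-brain diffusion MRI, in R.

White matter in aging brains — especially in regions of leukoaraiosis seen
as white matter hyperintensities (WMH) on FLAIR — contains excess free
water that dilutes the directional diffusion signal. That makes every stage
of a tractometry pipeline less reliable: voxelwise fiber orientation
distribution functions (fODFs), tract delineation, and along-tract tissue
profiles. This package implements computational free-water elimination and
a complete desk-scale tractometry pipeline around it, for methodologists
and imaging researchers who want to study, test or teach the approach
without access to a clinical cohort.

## The model

Each white-matter voxel is a two-compartment mixture ("bi-tensor" or
free-water DTI model):

```
S(θ, b) = S0 (1 − f) exp(−b θᵀQθ) + S0 f exp(−b D_iso),   D_iso = 3e−3 mm²/s
```

with tissue tensor `Q`, free-water fraction `f ∈ [0, 1]`, direction `θ`
and weighting `b`. Elimination subtracts the isotropic term:

```
S_fwe(θ, b) = S(θ, b) − S0 f exp(−b D_iso)
```

The package fits this model by per-voxel non-linear least squares on
multi-shell data (`fitFwdtiMultishell`) and by spatially regularized
gradient descent on single-shell data (`fitFwdtiSingleshell`), then
corrects the signal (`eliminateFreeWater`). Around the model it provides:

- acquisition handling: shells, FSL-style bvals/bvecs and NIfTI IO,
  single-shell subsampling, per-shell random split-half construction, and
  the neighboring-DWI-correlation (NDC) quality metric with
  mean − 2 SD exclusion;
- constrained spherical deconvolution fODFs on a frozen 362-vertex
  sphere, peak extraction, probabilistic tractography, ROI-based bundle
  selection, outlier cleaning and 100-node tract profiles;
- DTI/DKI/WMTI scalar maps (FA, MD, MK, AWF);
- split-half reliability statistics: per-voxel fODF explained variance
  (r²) with percent-increase summaries, weighted Dice between tract
  density maps, ICC(2,1) over profile nodes;
- WMH probability-map thresholding and periventricular/deep ROI
  categorization;
- cross-validated ordinal severity prediction from tract profiles (ridge
  multinomial logistic regression, 95%-variance PCA, repeated stratified
  5-fold CV), cumulative ROC curves and DeLong's test;
- synthetic phantoms and cohorts (`buildPhantom`, `simulateCohort`,
  `runReliabilityExperiment`) that emulate the reference acquisition
  (26 b=0 volumes; b = 500/1000/2500 s/mm² at 32/64/128 directions) so
  every stage runs without external data.

The pipeline enforces one wiring rule throughout (`runCondition`): in the
FWE condition, tractography is derived from the corrected signal, while the
tissue metrics sampled into profiles always come from the original signal —
keeping the tracking benefit without the metric bias.

## Worked example

```r
library(fwetract)

gtab <- makeGradientTable(acquisitionSpec(), seed = 42)
gtab
#> GradientTable with 250 volumes
#>   shells (b ~ n): 0 x 26, 500 x 32, 1000 x 64, 2500 x 128

# phantom with a free-water lesion (f = 0.5) in the bundle middle, SNR 30
phantom <- buildPhantom(phantomSpec(
  lesions = list(list(min = c(6, 1, 1), max = c(9, 12, 7), f = 0.5)),
  snr = 30, seed = 7), gtab)

fit <- fitFwdtiMultishell(phantom$dwi, mask = phantom$truth$wmMask)
fit
#> FreeWaterFit on 84 voxels; f median 0.061 [0.025, 0.531]; 100% converged
median(freeWaterFraction(fit)[phantom$truth$wmhMask])   # 0.51  (truth 0.5)
median(freeWaterFraction(fit)[phantom$truth$nawmMask])  # 0.054 (truth 0.05)

# split-half reliability of the fODFs, with and without FWE
split <- splitHalf(phantom$dwi, seed = 11)
tract <- phantomTractDefinition(phantom$truth)
rel <- reliabilityStudy(split, list(tract),
                        strata = list(wmh = phantom$truth$wmhMask,
                                      nawm = phantom$truth$nawmMask),
                        seed = 13)
rel
#> ReliabilityReport:
#>   voxel rows: 4  dice rows: 2  icc rows: 8
#>   summary:
#>             statistic stratum    value
#>  fodf_r2_pct_increase     wmh 1.316254
#>  fodf_r2_pct_increase    nawm 0.137814
```

The fitted free-water map recovers the lesion (f ≈ 0.51 against a truth of
0.5) and the summary shows the split-half fODF explained variance rising
under FWE, more in the lesion than in normal-appearing white matter — the
qualitative signature the method is built to produce.

A cohort-scale run — 20 synthetic subjects whose ordinal severity score
(2–6) drives lesion extent, with per-subject split-half reliability and
cross-validated score prediction under both conditions — is one call:

```r
ex <- runReliabilityExperiment(nSubjects = 20, seed = 1)
ex$summary          # percent-increase and weighted-Dice contrasts with SEM
ex$prediction$fwe   # PredictionReport: MAE, R², per-cut AUCs
```

A thin CLI over these functions ships in `inst/scripts/fwetract.R`
(subcommands: `simulate-phantom`, `simulate-cohort`, `split`, `qc-ndc`,
`fwe-fit`, `run-experiment`).

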