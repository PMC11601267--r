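---
title: "Free-water-eliminated tractometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-water-eliminated tractometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fwetract)
```

# The problem

Diffusion MRI tractometry quantifies tissue properties along major white
matter pathways. In aging brains, white matter — and especially regions of
leukoaraiosis visible as white matter hyperintensities (WMH) on FLAIR —
contains excess free water (CSF-like isotropic water). Free water dilutes
the directional diffusion signal, making fiber orientation estimates, tract
delineation and along-tract tissue metrics less reliable. `fwetract`
implements computational free-water elimination (FWE) for every stage of a
tractometry pipeline, a split-half framework that measures the reliability
benefit, and a cross-validated ordinal prediction analysis that measures
whether the benefit translates into better inferences about lesion
severity.

# The bi-tensor free-water model

In each white-matter voxel the signal for a gradient direction
$\theta$ (unit vector) at diffusion weighting $b$ (s/mm²) is modeled as a
two-compartment mixture:

$$S(\theta, b) = S_0\,(1 - f)\,e^{-b\,\theta^\top Q\,\theta}
              + S_0\, f\, e^{-b\,D_{iso}}$$

with $S_0$ the non-weighted signal, $Q$ a symmetric tissue diffusion tensor
(six free parameters, mm²/s), $f \in [0, 1]$ the free-water volume
fraction, and $D_{iso} = 3\times10^{-3}$ mm²/s the fixed diffusivity of
free water at body temperature (water self-diffusion at 37 °C is
$\approx 3\,\mu m^2/ms = 3\times10^{-3}$ mm²/s; the constant is sometimes
quoted in $\mu m^2/ms$ units, which differ by the $10^{-3}$ factor).

Free-water elimination subtracts the isotropic compartment:

$$S_{fwe}(\theta, b) = S(\theta, b) - S_0\,f\,e^{-b\,D_{iso}}
                    = S_0 (1 - f) e^{-b\,\theta^\top Q\,\theta},$$

clamping negative results at zero (`eliminateFreeWater()`).

## Multi-shell fitting

With two or more nonzero shells the model is well posed voxelwise.
`fitFwdtiMultishell()` minimizes the nonlinear least-squares residual of
the mixture model per voxel. Numerically it uses variable projection:
$S_0$ comes from the mean $b=0$ signal; for a candidate $f$ the corrected
signal is log-linear in $Q$, so the tensor has a closed-form least-squares
solution; a coarse grid then a Brent search minimize the residual over
$f \in [0, 1]$; finally a damped Gauss–Newton polish refines
$(\log S_0, f, Q)$ jointly. On noise-free mixtures the recovered $f$ is
exact to the search tolerance (~1e-7) and the tensor to ~1e-12 mm²/s.
Post-fit, tensor eigenvalues are clamped to $[10^{-5}, 2.5\times10^{-3}]$
mm²/s and $f$ to $[0, 1]$. All-zero voxels are flagged unconverged and get
$f = 0$ with an isotropic default tensor.

## Single-shell fitting

With a single shell the voxelwise problem is ill posed (trade-offs between
$f$ and tensor shape are weakly identified), so `fitFwdtiSingleshell()`
uses spatially regularized gradient descent. The free-water fraction is
initialized per voxel by interpolating the observed $b=0$-normalized mean
shell attenuation between a typical-tissue bound
($e^{-b \cdot 0.6\times10^{-3}}$) and the pure-water bound
($e^{-b D_{iso}}$), and is kept inside the per-voxel interval implied by
tissue diffusivities in $[0.1, 2.5]\times10^{-3}$ mm²/s. The tensor field
is initialized from the log-linear fit of the f-corrected signal (without
an intercept: at a single b-value an intercept is collinear with the tensor
trace) and refined by `nIter = 100` descent steps of size `step = 1e-3` on
unit-scaled parameters, with a first-difference smoothness penalty
(`regWeight = 1`) coupling the 6 tensor components of 6-neighbor voxels.
These are configuration defaults, not claims about any external
implementation. Consistent with known biases of single-shell FWE metrics,
the corrected signal is intended for orientation estimation and tracking,
not for tissue metrics.

# Condition wiring

`runCondition()` enforces the pipeline's central rule: in the `fwe`
condition, response estimation, constrained spherical deconvolution (CSD),
the FA stopping map and probabilistic tractography all consume the
FWE-corrected signal, while the DTI/DKI metric maps sampled into tract
profiles are always computed from the original signal. This keeps the
tracking benefit of FWE while avoiding metric bias from the correction
itself. Every stage's signal source is recorded in a provenance table and a
wiring violation is a hard error. In the `original` condition no corrected
volume is ever created.

# Fiber orientations and tracking

CSD deconvolves the diffusion-weighted signal by a prolate single-fiber
response estimated from high-FA voxels (`estimateResponse()`, threshold
0.7). The signal is first projected onto even real spherical harmonics per
shell (each shell capped at the order its direction count supports), and
the per-degree rotational response coefficients couple the shells. The
non-negativity constraint is iterative and hard: amplitudes on a frozen
362-vertex electrostatic-repulsion sphere below $\tau = 0.1$ of the mean
$l=0$ amplitude are driven to zero, with the constraint weight scaled to
the RMS of the forward operator; the active set usually stabilizes within
a few iterations (cap 50). `lmax` defaults to the largest order (at most
8) supported by the acquisition. The same frozen sphere discretizes fODFs
for reliability analysis (`discretizeFodf()`), so split-half correlations
are comparable across runs and machines.

`trackProbabilistic()` seeds 8 jittered start points per white-matter
voxel, tracks bidirectionally in 0.9 mm steps (half the 1.8 mm design
voxel), samples each step direction from the non-negative fODF amplitudes
within a 30° cone of the previous heading (amplitudes below 10% of the
voxel maximum are never sampled), and stops on leaving the volume or when
the stopping map — by default the FA of the tracking signal — falls below
0.2. Bundles are selected by ordered inclusion ROIs and exclusion ROIs,
cleaned by iteratively removing streamlines whose mean distance to the
node-wise median trajectory exceeds 5 SDs (computed leave-one-out, since an
inclusive z-score is bounded by $(n-1)/\sqrt{n}$ and could never reach 5
in bundles smaller than 27), and resampled to 100 arc-length-uniform
nodes. Tract profiles weight each streamline's node value by
$1/(d + 0.1\,\mathrm{mm})$ where $d$ is the node point's distance from the
node's median position; streamlines are orientation-normalized against the
bundle's first streamline so point-order reversal cannot scramble nodes.

# Reliability statistics

- **fODF explained variance**: per voxel, the squared Pearson correlation
  of the 362 discretized amplitudes between the two split-halves;
  summarized as the percent increase of the FWE condition over the
  original, $(r^2_{FWE} - r^2_{Orig})/r^2_{Orig} \times 100$, with
  subject-level SEM and a Wilcoxon signed-rank test.
- **Weighted Dice** between split-half tract density maps (visitation
  proportions): $\sum_{v \in A \cap B}(w_a + w_b) / (\sum_A w_a + \sum_B
  w_b)$.
- **ICC(2,1)**: two-way random effects, absolute agreement, single rater,
  over the 100 profile nodes of each tract and metric, treating the halves
  as raters. Computed from the ANOVA mean-squares decomposition and
  verified against an independent `aov()` oracle to 1e-10.

WMH handling follows the probability-map rule: voxels at or above 0.5 are
WMH; connected components use 26-connectivity; components within the
rim-dilated ventricle boundary are periventricular, others deep; the rim
("within 1 mm") converts to one voxel at the 1.8 mm design resolution by
ceiling division, which is the coarsest faithful reading of a sub-voxel
margin.

# Ordinal severity prediction

Tract profiles become a subjects × (tract × metric × node) matrix.
Within every training fold — never on the test fold — features are
z-scored, projected on principal components retaining 95% of variance, and
fed to a ridge-penalized multinomial logistic regression with class weights
inversely proportional to class frequencies; the penalty is tuned by an
internal stratified 3-fold CV over an 8-decade grid below
$\lambda_{max}$ (the default glmnet path stops far above the optimum for
well-separated data). The outer stratified 5-fold split repeats 20 times
by default. MAE uses the arg-max class; $R^2$ is computed on predicted
class values ($1 - SS_{res}/SS_{tot}$) — a pragmatic operationalization
for a classifier, stated rather than inherited. Cumulative ROC analysis
dichotomizes the ordered scores at each cut (low bin absorbing one more
class per step) with the summed high-bin probability as decision score;
AUCs are trapezoid-rule (equal to the Mann–Whitney statistic) and
condition comparisons use DeLong's test for correlated AUCs with midrank
placements.

# What the synthetic data emulate — and what they do not

`makeGradientTable(acquisitionSpec())` reproduces the reference
acquisition: 26 interleaved $b=0$ volumes plus shells at $b$ = 500, 1000
and 2500 s/mm² with 32, 64 and 128 electrostatic-repulsion directions (250
volumes). Phantoms place prolate tensor bundles
($\lambda = (1.7, 0.2, 0.2)\times10^{-3}$ mm²/s, FA 0.87) as cylinders in
a 1.8 mm isotropic grid; voxels outside tissue are pure free water; lesion
boxes elevate $f$; Rician noise (two Gaussian channels, magnitude) is
referenced to $S_0$ with SNR 30 by default. Cohort profiles are smooth
base curves depressed around mid-tract proportionally to an ordinal score
(2–6), plus node noise smoothed to a correlation length of about an eighth
of the tract — real tract profiles vary smoothly, and this is what makes
the z-score/PCA preprocessing behave as it does on real data.

The cohort-scale experiment (`runReliabilityExperiment()`) simulates 20
subjects on a 12×11×7 grid with a straight bundle of 3.6 mm radius; each
subject's score sets the along-tract extent of a focal, off-center lesion
with $f = 0.5$ at SNR 30, and every subject carries its own simulation,
split and tracking seeds. Problem sizes (grid, one tract, 5 CV repeats for
the experiment) are chosen so a full run takes a few minutes on one CPU.

Two desk-scale limitations matter for interpreting the experiment, and are
deliberate subjects of honesty rather than tuning:

1. **Tract delineation is much easier than in vivo.** With seeds in every
   bundle voxel, the selected streamlines cover essentially the whole
   bundle in both halves, so the split-half weighted Dice saturates near 1
   in both conditions and their difference is numerical noise around a
   tie. The in-vivo regime — sparse survivors in a large tract volume,
   where the original condition visibly loses reliability — is not
   reachable at this phantom size with full seeding.
2. **The stopping regime is not engaged.** With the reference tensor
   (FA 0.87) and $f = 0.5$, lesion FA stays far above the 0.2 stopping
   threshold in both conditions, so free water degrades fODF reliability
   (which the experiment reproduces with the right sign) without
   derailing tractography.

Consequently the experiment demonstrates the fODF-level reliability gain
robustly, while the tract-level (weighted Dice) and prediction-level
(ΔAUC) contrasts are ties up to noise at this scale: their expected
difference is approximately zero by construction, and the observed sign of
a single run is a coin flip. Passing or failing a sign check on those two
quantities at desk scale says little about real data either way; on the
real cohort the mechanism that separates the conditions (sparse, noisy
tract delineation through lesions) is present.

# Numerical choices

- Shell clustering: single-linkage with 100 s/mm² gap tolerance;
  $b \le 50$ s/mm² counts as $b=0$; an in-cluster spread above the
  tolerance is an "ambiguous shells" error.
- Odd split-half shells give the extra volume to half A.
- The NDC quality metric pairs each weighted volume with its most parallel
  neighbor (antipodally folded); ties break by smallest b-value difference,
  then volume index, so an exact duplicate beats a same-direction volume on
  another shell. $b=0$ volumes are excluded.
- Log-signal fits floor non-positive signals at $10^{-6} S_0$.
- Mean kurtosis averages the apparent kurtosis (clamped to $[-3/7, 10]$)
  over 180 repulsion directions; the quadrature error is below $10^{-3}$.
  The axonal water fraction uses the kurtosis-maximum construction
  $K_{max}/(K_{max} + 3)$ over the same direction set.
- Uniform fODFs return the lowest-index vertex as their single peak.
- All randomness flows through explicit integer seeds; phantom generation,
  splitting, tracking and cross-validation are bit-reproducible given the
  same seeds.

# Known limitations

- Single-shell FWE metrics are biased by construction; the package uses
  the corrected signal only upstream of tracking, as the wiring rule
  requires.
- The WMTI axonal water fraction assumes well-aligned white matter; in
  crossing voxels it is only an index.
- The 362-vertex sphere and SH conventions are frozen package choices;
  absolute reliability numbers depend on them, comparative (FWE vs
  original) statements do not.
- Atlas-based tract recognition is out of scope: tract definitions take
  subject-space ROI masks, with the 28-tract vocabulary shipped as data.
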