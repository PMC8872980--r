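---
title: "Mapping unbound drug transport across the blood-brain barrier with quantitative MSI"
author: "msiKpuu"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping unbound BBB transport with quantitative MSI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msiKpuu)
```

## The problem and the model

Only the unbound fraction of a drug crosses the blood-brain barrier (BBB)
and engages targets in brain parenchyma. The extent of unbound transport is
summarized by the unbound brain-to-plasma partition coefficient at steady
state,

$$K_{p,uu,brain} = \frac{C_{u,brain,ss}}{C_{u,plasma,ss}},$$

with $K_{p,uu} < 1$ indicating net efflux, $\approx 1$ passive transport,
and $> 1$ active uptake. Neither unbound concentration is directly
observable in a tissue image. The package therefore combines two
steady-state experiments on the same coronal level:

* an **in vivo** experiment (constant-rate intravenous infusion) giving the
  total tissue concentration $C_{tot,brain,ss}$;
* an **in vitro brain-slice** experiment (slices equilibrated in buffer at
  concentration $C_{u,buffer,ss}$) giving $C_{tot,slice,ss}$ and the unbound
  volume of distribution
  $V_{u,brain} = C_{tot,slice,ss} / C_{u,buffer,ss}$ (mL g$^{-1}$), which
  measures tissue binding and cellular uptake. When the slice amount still
  includes the adherent buffer film, the corrected form
  $(A - V_i C_u)/(C_u (1 - V_i))$ with $V_i = 0.094$ mL g$^{-1}$ applies;
  it reduces continuously to the ratio form as $V_i \to 0$.

Writing $C_{u,brain,ss} = C_{tot,brain,ss} / V_{u,brain}$ gives the central
identity used here: when the unbound plasma and buffer concentrations are
matched,

$$K_{p,uu,brain} = \frac{C_{tot,brain,ss}}{C_{tot,slice,ss}},$$

and per annotated region of interest (ROI),
$K_{p,uu,ROI} = CF \cdot C_{tot,ROI}^{vivo} / C_{tot,ROI}^{slice}$ with the
correction factor $CF = C_{u,buffer,ss} / C_{u,plasma,ss}$ when the two
differ. Because both totals are ratios of images acquired the same way,
matrix effects largely cancel. The reference route (the combinatory mapping
approach) computes the same quantity from bulk measurements as
$K_p / (V_u f_{u,plasma})$; `neuroPKTable()` reports both routes, and they
agree identically on consistent inputs — a property the test suite asserts
to $10^{-10}$.

## From ion images to concentrations

Quantitation follows standard on-tissue calibration practice:

1. **IS normalization** (`normalizeToIS`): the analyte image is divided
   pixelwise by the image of a sprayed deuterated internal standard.
   Pixels with IS intensity below 1% of the median on-tissue IS level are
   flagged invalid and excluded from region means (a guard against dead
   pixels; at the defaults it removes none).
2. **Tissue-equivalent standards** (`spotTissueEquivalent`): a spotted
   standard of concentration $c$ (ng mL$^{-1}$) and volume $v$ (nL) over a
   spot of area $A$ (mm$^2$) on a section of thickness $t$ and density
   $\rho$ mimics $c\,v / (A\,t\,\rho)$ ng per g tissue. With the default
   1.0-mm spot, 40 nL, 12 um and 1.027 g cm$^{-3}$, the lowest standard
   (25 ng mL$^{-1}$) converts to 103 ng g$^{-1}$, which is also the LLOQ.
3. **Curve fitting** (`fitCalibration`): linear least squares of mean
   normalized spot intensity on tissue-equivalent concentration. The
   default weighting is $1/x^2$: pixel noise is multiplicative, so
   residual variance grows with the square of the signal and an unweighted
   fit lets the top standard dominate, biasing the intercept and with it
   every estimate near the low standards. Acceptance requires a positive
   slope, regression F-test $p < 0.05$, and (for weighted fits)
   $R^2 \ge 0.99$. LOD is $3.3\,\sigma/S$ with $\sigma$ the standard error
   of the intercept; LLOQ is the lowest nonzero standard.
4. **Region quantitation** (`quantifyRegion`, `quantifySection`): the mean
   normalized intensity within the ROI is converted through the curve
   (ROI-mean first, then conversion — not per-pixel conversion and
   averaging). Negative estimates clip to zero and are flagged; estimates
   below the LLOQ are reported with a `belowLloq` flag rather than dropped,
   because the downstream ratio needs a value — the flag propagates into an
   `unreliable` mark on any $K_{p,uu}$ ratio that consumed it.
5. **Whole-section value**: computed on the tissue mask minus dilated
   calibration-spot footprints, and equal by construction to the
   pixel-count-weighted mean of the region and background values.

## Study design and aggregation

The packaged design mirrors a typical steady-state neuroPK study: six in
vivo animals (one section each) and three brain-slice replicates. Each
animal's regional concentration is divided by the mean slice concentration
of that region (animals and slices are unpaired), giving six per-animal
$K_{p,uu,ROI}$ values per region; their mean and SD feed a t-based 95%
interval used by `classifyTransport` (efflux if the interval lies below 1,
uptake above, passive if it covers 1; points without an interval within 0.1
of unity are indeterminate). $CF$ defaults to 1 and is applied only when
both bulk concentrations are supplied.

Statistics follow the conventions of such studies: a Shapiro-Wilk gate
(pass at $p > 0.05$), one-way ANOVA pooled error with two-sided
Dunnett-adjusted comparisons of each region against the whole-section
reference (adjusted p from the equicoordinate multivariate-t distribution,
computed by quadrature to $10^{-3}$), unpaired pooled-variance t-tests for
two-group method comparisons, and robust outlier flagging (median/MAD
z-scores with Benjamini-Hochberg control at $Q = 1\%$) as an open surrogate
for proprietary regression-based outlier removal. Default $\alpha$ is 0.01
for figure-level region comparisons and 0.05 elsewhere.

## The synthetic-section generator

No instrument data ship with the package; the generator provides the
ground truth every stage is validated against. Its forward model is the
steady-state theory itself: regional truths
$C^{vivo}_{ROI} = K_{p,uu,ROI} V_{u,ROI} C_{u,plasma,ss}$ and
$C^{slice}_{ROI} = V_{u,ROI} C_{u,buffer,ss}$ painted onto a stylized
coronal atlas (eleven regions: cc, ec, aca, CgCx, MCx, SCx, InCx, Pir, CPu,
NAc, LS) on an 80 x 100 px grid at a 100-um raster. Detection applies a
response factor per gram analyte, a smooth quadratic multiplicative gain
field *shared between the analyte and IS channels* of a section
(matrix/spray inhomogeneity — exactly what IS normalization is meant to
cancel, and a cancellation the tests verify to $10^{-12}$), lognormal
per-pixel noise (default CV 0.15), extra IS-layer heterogeneity (CV 0.05,
consistent with accepted runs keeping IS response RSD below 6%), and an
additive exponential background (mean 0.5 intensity units against analyte
signals of order 10-100).

Ground-truth parameters follow the published whole-brain values for the
three packaged antipsychotics — $K_{p,uu,brain}$ 0.10 (risperidone), 0.31
(clozapine), 0.82 (olanzapine); risperidone motor cortex 0.08 and piriform
cortex 0.12 — while the remaining regional values are constructed to match
the qualitative published picture (white-matter tracts with half the
gray-matter $V_u$, hence lower totals in both conditions; lateral septum
lowest for olanzapine; anterior commissure highest). Two parameters are
solved at construction so the printed constraints hold exactly under the
default atlas geometry: the unannotated-tissue $K_{p,uu}$ (making the
area-weighted tissue mean equal the whole-brain value) and the
insular-cortex $V_u$ (making the in vivo concentration excess exactly 1.3-,
1.2- and 1.5-fold). Unbound concentrations default to matched plasma and
buffer levels (CF = 1); risperidone's are set to 200 ng mL$^{-1}$ so in
vivo whole-section totals clear the 103 ng g$^{-1}$ LLOQ, mirroring the
raised risperidone dosing used for MSI sensitivity. Gray-matter $V_u$
defaults (8, 20, 15 mL g$^{-1}$) are plausible high-binding values; they
cancel in $K_{p,uu}$ and are free parameters.

One subtlety is documented rather than hidden: the whole-section
concentration ratio estimates a *binding-weighted* (area x $V_u$) mean of
regional $K_{p,uu,ROI}$, not the plain area-weighted mean. Under the
default geometry the two differ by less than 2%, well inside the
estimator's tolerance.

What the generator does **not** emulate: mass spectra and isotope patterns,
peak picking, spatial autocorrelation of pixel noise beyond the smooth gain
field, section-to-section registration error, and tissue-type ionization
suppression differences (a real phenomenon the cross-validation literature
attributes to sample preparation). Passing tests therefore demonstrate that
the estimator chain is correct and stable under realistic noise, not that
instrument data will meet the same error bounds.

## Numerical choices and degenerate inputs

* Coordinates are 1-based row-major matrices (R convention); pixel (i, j)
  covers a square of side `rasterStep` um.
* Exact-fit calibrations (residual sum of squares numerically zero) report
  $\sigma = 0$, LOD 0, $R^2 = 1$, F-p 0 rather than NaN.
* Curves with non-positive slope are rejected, never inverted.
* Empty masks (after invalid-pixel exclusion, or when spots tile the whole
  tissue) raise degenerate-input errors.
* Zero pooled variance makes Dunnett comparisons degenerate; the pipeline
  reports an empty comparison table with the reason instead of failing the
  run, because noiseless synthetic studies are legitimate inputs.
* All generator draws derive per-component subseeds deterministically from
  the master seed; identical seeds give bit-identical sections.
* Region atlas masks must be mutually disjoint and inside the tissue mask;
  disjointness is re-checked when an atlas is loaded from disk.

## Problem sizes

The packaged defaults (80 x 100 grid, ~5,000 tissue pixels, 6 + 3 + 2
sections per drug) run a full three-drug study in a few seconds and keep
the complete test suite, including a 2,000-replicate null simulation of the
Dunnett family-wise error rate, under a minute. These sizes were chosen as
the smallest at which the atlas regions remain multi-pixel structures and
the published sample design (n = 6 vs n = 3) is represented faithfully.

## Worked example

```{r example}
atlas <- defaultAtlas()
profile <- defaultProfiles()$risperidone
study <- simulateStudy(profile, noise = NoiseModel(), seed = 42)
curve <- calibrateSection(study$calibration, study$layout, "risperidone")
curve
ivq <- lapply(study$invivo, quantifySection, atlas = atlas,
              curve = curve, analyteId = "risperidone")
slq <- lapply(study$slices, quantifySection, atlas = atlas,
              curve = curve, analyteId = "risperidone")
map <- buildKpuuMap(ivq, slq)
map$table[, c("region", "kpuu", "sd", "transportClass", "unreliable")]
```

## Known limitations

* The spot-geometry assumption (1.0-mm disc) reproduces the risperidone
  LLOQ; published LLOQs for the other drugs imply slightly different spot
  areas, so per-spot areas are configurable.
* Saturable (concentration-dependent) BBB transport is out of scope; the
  correction-factor route assumes concentration independence.
* Brain metabolism and bulk-flow corrections are not modelled.
* The imzML reader is a minimal ingestion path (continuous or processed
  mode, externally stored 32/64-bit float arrays); it does no spectral
  preprocessing.
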