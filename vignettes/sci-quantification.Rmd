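---
title: "Quantifying silent cerebral infarction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying silent cerebral infarction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sciquant)
```

This vignette is the package's own account of its methods: the
quantification model and its assumptions, the tunable parameters and their
defaults, what the synthetic generators emulate (and do not), the numerical
choices, and known limitations. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## The quantification model

Silent cerebral infarctions (SCI) appear as focal white-matter
hyperintensities on FLAIR. The package assumes the human part of the
workflow has already happened: a radiologist has identified candidate
lesions and drawn one ROI per lesion (in phantoms, the generator plays this
role), and FLAIR/T1 volumes plus cortex / white-matter / ventricle masks
are co-registered on one voxel grid. Everything downstream is
deterministic:

1. **Cortex-referenced thresholds.** The cortical mean anchors both
   intensity criteria: voxels inside an ROI join the FLAIR lesion mask when
   `FLAIR >= m x mean(FLAIR | cortex)` and a lesion voxel is
   T1-hypointense when `T1 <= m x mean(T1 | cortex)`, with `m = 1.02` by
   default. Referencing cortex makes the criterion self-calibrating across
   participants and scanners; a lesion must be brighter than cortex on
   FLAIR, and no darker than "iso-intense to grey matter" on T1. Both
   comparisons are inclusive: the criterion is a boundary for inclusion,
   and keeping the boundary voxel makes the multiplier's effect monotone
   and auditable. The T1 criterion is applied only *within*
   FLAIR-surviving voxels (threshold order matters: T1 hypo-intensities
   outside the FLAIR mask are deliberately not captured).
2. **Clustering.** Surviving voxels are split into connected components
   (default 26-connectivity — faces, edges, corners — configurable to 6 or
   18). Because each ROI corresponds to one identified lesion, all
   components within an ROI are merged into a single lesion mask; the
   component count is retained for diagnostics. ROIs with no surviving
   voxel are recorded as non-surviving rather than dropped, so the
   attrition from "identified" to "quantified" is visible. A minimum
   surviving-voxel count is exposed (`min_voxels`, default 1).
3. **Definitions.** Liberal = any surviving voxel; Traditional = Liberal
   and caliper greatest dimension >= 3 mm (inclusive — "at least 3 mm");
   Restrictive = Traditional and >= 1 T1-hypointense voxel. The flags are
   nested by construction. Per-subject volumes follow the same nesting,
   with one deliberate asymmetry: the Restrictive volume sums only the
   T1-surviving voxels, because that subset is what the Restrictive
   criterion actually retains (and it is the only reading under which
   Restrictive volumes are far smaller than Traditional ones, as observed
   in practice). Raw voxel counts are emitted alongside mm^3 volumes.

### The caliper measurement

Manual "greatest dimension" is an on-screen ruler measurement, so the
package measures edge to edge: for the pair of voxels whose centres are
furthest apart, the dimension is the centre distance plus each end voxel's
half-extent along that line; a single voxel measures its own diagonal.
Five collinear 0.65 mm voxels therefore measure exactly 3.25 mm. A
centre-to-centre measure would shrink every lesion by about one voxel and
flip 3 mm boundary cases, which matters because the Traditional criterion
is exactly such a boundary. The default mode measures within single
coronal slices (the plane lesions are identified in) and takes the maximum
over slices; a `3d` mode uses all voxel pairs and is never smaller. The
slice axis defaults to the third array axis and is configurable.

### Regional topology

Adult absolute-distance rules (e.g. 10 mm to the ventricle) are avoided
deliberately in a paediatric-to-young-adult range; bands are instead
participant-specific percentiles of distance:

- periventricular: white-matter voxels within the 5th percentile of
  distance-to-ventricles (computed over white matter);
- juxta-cortical: of the remaining white matter, voxels within the 75th
  percentile of distance-to-cortex (quantile over the remaining voxels,
  matching the stated exclusion order; a flag switches the quantile domain
  to all white matter for sensitivity analysis);
- deep: the remainder.

Distance maps are Euclidean in millimetres and anisotropy-aware (the
separable lower-envelope distance transform, implemented in C++), since
slices are 1.0 mm against 0.65 mm in-plane. Distances on a lattice are
heavily tied, so percentile masks are rank-based: ties at the quantile
boundary are broken by voxel scan order, which keeps the band size at the
exact percentile rank and makes the partition deterministic. Raising the
juxta-cortical percentile can only move voxels from deep to juxta-cortical,
never the reverse.

Lesions take the band containing the strict majority of their FLAIR
voxels. Equal counts are surfaced as ties (`tie = TRUE`, region `NA`) and
excluded-with-flag from count-based summaries — in the source workflow
such ties went to a human adjudicator, and silently breaking them would
fabricate a label. Volumes, by contrast, are split across bands
(within-lesion overlap allowed), so band volumes sum to the lesion's
white-matter volume. The 12-zone bullseye crosses the three bands with
four lobes; lobe labels are metadata carried by the ROI (radiologist- or
generator-supplied), not derived from an atlas.

## The statistics battery

- **Cochran's Q** (own implementation; no base-R equivalent):
  `Q = (k-1)(k*sum(Cj^2) - N^2) / (k*sum(Ri) - sum(Ri^2))`, df `k-1`.
  All-constant rows leave the denominator zero, and Q is then defined as 0
  with p = 1. At k = 2 the statistic reduces to the uncorrected McNemar
  statistic, which the tests exploit as an oracle.
- **Friedman with Kendall's W** (own implementation to get average-rank
  tie correction, cross-checked against `stats::friedman.test` on
  tie-free data); `W = Q/(n(k-1))`.
- **2x2 chi-square** via `stats::chisq.test` with the Yates correction on
  by default (toggleable), `phi = sqrt(X^2/N)`.
- **Fisher's exact test** with the *conditional maximum-likelihood* odds
  ratio: the estimate solves `E[X | psi] = a` under the noncentral
  hypergeometric distribution (root-finding on `log psi`), which is the
  estimator exact-test software reports and differs from the sample
  cross-product ratio. Tables whose observed cell sits on the support
  boundary (a structural zero) have an unbounded estimate and are reported
  `NA` with a note. `stats::fisher.test` serves as an independent
  cross-check in the tests, never as the implementation.
- **Mann-Whitney U** with tie-corrected normal approximation
  (continuity-corrected p, matching common software) and effect size
  `r = |Z|/sqrt(N)` from the uncorrected Z; an exact mode computes the
  null distribution of U by dynamic programming (tie-free data only) and
  is checked against full enumeration.
- **Spearman screens** via `stats::cor.test`, flagged at p < 0.05
  *without* multiple-comparison correction — a deliberate
  sensitivity-maximising choice, so flagged pairs are screening output,
  not confirmatory findings.
- **Group-mean imputation** for sporadically missing hemoglobin/SpO2,
  with the imputation count recorded.

### The regression ladder

Six models per outcome x definition, adding lesion metrics stepwise:
presence; + presence x group; + log count; + both interactions; + log
volume; + volume interactions. Count and volume predictors are
`log(1 + x)` because zeros are ubiquitous among lesion-free subjects.
Interactions multiply the lesion metric by *mean-centred* group status,
with no group main effect added — the ladder estimates whether the lesion
metric's effect differs by group, not the group difference itself. Fixed
covariates: age, sex, intracranial volume, SpO2, education decile
(+ hemoglobin in patient-only runs). Continuous outcomes use OLS;
impairment (any index < 70) uses logistic regression. Variance inflation
factors come from `car::vif`; when a lesion term exceeds VIF 5 (or is
aliased outright), the binary indicator terms are dropped, the model
refitted, and the drop recorded in the report. Semi-partial correlations
for lesion terms use `sr = t * sqrt((1 - R^2)/df_res)`.

## What the generators emulate — and what they do not

**Phantoms** are nested ellipsoids: brain, a cortical ribbon
(2.5 mm), white matter, and a central ventricular ellipsoid, on a
96^3 grid at 0.65 x 0.65 x 1.0 mm by default (in-plane resolution finer
than slice thickness, as in a coronal 3D FLAIR acquisition). FLAIR shows
CSF dark and cortex brighter than white matter; T1 shows white matter
brightest. Lesions are uniform intensity plateaus
(`multiplier x cortical mean`) over approximately spherical white-matter
voxel sets — a sharp plateau keeps threshold behaviour analytically
predictable (a smooth-edge ramp exists but is off by default). The
generator chooses centres so that (i) the intended band holds a strict
majority of the realized voxels, (ii) the realized coronal caliper falls
on the same side of 3 mm as the target diameter, and (iii) lesions and
ROIs do not overlap; this is what makes ground-truth recovery a sharp
100% criterion rather than a fuzzy one. Lobes are octants of the
white-matter bounding box — a stand-in for the radiologist's lobe call.
Default noise is zero so the recovery tests are exact; Gaussian noise per
modality is available. The brain and ventricle proportions (0.92 of the
half grid extent; ventricles 0.16) were chosen so that all three bands are
thick enough to host 2–5 mm lesions with unambiguous band majority.

Phantoms deliberately do **not** model: realistic anatomy or cortical
folding, bias fields, partial-volume ramps (by default), registration
error, or lesion-mimics such as perivascular spaces. Passing recovery
tests therefore demonstrates that the *pipeline logic* (thresholds,
clustering, measurement, classification) is correct, not that the
thresholds are robust to real-world intensity artefacts — that robustness
came from the human-in-the-loop ROI step the package assumes upstream.

**Cohorts** emulate the statistical structure the analysis assumes: two
groups (106 patients, 48 controls by default), nested lesion status drawn
by comparing one uniform variate against the three nested prevalences
(guaranteeing monotone rows), zero-truncated negative-binomial lesion
counts and log-normal volumes given presence (thinned down the nesting),
Gaussian cognition with configurable group means/SDs (defaults: patients
93.15/13.28 IQ, 92.04/14.18 WMI, 89.56/12.99 PSI; controls 97.29/11.78,
98.90/13.34, 97.10/13.03), an injectable linear lesion effect on
`log(1 + Liberal volume)` (default 0), plausible covariate distributions,
and sporadic missingness in hemoglobin (patients) and SpO2 (controls).
Impairment arises from the same Gaussian distributions via the < 70
cut-off; there is no separate impairment process.

### Null calibration design

The type-I-error simulation for the ladder's lesion term sets the lesion
effect to zero *and* equalises cognition means across groups. With
unequal group means, lesion presence is marginally associated with
cognition through group membership (prevalence differs by group, and
Model 1 carries no group main effect), so rejections of the lesion term
would reflect real confounding rather than test miscalibration. Equalising
the means isolates the property under test: with no true association
pathway, the lesion term must reject at the nominal 5% rate.

## Numerical choices

- Voxel indices are 1-based array indices; all distances and dimensions
  are in mm; voxel volume is the product of spacings.
- The distance transform is exact (algebraically, not approximately) and
  verified against brute-force nearest-target search on small grids.
- Quantile ties: rank-based band selection with scan-order tie-breaks
  (above).
- Region ties: surfaced, never broken.
- Degenerate inputs: empty cortex masks, empty distance targets,
  zero-margin 2x2 tables, all-missing imputation groups and
  under-determined regressions raise errors naming the problem;
  all-constant Cochran rows and fully tied Friedman rows return the
  defined degenerate statistic (0, p = 1); the regression battery captures
  per-model failures as error reports instead of aborting.
- Determinism: a phantom or cohort spec plus its seed reproduces outputs
  bit for bit; pipeline runs serialize their configuration and seed.

## Problem sizes used by the test suite

The suite exercises: 50 randomized recovery phantoms at 96^3 with four
lesions each spanning {2 mm, 5 mm} x {T1-hypointense, T1-normal} x three
bands; 2,000 simulated null cohorts of n = 154 for the calibration check
(binomial 95% band around 0.05); 500 cohorts of n = 500 for recovery of an
injected −5-points-per-log-unit volume effect; exhaustive oracles on
grids <= 15^3 (distance maps), 10 x 3 matrices (Cochran), and n = 6–7 per
group (Mann-Whitney enumeration). These sizes were chosen as the smallest
that make the checks sharp: recovery is all-or-nothing per lesion, and the
Monte-Carlo bands are tight enough to detect a miscalibrated test.

## Known limitations

- Candidate ROIs are required input: the package quantifies identified
  lesions, it does not detect them.
- Lobe assignment is metadata passthrough, not atlas parcellation.
- The juxta-cortical 75th-percentile convention makes "deep" the thinnest
  band (roughly a quarter of non-periventricular white matter); both
  percentiles are configurable, and the quantile-domain flag supports
  sensitivity analyses.
- The maximum-corrected concordance effect size sometimes reported
  alongside Cochran's Q has no agreed formula and is not implemented;
  `Q/(n(k-1))` is reported instead and labelled as such.
- Exact Mann-Whitney p-values are limited to tie-free data; tied data use
  the tie-corrected normal approximation.
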