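---
title: "Methods: BBB leakage hotspot mapping and colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BBB leakage hotspot mapping and colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bbbhotspots)
```

## The model

Dynamic contrast-enhanced MRI tracks the tissue concentration of a
gadolinium tracer over time. In tissue with an intact or mildly leaky
blood–brain barrier, the Patlak graphical model describes the tissue curve
as a plasma compartment plus irreversible uptake:

$$C_t(t) = v_P\,C_p(t) + PS \int_0^t C_p(\tau)\,d\tau$$

with two assumptions: cerebral blood flow is high relative to the leakage
rate, and backflux of tracer from tissue to plasma is negligible over the
acquisition. Under them, regressing $C_t$ on the two columns
$[C_p(t), \int C_p]$ with no intercept gives $v_P$ (fractional plasma
volume, dimensionless) and $PS$ (permeability–surface-area product, min⁻¹).
`fit_patlak_voxel()` and `map_patlak()` implement exactly this ordinary
least-squares fit; since every voxel shares one design matrix, a whole map
is a single normal-equations solve.

Two modelling commitments follow from the estimator, not from convention:

* **No clamping.** White-matter $PS$ is of order $10^{-4}$ min⁻¹, close to
  zero relative to noise, so the fit legitimately produces negative
  estimates — whole-arm mean NAWM PS can be negative in real cohorts. The
  package preserves signs everywhere and exposes QC counts instead of
  truncating.
* **No backflux term.** A two-parameter Patlak fit, not extended Tofts; the
  method targets low-leakage white matter where backflux is not
  identifiable at these acquisition lengths.

The fit window defaults to all post-arrival frames. Pre-arrival frames are
all-zero design rows and contribute nothing to the normal equations either
way; excluding early bolus frames is exposed via `frame_window` but off by
default.

## Analysis rules and their parameters

| Parameter | Default | Meaning |
|---|---|---|
| `fraction` | 0.10 | upper tail of the per-patient PS distribution defining hotspot voxels |
| `min_size` | 5 voxels | minimum cluster size for a hotspot |
| `connectivity` | 26 | contiguity rule for clusters |
| erosion kernel | 3×3×3 cube | one-voxel erosion of the WM analysis mask |
| `band_radius` | 1 voxel | WMH contact band thickness |
| `contact_radius` | 2 voxels | contact band for lacunes and CMBs |
| `nawm_fraction_threshold` | 0.10 | minimal-NAWM exclusion for the WMH subgroup |
| regional load cut-offs | 1 / 3 / 6 | counts mapping to low / medium / high |

The threshold is *relative* (nearest-rank decile per patient), which makes
hotspot extraction invariant under any strictly monotone transform of the
PS map and robust to inter-individual PS scale differences. With $N$ mask
voxels, $k = \mathrm{round}(0.1N)$ and the threshold is the $k$-th largest
value; ties at the threshold are all included, so an all-constant map
degenerates to selecting the whole mask (flagged in the QC output, not an
error).

"One voxel-kernel erosion" is read as the full 3×3×3 (26-neighbourhood)
structuring element — the word *kernel* suggests the cubic brush — with the
6-neighbourhood cross available via `kernel = "cross"`. The erosion is
applied to WM ∪ WMH: hotspots can occur *within* WMH, so WMH must lie
inside the analysis mask. "Contiguous" is read inclusively as
26-connectivity; 6-connectivity is a config value and exercised in tests.

**Contact bands.** A lesion's outer band is its 26-neighbourhood dilation
minus the lesion. For cavity lesions this package defaults the contact band
to radius 2 rather than 1, and that choice is forced by geometry, not
taste: hotspot voxels live inside the one-voxel-eroded WM mask, and every
voxel of a cavity's radius-1 band is adjacent to non-WM, which the cubic
erosion removes — so a radius-1 contact rule can never fire. Radius 2 is
the literal meaning of "direct contact across the eroded margin". The WMH
band stays at radius 1 because WMH is inside the analysis mask.

**Within vs at the WMH edge.** *Within* requires every hotspot voxel inside
the WMH mask; any partial overlap is *at the edge*. Full containment makes
the two categories mutually exclusive per hotspot, matching their separate
reporting; a majority-containment alternative is plausible (intra-rater
agreement for these categories is only substantial in human readings,
suggesting borderline cases) and the rule is config-exposed.

**Subgroups.** A patient enters the lacune/CMB analyses when a lesion
centroid lies in deep white matter. Because lesion interiors are carved out
of the WM mask, the test fills lesion interiors back into the mask before
eroding; otherwise no centroid could ever qualify. The WMH subgroup needs
more than minimal WMH (deep Fazekas > 0 or periventricular Fazekas > 1) and
at least 10% NAWM remaining — the published rule gives no number for
"minimal NAWM left", so 0.10 is this package's config value.

**Regional load.** Hotspot counts per region and side map to
0 (absence), 1 (1–2), 2 (3–5), 3 (≥ 6), summed left+right to 0–6. The
defining source for these cut-offs is not public; these are the package's
own convention, recorded in the output attributes so downstream users see
them.

**Region assignment** is a majority vote of the hotspot's atlas codes with
ties broken toward the lowest code, and component labels follow raster-scan
order — both choices exist purely so outputs are bit-reproducible.

## Statistics layer

Descriptive tables follow clinical reporting conventions: mean (SD) for
normal continuous variables, median (IQR) for ordinal or non-normal ones,
n (%) for binaries. Normality triage uses a Shapiro–Wilk check at
α = 0.05 (the convention source does not name its criterion). Group
comparisons: Student t / ANOVA or Mann–Whitney / Kruskal–Wallis as
appropriate; Pearson chi-square, switching to Fisher's exact test when any
expected cell is below 5; Spearman correlation for ordinal–ordinal pairs.
Constant variables return an explicit "not applicable" marker.

Candidate covariates pass a strict p < 0.1 univariable screen, with the
vascular function measures (PS, vP, CVR) always added. The presence of
colocalized hotspots is modelled by logistic regression, their number by a
proportional-odds ordinal model (`MASS::polr`; the link is an assumption,
labelled in the output). Counts above the cohort's 90th percentile are
collapsed into one top category before the ordinal fit — sparse extreme
levels otherwise destabilize the threshold estimates. Model 1 adjusts for
age, log₁₀ normalized WMH volume, lacune count and CMB count; model 2 adds
SVD type. Missing CVR is handled complete-case per model and the n used is
always reported; separation and non-convergence raise flags on the result
object rather than silently returning estimates. VIFs are computed from
their definition, $1/(1-R_j^2)$, on the model's design matrix, with VIF < 5
acceptable and exact dependence marked infinite. Intervals are Wald 95% CIs
on the log-odds scale; no multiple-testing correction is applied, matching
the analysis style the package reproduces.

Weighted kappa uses linear disagreement weights $w_{ij}=|i-j|/(k-1)$ over
the shared category set; quadratic weights are available. Fewer than two
distinct categories is an explicit undefined-kappa error (the degenerate
"100% agreement on one category" case).

## The synthetic cohort generator

The generator exists so that every stage has a ground truth. It emulates:

* **Geometry** — nested ellipsoids (cortex, WM), paired ventricles, a
  brainstem cylinder, a cerebellum, and a left/right six-region WM atlas
  (cerebellum, internal capsule, temporal, anterior/posterior horn WM,
  centrum semiovale). Lacunes are CSF-filled cavities strictly inside WM,
  WMH blobs grow from periventricular (and some deep) seeds, CMBs are 1–2
  voxel spheres in NAWM.
* **Signal** — piecewise-constant $PS$/$v_P$ baselines per tissue class
  with planted high-PS foci attached to lesion geometry, a population
  biexponential vascular input function (amplitudes 4 and 1.5 mM, decay
  rates 0.05 s⁻¹ and 8×10⁻⁴ s⁻¹, arrival 30 s, no hematocrit correction),
  and i.i.d. Gaussian concentration noise (default SD 0.002 mM, chosen so
  single-voxel PS standard errors are a fraction of the between-subject SD
  seen in white-matter cohorts). Synthesis happens directly in
  concentration space: the contribution starts at PS estimation, so
  T1-signal modelling is out of scope. The DCE grid defaults to 24 s
  spacing over about 20 minutes — a typical low-temporal-resolution
  permeability protocol; the true grid of any given study is
  config-exposed, not asserted.
* **Cohort structure** — a two-arm design (sporadic vs CADASIL ≈ 0.39)
  whose covariate defaults reproduce published arm profiles: CADASIL
  younger, fewer vascular risk factors, heavier lesion load, lower NAWM
  PS/vP, lower WMH CVR. Fazekas grades map monotonically from WMH volume;
  PVS grades are sampled scalars (no PVS geometry). CVR values are sampled
  covariates — BOLD processing is out of scope — and are missing at random
  in ≈ 9% of patients, mirroring real missingness, never imputed.
* **Planted effects** — logistic (presence) and log-linear (count) effects
  on *standardized* covariates, standardized with fixed design constants so
  the planted log-odds are exact rather than sample-dependent. The default
  plants lower WMH CVR → more lacune-edge hotspots and higher WMH volume →
  more hotspots within/at WMH edges. In imaging mode the same count models
  drive how many foci are planted at each attachment.

What it does **not** emulate: MR signal/relaxometry physics, motion or
registration artefacts, partial-volume effects, spatially correlated noise,
realistic lesion shapes beyond clipped balls, or gray-matter analysis
(excluded from the method for partial-volume reasons). Passing tests
therefore validate the *analysis logic and its statistical guarantees*, not
acquisition robustness.

## Numerical choices and degenerate inputs

* Patlak designs with `rcond` below machine epsilon raise a singular-fit
  error; voxels with non-finite concentrations are dropped from the fit
  mask and counted, never imputed.
* Noise-free forward/inverse consistency is tested to relative error
  < 1e−8; the estimator is exactly linear in the tissue curve.
* Empty ROIs error by name ("empty ROI: WMH"); empty hotspot sets are
  valid results (count 0), not errors.
* Configuration validation reports all problems in one message and rejects
  unknown keys.
* Every stochastic operation takes an explicit seed and restores the
  caller's RNG state; pipeline outputs are byte-identical for identical
  config + seed (content-hashed in the run manifest).

## Problem sizes

Tests and the acceptance script run at desk scale: 40³–48³ phantoms
(2 mm voxels, ≈ 7–12 k analysis-mask voxels), 21–51 DCE frames,
threshold-fidelity checks on 10⁵-voxel maps, 500-replicate Monte-Carlo bias
checks, 20-patients-per-arm planted-structure comparisons, and 100
replicates of n = 200 cohorts for regression sign recovery and null CI
coverage.

One desk-scale caveat deserves emphasis: in a 40³ phantom, three lacunes'
contact bands cover a few percent of the analysis mask, so chance contact
between noise-driven hotspots and lacunes is far more common than in a
full-resolution brain, where the same bands cover a fraction of a percent.
The planted-structure check is therefore *relative* — cohorts with foci
planted at lacune rims must show a higher fraction of lacunes with hotspots
than matched cohorts with randomly placed foci — rather than a comparison
against the absolute colocalization percentages reported from patient
cohorts, which also depend on brain-scale geometry.

## Known limitations

* The proportional-odds link for count outcomes is an assumption; the
  package labels it but offers no alternative ordinal link.
* The ICV definition (all non-background intracranial labels including
  CSF) is the standard one but matters only through WMH normalization.
* Cerebellar white matter is inside the analysis mask by default
  (`include_cerebellum = FALSE` requires the atlas) — the regional
  vocabulary includes the cerebellum, but whether it belongs in the
  permeability mask is genuinely ambiguous.
* Real-data ingestion expects co-registered label volumes; no registration
  is performed.
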