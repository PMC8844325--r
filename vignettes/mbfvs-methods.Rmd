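---
title: "Vessel-specific myocardial blood flow from dynamic PET: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vessel-specific myocardial blood flow from dynamic PET: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Standard myocardial perfusion quantification reports blood flow (MBF, in
mL/min/g) over coarse vascular territories. `mbfvs` implements a
finer-grained alternative: flow sampled in small regions of interest (ROIs)
that follow a coronary artery's 3D path from the base to the apex of the
heart, producing a *vessel-specific* flow profile, MBF^vs. The profile can be
compared point by point against ranges derived from low-risk subjects to
flag the location of flow-limiting lesions.

The pipeline needs two inputs that live in different spaces: dynamic
13N-ammonia PET (the flow signal) and CT-derived anatomy — binary masks of
the LV blood pool, RV blood pool and the biventricular epicardial envelope
(EPI), plus coronary centerlines. The central empirical question the package
is built to study is *robustness*: how much do the flow profiles and their
normal/abnormal classification change when the anatomy driving the fusion
comes from an automated segmentation (FA), or from a briefly corrected
automated segmentation (C), instead of careful manual delineation (M)?
Because the patient images behind that question are not public, the package
ships a digital cardiac phantom and reruns the M/FA/C comparison end to end
at desk scale.

## The kinetic model

Tissue tracer kinetics follow the irreversible two-tissue compartment model
conventional for 13N-ammonia:

$$\frac{dC_1}{dt} = K_1 C_a(t) - (k_2 + k_3)\,C_1,\qquad
  \frac{dC_2}{dt} = k_3\,C_1,$$

with measured activity $(1 - v_b)(C_1 + C_2) + v_b\,C_a(t)$. $K_1$
(mL/min/g) is reported as MBF with no extraction-fraction correction — a
configurable hook exists but defaults off, because the clinical pipeline the
package mirrors reports the model output directly. There is no $k_4$
(irreversible trapping) and no metabolite correction of the input function.

The ODEs are solved on a uniform fine grid (default 0.5 s) with an
exponential integrator that is exact for piecewise-linear $C_a$, implemented
in C++ (`src/morph.cpp`); frame values are trapezoid duration-averages, so
the forward model predicts exactly what a frame measures.

**Fitting.** `fit_kinetics()` minimizes duration-weighted least squares with
L-BFGS-B inside fixed bounds ($K_1 \in [0,6]$, $k_2, k_3 \in [0,3]$,
$v_b \in [0,0.6]$, init $(0.8, 0.3, 0.1, 0.3)$), optionally polished by
Nelder-Mead. All fits are deterministic given the data. Bulk profile fitting
(hundreds of ROIs) uses the unpolished path at a 1 s step: on noise-free data
this is still accurate to ~0.02% in $K_1$, and about five times faster.
Whether $v_b$ is fitted or frozen is a flag (`fit_vb`), fitted by default.

## The digital phantom

`phantom_spec()` states the simulated world once; nothing in it is derived
from test outcomes:

* **Grid**: 96³ voxels at 2 mm isotropic. The clinical pipeline works on a
  512³ short-axis volume; the phantom preserves the geometry ratios at a
  size where the full experiment runs in minutes.
* **Anatomy**: the LV is a half-ellipsoid cavity (radius 16 mm, base-to-apex
  70 mm) cut at the base plane; the epicardium is the exact 10 mm
  morphological dilation of the blood pools (exact Euclidean distance
  transforms, thinner — 4 mm — over the RV free wall); the RV is an
  ellipsoid crescent against the septum. Myocardium = EPI minus blood pools.
* **Territories**: the myocardial shell is partitioned into LAD (anterior),
  LCX (lateral) and rPDA (inferior) territories by geodesic nearest-seed
  labelling (multi-source Dijkstra inside the shell). The source study uses
  anatomic territories without defining boundaries; nearest-seed geodesics
  are the package's convention.
* **Flows**: rest 0.8, stress 2.4 mL/min/g in all territories — typical
  ammonia literature values for normal myocardium; per-phantom population
  spread is added in experiments as a Gaussian multiplier (CV 0.15,
  truncated at 0.3), a realistic between-subject flow variability. Lesions
  are arc-length intervals along a vessel with stress flow scaled down.
* **Tissue rates**: $k_2 = 0.4$, $k_3 = 0.1$ /min, $v_b = 0.3$, constant
  across rest and stress. Real $k_2$ rises somewhat with flow; holding it
  fixed keeps the truth maps interpretable and does not affect the
  comparisons the package makes (both arms of every comparison share it).
* **Input function**: gamma variate $A (t - t_0)^{\alpha} e^{-(t-t_0)/\beta}$
  with $t_0 = 10$ s, $\alpha = 3$, $\beta = 8$ s (peak at 34 s, peak
  amplitude normalized to 100 kBq/mL) plus a 15% recirculation tail with a
  20 min clearance — a plausible dispersed venous bolus.
* **Noise**: Gaussian, zero-mean, $\sigma = \texttt{noise\_scale}
  \sqrt{\text{activity}/\text{duration}}$ per voxel and frame
  (scaled-Poisson surrogate; reconstruction physics is out of scope),
  `noise_scale = 1` by default, fully seeded.
* **Schedules**: the two clinical list-mode binnings are built in:
  `"SNUH"` (12×10 s, 6×30 s, 2×60 s, 1×180 s; 600 s) and `"SMC_CNUH"`
  (12×5 s, 6×10 s, 3×20 s, 6×30 s; 360 s).

**Segmentation defects** (`perturbation_spec()`) emulate what automated CCTA
segmentation gets wrong in practice: truncated apical coverage (the most
common automated failure), RV over-segmentation into the liver, smooth
boundary jitter, and merged septal borders. The jitter field's *shape*
depends only on the seed, never on the amplitude, so component-wise larger
specs produce pointwise-nested defects — the monotonicity property the
robustness experiment relies on.

What a green test does **not** establish: the phantom has no cardiac or
respiratory motion, no attenuation/scatter physics, no partial-volume blur
beyond the voxel grid, no CT contrast appearance, and its noise is Gaussian
rather than reconstructed-Poisson. Conclusions transfer to the algorithmic
pipeline, not to scanner physics.

## Fusion

PET_sum is the duration-weighted sum of the frames whose start time lies at
or past the midpoint of the acquisition ("second half"); a frame straddling
the midpoint is included only if its start is past it — whole-frame
selection avoids partial-frame weighting that is otherwise unspecified.

Registration is rigid and proceeds in two stages, mirroring the clinical
chain:

1. **Blob initialization.** The left heart is segmented from PET_sum at half
   maximum (largest 6-connected component, ties broken toward the lowest
   voxel index, holes filled). On ammonia PET_sum this captures the filled
   left-heart envelope — cavity plus myocardium — so its CT counterpart in
   the overlap stage is the *filled epicardial envelope*, not the bare blood
   pool. Centroid plus principal-axes candidates (all four proper sign
   combinations) seed a Nelder-Mead refinement of mask Dice at 4 mm.
2. **Mutual-information refinement.** 32-bin joint-histogram MI between
   PET_sum intensities and a 4-level labelled rendering of the anatomy
   (background / myocardium / LV / RV), over two resolutions with the PET
   block-averaged at the coarse level. A deterministic ±18° angle-grid scan
   precedes the simplex (the principal axes of the PET blob and the CT
   envelope genuinely differ by up to ~15°, and the MI peak is only a few
   degrees wide), and coordinate-wise line searches polish the result. The
   stage never returns a transform whose metric is below its input's.

Two numerical choices matter enough to name. First, all optimization is
parameterized as *rotation about the anatomy centroid*: about the world
origin, one degree of rotation also drags the heart by ~2 mm per 100 mm of
lever arm, which couples angles to translation and defeats simplex search.
Second, every optimizer is deterministic (fixed starts, caps, and grid
scans; no stochastic sampling), so identical inputs give identical
transforms bit for bit.

Transforms map CT world coordinates into PET world coordinates and are
stored as ZYX Euler angles (degrees) plus translation in a JSON sidecar.

## Vessel ROIs and profiles

The fused centerline is walked base to apex in 4 mm arc-length steps; each
step's sampling element is a 4 mm axis-aligned cube. The study fixes only
the longitudinal size; cubes with equal transverse extent are the literal
reading, and members are clipped to the myocardium by default
(`clip_to_myocardium = FALSE` restores pure cubes) to avoid blood-pool
contamination. Cube centres snap from the epicardial centerline to the
nearest *mid-wall* voxel by minimizing (distance to the sample point minus
myocardial depth), which keeps thin-wall ROIs inside tissue; membership is
voxel-centre-in-half-open-cube, so it is unambiguous. ROI positions are
$(i - \tfrac12) \times 4$ mm regardless of the masks, which is what makes
profiles from different mask pedigrees comparable point by point.

A step with no myocardial voxels within 15 mm is an error naming the arc
position — the signature of gross misregistration. In the experiment runner
trailing empty steps are instead truncated (`on_empty = "truncate"`),
because apex-truncated FA masks legitimately end earlier; interior gaps
still error.

The arterial input is sampled from the LV cavity eroded by 4 mm (spill-in
control). Per-ROI TACs are unweighted voxel means; profile values are the
fitted $K_1$ per ROI, and the continuous curves through the markers use
monotone (Fritsch–Carlson) piecewise-cubic interpolation.

## Classification and agreement

Normal ranges are per-position bands, `mean ± k_sd · SD` (default
`k_sd = 2`, clipped below at zero) over low-risk profiles resampled to a
common grid — a convention; the clinical ranges' exact construction is
external to this package. In experiments the band comes from 15 simulated
low-risk phantoms, matching the size of the clinical low-risk cohort.

A ROI value is *abnormal* iff it falls strictly below the interpolated lower
bound; a value at the bound, or above the upper bound, is *normal* — the
dichotomy is "within the range versus below the range". Decreasing a value
can therefore never turn an abnormal label normal.

Two Dice readings are implemented and both are reported:

* **matched-fraction** (default): $DC = 2m/(n_a + n_b)$ with $m$ the number
  of positions with identical labels — with equal lengths this is the
  matched fraction, the reading under which fully-normal vessel pairs score
  1.00;
* **abnormal-set**: classical set Dice over the abnormal index sets, defined
  as 1 when both sets are empty.

Pooling always recomputes DC over concatenated ROI samples (never a mean of
per-vessel DCs), globally and per territory, rest and stress separately.
Group comparisons use two-sided Student's t tests — paired when the same
vessels underlie both groups (the two-user corrected-mask comparison),
unpaired pooled-variance otherwise, with explicit handling of zero-variance
degenerate inputs; no multiple-testing correction is applied.

## The mask-robustness experiment

`run_mask_comparison_experiment()` draws seeded phantoms, simulates rest and
stress series, builds FA/C (and optionally second-user C2) masks by
perturbation, fuses each arm independently (registration per arm is what
lets mask defects propagate into the profiles, as they do clinically),
extracts the three vessels' profiles, classifies them against the low-risk
ranges, and emits per-vessel and pooled DC tables plus the paired t tests.
Every seed derives from the single config seed; rerunning a stored config
reproduces the outputs bit-identically. Outputs are staged to a temporary
directory and renamed into place only on success.

By default the experiment uses the blob-initialization registration without
the MI stage (`mi_refine = FALSE`): the phantom arms start co-registered, so
the LV stage carries all the mask-difference signal at a fifth of the cost;
MI refinement is validated separately by the recovery criterion and can be
switched on.

## Known limitations

* Oblique reslicing is unsupported; orientations are signed axis
  permutations (the phantom is generated short-axis aligned).
* The registration initialization is tailored to ammonia-like PET_sum
  contrast (hot myocardium + cavities); very different tracer contrasts
  would need a different PET-side segmentation.
* No partial-volume or spillover correction is applied to ROI TACs, by
  design parity with the mirrored pipeline.
* The normal-range construction and the per-phantom flow variability are
  package conventions, stated above, not facts inherited from any cohort.
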