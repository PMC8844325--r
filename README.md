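# mbfvs — vessel-specific myocardial blood flow from dynamic PET

`mbfvs` quantifies myocardial blood flow (MBF, mL/min/g) along individual
coronary arteries by fusing dynamic 13N-ammonia PET with CT-derived
biventricular anatomy. Instead of one flow value per vascular territory, it
produces a *flow profile*: the myocardium subtended to a vessel is
discretized into contiguous 4-mm cubic ROIs following the vessel's 3D path
from base to apex, each ROI's time-activity curve is fit with the
irreversible two-tissue compartment model

    dC1/dt = K1·Ca(t) − (k2 + k3)·C1,   dC2/dt = k3·C1,
    measured = (1 − v_b)(C1 + C2) + v_b·Ca

and the fitted K1 is reported as MBF^vs(s), a function of arc length s.
Profiles are classified **normal / abnormal** against per-position low-risk
ranges (abnormal = strictly below the lower bound), and the agreement of
classifications obtained with differently derived anatomy masks — manual
(M), fully automated (FA), briefly corrected (C) — is scored with Dice
coefficients, pooled globally and per territory, with Student's t tests
between groups.

The package is aimed at researchers studying the robustness of multimodal
MBF quantification pipelines. Because the underlying patient images are not
public, it ships a **digital cardiac phantom**: half-ellipsoidal LV + RV
crescent anatomy on a 96³ × 2 mm grid, geodesic LAD/LCX/rPDA territories,
gamma-variate arterial input, full dynamic-frame simulation with seeded
scaled-Poisson noise, and controlled segmentation defects (apex truncation,
RV over-segmentation, boundary jitter, septal merge) that emulate FA/C
masks — so the whole M-vs-FA-vs-C experiment reruns end to end in minutes.

## Worked example

```r
library(mbfvs)

spec  <- phantom_spec(seed = 1L)            # the stated phantom world
truth <- generate_anatomy(spec)             # LV/RV/EPI masks + flow truth
cl    <- generate_centerline(truth, "LAD")
series <- simulate_dynamic_pet(truth, state = "stress")   # SNUH binning

tf   <- fuse_series(series, truth$masks, mi_refine = FALSE)
rois <- subtended_rois(transform_centerline(cl, tf), truth$masks)
ca   <- arterial_input_tac(series, truth$masks)
prof <- vessel_flow_profile(rois, series, ca, polish = FALSE, dt_s = 1)

length(rois$rois)          # 23 ROIs along 94 mm of LAD
round(mean(prof$mbf), 2)   # 2.44  (truth stress flow: 2.4 mL/min/g)
round(range(prof$mbf), 2)  # 2.40 2.49
```

The printed numbers are what this code produces on this phantom: 23
contiguous 4-mm ROIs along the 94-mm LAD path, and a stress profile whose
fitted flows recover the simulated truth of 2.4 mL/min/g to within a few
percent (the small positive bias comes from linearly interpolating the
frame-sampled arterial input).

The full mask-robustness experiment, including normal-range construction
from 15 simulated low-risk phantoms, per-arm registration, classification
and Dice tables:

```r
cfg <- experiment_config(n_phantoms = 10L,
                         fa_spec = perturbation_spec(apex_truncation_slices = 2L,
                                                     rv_dilation_mm = 6),
                         c_spec  = perturbation_spec(apex_truncation_slices = 1L),
                         seed = 1L, output_dir = "results/experiment")
report <- run_mask_comparison_experiment(cfg)
report$pooled          # global + per-vessel DC, rest and stress
report$tests$fa_vs_c   # paired t test between DC_FA and DC_C
```

A command-line interface wraps the same operations
(`simulate`, `fuse`, `flow`, `classify`, `compare`, `experiment`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "mbfvs.R", package = "mbfvs"))')
Rscript "$CLI" simulate --preset SNUH --seed 2 --out sim_out
Rscript "$CLI" experiment --config config.yaml --out results/run1
```

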