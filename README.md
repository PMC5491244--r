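# bnctplan

Dosimetric feasibility analysis of multi-field boron neutron capture
therapy (BNCT) for diffuse intrinsic pontine glioma (DIPG), as an R
package plus a scripted analysis.

DIPG infiltrates the brainstem, so it cannot be resected, and the
brainstem dose constraint blocks photon dose escalation. BNCT irradiates
¹⁰B-loaded tissue with epithermal neutrons; the ¹⁰B(n,α)⁷Li capture
reaction deposits its energy within ~10 µm, so tissue that concentrates
boron (tumor-to-normal ratio T/N ≈ 3.5 for BPA) is selectively hit. The
catch is the advantage depth (AD): the depth at which the tumor dose falls
to the maximum normal-tissue dose along the beam, 8.5 cm for the
epithermal beam modelled here. A pontine target lies 8.3–12.8 cm from the
surface depending on beam angle, deeper than the AD, so a single field
cannot help — but several crossed fields can. This package rebuilds that
analysis end to end on synthetic data: voxel head phantoms stand in for
patient CTs, and a calibrated parametric four-component beam model stands
in for Monte Carlo transport.

The dose model: each field deposits four physical dose-rate components
(thermal neutron, fast neutron, photon, boron capture) along its path,
scaled per component by dose-rate scaling factors
DRSF = (0.64, 1.39, 0.96, 0.65), then combined into biologically weighted
dose

    D[Gy-Eq] = 3.2·D_thermal + 3.2·D_fast + 0.5·D_photon
               + CBE·(c_B/c_ref)·D_B10,   CBE = 3.8 (tumor), 1.3 (brain)

Plans use 2, 3 or 4 coplanar fields (14-cm collimator), field weights
balanced until per-field normal-tissue maxima agree within 10%, and are
normalized so that 80% of the CTV receives 20 Gy-Eq. Evaluation covers
DVH metrics (D95/D5, homogeneity index HI = D5/D95, integral dose),
therapeutic gain CTVmin/NTmax, organ-at-risk tolerances (normal brain
< 13 Gy-Eq, optic nerves < 10, circle of Willis < 12), and beam-on time;
a 12-phantom cohort is compared across 2F/3F/4F with one-way ANOVA.

## Worked example

```r
library(bnctplan)

phantom <- generate_head_phantom(phantom_params(seed = 101))
plan    <- plan_treatment(phantom, standard_field_set(4))
metrics <- plan_metrics(plan, phantom$structures)

round(c(minutes = plan$total_minutes, CTV_min = metrics$CTV_min,
        NB_Dmax = metrics$NB_Dmax, gain = metrics$gain, HI = metrics$HI), 2)
#> minutes CTV_min NB_Dmax    gain      HI
#>   65.15   18.10    6.46    1.80    1.18
```

65 beam-on minutes of four-field irradiation deliver 20 Gy-Eq to 80% of
the CTV; the coldest CTV voxel still receives 18.1 Gy-Eq while no normal
brain voxel exceeds 6.5 Gy-Eq (tolerance 13), and the therapeutic gain
CTVmin/NTmax is 1.80 — every target voxel receives 1.8× any
normal-tissue voxel, for a target deeper than the advantage depth.

The full study is scripted under `analysis/` (run from the repository
root, outputs under `results/`):

1. `01_build_phantoms.R` — cohort geometry: structure volumes and
   per-angle deepest CTV depths.
2. `02_beam_calibration.R` — beam model curves and the AD calibration.
3. `03_plan_cohort.R` — 12 phantoms × {2F, 3F, 4F} planned and evaluated
   (~3 min).
4. `04_summaries.R` — mean ± SD tables, ANOVA, tolerance verdicts, DVHs.

On the default cohort the mean normal-brain maximum dose falls
monotonically with field count (9.8 → 7.6 → 6.5 Gy-Eq) while the mean
therapeutic gain rises (1.57 → 1.72 → 1.81), at roughly constant beam-on
time — the dosimetric case for treating DIPG with four-field BNCT without
craniotomy.

## Layout

- `R/`, `src/` — phantom generator, beam model, dose engine, planner,
  DVH/metric evaluation, cohort driver; one C++ ray-tracing kernel.
- `inst/extdata/thor_default.yaml` — shipped calibrated beam parameters.
- `vignettes/methods.Rmd` — model assumptions, parameter choices, and
  what the synthetic cohort does and does not show.
- `analysis/`, `scripts/` — the scripted study and the acceptance check.
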