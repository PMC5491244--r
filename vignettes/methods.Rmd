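---
title: "Methods: synthetic phantoms, beam model and plan evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic phantoms, beam model and plan evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models behind `bnctplan`, the parameters that
matter, the choices made where the design was genuinely open, and what the
synthetic study does and does not demonstrate.

## The problem being modelled

Diffuse intrinsic pontine glioma sits in the brainstem at 8.3–12.8 cm from
the body surface depending on beam angle. For an epithermal neutron beam
with an advantage depth (AD) of 8.5 cm — the depth at which the
boron-boosted tumor dose falls to the maximum normal-tissue dose along the
beam — a single field therefore cannot create a therapeutic window; the
question is whether two to four crossed coplanar fields can, within normal
tissue tolerances. The original analysis ran Monte Carlo transport on
patient CTs; those inputs are private, so this package replaces them with
two calibrated surrogates: a synthetic voxel head phantom and a parametric
per-component depth-dose model. Everything downstream of those surrogates
— DRSF and RBE/CBE weighting, field balancing, prescription normalization,
DVH metrics, the cohort design and its ANOVA — is implemented as specified
by the protocol it reproduces.

## Synthetic head phantom

`generate_head_phantom()` builds a labelled voxel grid (air, soft tissue,
bone, brain, tumor; 2-mm isotropic voxels by default, LPS axes, beams in
the axial plane) and a structure set (body, CTV, normal brain NB = brain −
CTV, left/right optic nerves, circle of Willis). Geometry is a nested
superellipsoid family:

- Head: semi-axes 8.45 × 9.35 × 8.0 cm, axial superellipse exponent 1.95,
  a barrel-shaped z-profile (exponent 3, so the head keeps near-full width
  down to the skull base, as real heads do at the mastoid level), a
  0.5-cm scalp over a 0.7-cm skull shell, and a prismatic neck continuing
  the skull-base cross-section downward. A closed ellipsoid would taper to
  a thin inferior tip that opposed lateral fields enter at shallow depth
  from both sides — an artifact a head-on-neck does not have.
- Brain: 6.95 × 8.0 × 5.8 cm with axial exponent 1.4: its cross-section
  is leaner along the diagonals than the head's, emulating the CSF-filled
  basal cisterns, so brain voxels under the 45° surface lie deeper from
  the cardinal beam directions than the cardinal-entry brain voxels.
- CTV: an ellipsoid (1.3 × 1.3 × 1.6 cm) posterior-inferior of the brain
  centre, the pons position; optic nerves as 0.41-cm-radius cylinders
  anterior-superior of the target; circle of Willis as a small torus
  anterior-inferior, clear of the CTV.

Anatomical realism is explicitly not the goal. The defaults were set to
reproduce two statistics of the clinical cohort the study emulates: the
per-angle deepest CTV depth (11.9/10.2/9.5/9.3/9.6/10.4 cm at
0/60/90/180/270/300°, all inside the published ranges; the oblique-angle
means sit high within their ranges, a consequence of the near-elliptic
head) and structure volumes (NB ≈ 1.1 L, optic nerves ≈ 1.6 cm³, circle of
Willis ≈ 0.9 cm³). Inter-phantom variation is multiplicative jitter on the
head/brain axes (sd 1.5%) plus CTV position (sd 0.5 mm) and size (sd 3%)
jitter — deliberately milder than real inter-patient variation so that
every seeded phantom stays inside the published per-angle depth ranges; a
real cohort would also vary tissue composition, asymmetry and posture,
none of which is emulated. `synthesize_hu()`/`assign_materials()` provide
the CT-number view of the phantom (means −1000/40/700/35/38 HU, thresholds
−500 and +300 HU); brain and tumor are not separable by CT number, which
is why structures are carried as masks rather than re-derived from HU.

## Beam model

`component_depth_dose_rate()` gives each component a closed-form depth
dose in water-equivalent tissue at the reference reactor power (1.2 MW,
epithermal flux 1.28 × 10⁹ n cm⁻² s⁻¹):

- thermal neutron and boron capture: `A(exp(-d/λ) - exp(-d/1.3))` — the
  thermal flux builds up over the first ~2 cm by moderation and then
  attenuates with a common penetration length λ;
- fast neutron: the same two-exponential form with a short 0.45-cm
  build-up (recoil-proton charged-particle equilibrium) and a steep
  1.3-cm decay; a configuration without a fast build-up falls back to a
  plain monotone exponential;
- photon (capture gammas): build-up 1.3 cm, slow 16-cm decay.

The lateral profile is an error function with its half-value at the 7-cm
collimator edge at the surface (penumbra σ = 2 cm), and the effective
field edge contracts with depth at 0.4 cm per cm (floor 3.5 cm): deep in
tissue the useful thermal field is sustained by the field core, so
off-axis points at depth see much less fluence than the geometric field
would suggest. The boron component is stored at the reference
normal-tissue concentration (25 ppm, a standard BPA infusion value) and
scales linearly with local concentration.

The transport-level anchor is the advantage depth: `calibrate_beam_model()`
root-finds the shared thermal/boron penetration length so that
`compute_advantage_depth()` — largest depth where the tumor-weighted
curve equals the maximum of the normal-weighted curve, bisected to
0.01 cm — returns 8.5 cm with the full DRSF/RBE/CBE set at T/N = 3.5.
The shipped `thor_default.yaml` carries the calibrated value
(λ = 3.529 cm). AD is invariant under uniform amplitude rescaling; the
absolute amplitudes are a separate, soft calibration chosen so a typical
multi-field plan's total beam-on time lands in the 40–75-min range, and
the component mix (boron-dominated, with a steep fast component carrying
the shallow normal-tissue dose and a small photon floor) was chosen so
that single-field entry peaks — not multi-field overlap regions — are the
hottest normal-tissue voxels. That last property is what makes the
study's qualitative contrasts emerge mechanically: with entry peaks
dominating, each field's peak is diluted by its time share, so the
normal-brain maximum falls roughly as t_k/k with field count while the
target dose is held fixed by the prescription.

## Dose engine

`radiological_depth()` integrates water-equivalent density (air 0, soft
tissue/brain/tumor 1.0, bone 1.4) from the entry surface along the beam
direction, by 1-mm stepped ray tracing (compiled; nearest-neighbour
sampling). `trace_field()` evaluates the four component curves at each
in-body voxel's radiological depth times the radial profile about the
axis through the CTV centroid (parallel beam; divergence is out of
scope). `apply_drsf()` multiplies each component by its DRSF exactly once
(a provenance flag refuses double application). `rbe_weighted_dose()`
forms Gy-Eq with RBE 3.2/3.2/0.5 for thermal/fast/photon and the boron
CBE selected by the CTV mask (3.8 inside, 1.3 elsewhere): target voxels
are tumor radiobiologically even where their material density is
brain-like. The boron term scales with the local concentration from
`build_boron_map()` (reference in body, T/N × reference in the CTV).
Everything is linear in beam time and superposes across fields.

## Planning

`standard_field_set()` encodes the protocol's arrangements: 2F = opposed
laterals (90/270°), 3F = anterior obliques plus posterior (60/300/180°),
4F = the four cardinal directions; a 1F anterior plan exists only to
demonstrate single-field futility. `balance_field_weights()` automates
the manual weight optimization: per-field maximal dose to normal tissue
(body minus CTV) is equalized by the fixed point w ∝ 1/NTmax, iterated
until the relative spread is within 10% (one step suffices for positive
maps; a 100-iteration cap guards degenerate input).
`normalize_to_prescription()` finds the total beam-on time putting
20 Gy-Eq at 80% CTV coverage: the exact interpolated voxel quantile seeds
the time, which is then refined against the binned cumulative-DVH
inversion used for reporting until the re-measured coverage dose is
within 0.075% of the prescription — a histogrammed DVH with 0.05-Gy-Eq
bins cannot represent discrete dose levels more precisely than one bin,
so the refinement target sits inside the 0.1% normalization guarantee.
Beam-on time is shared across fields in proportion to weight (sequential
delivery; patient set-up intervals between fields are not modelled).

## Evaluation and cohort

`cumulative_dvh()` is an exact voxel-counting cumulative histogram
(default bin 0.05 Gy-Eq); `dose_at_volume()` inverts it by linear
interpolation (D95, D5, and the coverage dose); `homogeneity_index()` is
D5/D95; `integral_dose()` is mean dose × volume in litres;
`therapeutic_gain()` is CTVmin/NTmax with NT defaulting to body minus CTV
(configurable to NB for sensitivity runs). Organ-at-risk maxima are
checked strictly (`Dmax < limit`; a value exactly at the limit fails):
normal brain 13 Gy-Eq, optic nerves 10, circle of Willis 12; a missing
structure is reported as absent, never silently skipped.
`max_tumor_depth()` measures geometric (not radiological) depth from the
body surface, matching how tumor depth is read off CT images.

`run_cohort()` reproduces the experimental design: 12 seeded phantoms
(study seeds 101–112), each planned as 2F/3F/4F with traces shared across
plan types, summarized as mean ± sample SD per plan with one-way ANOVA
across plan types and Tukey-HSD pairwise p values (`one_way_anova()`,
implemented directly as part of the procedure and cross-checked against
`stats::aov`; the original report does not name its post-hoc method, so
Tukey is a choice, and its pairwise p values are not claimed to match).
On this cohort the mean normal-brain Dmax decreases 9.8 → 7.6 → 6.5 Gy-Eq
and the mean therapeutic gain increases 1.57 → 1.72 → 1.81 from 2F to 4F
at ~58–65 min beam-on time, with every 4F plan inside all three
organ-at-risk tolerances — the qualitative conclusions of the clinical
dosimetric study, at more conservative absolute contrasts.

## Numerical choices and degenerate inputs

- Ray step 1 mm (half a voxel), midpoint sampling, entry-surface depth
  accurate to about half a voxel; grid borders are kept air so boundary
  clamping is harmless.
- AD search: 0.05-cm bracketing scan to 40 cm, `optimize()` refinement of
  the normal maximum, `uniroot()` bisection to 10⁻⁴ cm; coincident tumor
  and normal curves (T/N = 1 with equal CBE) return the normal-maximum
  depth; a tumor curve that never reaches the normal maximum is an
  explicit error, as is a calibration bracket without a root. The
  two-exponential shape degenerates to zero when build-up and decay
  lengths coincide, and the calibration bracket is clamped above the
  build-up length.
- Balancing on already-balanced maps leaves weights unchanged (spread
  already within tolerance); a field with zero normal-tissue dose is an
  error.
- DVH inversion on a flat segment returns the segment's lower edge dose;
  empty masks error rather than returning NaN metrics.

## Limitations

The beam surrogate is phenomenological: no spectrum, no angular flux, no
divergence, no scatter tails beyond the parametric penumbra/contraction,
and one water-equivalent density per material. The phantom varies only
size and target geometry across the cohort. Absolute dose-rate levels,
and therefore beam-on times, are soft-calibrated, not measured. Passing
the cohort-level checks here shows the pipeline reproduces the protocol's
logic and its qualitative multi-field contrasts on inputs with the stated
geometry statistics — it does not validate the surrogates against
measured beam data or patient anatomy.
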