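---
title: "Four-dimensional treatment planning with tumor tracking: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Four-dimensional treatment planning with tumor tracking: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Respiratory motion blurs dose in lung radiotherapy. The standard clinical
answer is the internal target volume (ITV): contour the tumor on every
breathing phase of a 4D image set, take the union, add a setup margin, and
irradiate that whole envelope with a fixed set of MLC-shaped fields. The
envelope grows with motion amplitude, and with it the dose to nearby organs
at risk (OARs) — a particular concern for centrally located tumors treated
with stereotactic ablative doses, where the esophagus, heart, great vessels,
trachea and spinal canal sit close to the target.

MLC tumor tracking is the alternative: the aperture follows the tumor each
phase, so only a planning target volume (PTV, the single-phase tumor plus
margin) is irradiated at any instant. `track4d` implements a desk-scale 4D
planning pipeline that quantifies the dosimetric benefit of tracking over the
ITV approach: it builds both plans on the same synthetic 4D phantom, computes
per-phase doses, weights them by the fraction of breathing time spent in each
phase, warps them onto a common reference anatomy, accumulates, and compares
DVH and TG-101-style dose metrics between the arms.

The comparison is stratified by three covariates: tumor motion amplitude,
OAR-to-target proximity at maximum inhale (`d_inh`, signed: negative when
the OAR overlaps the tumor), and the relative organ motion

```
ROM = | d_exh - d_inh |
```

the change in minimum GTV–OAR distance between end exhale and maximum
inhale. OARs with large ROM move relative to the tumor over the cycle and
are the ones a tracking aperture can dodge.

## The pipeline

Phase 0% (maximum inhale) is the reference phase throughout; phase 50% is
end exhale. The eight phases are amplitude-binned: each phase is an
amplitude level of the breathing signal, with the three intermediate levels
appearing once per limb (descending 12.5/25/37.5%, ascending 62.5/75/87.5%).

1. **Phantom.** An 8-phase digital phantom with analytic structures: sphere
   tumor (GTV), tube OARs (esophagus, trachea, spinal canal, great vessels),
   ellipsoid heart, two low-density lung ellipsoids, elliptic-cylinder body.
   Each structure follows its own rigid trajectory; ground-truth deformation
   fields are derived from those trajectories, so registration error is
   controlled rather than estimated.
2. **Breathing PDF.** A bellows-like trace is decimated by a block-mean
   filter (window 50, one output per 50 inputs), segmented into
   peak-to-peak periods, amplitude-binned into 8 phase weights per period,
   and averaged over periods. The weights `w_p` sum to 1 and estimate the
   fraction of breathing time spent in each phase.
3. **Plans.** The ITV arm builds one beam's-eye-view aperture per beam
   around the ITV. The tracked arm (4D-MRL style) apertures the phase-0 PTV
   and translates the aperture per phase by the GTV centroid displacement —
   a virtual couch shift: the isocenter never moves, the leaves do.
4. **Dose.** A deterministic engine computes, per beam,
   `D(v) = F(v) * exp(-mu * d_rad(v)) * (SAD / r(v))^2`, where `F` is the
   aperture indicator convolved with a Gaussian penumbra and sampled at the
   voxel's projection through the point source onto the isocenter plane
   (penumbra width therefore scales with magnification), `d_rad` is the
   density-weighted depth from the body surface along the beam direction,
   and `r` the source distance.
5. **Accumulation.** `sum_p w_p * warp(D_p, u_p)` on the inhale anatomy,
   then normalization so that 100% of the GTV receives at least 99% of the
   prescription (V99% = 100%) — both arms identically.
6. **Metrics.** DVHs, Vx/Dmax/Dmean per OAR against TG-101-style SABR
   limits, signed distances and ROM, the OLS regression of mean-dose
   sparing (normalized to prescription) on ROM, a sparing-vs-proximity
   profile, and the irradiated-volume reduction.

## Parameters that matter

- **Grid**: 0.25 cm isotropic voxels (the dose-grid resolution used for all
  headline numbers); cohort phantoms use 96^3 voxels (24 cm field of view).
- **Machine**: MRI-linac geometry by default — SAD 143.5 cm, projected leaf
  width 0.72 cm at isocenter; a conventional preset (100 cm / 0.5 cm)
  exists. 7 equispaced coplanar beams by default; the clinical beam
  arrangement behind the published comparison is not stated anywhere, so
  the count is a declared default, not an inference.
- **PTV margin**: 5 mm isotropic.
- **Engine**: attenuation mu = 0.045 /cm and penumbra sigma = 0.3 cm at
  isocenter (80–20 penumbra 1.683 sigma ≈ 5 mm), chosen to give a
  megavoltage-like depth falloff; both configurable. Absolute calibration is
  irrelevant because every plan is rescaled by the V99% normalization.
- **Breathing**: raised-cosine-power cycles `A cos^{2n}(pi t / T)` with
  n = 2, period jitter 15% (periods drawn per cycle), sampled at 250 Hz for
  120 s; cohort periods span 2.7–6.6 s around a 5 s mean, matching typical
  clinical breathing statistics.
- **Densities**: lung 0.26 g/cc, soft tissue 1.0, spinal cord/bone channel
  1.3, outside-body air ~0.001, plus a seeded anatomy-fixed Gaussian
  texture (sd 0.02 g/cc) shared by all phases.

## The synthetic cohort

`inst/extdata/cohort.yaml` describes five phantoms emulating a central-lung
SABR cohort: tumor amplitudes 1.74/0.12/0.25/0.86/0.18 cm, GTV volumes
15.2/6.1/21.3/1.3/12.0 cc, prescriptions 52 Gy in 4 fractions for the large
mover and 50 Gy in 5 for the rest, and per-OAR `d_inh` (from -0.58 to
7.5 cm) and ROM (0 to 1.28 cm) spanning the clinically reported ranges.
Tumor motion is cranial–caudal except one phantom with lateral-dominant
motion. OARs realize their requested ROM by approaching the tumor in the
axial plane between inhale and exhale (`d_exh = d_inh - ROM`); their
trajectories also carry the tumor's in-plane motion component so the
requested relative motion holds exactly even for the laterally moving
tumor. An infinite tube's minimum distance to the tumor is insensitive to
cranial–caudal motion, which is why the approach must be in-plane — real
mediastinal organs also move cranio-caudally, a component this construction
deliberately folds into the relative in-plane approach.

## Numerical choices

- **Rasterization**: masks are voxelized with 2×2×2 supersampling and a
  majority vote, which keeps closed-structure volumes stable to <5% under
  sub-voxel rigid motion. Thin infinite tubes reduce to 2D disk
  rasterization whose binarized area at 0.25 cm fluctuates of order 10%
  across sub-pixel offsets for any supersampling level; distance-based
  metrics, not tube volumes, are what the pipeline consumes.
- **Margin expansion**: distance-transform threshold at
  `margin + h/3` (h = voxel size). The one-third-voxel surface offset
  removes the volume bias of center-to-center binary dilation (calibrated
  against analytic sphere dilations over random grid alignments).
- **Signed distances**: computed on Euclidean distance transforms
  (separable Felzenszwalb–Huttenlocher, compiled); disjoint minima are
  corrected by one voxel for the two half-voxel surface offsets plus
  lateral quantization (again calibrated on random analytic scenes), and
  floored at a quarter voxel so disjoint masks stay positive. Overlap depth
  is the largest in-mask distance-transform value over the other mask's
  boundary voxels, negative by convention — reproducing the negative
  proximity values clinical tables report for OARs inside the target
  region. All distance checks carry a 2-voxel tolerance.
- **Deformation fields**: per-structure rigid translations blended by
  inverse-square-distance weights to each structure's motion envelope,
  modulated by a Gaussian falloff (sigma 2 cm) and normalized against a
  constant background weight (0.25) so displacement decays to zero away
  from the anatomy. Inside an envelope the field equals that structure's
  translation (static organs anchor zero, as an anatomy-driven registration
  would); warping the exhale GTV back to inhale achieves Dice 1.0 at the
  study amplitudes. Cascaded phase-to-phase fields compose to within one
  voxel of the direct field for single-structure motion; where two moving
  envelopes interact the falloff shells disagree more — only the direct
  fields are used in the pipeline.
- **Mask propagation**: pull-back trilinear interpolation of the indicator,
  threshold 0.5. An exactly-half-voxel translation places the interpolated
  indicator exactly at the threshold on both boundary faces and any
  tie-break grows or shrinks the mask by a layer; generic sub-voxel shifts
  round-trip with Dice ≥ 0.95. The pipeline uses generator ground-truth
  masks per phase; propagation exists for contour-transfer checks.
- **V99% normalization**: scale by `0.99 Rx / min(dose over GTV)` (with a
  1e-12 guard so the coldest voxel cannot round below threshold). Under
  this rule "the volume receiving 99% of prescription is 100%" and "the
  dose to 99% of the volume is the prescription" coincide, so the
  ambiguity between the two readings is moot.
- **Leaf-row quantization**: cranial–caudal aperture shifts round to the
  nearest leaf row with ties toward cranial (an arbitrary, documented
  choice); lateral shifts are continuous.
- **Fractionation** is metadata: all doses are total-course Gy.
- **PDF weighting** multiplies dose, which under a linear engine is
  equivalent to weighting delivery time.
- **Irradiated volume** is the body volume above a configurable fraction of
  prescription (default 0.5), since no operational definition is standard.
- **Dmax** is the single-voxel maximum; no multiple-testing correction is
  applied anywhere (a single regression p-value is reported).
- **Amplitude levels** in the phase PDF are equal-width in amplitude
  (consistent with amplitude-binned 4D imaging); equal-count binning is the
  other defensible convention and was not chosen.

## What the tests do and do not show

The test suite checks every stage against independent closed forms: the
arcsine law for the cosine-trace PDF, sphere/lens volumes for margins and
ITV unions, analytic chords for apertures, exponential × inverse-square
ratios and the 1.683-sigma penumbra for the engine, exact convex-combination
conservation for accumulation, and sphere-scene distances for ROM. The
cohort-level checks are directional: tracking spares OARs more the larger
the amplitude and the relative motion, sparing attenuates beyond ~2 cm
proximity, and the irradiated volume shrinks (by ~30% for the largest
mover). Problem sizes: unit tests run on 25–64 voxel grids; the cohort runs
all five phantoms at 96^3.

A passing suite shows the machinery is internally consistent and reproduces
the qualitative clinical findings on rigid, analytically deformed anatomy.
It does not show performance on real patients: no deformable (non-rigid)
organ deformation, no image-derived registration error, no
magnetic-field dose effects (electron return), no MLC leakage or latency,
no intra-fraction baseline drift. The dose engine is an analytic surrogate,
not Monte Carlo; only dose *differences* between arms computed with the
same engine are meaningful, not absolute dosimetry.

## Known limitations

- Sparing magnitudes depend on the declared beam arrangement and engine
  parameters; the directional findings are robust to them, the Gy values
  are not.
- The ROM mechanism for tube OARs is purely in-plane by construction.
- The accumulated-ITV and tracked arms share the ground-truth fields, so
  registration uncertainty — a real clinical error source — is absent.
- With rigid per-phase anatomy the union of per-phase PTVs equals the ITV
  exactly (dilation commutes with union); the tracked benefit comes from
  irradiating one PTV at a time, not from a smaller union.
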