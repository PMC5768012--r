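# track4d

Desk-scale 4D radiotherapy treatment planning for respiratory-moving lung
tumors: quantify what MLC tumor *tracking* buys over the clinical *ITV*
(internal target volume) approach in organ-at-risk (OAR) sparing.

Central lung tumors move with breathing, and the standard ITV plan
irradiates the whole motion envelope with fixed fields. A tracking system
(as on an MRI-linac) instead shifts the MLC aperture to follow the tumor
each breathing phase while the isocenter stays fixed (a "virtual couch
shift"). `track4d` builds both plans on seeded synthetic 4D phantoms and
compares them with the field's standard dose metrics. It is aimed at medical
physicists and methods developers who want a controlled, fully synthetic
testbed for 4D dose accumulation — every deformation field is analytic
ground truth, so registration error is excluded by construction.

## The method

For each of 8 amplitude-binned breathing phases `p` (0% = maximum inhale =
reference, 50% = end exhale), a per-phase dose `D_p` is computed on that
phase's anatomy with a deterministic engine

    D(v) = sum_beams F(v) · exp(-mu · d_rad(v)) · (SAD / r(v))²

(`F` = Gaussian-penumbra aperture fluence at the voxel's source-ray
projection, `d_rad` = radiological depth, `r` = source distance). A
patient-specific breathing trace is decimated (block mean, window 50),
segmented into periods at its peaks, amplitude-binned into per-period phase
probability density functions, and averaged, giving weights `w_p` (the
fraction of breathing time spent in phase `p`). The accumulated dose on the
reference anatomy is

    D_acc = sum_p w_p · φ_p(D_p),     φ_p = pull-back warp through the
                                            phase-p deformation field

normalized so the GTV's V99% is 100%. The tracked arm uses per-phase
virtual-couch-shift apertures around the single-phase PTV; the comparison
arm ("accumulated ITV") recalculates one fixed ITV aperture set on every
phase and is pushed through the identical weighting/warping/accumulation.
Sparing is stratified by tumor amplitude, OAR proximity `d_inh`, and the
relative organ motion `ROM = |d_exh − d_inh|` (the change in minimum
GTV–OAR distance between exhale and inhale), with an OLS regression of
mean-dose sparing on ROM and TG-101-style limit tables.

## Worked example

```r
library(track4d)

entry <- phantom_entry(
  name = "demo", prescription_gy = 50, fractions = 5,
  tumor = list(volume_cc = 10, amplitude_cm = 1.5),
  oars  = list(ESO = list(d_inh = 0.75, rom = 0.5)),
  body = c(7, 7), grid = list(shape = c(64, 64, 64), spacing = 0.25))
phantom <- generate_phantom(entry, seed = 1)

pdf <- trace_to_pdf(generate_breathing_trace(period_s = 5, duration_s = 120,
                                             sample_rate_hz = 250, seed = 1))
print(pdf)
#>     0%  12.5%    25%  37.5%    50%  62.5%    75%  87.5%
#> 0.1973 0.0566 0.0493 0.0584 0.4756 0.0554 0.0564 0.0511

cache  <- new.env()
tracked <- run_4dmrl(phantom, pdf = pdf, cache = cache)
itv     <- run_itv_acm(phantom, pdf = pdf, cache = cache)

eso <- phantom_mask(phantom, "ESO", 0)
rom(phantom_mask(phantom, "GTV", 0), phantom_mask(phantom, "GTV", 4),
    eso, phantom_mask(phantom, "ESO", 4))
#> ESO d_inh = 0.54 cm, d_exh = 0.10 cm, ROM = 0.44 cm
mean(itv$accumulated$values[eso$voxels])      # 9.82 Gy
mean(tracked$accumulated$values[eso$voxels])  # 6.68 Gy
irradiated_volume_reduction(itv$accumulated, tracked$accumulated,
                            phantom_mask(phantom, "BODY", 0), 50)
#> irradiated volume: ITV 91 cc vs tracked 61 cc (-33.5%)
```

The breathing PDF dwells at end exhale (weight 0.48 at the 50% phase), as
real traces do. The esophagus, 0.75 cm from the tumor with 0.5 cm relative
motion, receives a third less mean dose under tracking, and the body volume
above half the prescription shrinks by 33%.

`run_cohort()` drives the whole comparison over a cohort described in YAML
(`inst/extdata/cohort.yaml` ships a 5-phantom cohort with tumor amplitudes
0.12–1.74 cm and OAR proximities −0.58 to 7.5 cm) and returns per-OAR
TG-101 tables for both arms, sparing records, the sparing-vs-ROM
regression, the proximity profile, and irradiated-volume reductions. A thin
CLI over the same functions lives at `inst/cli/track4d.R`
(`trace`, `pdf`, `phantom`, `plan`, `dose`, `accumulate`, `cohort` verbs).

## Documentation

The methods vignette (`vignettes/fourd-planning.Rmd`) documents the models,
parameter choices, numerical decisions (rasterization, distance-transform
corrections, field blending) and the limits of what the synthetic cohort
can show about real patients.
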