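# thoraxmc

Voxelized Monte Carlo simulation of near-infrared photon migration
through the anterior thorax, built to study whether pulmonary embolism
(PE) can be sensed optically from the skin surface.

## The scientific problem

An embolus in the pulmonary artery deranges pulmonary hemodynamics:
arterial and venous oxygen saturation fall with disease severity, and at
800 nm desaturated hemoglobin absorbs more strongly than oxygenated
hemoglobin. A light source placed over the sternum between two ribs and a
detector a few centimeters away on the skin therefore see, in principle,
an intensity that decreases as the embolism worsens. Whether enough
photons actually reach a pulmonary artery 33 mm deep and return — and at
which source–detector separation the artery contributes most to the
signal — is a photon-transport question. `thoraxmc` answers it by
simulation:

* **Phantom** — `build_thoracic_phantom()` paints a deterministic,
  parametric labeled voxel volume (0.4 mm voxels): skin / fat / sternum
  with an inter-rib gap / muscle over a mediastinal fat column flanked by
  lung, with the pulmonary artery (2 mm wall, 13 mm venous lumen)
  embedded at 33 mm depth, plus embedded arterial/venous vessels. Optical
  properties at 800 nm (`default_tissue_table()`) give per-tissue
  refractive index *n*, absorption `mua`, scattering `mus` (cm⁻¹), and
  Henyey–Greenstein anisotropy *g*.
* **Transport** — `propagate()` drives a compiled photon-packet kernel:
  exponential step sampling spent across voxels of differing
  `mut = mua + mus`, albedo-weight deposition (`w · mua/mut`) per
  interaction, Henyey–Greenstein scattering, unpolarized Fresnel
  reflection/refraction at refractive-index mismatches, Russian roulette,
  and a square-aperture surface detector recording exit weight plus total
  and per-tissue path lengths for every detected packet.
* **Sensitivity** — fluence `F = A/mua` per voxel (Eq.-style conversion
  of the absorption map), adjoint runs for the detector-side Green's
  function, and the spatial sensitivity distribution
  `SSD(r) = F_source(r) · F_detector(r)` with per-tissue percentage
  shares (`tissue_ssd_proportions()`).
* **Pathlength factors** — `compute_dpf()` (mean detected path /
  separation), `compute_ppf()` for focal regions such as the pulmonary
  artery, and `sweep_separations()` to locate the optimal separation.
* **Severity study** — `run_pe_study()` evaluates the four oxygenation
  groups (Normal, Level I–III; SaO₂ 95/93/91/89 %, SvO₂ 75/71/67/63 %),
  normalizes detected intensity to the Normal group, and fits
  `normalized intensity ~ level` by ordinary least squares.

## Worked example

```r
library(thoraxmc)

study <- run_pe_study(pe_study_config(
  run = run_config(n_photons = 1e5, n_repeats = 2, base_seed = 5,
                   roulette_threshold = 1e-9)))
print(study)
```

```
Pulmonary-embolism severity study
  separation 2.90 cm | 100,000 photons x 2 repeats per condition
 condition level sao2 svo2        raw         se normalized
    Normal     0   95   75 2.1469e-06 1.1312e-06    1.00000
    LevelI     1   93   71 2.1455e-06 1.1302e-06    0.99935
   LevelII     2   91   67 2.1442e-06 1.1293e-06    0.99871
  LevelIII     3   89   63 2.1428e-06 1.1284e-06    0.99806
Linear severity fit: intensity = 1.00000 -0.00065 * level (r^2 = 1.0000, p = 2.16e-06)
```

Reading the numbers: `raw` is the detected weight per launched packet at
a 2.9 cm separation — about 2 × 10⁻⁶, i.e. roughly one packet in half a
million reaches the detector with its residual weight. Desaturating the
blood from the Normal group to Level III raises blood absorption by
0.015–0.03 cm⁻¹ and trims the detected intensity by ≈ 0.06 % per severity
level; because blood absorption is affine in the level index the
normalized intensities fall on an almost perfect line (`r^2` here 1.0000
to four digits), which is what makes the detected intensity a usable
severity scale. The large `se` on the raw intensities reflects genuine
shot noise between repeats; the severity *ratios* are estimated from
paired packets (see the methods vignette) and are far more precise than
the raw values.

Other entry points:

```r
vol  <- build_thoracic_phantom(phantom_config())
src  <- source_config(24, 12)
sw   <- sweep_separations(vol, default_tissue_table(), src,
                          seq(1, 4, 0.6),
                          run_config(n_photons = 1e6, n_repeats = 1),
                          detector_side_mm = 8,
                          region_mask = pa_region_mask(vol, phantom_config()),
                          ppf_estimator = "ssd")
plot(sw)     # DPF, PPFpa, PPFpa/DPF, and PA absorption vs separation
```

A thin command-line driver with subcommands `phantom`, `run`, `ssd`,
`sweep`, `pe-study`, and `validate` is installed at
`system.file("cli", "thoraxmc", package = "thoraxmc")`.

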