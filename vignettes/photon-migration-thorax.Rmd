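---
title: "Modeling near-infrared photon migration through the thoracic wall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling near-infrared photon migration through the thoracic wall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(thoraxmc)
```

## The question the package addresses

Pulmonary embolism disturbs pulmonary hemodynamics before anything else:
blood pooled behind an obstructed pulmonary artery desaturates, and
desaturated hemoglobin absorbs more strongly at 800 nm. If near-infrared
light launched on the anterior chest wall can reach the pulmonary artery
and return to a nearby detector, the detected intensity becomes an optical
proxy for embolism severity. `thoraxmc` provides the simulation machinery
to study that question in silico: a parametric voxel phantom of the
anterior thorax, a photon-packet Monte Carlo transport kernel, spatial
sensitivity analysis, pathlength factors over source--detector
separations, and the four-group oxygenation study with its linear
severity--intensity fit.

## Transport model

Photon packets enter the tissue as a pencil beam along the inward surface
normal. Each packet performs the standard voxelized random walk:

* **Step sampling.** A dimensionless optical depth $\tau = -\ln \xi$ is
  drawn and spent across voxels: within a voxel of total attenuation
  $\mu_t = \mu_a + \mu_s$ (cm$^{-1}$) the packet may travel $\tau/\mu_t$;
  crossing a voxel face consumes the traversed depth and the remainder is
  spent in the next voxel at its own $\mu_t$.
* **Absorption.** At each interaction site the fraction
  $\mu_a/\mu_t$ of the packet weight is deposited into the local voxel
  (albedo weighting). The per-voxel sums form the absorption map $A$.
* **Scattering.** The deflection cosine is drawn from the
  Henyey--Greenstein inverse CDF with the local anisotropy $g$; the
  azimuth is uniform.
* **Boundaries.** Where the refractive index changes between voxels (and
  at tissue--air surfaces) unpolarized Fresnel reflectance decides between
  specular reflection and refraction; total internal reflection is
  handled exactly. Most thoracic tissues share $n \approx 1.4$, so
  internal mismatches arise mainly at skin/fat/bone interfaces.
* **Termination.** Packets leaving the tissue are tallied (top, bottom,
  side); those exiting the top surface within the square detector
  aperture are recorded with their exit state, total path length, and
  per-tissue partial path lengths. Low-weight packets undergo Russian
  roulette (threshold $10^{-4}$, survival probability $0.1$, survivors
  boosted $\times 10$), which terminates them without bias.

Energy bookkeeping is exact: with roulette disabled, launched weight
equals absorbed plus exited weight to floating-point precision (the
kernel accumulates totals in extended precision and derives each deposit
as the exact difference of consecutive weights); with roulette enabled
the identity holds in expectation and the kernel additionally reports the
killed and injected roulette weight so the ledger always closes exactly.

**Randomness.** Every photon draws from its own counter-seeded
xoroshiro128+ substream derived from (run seed, photon index). Runs are
bit-reproducible from a single integer seed, and — decisive for the
severity study — two runs that differ only in optical coefficients remain
paired photon-by-photon: a packet whose history diverges cannot perturb
any other packet.

## The synthetic thoracic phantom

No anatomical dataset ships with the package; `build_thoracic_phantom()`
paints a deterministic parametric stand-in that reproduces the depth
structure the results depend on:

* flat layers of skin (2 mm), subcutaneous fat (6 mm), an 8 mm bone plate
  (sternum/ribs) interrupted by a 15 mm inter-rib gap of intercostal
  muscle at the source site, and a 4 mm muscle sheet;
* a central **mediastinal fat column** (half-width 22 mm) behind the
  chest wall, flanked by lung parenchyma. The pulmonary artery — a 2 mm
  vessel wall around a 13 mm-radius venous lumen, running along the body
  axis — is embedded in this column with its anterior wall 33 mm below
  the skin. The mediastinum matters: lung tissue absorbs strongly at
  800 nm ($\mu_a = 1.0$ cm$^{-1}$), and a lung-filled prepulmonary space
  would attenuate the fluence by several orders of magnitude more than
  thoracic photon-migration measurements report; anatomically the main
  pulmonary artery indeed lies in the mediastinum, not behind lung.
* small arterial/venous vessel inclusions: intercostal vessels in the rib
  gap, a vessel grid in the muscle sheet, great-vessel stand-ins flanking
  the artery, and a vessel lattice in the lung. These give every blood
  pool a realistic presence in the sampled volume, so that a change in
  blood absorption is visible to detected light.

All dimensions are configurable; construction is fully deterministic.
Optical properties default to the 800 nm table (per-tissue $n$, $\mu_a$,
$\mu_s$, $g$) used throughout thoracic NIRS modeling, and
`apply_condition()` maps arterial/venous oxygen saturation to blood
$\mu_a$ by the straight line through the two normally saturated anchor
points (95%, 2.33 cm$^{-1}$) and (75%, 2.38 cm$^{-1}$). The line is a
deliberate, minimal calibration: published values pin down only those two
points, and the four study conditions stay within their neighborhood.

What the phantom does **not** emulate: anatomical curvature and
inter-subject variability, heterogeneous marrow/cartilage in bone,
respiratory and cardiac motion, and any tissue boundary roughness. Tests
passing on this phantom demonstrate correctness of the transport and
analysis machinery and qualitative transferability of the depth
structure, not quantitative prediction for a particular patient.

## Sensitivity and pathlength analysis

Fluence is recovered from the absorption map voxelwise as
$F = A / \mu_a$ (per launched packet); an independent pathlength tally
($\sum w\,\ell$ per voxel) is available as a cross-check. The spatial
sensitivity distribution is the three-point Green's-function product
$\mathrm{SSD}(r_S, r_D, r_m) = F(r_S, r_m)\, F(r_D, r_m)$, with the
detector-side factor obtained from an explicit adjoint run (a source
placed at the detector). Per-tissue SSD sums and percentage shares
quantify each tissue's involvement in the detected signal.

Pathlength factors follow the NIRS conventions: the differential
pathlength factor DPF is the detected-weight-weighted mean total path
length divided by the separation $d$; the partial pathlength factor of a
focal region (here the pulmonary artery: vessel wall plus lumen blood,
selected by a geometric region mask so venous vessels elsewhere are
excluded) replaces the total path by the partial path. Across any
partition of the tissues the PPFs sum exactly to the DPF.

**Two PPF estimators.** The record-based estimator is unbiased but
rare-event-limited: at desk-scale budgets (about $10^6$ packets) no
detected packet traverses a region 3 cm deep, so PPFpa estimates are
zero with high probability. `sweep_separations()` therefore offers a
Green's-function estimator: since the voxelwise mean partial path of
detected light is proportional to $F_S F_D$ with one common
normalization, the ratio PPFpa/DPF equals the pulmonary-artery share of
the SSD, $\sum_{\mathrm{pa}} F_S F_D / \sum F_S F_D$. Fluence reaches
centimeter depths with usable statistics long before detected round-trip
photons do, so the ratio curve over separations is resolvable at moderate
budgets. The fluence maps are block-averaged (default 4 mm for sweeps)
before the product to tame the variance of products of sparsely sampled
voxels; the bias is a smoothing on the scale of the bin.

Sweeps run one transport simulation that records every top-surface exit
and apply each separation's detector aperture as a post-filter, so all
separations share one photon ensemble — cheaper by the number of
separations, and the resulting curves vary smoothly because their noise
is common.

## The severity study

`run_pe_study()` evaluates the four oxygenation groups (Normal and Levels
I--III: SaO2 95/93/91/89%, SvO2 75/71/67/63%) at a 2.9 cm separation,
normalizes detected intensities to the Normal group, and fits intensity
against the level encoding 0--3 by ordinary least squares
(`fit_linear()`, reporting slope, $r^2$, and the slope's two-sided
$t$-test $p$-value).

**Intensity estimation.** The default estimator exploits that the
conditions differ only in blood $\mu_a$. For trajectories sampled under
the reference condition, the exact reweighting identity for an
absorption-only perturbation cancels the interaction-density and albedo
factors, leaving per detected packet
$w_c = w \exp\!\big(-\sum_t \Delta\mu_{a,t} L_t\big)$,
with $L_t$ the recorded per-tissue partial path lengths. One transport
run per repeat therefore yields unbiased intensities for all four
conditions with *perfectly paired* noise, and the condition ratios become
smooth functions of the saturation shift. The alternative
(`estimator = "independent"`) simulates each condition separately with
common per-repeat seeds; it reproduces the same expectations but its
ratios carry trajectory-divergence noise of the order of percent at
$10^5$--$10^6$ packets — larger than the per-level intensity change
itself — which is why the paired estimator is the default at desk scale.
The study default also lowers the roulette threshold to $10^{-9}$ so
detected packets rarely roulette, and uses an 8 mm collection aperture
(the single-photodiode die of 2.29 mm remains the transport default):
normalized ratios are first-order invariant to aperture size, while the
larger aperture keeps the detected ensemble populated.

Because both arterial and venous saturation fall in equal steps across
the levels, blood $\mu_a$ is affine in the level index and the log of
the normalized intensity is nearly exactly linear in level; the OLS fit
measures how well that linearity survives sampling noise.

## Numerical choices and problem sizes

* Voxels are 0.4 mm isotropic by default; positions are continuous and
  voxel indices are tracked alongside, so face crossings are exact.
* Transport runs default to $10^6$ packets $\times$ 10 repeats (the
  convention of the thoracic NIRS literature); the package's own test
  suite and the bundled acceptance analysis use $10^5$--$10^6$ packets
  per run on phantoms of roughly $220 \times 180 \times 60$ voxels,
  which resolves every tested quantity at its stated tolerance while
  keeping a full run in minutes on one core.
* Degenerate inputs are rejected up front: non-positive thicknesses,
  geometry overflowing the domain, zero vessel-wall thickness, missing
  blood entries, saturations outside [0, 100], identical calibration
  anchors, detectors off the surface, empty record sets.
* Ties and edge cases: a packet exactly on a face progresses by index
  stepping, not positional nudging; $\xi = 1$ gives a zero-length step;
  $g = 0$ falls back to isotropic sampling; air voxels terminate
  transport (air participates in no physics).

## Known limitations

* The phantom is a layered idealization; absolute quantities tied to a
  specific anatomy (per-tissue SSD percentages, absolute attenuation to
  the artery) are qualitative analogues, not reproductions.
* The saturation-to-$\mu_a$ line is a two-point calibration; outside
  roughly 60--100% saturation it should be replaced by an
  extinction-coefficient model.
* Whether severity perturbations should apply to all blood pools or only
  the pulmonary artery is physiologically ambiguous; the package
  perturbs both pools, which is the conservative reading of a systemic
  hypoxemia.
* The detector accepts all exit angles; numerical-aperture-limited
  collection would scale intensities but not normalized ratios.
* No time-resolved or frequency-domain quantities, no polarization, no
  mesh geometry.
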