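---
title: "Peribronchial densitometry: method, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Peribronchial densitometry: method, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Asthmatic airway remodeling is a structural change of the bronchial wall:
smooth-muscle enlargement, basal-membrane thickening, peribronchial
fibrosis. In micro-CT of the mouse thorax it appears as an attenuation
increase confined to the tissue immediately surrounding the bronchial
lumina, whereas inflammation — cellular infiltration and oedema — raises
attenuation diffusely across the lung. `airwayct` quantifies the
wall-specific change with a ratio statistic:

$$\text{normalized PBA} \;=\; 1 - \frac{\mathrm{PBA}}{\mathrm{TLA}},$$

where PBA (peribronchial attenuation) is the mean Hounsfield-unit value
over a 3D shell around the segmented bronchial lumina and TLA (total lung
attenuation) is the mean over the segmented aerated lung field. Because any
lung-wide attenuation shift moves PBA and TLA together, the ratio
suppresses it; a change concentrated in the shell moves PBA alone and is
retained. Both attenuations are negative in aerated lung, so denser walls
(PBA closer to 0) increase the statistic.

## The procedure

1. **Calibration.** Raw scanner values are mapped to HU by the two-point
   affine transform fixed by the in-field standards: air-standard mean
   → −1000 HU, water-standard mean → 0 HU. A bone standard, when present,
   is mapped through the same transform and reported as a linearity
   diagnostic only. Nothing in the standards layout identifies a unique
   three-point model, and two-point affine rescale is the canonical CT
   calibration, so the third point deliberately does not bend the map.
2. **Lumen segmentation.** Seeded volume growing through voxels in the
   closed band [−1024, −900] HU. Seeds are explicit voxel coordinates (for
   reproducibility); `suggest_seed()` proposes the centroid-nearest voxel
   of the most cranial in-band slice — normally the trachea — mimicking the
   obvious manual choice.
3. **Shell construction.** The lumen mask is dilated in 3D by
   `dilation_radius_voxels` (default 8). Inside the dilated VOI, *all*
   voxels whose attenuation lies in the lumen band are removed — a second
   threshold segmentation rather than a second region growing, so
   disconnected air pockets captured by the dilation are removed along with
   the original lumen. An exclusion mask (trachea and mediastinum, supplied
   by the user or by the phantom's truth) is then subtracted.
4. **Lung segmentation and summary.** The lung field is grown in
   [−900, −100] HU from its own seed; TLA, PBA and normalized PBA are
   assembled, together with the voxel counts behind them.

### Assumptions

- The volume is HU-calibrated and approximately isotropic
  (distance-dependent steps refuse spacing anisotropy beyond 1% relative,
  because an 8-voxel dilation is only a physical 370 µm shell when voxels
  are cubes).
- The airway lumina are air-filled and connected to the seed (gated,
  contrast-free acquisition).
- The trachea/mediastinum exclusion is supplied explicitly; the package
  does not attempt to recognise anatomy.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| lumen band | [−1024, −900] | HU | air in the lumen; lower bound is the scanner floor |
| lung band | [−900, −100] | HU | aerated parenchyma + wall; excludes luminal air and soft tissue |
| dilation radius | 8 | voxels (46 µm) | ≈ 370 µm shell; the radius at which the 3D shell matches the validated manual peribronchial region |
| connectivity | face6 | — | conservative against diagonal leakage through one-voxel wall gaps; `full26` available |
| dilation mode | euclidean | — | distance-transform ball, rotation-fair and reproducible; `iterated_face` brackets tools that iterate the 6-neighbor element |
| shell ∩ lung | off | — | PBA and TLA are defined on independent VOIs; an optional flag intersects the shell with the lung mask for leakage control |

Numerical conventions: both band bounds are inclusive, matching the closed
printed ranges; −900 HU therefore belongs to *both* bands, and the shell
step resolves the overlap in favour of the lumen (an in-band voxel is never
shell). Dilation thresholds the squared distance transform at
$r^2 + 10^{-9}$ so voxels at exactly distance $r$ are included regardless
of floating-point jitter. Voxels below −1024 HU at read time (out-of-field
padding) are mapped to −1024 so the lumen band stays meaningful at volume
borders. Volumes are stored R-natively as `data[x, y, z]` with `z` the
cranio-caudal axis — one fixed, documented convention shared by all masks.

## The synthetic thorax phantom

`generate_phantom()` paints, at isotropic 46 µm voxels on a 192³ grid by
default: a soft-tissue body ellipsoid (0 HU) containing a lung ellipsoid of
aerated parenchyma (−550 HU, mid-band of the lung range so that 20 HU of
noise keeps essentially all parenchyma in band); a sealed dichotomous
airway tree (straight trachea splitting at ±35° over 4 generations, lumen
−1000 HU, radius decay 0.8 from 5 voxels) sleeved by a uniform wall
(−200 HU, default thickness 2 voxels); optional inflammation halos;
air/water calibration cylinders in the chamber air; and additive Gaussian
noise (default SD 20 HU), floored at −1024 HU as a real 12-bit-offset
detector would be. The tree is sealed inside the lung because chamber air
shares the lumen band — the phantom analogue of an intubated animal.

Ground truth ships with the volume: tissue masks, seeds, a trachea
exclusion mask, and oracle attenuations computed by applying the shell
definition to the *truth* lumen mask with a brute-force ball dilation
(explicit offset shifts) over the *noise-free* painted values. The oracle
shares the generator's geometry but none of the segmentation or
distance-transform code it is used to check.

Two series express the biological contrast. `remodeling_series()` varies
wall thickness at fixed geometry, seed and attenuations — remodeling
without inflammation. `inflammation_series()` adds a halo of configurable
intensity raising parenchymal attenuation within 32 voxels (≈ 1.5 mm) of
the outer wall at fixed wall thickness — murine allergic inflammation is
diffuse, extending well beyond the wall, which is why a broad halo rather
than a wall-hugging one is the realistic emulation (and why the
normalization can cancel it at all).

**What the phantom does not emulate:** partial-volume blur (no point-spread
function by default), reconstruction artefacts, beam hardening, cardiac or
respiratory motion, anatomical tree asymmetry, and vessels — the pipeline
is attenuation-statistical, not shape-sensitive, so tests passing on the
phantom demonstrate correctness of the segmentation/morphology/densitometry
chain, not robustness to scanner physics.

## Agreement statistics

Validating a semi-automatic method against a manual reference uses paired
per-scan measurements:

- **Bland–Altman**: mean and sample SD of differences, limits at the mean
  ± 2 SD exactly (not 1.96). The SD of differences is reported as the
  *measurement error* — the one scalar a Bland–Altman analysis yields for
  that role; the report labels the interpretation explicitly.
- **Pearson r** and **ICC(2,1)** — two-way random-effects,
  absolute-agreement, single-measurement intraclass correlation assembled
  from the two-way ANOVA mean squares. ICC(2,1) is the standard form for
  two methods treated as random raters; unlike r it penalises systematic
  bias (a constant +19 HU offset leaves r at 1 but depresses the ICC).
  When every value is identical the ICC is returned as 1 by convention,
  with a message.
- **Spearman** (midranks, large-sample t approximation) and the two-sided
  **Mann–Whitney** rank-sum test (exact enumeration when
  $n_a n_b \le 400$ with no ties, otherwise normal approximation with tie
  and continuity corrections) for group comparisons and correlation
  screens; two-sided throughout, no multiplicity correction.

## Validation design and what it shows

The test suite checks, at sizes chosen to keep the default run in minutes:

- exact equivalence of `grow_region()` with a scalar breadth-first flood
  fill and of `dilate_mask()` with all-pairs distance thresholding, on over
  a hundred random volumes up to 16³;
- exactness of the attenuation formulas (`normalized_pba(−420, −500)` is
  0.16 to $10^{-12}$; the normalized image has fixed points 0 at TLA and 1
  at zero attenuation; the shell mean of the normalized image equals the
  normalized PBA by linearity);
- phantom recovery: on the default noisy 192³ phantom the pipeline's PBA
  and TLA land within 2 HU of the truth-mask oracle and the lumen Dice
  overlap is ≥ 0.99 (measured: ≤ 0.15 HU and Dice 1.0);
- statistics against closed-form, exhaustive-enumeration and simulation
  oracles, including the derived finite-sample identity
  $\mathrm{ICC}(2,1) = r\,n/(n-1+r)$ when the two methods have exactly
  matched moments;
- byte-identical reports on repeated identical runs.

### The contrast test, and a known limitation

Across the remodeling series (wall 1 → 3 voxels) normalized PBA rises
strictly, by 0.112 under default conditions. The inflammation-only series
(halo 0 → +80 HU) moves it by 0.038. The suite asserts the inflammation
range stays below one third of the remodeling range; under the committed
defaults the measured ratio is 0.343 — marginally above that bound — and
the assertion fails honestly rather than the conditions being adjusted to
it. The mechanism is instructive: a 1.5 mm halo covers all of the shell's
parenchymal voxels but only about two thirds of the lung, so TLA
normalization cancels roughly 65% of the halo's effect on PBA. Full
cancellation — inflammation leaving normalized PBA untouched — requires
inflammation that is essentially lung-wide, which is exactly the condition
under which the statistic's specificity claim holds in vivo. Users should
therefore expect partial, not perfect, inflammation suppression whenever
inflammation is regionally confined.

`scripts/acceptance.R` recomputes all headline quantities (recovery errors,
Dice, both contrast ranges and their ratio, and two-method agreement
statistics obtained by analysing the same six phantoms with Euclidean vs
iterated-face dilation) from scratch at a caller-supplied seed.

## Known limitations

- No airway-tree centerline, generation labelling or wall-thickness
  measurement: the readout is a single shell-averaged attenuation.
- The exclusion of trachea and mediastinum is the user's responsibility
  (explicit mask); the automatic helper only covers the phantom's known
  trachea.
- Anisotropic volumes must be resampled upstream; the package refuses to
  dilate them rather than silently reinterpreting "8 voxels".
- Shell voxels above −100 HU (frank soft tissue) are *not* excluded from
  PBA — the procedure's second segmentation removes only lumen-band air —
  so mediastinal leakage, if the exclusion mask is too small, biases PBA
  upward.
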