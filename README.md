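# airwayct

Quantification of **bronchial (airway) remodeling** in murine micro-CT by
peribronchial densitometry.

Airway remodeling — smooth-muscle enlargement, basal-membrane thickening and
peribronchial fibrosis — is the structural component of asthma, and until
recently could only be measured invasively (histology). In respiratory-gated
micro-CT of the mouse thorax (isotropic 46 µm voxels), remodeling manifests
as denser tissue immediately around the bronchi. `airwayct` implements a
semi-automatic 3D densitometric readout of that change:

1. **Lumen segmentation** — seeded bi-threshold volume growing of the
   air-filled bronchial lumen, band −1024 to −900 HU.
2. **Shell construction** — 3D morphological dilatation of the lumen by
   8 voxels; a second lumen-band segmentation inside the dilated VOI removes
   all luminal air; the trachea and mediastinum are subtracted via an
   exclusion mask. What remains is the peribronchial shell.
3. **Densitometry** — the shell's mean attenuation **PBA** (peribronchial
   attenuation, HU), the mean attenuation **TLA** of the lung field grown in
   the −900 to −100 HU band (total lung attenuation), and the statistic

   ```
   normalized PBA = 1 − (PBA / TLA)
   ```

   Dividing by TLA cancels attenuation changes that affect the whole lung
   (diffuse inflammation, inflation state), leaving a statistic specific to
   the bronchial wall. A voxelwise analogue `y = 1 − (x / TLA)` renders
   normalized images.

The package also provides HU calibration from in-field air/water standards,
readers/writers for NIfTI, MetaImage and DICOM series, the agreement
statistics used to validate such a method against a manual reference
(Bland–Altman limits at ±2 SD, Pearson r, ICC(2,1), Spearman, exact
Mann–Whitney), and a **synthetic thorax-phantom generator** with
ground-truth masks and oracle attenuations, so the entire pipeline is
testable without animal data.

## Worked example

Generate a noisy synthetic thorax (96³ voxels, 3 airway generations,
noise SD 20 HU) and run the full pipeline against its ground truth:

```r
library(airwayct)

spec <- phantom_spec(grid_shape = c(96, 96, 96), tree_depth = 3,
                     root_radius_voxels = 4)
ph <- generate_phantom(spec)

cfg <- pipeline_config(ph$volume,
                       seeds_lumen = matrix(ph$truth$seed_lumen, nrow = 1),
                       seeds_lung  = matrix(ph$truth$seed_lung, nrow = 1),
                       exclusion_mask = ph$truth$trachea_exclusion_mask)
report <- run_pipeline(cfg)
print(report)
#> Pipeline report (airwayct 0.1.0)
#>   input: in-memory volume
#> Attenuation summary
#>   TLA               -539.51 HU  (159848 lung voxels)
#>   PBA               -505.50 HU  (18756 shell voxels)
#>   normalized PBA     0.0630     [1 - (PBA/TLA)]
#>   bands: lumen [-1024, -900], lung [-900, -100] HU; dilation 8 voxels (euclidean); face6

dice_overlap(report$masks$lumen, ph$truth$lumen_mask)
#> [1] 1
print(ph$truth)
#> <phantom_truth> grid 96x96x96, 3 airway generations
#>   expected TLA -539.47 HU, PBA -505.36 HU, normalized PBA 0.0632
```

TLA is the mean lung-field attenuation (aerated parenchyma plus bronchial
wall); PBA, averaged over the 8-voxel shell around the airways, is less
negative because the shell is enriched in wall tissue. Despite 20 HU of
noise, both recover the phantom's ground-truth oracle to within a fraction
of an HU, and the segmented lumen matches the true lumen voxel-for-voxel
(Dice 1). Thickening the phantom's bronchial walls raises normalized PBA;
adding a diffuse inflammation halo instead changes it far less — the
contrast the statistic is designed for.

Real scans enter the same way via `read_volume()` (DICOM series directory,
`.nii/.nii.gz`, `.mha/.mhd`), with `calibrate_to_hu()` mapping raw scanner
values through the in-field air/water standards, and YAML-driven runs via
`run_pipeline("config.yaml")`. A thin CLI wrapper lives at
`inst/cli/airwayct.R` (`run`, `phantom`, `agreement` subcommands).

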