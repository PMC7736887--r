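# dualPET

Quantitative comparison of **dedicated-breast PET (dbPET)** and
**whole-body PET (wbPET)** images of the same breast tumor.

dbPET scanners image the prone breast at ~1 mm voxel resolution;
routine wbPET reconstructs the same lesion on a ~4 mm grid with a much
wider point spread. For lesions that are small relative to the scanner
resolution, the partial volume effect depresses measured uptake — so
the two modalities disagree in characteristic, size-dependent ways.
`dualPET` implements the full analysis needed to quantify that
disagreement, plus a digital phantom simulator so every stage is
testable without patient data:

- **Phantom & acquisition simulation** — a fine-grid (0.5 mm)
  ground-truth activity phantom (two breasts, one spherical lesion with
  correlated intratumoral heterogeneity, a liver region in the
  whole-body field of view only), imaged through an image-domain
  acquisition model: isotropic Gaussian point spread → block-averaging
  onto the output voxel grid → additive heteroscedastic noise
  (sd ∝ √signal).
- **PERCIST-style uptake quantification** — SUV = C / (decay-corrected
  dose / body weight); SUL = SUV · LBM/W (Janmahasatian lean body
  mass); seeded threshold segmentation (SUV ≥ 3.0 for dbPET, ≥ 2.5 for
  wbPET); SUL_max, SUL_mean, SUL_peak (1.2 cm spherical kernel mean);
  MTV (voxels ≥ 40% of the VOI mean SUV); TLG = MTV × SUV_mean;
  tumor-background ratios against 1.2 cm liver / contralateral-breast
  VOIs.
- **Radiomics** — isotropic 2 mm resampling, fixed-bin-width (w = 0.5)
  discretization, and the 20 morphology / intensity / GLCM / NGTDM
  features, all computed from first principles (including a
  marching-cubes surface mesher for mesh volume, surface area and
  sphericity = (36π V²)^⅓ / A).
- **Paired statistics** — exact Wilcoxon signed-rank (full 2^n
  enumeration for n ≤ 20 without ties), Hodges–Lehmann median
  differences with exact-distribution confidence intervals, and
  d_MRI-stratified (≤ 2.5 cm vs > 2.5 cm) fold changes of stratum
  medians.

## Worked example

```r
library(dualPET)

# one 3 cm lesion, imaged by both modalities
ph  <- buildPhantom(lesionSpec(diameter = 3), seed = 7)
db  <- simulateAcquisition(ph, acquisitionConfig("db"), seed = 8)
at  <- ph@attrs$db
suv <- computeSUV(db, at, decayParams(interval = at@uptakeTime))
sul <- suvToSUL(suv, at)
tum <- segmentTumor(suv, "db", c(41, 41, 43))
bg  <- backgroundVoi(sul, "contralateral",
                     center = "contralateral-centroid",
                     exclude = c(41, 41, 43))
uptakeMetrics(sul, suv, tum, list(contralateral = bg), d_MRI = 3)
```

prints (one row per lesion × modality):

```
  SUL_max SUL_mean SUL_peak MTV_mL     TLG TBR_liver TBR_contralateral d_MRI_cm
1   6.556     4.22    5.134  15.79 107.627        NA             5.525        3
```

i.e. on this simulated dbPET image the lesion's peak lean-mass-scaled
uptake is 5.13 mL⁻¹, its metabolic volume 15.8 mL, total lesion
glycolysis 107.6, and its SUL_peak is 5.5× the mean uptake of the
contralateral-breast background VOI. `extractFeatures(suv, tum)`
returns the 20-feature radiomic vector for the same lesion, and
`runPipeline(runConfig(n = 10, seed = 1))` runs the whole cohort
workflow (simulate → quantify → featurize → compare) and writes NIfTI
volumes, CSV tables, comparison reports and a provenance manifest.

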