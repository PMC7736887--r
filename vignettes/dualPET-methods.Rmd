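---
title: "dualPET: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dualPET: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dualPET` quantifies how the same breast tumor reads out on a
high-resolution dedicated-breast PET (dbPET) image versus a standard
whole-body PET (wbPET) image. This vignette documents the models
behind each stage, the tunable parameters with their defaults and
units, and the places where the design was genuinely open and a choice
had to be made.

## The physical picture

A reconstructed PET image is, to a good approximation, the true
activity distribution convolved with the scanner's point-spread
function (PSF), sampled onto a voxel grid, with noise. dbPET
reconstructs ~1 mm voxels with a narrow PSF; clinical wbPET
reconstructs ~4 mm voxels with a PSF several times wider. For lesions
whose diameter is not much larger than the PSF, blurring moves counts
out of the lesion — the *partial volume effect* (PVE) — so wbPET
underestimates peak uptake more strongly for small lesions. That is
the effect the paired analysis is built to resolve, and the phantom
simulator is built to reproduce.

## Phantom and acquisition model

`buildPhantom()` lays out a fixed anatomy on a 0.5 mm grid
(160 × 80 × 168 mm): two 35 mm-radius parenchyma spheres (ipsilateral
breast with the lesion, contralateral breast for the background VOI),
and a 26 mm-radius liver sphere that only the whole-body field of view
reaches. The lesion is a sphere of the requested diameter whose uptake
is `baseUptake × (1 + a·F)`, where `F` is a unit-amplitude correlated
random field (Gaussian-smoothed white noise, correlation length
`heterogeneityLength`, default 8 mm) and `a` is the heterogeneity
amplitude (default 0.2). With `a = 0` the lesion is exactly uniform.
Uptake magnitudes are held in SUV units and scaled to Bq/mL through
each modality's injected dose and the patient's weight, so that the
SUV/SUL conversion round-trips exactly.

Per-phantom background draws emulate inter-patient variation:
parenchyma SUV ~ U(0.3, 1.5), liver SUV ~ U(1.8, 2.6), lesion base
SUV ~ U(4, 15) in cohorts. These ranges are stand-ins consistent in
magnitude with clinical experience; they are deliberately wide, and
they are the one place where the simulation is *not* calibrated to a
real cohort (no parenchyma SUV distribution is published for these
patients). An optional chest-wall "crosstalk" hot region (off by
default) emulates myocardial spill-in near the edge of the breast
field of view.

`simulateAcquisition()` is purely image-domain:

1. isotropic Gaussian blur at the configured FWHM (default 2 mm for
   db, 7 mm for wb — chosen to produce the qualitative db/wb contrast
   at the stated voxel sizes; no sinogram-level reconstruction is
   modeled);
2. block-averaging onto the output grid (1 mm db / 4 mm wb), which
   preserves total activity exactly — interpolation would not;
3. additive Gaussian noise with sd = `noiseCoef · sqrt(signal)` on the
   SUV scale (default 0.15 db, 0.10 wb; dbPET carries the higher
   background noise), an image-space approximation to
   post-reconstruction Poisson-derived noise;
4. field-of-view cropping. The "breast" FOV keeps both breasts —
   dbPET is acquired bilaterally, and its background VOI lives in the
   contralateral breast — while only the whole-body FOV includes the
   liver.

The simulator's invariants (conservation under blur-free
block-averaging, max never increased by blur, recovery coefficient
monotone in lesion diameter, bit-level seed determinism) are enforced
by tests, with a closed-form Gaussian-sphere convolution as the
analytic oracle for recovery.

Cohort diameters default to a two-component mixture (40% U(2.1, 2.5)
cm, 60% U(3.0, 5.6) cm) so that both sides of the 2.5 cm stratification
cutoff are reliably populated at n = 20, mirroring a cohort whose
small-lesion stratum sits just below the cutoff; a plain uniform range
can be configured instead.

## Uptake quantification

* **SUV** = C / (D/W) with the dose decayed to scan time over the
  configurable `decayParams` interval (F-18 half-life 109.77 min). The
  reference time point is configurable because conventions differ
  between sites; the pipeline decays over the uptake time, which makes
  the simulated round trip exact.
* **SUL** multiplies SUV by LBM/W. The default LBM formula is
  Janmahasatian (female form; the emulated cohort is all female), with
  James and identity selectable. The identity option turns SUL checks
  into SUV checks, which the tests exploit.
* **Segmentation** realizes "semi-automated" delineation as a seeded
  26-connected component of the supra-threshold set (SUV ≥ 3.0 db /
  2.5 wb), the seed standing in for the operator's click. It is
  idempotent: re-seeding anywhere inside the output reproduces it.
* **SUL_peak** is the maximum over tumor voxels of the image mean
  within 0.6 cm of the voxel center — the ~1 mL PERCIST sphere,
  interpreted as 1.2 cm *diameter*. The kernel may extend beyond the
  mask; at the image boundary it is truncated to in-grid voxels. On a
  4 mm grid it covers 19 voxel centers (1 center + 6 face neighbors +
  12 diagonal neighbors at 5.66 mm).
* **Background VOIs** are 1.2 cm-diameter shapes by voxel-center
  inclusion: a cylinder (height = diameter, axis along the image's
  third axis) at the contralateral-breast centroid for db, spheres in
  liver and contralateral breast for wb. Cylinder height and axis are
  conventions chosen here; none are dictated by PERCIST.
* **MTV/TLG**: SUV_mean is computed over the whole VOI, the MTV region
  is {SUV ≥ 0.4 · mean}, MTV is its summed voxel volume, and
  TLG = MTV × mean over the *MTV region* (the prevailing convention;
  a switch selects the VOI mean instead, since the defining sentence
  is ambiguous between the two).
* **TBR** = SUL_peak(tumor) / SUL_mean(background); a non-positive
  background mean yields NA, never infinity. The liver TBR exists only
  for wb.

## Radiomics

Feature extraction resamples image and mask to 2 mm isotropic
(trilinear; the mask as a real field re-binarized at 0.5), so dbPET is
down-sampled and wbPET up-sampled to a common resolution, then
discretizes with a fixed bin width w = 0.5 anchored at zero —
anchoring at the ROI minimum would destroy comparability of absolute
SUV bins across patients and modalities. Levels are
`floor(x/w) + 1` on half-open bins [kw, (k+1)w).

First-order entropy and uniformity are computed on the discretized
histogram; skewness, kurtosis and SD on raw values with population
moments. Kurtosis is un-excess (Pearson): a Gaussian scores 3, which
is the convention consistent with typical PET tumor values near 3.

GLCM matrices are built per direction (13 unique 3D offsets at
Chebyshev distance 1), symmetrized, normalized, and *the matrices*
(not per-direction feature values) are averaged, dropping directions
with no pairs. NGTDM uses 26-neighborhoods restricted to in-mask
voxels; voxels with no in-mask neighbor are excluded from N.
Degenerate conventions are explicit: constant-ROI GLCM correlation is
1 (flagged); NGTDM coarseness is capped at 10⁶ for flat regions;
strength and contrast are 0 when their denominators vanish. All
logarithms are base 2. Every GLCM/NGTDM feature is validated against
an independent brute-force enumeration (shipped in `inst/oracle/`) to
1e-10 relative error on ≥ 50 random ROIs.

Morphology features come from a triangle mesh of the mask surface.
The mesher is a marching-cubes variant whose 256-case table is
generated at first use by walking cube faces (runs of inside corners
bound face segments; chaining them yields closed, consistently
oriented polygons; saddle faces always separate diagonal corners,
which keeps the surface watertight across cubes). A binary mask meshed
directly at the 0.5 level has a bumpy "midpoint" surface whose area
overestimates a sphere's by ~8% (sphericity ~0.92 for a digitized
r = 15 ball); `dualPET` therefore meshes a lightly smoothed indicator
field (Gaussian, sigma 0.8 voxel) — an anti-aliasing step that brings
the digitized ball to sphericity ~0.99 with ~1% volume error, with
error decreasing as the grid is refined. Masks too small to support a
smoothed 0.5-level surface (e.g. a single voxel) fall back to an exact
voxel-box mesh and are flagged degenerate. Mesh volume uses the
divergence theorem over signed tetrahedra; the maximum 3D diameter is
the largest pairwise distance between *surface-voxel centers* — a
deliberate, documented deviation from mesh-vertex conventions, chosen
so the value cannot depend on mesher internals.

## Paired inference

The Wilcoxon signed-rank test drops zero differences (the classical
convention), ranks |d| with midranks, and computes the two-sided
p-value exactly — by enumerating all 2^n sign assignments — whenever
n ≤ 20 and the |d| are tie-free; otherwise it uses the normal
approximation with continuity correction and tie-corrected variance.
The Hodges–Lehmann estimate is the median of the n(n+1)/2 Walsh
averages; CI endpoints are the k-th extreme Walsh averages with k from
the exact signed-rank null distribution, giving conservative coverage
(≥ 95% nominal; ≥ 93% is asserted empirically). Stratified summaries
split at d_MRI = 2.5 cm and report medians, IQRs
(linear-interpolation quartiles — the convention must be stated, since
published IQRs rarely state theirs) and db/wb fold changes of stratum
medians. No multiplicity adjustment is applied by default, matching
the source analysis; Holm adjustment is available for reuse.

## Problem sizes and numerical choices

The test suite and acceptance script run, as the package's study
conditions: a 20-case paired cohort at the default noise levels for
the partial-volume checks; a 5-case noise-free cohort (diameters
2.0–5.2 cm) for volumetric accuracy; 50 random 5–6³ ROIs for the
texture oracles; 2000 simulated null cohorts (n = 10) for the type-I
error of the exact test; and a digitized r = 15 voxel ball for mesh
convergence. The phantom grid is fixed at 0.5 mm (block-averaging
factors must be integers; 1 mm and 4 mm outputs are). Floating-point
tolerances: exact identities (SUL scaling, TLG = MTV × mean, GLCM
normalization) are asserted at 1e-12; oracle equivalence at 1e-10
relative; mesh invariance under axis permutation at 1e-5 (axis-wise
smoothing changes summation order).

## Known limitations

* The acquisition model is image-domain only: no sinogram statistics,
  reconstruction algorithm, time-of-flight, attenuation/scatter
  correction, or motion. Passing tests demonstrate correctness of the
  quantification pipeline under a controlled PVE model, not fidelity
  to any particular scanner.
* The fixed-threshold segmentation genuinely under-covers lesions
  whose base uptake is close to the threshold: a d ≈ 2 cm lesion at
  base SUV ~4 against the db threshold of 3.0 is cut at ~74% of its
  max, and its measured metabolic volume can fall ~15–20% short of
  truth even without noise. This is a property of the method being
  modeled, and the simulator reproduces it.
* Background uptake ranges are plausibility choices, not cohort
  calibrations; simulated tumor-background ratios should be read as
  directional, not as reproductions of published magnitudes.
* One lesion per phantom; multi-focal disease and bilateral
  involvement are out of scope.
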