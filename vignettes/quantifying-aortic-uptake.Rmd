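---
title: "Quantifying thoracic-aortic 18F-NaF uptake: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying thoracic-aortic 18F-NaF uptake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aortama)
```

## The measurement problem

¹⁸F-sodium fluoride PET highlights active microcalcification in the
arterial wall. In the thoracic aorta the conventional readout draws a
2-D region of interest around the vessel on every 3-mm axial slice from
the level where the right pulmonary artery first appears to the last
slice of the arch, records SUVmean and SUVmax per slice, and averages
them; dividing by blood-pool activity gives whole-vessel TBRmean and
TBRmax. The *most diseased segment* (MDS) variant keeps only the three
consecutive slices with the highest mean (and, independently, the
highest max), as a proxy for the single most intense lesion.

Aortic microcalcification activity (AMA) replaces the slice-by-slice
work with two tubular volumes of interest grown around the vessel
centerline — ascending aorta (sinotubular junction up to just proximal
of the brachiocephalic origin) and arch (to just distal of the left
subclavian origin) — and summarizes each as cumulative voxel intensity
divided by VOI volume in cm³, normalized by the blood-pool intensity per
cm³. The result is unitless; a vessel whose VOI is indistinguishable
from blood scores exactly 1. The descending aorta is deliberately never
quantified: it runs alongside the thoracic spine and is contaminated by
bony spill-over.

All three methods share one blood-pool estimate: the mean SUV over two
2-cm³ spheres placed in the right and left atrium.

## Geometric conventions

* Voxel indices are 0-based in formulas; a voxel's position is its
  center, `world = origin + index * spacing` (mm). Nothing is ever
  resampled — every mask is built on the PET grid, and PET–CT
  co-registration is assumed done upstream.
* The tubular VOI radius per section is `(maximal lumen diameter + 4)/2`
  mm. The 4-mm margin reflects the PET point-spread function, tolerance
  to residual misregistration, and the tendency of wall uptake to sit at
  the outer perimeter.
* A voxel belongs to a tube section iff the nearest point of the
  centerline (densely resampled at ≤ 0.25 mm) falls inside the section's
  half-open arc-length interval `[a, b)` *and* lies within the VOI
  radius. Half-open intervals make adjacent sections exactly disjoint —
  the arch starts on "the slice immediately distal" to the ascending
  VOI. Nearest-point ties keep the most proximal sample, so masks are
  deterministic.
* Voxel-center inclusion with no partial-volume weighting, for spheres
  and tubes alike; this matches clinical workstation behavior and makes
  the masks verifiable against exhaustive brute-force geometry, which
  the test suite does on randomized grids up to 64³ (exact set
  equality).
* Dense polyline resampling rather than analytic projection was chosen
  because it is trivially oracle-verifiable and its 0.25-mm
  discretization error is far below the voxel size.
* The arch VOI's distal boundary sits 6 mm past the left subclavian
  landmark by default (`arch_end_mm`), two slices of headroom at 3-mm
  spacing for "immediately distal".

## The bone-exclusion threshold

Sternum and clavicle take up ¹⁸F-NaF avidly; their spill-over would
inflate AMA. Contamination is excluded with an upper voxel-intensity
limit set to the SUVmax of a reference VOI placed in soft tissue
immediately outside the sternum — close enough that its own spill-over
level matches what leaks into the aortic VOI at a comparable distance
from bone. Voxels above the limit are removed from *both* the cumulative
intensity and the volume denominator: the wording "excluding all values
above it" is ambiguous, and removing them from both keeps AMA a mean
over retained tissue rather than penalizing the score for contaminated
volume. The excluded-voxel count is always reported. Thresholding is on
by default in the pipeline (`threshold_ref = "bone"`) and can be
disabled (`"off"`, threshold `+Inf`).

## Combining sections and slices

* Overall AMA pools the sections' cumulative intensities and volumes —
  equivalently a volume-weighted mean of section AMAs. This is the only
  combination consistent with "cumulative voxel intensity divided by the
  volume" applied to the union, and it guarantees the overall value lies
  between the section values.
* Whole-vessel values are *unweighted* means over slices, matching the
  slice-by-slice clinical procedure. Per-slice TBR is the slice's SUV
  statistic divided by the shared background; since the background is a
  single constant, averaging ratios or dividing the averaged SUV is
  mathematically identical.
* MDS windows for the mean and max series are selected independently;
  ties go to the most proximal window. Note that the "hottest 3
  consecutive slices" definition does *not* dominate the whole-vessel
  average for every conceivable series — a profile with hot slices at
  both extremes and a long cold middle (e.g. per-slice means
  3, 0, 0, 3) has a global mean above every 3-window mean. Real axial
  profiles, sampled every 3 mm under a ~5-mm PSF, are smooth enough that
  dominance holds in practice, and the test suite checks it on randomly
  generated vessel-like profiles while documenting the pathological
  counterexample.

## SUV conversion and background correction

SUV is body-weight normalized: `SUV = C / (D_decayed / W)` with activity
concentration in kBq/mL, the injected dose decay-corrected to scan time
(¹⁸F half-life 109.77 min), and weight in grams (1 g ≡ 1 mL). The
normalization variant (body weight vs. lean mass) is a convention
choice; body weight is the conventional default.

An exponential blood-pool clearance correction,
`value · exp(rate · (t_scan − t_ref))`, is available behind an explicit
flag (`time_delay_correct()`) but the pipeline default is **off**: the
correction was devised for coronary studies, and for aortic AMA the
appropriate choice is to leave background uncorrected unless the user
explicitly opts in.

## The phantom: what it emulates, what it does not

`phantom_config()` describes a "candy-cane" aorta: a vertical ascending
segment continuing into a semicircular arch, plus a short descending
stub next to a spine cuboid so the spine-overspill scenario exists in
the field of view. Anatomy sits at fixed world coordinates; a grid too
small to contain it is a configuration error rather than a silently
rescaled vessel.

Defaults and the reasoning behind them:

| parameter | default | why |
|---|---|---|
| grid, spacing | 128³, 2 mm | near the reconstructed resolution of a clinical cardiac PET (256×256 matrix, ~2-mm slices), desk-scale memory |
| `psf_fwhm` | 5 mm | emulates the 5-mm Gaussian post-filter of the clinical reconstruction |
| `blood_suv` | 1.0 | blood pool is the natural unit; TBR-type scores are ratios to it |
| `wall_tbr` | 1.3 | with the ~4:1 lumen:wall volume split of the VOI this yields AMA ≈ 1.05–1.10, the center of the clinically reported range |
| `tissue_suv` | 0.4 | soft tissue sits well below blood on NaF scans |
| lesions | two bumps (amplitude 1.0 and 0.6 SUV, σ 8–10 mm) | reproduces the qualitative spread of focal wall uptake; amplitudes keep TBRmax/MDS in their reported ranges |
| bones | sternum + spine cuboids, SUV 8 | bone NaF uptake is several-fold higher than any vascular signal |
| `noise_sd` | 0.1 SUV | ~10% of blood pool, a plausible reconstructed-image noise level |
| `ascending_length`, `arch_radius` | 95 mm, 30 mm | the span from the right-pulmonary-artery level to the arch apex then covers ~105 mm, i.e. 30–40 slices at 3-mm spacing |

Lesions are Gaussian bumps in *arc-length* added to the wall (a focal
ring), blurred with everything else; `fill_voi_uniform` overrides the
tube to a constant `wall_tbr · blood_suv` so exact-recovery tests have a
closed-form answer. Noise is i.i.d. Gaussian in SUV space, added after
blurring — the analysis operates on reconstructed SUV images, so noise
is modeled there rather than as Poisson counts. `rescan()` keeps the
noiseless signal and redraws only the noise, the digital analogue of a
repeat scan within days.

What the phantom does **not** emulate: attenuation/scatter, cardiac or
respiratory motion (and hence motion correction), list-mode
reconstruction, CT appearance, anatomical variation of the arch
branches, and spatially correlated reconstruction noise. Passing tests
therefore demonstrate correctness of the *measurement machinery* on
known geometry and its statistical behavior under image noise and VOI
redraw variability — not clinical performance on patient scans.

## Simulated validation studies

`scan_rescan_harness()` draws subjects from one anatomy with randomized
disease burden (baseline wall TBR uniform on 1.0–1.6; a Poisson(2)
number of lesions with random position, amplitude 0.3–1.5 and width
5–15 mm), simulates two noise realizations per subject and reports
Bland–Altman statistics and ICC per metric. `validate_study()` adds
observer rows: observers vary in where they *draw*, not in the image, so
intra-/inter-observer variability is modeled as seeded jitter of the VOI
geometry (rigid shift plus smooth centerline wobble, landmark and sphere
perturbations; 0.5 mm intra, 1.5 mm inter by default). The ICC variant
is fixed to ICC(2,1) — two-way random effects, absolute agreement,
single measurement — the standard choice for test–retest of a
measurement method; the coefficient of repeatability is 1.96·SD of the
paired differences and its percentage uses the grand mean of all 2n
measurements.

## Numerical choices and degenerate inputs

* Gaussian blurring is separable with a zero-padded kernel truncated at
  3σ and renormalized to unit sum; structures ≥ 3 FWHM from the grid
  faces conserve their total intensity to well under 1%.
* All randomness flows through explicit integer seeds; phantom
  generation is bit-reproducible, and the harness derives per-subject
  seeds below 2³¹ from its master seed.
* Degenerate inputs fail loudly: empty or overlapping background
  spheres, empty section VOIs, a section whose voxels are all above the
  threshold, fewer than 3 slices for MDS, zero-variance input to ICC,
  constant input to Pearson correlation, geometry outside the grid.
* Empty slices at the edges of the requested ROI range are dropped with
  a warning (the range endpoints are anatomical estimates); an empty
  slice in the interior is an error.

## Problem sizes in the test suite

The suite validates on 64³ grids with 3-mm voxels (the same fixed
anatomy, shortened ascending segment) so a full run stays in tens of
seconds: mask-vs-brute-force equality on 20 randomized geometries up to
36³; the scan-rescan harness with 20 subjects at three noise levels;
50-table statistical oracle comparisons at 1e-10. The acceptance script
uses the full 128³ clinical-geometry phantom. These sizes are choices of
the package's validation design, balancing coverage against run time.

## Known limitations

* One radius per section (the section's *maximal* lumen diameter), not a
  per-slice adaptive radius — faithful to the measurement protocol, but
  it includes more perivascular tissue where the vessel tapers.
* The 2-D arch ROIs are the intersection of the axial slice with the
  union of the tube masks, so at the arch apex both limbs merge into one
  elongated region; whether human observers would draw one contour or
  two is a convention the package fixes rather than infers.
* The bone-exclusion threshold is only as good as the reference VOI
  placement, which is a required input, not a heuristic.
* Agreement statistics come without confidence intervals, and no
  multiple-testing correction is applied to risk-score correlations.
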