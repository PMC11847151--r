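---
title: "Curating DICOM-RT datasets with rtcurate: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating DICOM-RT datasets with rtcurate: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical radiotherapy archives arrive as loose trees of DICOM files: CT
(or MR/PET) series stored one file per slice, RT Structure Sets holding
named contours as stacks of planar polygons in patient coordinates, RT
Plans, and RT Dose grids stored as scaled integers. Which files belong
together is encoded not in the folder layout — which is rarely
informative — but in DICOM reference metadata: an RTSTRUCT references its
image series, an RTDOSE references an RTPLAN, which references the
RTSTRUCT. Analysis pipelines, by contrast, want one coherent sample per
patient: an image volume, a segmentation mask on the same grid, and
optionally a co-registered dose map, in NIfTI or NRRD.

`rtcurate` automates that curation in three stages:

1. **Crawl** — open every file under a root (any depth, any layout),
   read its header only, and aggregate identifiers, modality and
   cross-references into a series-level index. The index is a
   few-kilobytes CSV artifact that can be shared, so that other users of
   the same dataset can skip the crawl entirely.
2. **Connect** — build a directed reference graph over series and answer
   modality queries such as `"CT,RTSTRUCT,RTDOSE"`, walking the
   RTDOSE→RTPLAN→RTSTRUCT→image chain transitively.
3. **Process** — per sample: optional resampling to a target spacing,
   optional Hounsfield windowing, contour rasterization onto the image
   grid, dose alignment, and export.

`run_pipeline()` (or the `inst/cli/autopipeline.R` wrapper) runs all
three from a single call; outputs are a pure function of the input bytes
and the configuration.

## Geometry model

All geometry lives in DICOM patient LPS coordinates. A volume is a 3-D
array with `origin` (mm), `spacing` (mm) and a 3×3 orthonormal
`direction` matrix, and the position of 0-based voxel index $(i,j,k)$ is

$$ \mathbf{x} = \mathbf{o} + D\,(\mathbf{s} \circ (i,j,k)) $$

— the single source of truth used by the readers, the rasterizer, the
interpolators and the writers alike. Voxel arrays are stored in
`(column, row, slice)` order, i.e. $x$ fastest: R arrays are
column-major, so this order matches both the byte order of DICOM
PixelData and the on-disk layout of NIfTI, and no transposes occur
anywhere in the package. Conversion to the RAS convention required by
NIfTI (sign flip of the first two axes) happens exactly once, inside
`write_volume()`; NRRD headers declare
`space: left-posterior-superior` and need no flip.

Slices of an image series are ordered by the projection of each file's
image position onto the slice normal (the cross product of the row and
column cosines), never by file name or instance number. Inter-slice gaps
must be uniform to a relative 1e-3; `allow_irregular = TRUE` downgrades
the error to a warning because real clinical series occasionally violate
uniformity by small amounts.

## DICOM input/output

No DICOM codec is available in this package's R dependency stack, so
`rtcurate` carries its own minimal Part-10 reader and writer. The reader
handles explicit and implicit VR little endian, nested sequences with
defined or undefined lengths, and a header-only mode that seeks past
PixelData — this is what keeps crawling cheap and the index small. The
writer emits explicit VR little endian with defined-length sequences.
Out of scope, by design: compressed transfer syntaxes, big-endian files,
and multi-frame image series (a clear error is raised); RT Dose
multi-frame grids *are* supported since that is their normal form.
Truncated files are detected (declared element length beyond end of
file) and fail loudly rather than silently reading zeros.

Dose grids are returned in Gy: stored integers × the dose grid scaling
factor, whose absence is an error — a silent default of 1.0 could be off
by orders of magnitude.

## Rasterization

The contour-to-mask rule is the even-odd (parity) rule evaluated at
voxel centers: a center is inside if a ray cast in $+x$ crosses the
polygon's edges an odd number of times. Multiple contours of one ROI on
the same slice combine by parity too, so inner contours punch holes. A
center lying exactly on an edge is resolved by nudging the test point by
$+10^{-9}$ (in continuous index units) along both axes — an arbitrary
but fixed and documented tie-break, chosen so that an axis-aligned
square with corners on the lattice contains exactly
`width × height` centers. The production implementation is a per-row
scanline; the test suite checks it voxel-for-voxel against an
independent brute-force point-in-polygon oracle on hundreds of random
convex polygons, and against closed-form volumes of sphere fixtures.

When resampling is requested, contours are rasterized directly at the
*final* (post-resample) image geometry rather than rasterized first and
resampled as labels. Label interpolation artifacts are thereby ruled
out; masks are never interpolated with anything but nearest neighbour.
ROI selection uses ordered, case-insensitive, full-string regular
expressions (`roi_patterns`): the first pattern set that matches wins,
several matching ROIs merge into one label, and a pattern with no match
follows `roi_missing_policy` (`warn` by default).

## Interpolation

`linear` (trilinear) is the default for images and dose; `nearest` is
available and is forced for masks. The smooth option is separable
Catmull-Rom cubic convolution (`cubic`, with `bspline` accepted as an
alias for familiarity with ITK-style naming). Cubic convolution can
undershoot; aligned dose is clamped at 0 Gy since negative absorbed dose
is meaningless. Resampling preserves the origin and covers the full
input extent with `ceiling(size × spacing / target)` voxels per axis;
values outside the source grid are border-clamped during resampling but
set to 0 Gy during dose alignment (a dose grid legitimately covers only
part of the image).

## Linking heuristics and sample multiplicity

`metadata` (default) uses only explicit reference UIDs.
`frame_of_reference` additionally links an RT series that has *no*
outgoing reference to every image series of the same patient sharing its
frame of reference UID; `study` finally falls back to same-study
linking. Fallbacks only ever add edges to otherwise unlinked series, so
the recovered sample set grows monotonically across the three levels,
and every edge records its provenance (`edge_kind`).

A patient with two structure sets on one CT yields two samples: the
cross-product policy makes one-to-many cases — the classic curation pain
point — explicit instead of silently picking one. `dedup = "latest"`
keeps, per anchor image, the tuple whose non-image members have the most
recent series date; ties break deterministically by sample id. Sample
ids are the first 10 hex digits of the MD5 of the sorted member series
UIDs: stable across runs, safe as folder names.

## Determinism engineering

Byte-identical outputs across repeated runs and worker counts are a
stated contract, relied on by the pre-crawled-index workflow. The
ingredients: records and samples are sorted with radix (byte-order)
string sorts, never locale-dependent ones; no wall-clock values enter
the index, the run manifest or any volume (timestamps only exist in the
log file under `.imgtools/logs`); gzip streams are written without
modification times; parallel workers process disjoint units and results
are reduced by deterministic sort. The manifest JSON of the synthetic
generator deliberately omits the output root so two generations of the
same specification are byte-identical wherever they land.

## The synthetic fixture generator

Every guarantee above is validated against `generate_dataset()`, which
writes genuine DICOM Part-10 files with analytic ground truth. The
canonical dataset (the defaults of `fixture_spec()`): 2 patients, each a
64×64×48 CT at 1 mm isotropic spacing, background −1000 HU and a 20 mm
radius sphere of +100 HU centred in the grid — soft-tissue-like contrast
that makes windowing and masking statistics exact. Contours are sampled
at 1° steps on every slice the shape intersects, written at 4-decimal
precision. The optional dose grid is coarser (2 mm) and holds a linear
gradient along $x$, quantized exactly: the scaling factor is chosen so
the maximum stored integer is 5000 (50 Gy at the default scaling of
0.01) and every stored value is an exact integer, so linear
interpolation must reproduce the analytic field to floating-point
accuracy, not approximately. Files are deliberately scattered across
unintuitive folders (CT inside patient trees, structure sets and doses
in shared top-level folders) to exercise the recursive crawl. All UIDs
derive from the seed under a fixed private root; no randomness enters
pixel data.

`corrupt_dataset()` severs reference metadata by splicing the targeted
element out of the file bytes — `drop_rtstruct_reference` removes the
explicit RTSTRUCT→CT link (recoverable by the frame-of-reference
heuristic), `drop_frame_of_reference` removes that fallback too.

What the generator does **not** emulate: acquisition noise and texture,
gantry tilt, variable slice spacing, multi-frame or compressed files,
vendor-specific tag quirks, misspelled or inconsistent ROI nomenclature,
and multiple acquisitions per study. Green tests therefore demonstrate
correctness of geometry, linking and processing logic under clean and
specifically-corrupted metadata — not robustness to every pathology of
clinical archives.

## Validation problem sizes

The shipped tests and the acceptance script use: 200 random convex
polygons on grids up to 24×24 for the rasterizer–oracle comparison;
the 2-patient canonical dataset (~100 files) for end-to-end, round-trip,
determinism and nnU-Net checks; and a 10-patient full-chain dataset
(~510 files) for graph recovery. These sizes keep the whole validation
run in well under two minutes while exercising every code path; all
quantities are scale-free (percentages, counts, relative errors), so
nothing about the checks depends on dataset size.

## Known limitations

* Single-file (multi-frame) image series and compressed transfer
  syntaxes are not read.
* No image registration, atlas segmentation or intensity harmonization
  beyond windowing — deliberate non-goals.
* The `study` fallback can legitimately over-link when one study holds
  several unrelated image series; the unmatched report and `edge_kind`
  provenance exist precisely so such links can be audited.
* Dose-volume histograms and RTPLAN beam geometry are not parsed; the
  plan is traversed only for its reference UIDs.
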