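# rtcurate

Bulk curation of raw DICOM / DICOM-RT datasets into analysis-ready
volumes, in R.

Clinical imaging archives — radiotherapy ones in particular — arrive as
arbitrarily organized trees of DICOM files: CT series stored slice by
slice, RT Structure Sets (contours), RT Plans and RT Dose grids, linked
to each other only through reference metadata buried in their headers.
Researchers who want the standard machine-learning starting point — one
image volume, one segmentation mask, optionally a co-registered dose map
per patient, as NIfTI or NRRD — typically re-write the same brittle
glue for every dataset. `rtcurate` replaces that glue with one
deterministic pipeline:

1. **Crawl** — recursively index every DICOM file's metadata (headers
   only) into a shareable, few-kilobytes series-level CSV index.
2. **Connect** — build a directed reference graph
   (RTDOSE→RTPLAN→RTSTRUCT→image) and resolve modality queries like
   `"CT,RTSTRUCT,RTDOSE"` into coherent per-patient samples, with
   frame-of-reference and study fallback heuristics for files with
   missing references.
3. **Process** — per sample: resample to a target spacing, clip to a
   Hounsfield window, rasterize contours onto the image grid (even-odd
   rule at voxel centers), align the dose grid, and write
   NIfTI/NRRD — plus an optional nnU-Net `imagesTr`/`labelsTr` export.

Outputs are byte-identical across repeated runs, worker counts, and the
crawl-versus-preloaded-index paths, so a saved index fully substitutes
for a crawl. The package also ships a deterministic synthetic DICOM-RT
generator (`generate_dataset()`) with analytic ground truth — spheres
and cuboids of known volume, exactly quantized linear dose gradients,
optionally corrupted reference metadata — against which every stage is
validated.

## Worked example

```r
library(rtcurate)

# a synthetic 2-patient dataset: 64x64x48 CT (1 mm), 20 mm sphere ROI,
# full RTDOSE -> RTPLAN -> RTSTRUCT -> CT chain
man <- generate_dataset(
  fixture_spec(n_patients = 2, include_rtplan = TRUE, include_rtdose = TRUE),
  "raw_dicom")

manifest <- run_pipeline(pipeline_config(
  input_dir = "raw_dicom", output_dir = "curated",
  modalities = "CT,RTSTRUCT,RTDOSE",
  processing = processing_params(roi_patterns = list(gtv = "GTV"))))

manifest[, c("patient_id", "status", "outputs")]
#>   patient_id status                                                  outputs
#> 1       P001     ok P001/9c2220ed29/CT.nii.gz;P001/9c2220ed29/RTDOSE.nii.gz;P001/9c2220ed29/mask_gtv.nii.gz
#> 2       P002     ok P002/44353d1c82/CT.nii.gz;P002/44353d1c82/RTDOSE.nii.gz;P002/44353d1c82/mask_gtv.nii.gz

# the rasterized mask recovers the analytic sphere volume
mask <- read_volume("curated/P001/9c2220ed29/mask_gtv.nii.gz")
sum(mask$voxels == 1) * prod(mask$spacing)
#> [1] 33381          # analytic: 4/3 * pi * 20^3 = 33510.3 mm^3 (0.39% off)

dose <- read_volume("curated/P001/9c2220ed29/RTDOSE.nii.gz")
max(dose$voxels)
#> [1] 50             # stored max 5000 x dose grid scaling 0.01 -> 50 Gy
```

Each sample directory holds the image, one binary mask per configured
label, and the dose aligned onto the image grid; `manifest.csv` and
`run_info.json` record per-sample status and the run parameters. The
crawl index lands under `raw_dicom/.imgtools/` — share its `series.csv`
and others can run the same pipeline with
`preloaded_index = "raw_dicom/.imgtools"` and get byte-identical
outputs without crawling.

From a shell, the same run is:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/autopipeline.R", package="rtcurate"))')" \
    raw_dicom curated --modalities CT,RTSTRUCT,RTDOSE --roi-yaml rois.yaml
```

(`--spacing`, `--window`, `--heuristic`, `--workers`, `--nnunet`,
`--index`, `--overwrite-policy` and a YAML `--config` are also
available; exit code 0 = success, 2 = completed with per-sample
failures, 1 = fatal.)

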