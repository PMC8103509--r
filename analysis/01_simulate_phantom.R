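#!/usr/bin/env Rscript
# Step 1 -- simulate the phantom study.
#
# Renders the fixed 10-layer texture scene once and acquires it on the two
# virtual scanner models at the seven study pixel spacings (14 scans in
# total, all images of the same object). Volumes and masks go to
# scratch/phantom/ as NIfTI; the scan manifest goes to results/.

suppressPackageStartupMessages(library(radstab))

base_seed <- 101L
dir.create("scratch/phantom", recursive = TRUE, showWarnings = FALSE)
dir.create("results", recursive = TRUE, showWarnings = FALSE)

message("Rendering the master scene and acquiring 14 scans ...")
dataset <- make_dataset(base_seed = base_seed)
saveRDS(dataset, "scratch/phantom/dataset.rds")

manifest <- do.call(rbind, lapply(dataset, function(s) {
  vol_path <- file.path("scratch/phantom",
                        paste0(s$meta$scan_id, "_image.nii.gz"))
  mask_path <- file.path("scratch/phantom",
                         paste0(s$meta$scan_id, "_mask.nii.gz"))
  write_volume(s$volume, vol_path)
  write_mask(s$mask, mask_path)
  data.frame(scan_id = s$meta$scan_id,
             scanner_model = s$meta$scanner_model,
             in_plane_spacing_mm = s$meta$in_plane_spacing_mm,
             slice_thickness_mm = s$meta$slice_thickness_mm,
             seed = s$meta$seed,
             hu_min = min(s$volume$voxels), hu_max = max(s$volume$voxels),
             image = vol_path, mask = mask_path,
             stringsAsFactors = FALSE)
}))
write.csv(manifest, "results/scan_manifest.csv", row.names = FALSE)

message(sprintf(
  "Done: %d scans, spacings %s mm, HU envelope [%.0f, %.0f].",
  nrow(manifest), paste(range(manifest$in_plane_spacing_mm), collapse = "-"),
  min(manifest$hu_min), max(manifest$hu_max)))
message("Manifest written to results/scan_manifest.csv")
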