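#!/usr/bin/env Rscript
# Step 1: generate the synthetic study material.
#
# Two paired cohorts (fetal and adult; 7 control + 7 IUGR hearts each, 3
# images per heart, 8 fibers per image) are simulated with ground truth set
# to the reference group configurations. Images are written as 16-bit TIFFs
# under scratch/images/ (bulky, regenerable); the ground-truth fiber tables
# and the cohort manifest go to results/.

suppressMessages(library(sarcomorph))

img_dir <- "scratch/images"
dir.create(img_dir, showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)

for (age in c("fetal", "adult")) {
  spec <- cohort_spec_from_reference(age, n_hearts = 7, images_per_heart = 3,
                                     fibers_per_image = 8,
                                     seed = if (age == "fetal") 101L else 102L)
  coh <- simulate_cohort(spec)
  for (id in names(coh$images)) {
    write_shgm_image(coh$images[[id]], file.path(img_dir, paste0(id, ".tif")))
  }
  manifest <- coh$manifest
  manifest$path <- file.path(img_dir, paste0(manifest$image_id, ".tif"))
  write_table_csv(manifest, sprintf("results/%s_manifest.csv", age))
  write_table_csv(coh$fibers, sprintf("results/%s_truth_fibers.csv", age))
  write_table_csv(coh$hearts, sprintf("results/%s_truth_hearts.csv", age))
  message(sprintf("%s cohort: %d hearts, %d images, %d fibers",
                  age, nrow(coh$hearts), nrow(manifest), nrow(coh$fibers)))
}
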