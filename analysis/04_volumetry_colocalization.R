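#!/usr/bin/env Rscript
# 3D lipid-droplet volumetry from the 2851 cm^-1 channel of phantom
# z-stacks (1 um steps), and alkyne-drug colocalization: Pearson r between
# the 2851 cm^-1 lipid channel and the 2233 cm^-1 alkyne channel when the
# drug is trapped inside the phospholipidosis inclusions versus placed
# independently in the cytoplasm.

suppressMessages(library(srsphasor))
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

## droplet volumetry across conditions. One *global* threshold is derived
## from the pooled within-cell intensities of all conditions and applied
## everywhere: per-condition Otsu would collapse onto the nucleus/cytoplasm
## split in a condition with hardly any droplets.
phantoms <- lapply(c(control = "control", steatosis = "steatosis"),
                   function(cond) generate_phantom(
                     default_phantom_config(cond, seed = 911L)))
pooled <- unlist(lapply(phantoms, function(ph) {
  channel_image(ph$stack, 2851)[ph$cell_instances > 0]
}))
thr <- attr(background_mask(array(pooled, c(length(pooled), 1)), "otsu"),
            "provenance")$threshold
cat(sprintf("global droplet threshold (pooled Otsu): %.3f\n", thr))

rows <- list()
for (cond in names(phantoms)) {
  ph <- phantoms[[cond]]
  ld <- ld_segment_3d(channel_image(ph$stack, 2851),
                      ph$stack$pixel_size, ph$stack$z_step,
                      method = "manual", manual_threshold = thr,
                      mask = ph$cell_instances > 0,
                      cell_instances = ph$cell_instances)
  dd <- ld$droplets
  if (nrow(dd)) dd$condition <- cond
  rows[[cond]] <- dd
  cat(sprintf("%-10s: %2d droplets, total %6.1f um^3, per-droplet median %5.2f um^3\n",
              cond, nrow(dd), sum(dd$volume_um3),
              stats::median(dd$volume_um3)))
}
droplets <- do.call(rbind, rows)
write.csv(droplets, "results/tables/droplets.csv", row.names = FALSE)

## alkyne colocalization: axis widened to cover the cell-silent region
ax <- build_wavenumber_axis(1031.4, 2200, 3050, 1.0)
tolc <- 0.75 * max(diff(ax$values))
coloc_r <- function(colocalized, counts, seed) {
  ph <- generate_phantom(phantom_config(seed = seed, droplet_counts = counts,
                                        alkyne_colocalized = colocalized,
                                        axis = ax))
  colocalize(channel_image(ph$stack, 2851, tol = tolc),
             channel_image(ph$stack, 2233, tol = tolc),
             ph$cell_instances > 0)
}
seeds <- 301:305
r_co <- sapply(seeds, function(s) coloc_r(TRUE,
  list(steatosis = 2L, phospholipidosis = 8L, alkyne = 6L), s))
r_ind <- sapply(seeds, function(s) coloc_r(FALSE,
  list(steatosis = 2L, phospholipidosis = 4L, alkyne = 4L), s))
coloc <- data.frame(seed = seeds, colocalized_r = r_co, independent_r = r_ind)
write.csv(coloc, "results/tables/colocalization.csv", row.names = FALSE)
cat(sprintf("lamellar-body trapping: r = %.2f +/- %.2f; independent: r = %.2f +/- %.2f\n",
            mean(r_co), sd(r_co), mean(r_ind), sd(r_ind)))
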