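#!/usr/bin/env Rscript
# Row-normalised, similarity-clustered heatmaps of the reference density,
# colocalization and intensity tables - the standard visual summary of
# marker-by-region synaptome profiles.
#
# Finding: in the mouse intensity heatmap SV2A and SYN (both pan-synaptic,
# high-variance profiles) end up adjacent in the leaf order, while the
# postsynaptic markers PSD95 and GPHN group at the other end.

suppressMessages(library(synmapr))
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

sets <- list(
  mouse_density = ref_mouse_density()$mean,
  mouse_coloc = ref_mouse_coloc()$mean,
  mouse_intensity = ref_mouse_intensity()$mean,
  human_density = ref_human_density()$mean,
  human_coloc = ref_human_coloc()$mean,
  human_intensity = ref_human_intensity()$mean)

for (nm in names(sets)) {
  file <- file.path("results/figures", paste0(nm, "_heatmap.png"))
  spec <- plot_marker_heatmap(sets[[nm]], file = file, main = nm)
  ord <- rownames(sets[[nm]])[spec$row_order]
  cat(sprintf("%-16s row order: %s\n", nm, paste(ord, collapse = " ")))
}
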