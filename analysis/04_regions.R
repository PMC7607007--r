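#!/usr/bin/env Rscript
# Fin geometry: fit the best-fit plane to the 18 edge landmarks, partition
# the fin into quadrants (x medial/lateral surfaces = octants), quantify
# per-octant afferent length and terminals, and estimate the axial
# innervation overlapped by the adducted (model) fin.

suppressMessages(library(finmorph))

reg <- run_regions("results/data", "results/data/landmarks.csv",
                   out_dir = "results")

cat("Quadrant areas (um^2):\n")
print(round(reg$regions$areas))
cat("\nConservation (octant sum vs fin-restricted total), max relative error:",
    format(max(reg$conservation$relative_error), digits = 3), "\n")

oct <- reg$octants
by_surface <- tapply(oct$length_um, oct$surface, sum)
cat("Innervation by surface (um):",
    paste(names(by_surface), round(by_surface), sep = "=", collapse = " "),
    sprintf("(medial share %.1f%%)\n",
            100 * by_surface[["medial"]] / sum(by_surface)))
by_region <- tapply(oct$length_um, oct$region, sum)
cat("Innervation by quadrant (um):",
    paste(names(by_region), round(by_region), sep = "=", collapse = " "), "\n")
cat("\nModel-fin adduction overlap, percent of axial innervation:\n")
print(round(summary(reg$overlap$model_overlap_percent), 1))
cat("\nOutputs: results/region_lengths.csv, results/axial_overlap.csv,",
    "results/conservation.csv\n")
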