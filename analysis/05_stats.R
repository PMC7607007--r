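#!/usr/bin/env Rscript
# Cohort statistics: medial-terminal vs under-fin axial-terminal Pearson
# correlation, the anteroposterior trend of total fin afferent length (with
# and without the Rohon-Beard neurons), and the axial-vs-fin total length
# comparison (chi-square as a goodness-of-fit of the summed totals, plus a
# paired Wilcoxon alternative).

suppressMessages(library(finmorph))

st <- run_stats("results/region_lengths.csv", "results/axial_overlap.csv",
                "results/features.csv", "results/data/metadata.csv",
                out_json = "results/statistics.json")

p <- st$pearson_medial_vs_axial_under_fin
cat(sprintf("Pearson, medial fin terminals vs axial terminals under the fin: r = %.3f, p = %.4g (n = %d)\n",
            p$r, p$p, p$n))
t1 <- st$ap_trend_all
cat(sprintf("Anteroposterior trend of fin afferent length: slope = %.2f um/um, F = %.2f, p = %.4g\n",
            t1$slope, t1$F, t1$p))
t2 <- st$ap_trend_without_rb
cat(sprintf("  without Rohon-Beard neurons: slope = %.2f, p = %.4g (n = %d)\n",
            t2$slope, t2$p, t2$n))
lc <- st$axial_vs_fin_length
cat(sprintf("Axial vs fin total length: chi-square = %.2f (p = %.3g); paired Wilcoxon p = %.3f\n",
            lc$chi_square$statistic, lc$chi_square$p, lc$wilcoxon$p))
cat("\nFull report: results/statistics.json\n")
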