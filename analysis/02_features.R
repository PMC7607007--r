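#!/usr/bin/env Rscript
# Compute the 13-parameter morphological feature vector for every simulated
# neuron (fin-restricted tree metrics plus the two soma parameters) and flag
# the neurons eligible for clustering.

suppressMessages(library(finmorph))

feats <- run_features("results/data", "results/data/metadata.csv",
                      out_csv = "results/features.csv")

cat("Feature table: results/features.csv —", nrow(feats), "neurons,",
    sum(feats$clusterable), "clusterable\n")
excluded <- feats$neuron_id[!feats$clusterable]
if (length(excluded)) {
  cat("Excluded from clustering (no branching in the fin):",
      paste(excluded, collapse = ", "), "\n")
}
cat("\nTotal fin afferent length (um):\n")
print(round(summary(feats$total_length)))
cat("Branch points:", paste(range(feats$n_branch_points), collapse = "-"),
    " Strahler:", paste(range(feats$strahler), collapse = "-"), "\n")
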