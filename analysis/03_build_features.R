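#!/usr/bin/env Rscript
# Step 3: build the thirteen biomarker feature sets.
#
# Every biomarker in the registry is constructed from the harmonized
# cohort: the four-variable global SA/eTIV set, regional maps, pairwise
# and summed inter-regional difference features, and the functional
# connectome derivations (partial correlations, degree centrality, the
# first two gradients). Feature tables are serialized as TSV; the wide
# pairwise sets are stored raw and PCA-reduced fold-safely at
# classification time.

suppressPackageStartupMessages(library(synmark))

hc <- load_cohort("results/cohort_harmonized")
dir.create("results/features", showWarnings = FALSE)

reg <- biomarker_registry(ncol(hc$area), ncol(hc$subcortical))
for (id in reg$id) {
  fb <- build_biomarker(hc, id)
  save_matrix(fb$values, file.path("results/features", paste0(id, ".tsv")))
  cat(sprintf("%-20s %5d features\n", id, ncol(fb$values)))
}

# the group-level structural covariance summary behind the thickness
# coupling comparison (case resamples sized to the case group)
case <- hc$meta$group == "case"
spec <- list(n_per_resample = sum(case), n_resamples = 20, seed = 1)
r_case <- structural_covariance(hc$thickness[case, ])$r_matrix
r_ctrl <- structural_covariance(hc$thickness[!case, ], spec)$r_matrix
save_matrix(r_case, "results/features/thickness_covariance_cases.tsv")
save_matrix(r_ctrl, "results/features/thickness_covariance_controls.tsv")
off <- upper.tri(r_case)
cat(sprintf("mean inter-regional thickness r: cases %.3f, controls %.3f\n",
            mean(r_case[off]), mean(r_ctrl[off])))
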