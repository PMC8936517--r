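#!/usr/bin/env Rscript
# Cohort-level analysis of the single-agent DSS matrix: Ward/Euclidean
# hierarchical clustering of samples and drugs, Newick dendrogram export,
# a heatmap, and a two-group Mann-Whitney comparison of a heterogeneous
# drug's DSS between the DSS-defined sample clusters.

suppressPackageStartupMessages(library(exscreen))

dss_tbl <- read_results("results/single_agent/dss.csv")
dir.create("results/cohort", showWarnings = FALSE, recursive = TRUE)

cohort <- assemble_cohort(dss_tbl[dss_tbl$source == "single", ])
cl <- cluster_cohort(cohort, axis = "both", k = 3)
labels <- cl$samples$labels
write_results(tibble::tibble(sample_id = names(labels),
                             cluster = unname(labels)),
              "results/cohort/sample_clusters.csv")
export_newick(cl$samples$hclust, "results/cohort/sample_dendrogram.nwk")
export_newick(cl$treatments$hclust, "results/cohort/drug_dendrogram.nwk")
message(sprintf("clustered %d samples x %d drugs into %d sample clusters (sizes: %s)",
                nrow(cohort$dss), ncol(cohort$dss), max(labels),
                paste(table(labels), collapse = ", ")))

# drug with the most heterogeneous response across samples
spread <- apply(cohort$dss, 2, stats::sd)
drug_het <- names(which.max(spread))
g <- ifelse(labels == labels[which.max(cohort$dss[, drug_het])],
            "sensitive-cluster", "other")
mw <- group_compare(cohort$dss[, drug_het], g)
message(sprintf(
  "most heterogeneous drug: %s (SD %.1f DSS units); Mann-Whitney between clusters: U = %g, p = %.3g (%s)",
  drug_het, max(spread), mw$U, mw$p, mw$method))
write_results(tibble::tibble(drug = drug_het, U = mw$U, p = mw$p,
                             method = mw$method),
              "results/cohort/group_comparison.csv")

# heatmap (best effort; skipped when pheatmap is unavailable)
if (requireNamespace("pheatmap", quietly = TRUE)) {
  dir.create("results/figures", showWarnings = FALSE)
  pheatmap::pheatmap(
    t(cohort$dss), clustering_method = "ward.D2",
    clustering_distance_rows = "euclidean",
    clustering_distance_cols = "euclidean",
    filename = "results/figures/dss_heatmap.png", width = 10, height = 6)
  message("heatmap written to results/figures/dss_heatmap.png")
}
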