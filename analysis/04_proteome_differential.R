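# Label-free proteome differential analysis: quantifiability filter, log2
# transform, downshifted-Gaussian imputation, one-way ANOVA with BH FDR,
# Tukey HSD post-hoc, pairwise t-tests, z-score profile clustering and
# sample PCA.

source(file.path("analysis", "00_config.R"))

qt <- read_quant_table(file.path(DATA_DIR, "proteome_quant.tsv"))
truth <- read.delim(file.path(DATA_DIR, "proteome_truth.tsv"),
                    comment.char = "#", stringsAsFactors = FALSE)

filtered <- filter_quantifiable(qt, CFG)
message("Quantifiable in >= ", CFG$min_quant_reps, " replicates of one ",
        "genotype: ", attr(filtered, "n_kept"), " of ",
        nrow(qt$values), " proteins")

completed <- impute_missing(log2_transform(filtered), CFG)
message("Imputed ", sum(attr(completed, "imputed_mask")), " missing cells")

av <- anova_bh(completed, CFG)
sig <- av$accession[av$significant]
save_tsv(av, "proteome_anova.tsv")
message("ANOVA with BH FDR < ", CFG$fdr_q, ": ", length(sig),
        " significant proteins")
true_eff <- truth$accession[truth$diff_class != "null"]
message(sprintf("  of %d proteins with true effects, %d detected (%.0f%%)",
                length(true_eff), sum(true_eff %in% sig),
                100 * mean(true_eff %in% sig)))

if (length(sig) > 0) {
  tk <- tukey_hsd(completed, sig, CFG)
  save_tsv(tk, "proteome_tukey.tsv")
  message("Tukey HSD flags per pair: ",
          paste(names(tapply(tk$flag, tk$pair, sum)),
                tapply(tk$flag, tk$pair, sum), collapse = ", "))
}

pt <- pairwise_t_flags(completed, CFG)
save_tsv(pt, "proteome_pairwise_t.tsv")

if (length(sig) >= CFG$n_clusters_k) {
  cl <- zscore_cluster(completed, sig, CFG)
  save_tsv(cl$clusters, "protein_clusters.tsv")
  save_tsv(data.frame(cluster = rownames(cl$profiles), cl$profiles,
                      check.names = FALSE), "cluster_profiles.tsv")
  message("Hierarchical clustering into ", CFG$n_clusters_k,
          " profile clusters; sizes: ",
          paste(table(cl$clusters$cluster), collapse = ", "))
}

pca <- pca_coordinates(completed, if (length(sig) >= 3) sig else NULL)
save_tsv(pca, "pca_coordinates.tsv")
ve <- attr(pca, "var_explained")
message(sprintf("PCA on significant proteins: PC1 %.0f%%, PC2 %.0f%% of variance",
                100 * ve[1], 100 * ve[2]))
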