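# Differential N-terminal peptide abundance between the overexpressor and
# knock-down genotypes: empirical-Bayes moderated t-tests, the P < 0.05
# and |log2 FC| > 0.58 significance filter, a volcano table, and the
# correlation of terminus fold changes with parent-protein fold changes.

source(file.path("analysis", "00_config.R"))

proteome <- build_proteome(
  read_fasta(file.path(DATA_DIR, "proteome.fasta")),
  read_targetp_table(file.path(DATA_DIR, "targetp.tsv")))
qt <- read_quant_table(file.path(DATA_DIR, "terminome_quant.tsv"))
ann <- read.delim(file.path(RESULTS_DIR, "annotations.tsv"),
                  comment.char = "#", stringsAsFactors = FALSE)

gA <- qt$design$genotype == "oe"
gB <- qt$design$genotype == "kd"
lvals <- log2(qt$values)
xA <- lvals[, gA, drop = FALSE]
xB <- lvals[, gB, drop = FALSE]
nA <- rowSums(!is.na(xA)); nB <- rowSums(!is.na(xB))
usable <- nA >= CFG$min_quant_reps & nB >= CFG$min_quant_reps
vA <- apply(xA, 1, var, na.rm = TRUE)
vB <- apply(xB, 1, var, na.rm = TRUE)
d <- nA + nB - 2L
s2 <- ((nA - 1) * ifelse(nA > 1, vA, 0) +
         (nB - 1) * ifelse(nB > 1, vB, 0)) / d

fit <- fit_moderation(s2[usable], d[usable])
message(sprintf("Variance prior: d0 = %.2f, s0^2 = %.4f (from %d termini)",
                fit$d0, fit$s02, sum(usable)))

res <- significance_filter(moderated_t(xA, xB, fit$d0, fit$s02, CFG), CFG)
save_tsv(res, "terminome_diff_oe_vs_kd.tsv")
cnt <- attr(res, "counts")
message("Tested termini: ", sum(!res$skipped), " of ", nrow(res),
        " (skipped: quantified in < ", CFG$min_quant_reps,
        " replicates of a genotype)")
message("Significant (P < ", CFG$alpha, ", |log2 FC| > ", CFG$log2fc_tau,
        "): ", cnt["up"], " up in oe, ", cnt["down"], " up in kd")

volcano <- volcano_table(res, ann, proteome)
save_tsv(volcano, "volcano_oe_vs_kd.tsv")

# terminus-vs-protein fold-change correlation
pq <- read_quant_table(file.path(DATA_DIR, "proteome_quant.tsv"))
completed <- impute_missing(log2_transform(filter_quantifiable(pq, CFG)),
                            CFG)
pA <- completed$design$genotype == "oe"
pB <- completed$design$genotype == "kd"
prot_fc <- rowMeans(completed$values[, pA]) -
  rowMeans(completed$values[, pB])
term_fc <- setNames(res$log2FC, ann$accession[match(res$id, ann$terminus)])
term_fc <- term_fc[!is.na(term_fc)]
corr <- correlate_termini_protein(term_fc, prot_fc)
message(sprintf(
  "Terminus vs protein fold change: Pearson r = %.2f (95%% CI %.2f-%.2f, n = %d)",
  corr$r, corr$ci_lo, corr$ci_hi, corr$n))
save_tsv(data.frame(n = corr$n, r = corr$r, ci_lo = corr$ci_lo,
                    ci_hi = corr$ci_hi, p_value = corr$p_value),
         "terminus_protein_correlation.tsv")
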