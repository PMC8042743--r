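# Shared in-code fixtures. Everything is built programmatically so tests
# carry no binary data.

# A tiny hand-crafted proteome covering every compartment and edge case.
toy_proteome <- function() {
  data.frame(
    accession = c("P1", "P2", "P3", "P4", "P5"),
    sequence = c(
      paste0("M", strrep("ASTGH", 20)),              # plastid, cleavage 50
      paste0("M", strrep("LKVRE", 16)),              # mito, cleavage 35
      paste0("M", strrep("QWNDC", 14)),              # secretory, cleavage 22
      paste0("M", strrep("FYPIT", 12)),              # cytosolic, no cleavage
      paste0("M", strrep("GGSAV", 10))               # plastid-encoded
    ),
    compartment = c("plastid", "mitochondrion", "secretory", "other",
                    "plastid"),
    cleavage_pos = c(50L, 35L, 22L, NA, NA),
    plastid_encoded = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

# Small quant table: 3 genotypes x 4 replicates with chosen missingness.
toy_quant <- function(values) {
  design <- data.frame(
    sample = as.vector(t(outer(c("wt", "oe", "kd"), 1:4, paste, sep = "_"))),
    genotype = rep(c("wt", "oe", "kd"), each = 4),
    replicate = as.character(rep(1:4, 3)),
    stringsAsFactors = FALSE
  )
  colnames(values) <- design$sample
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("prot%02d", seq_len(nrow(values)))
  }
  quant_table(values, design)
}

fast_sim_params <- function(...) {
  sim_params(n_proteins = 60L, n_termini = 200L, seed = 11L, ...)
}
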