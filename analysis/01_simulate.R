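# Simulate the study's data structure: a protein database with targeting
# predictions, an N-terminome, a label-free proteome, and a replicated
# pull-down — all with ground truth, written under results/simulated_data/.

source(file.path("analysis", "00_config.R"))

message("Generating synthetic proteome (", PARAMS$n_proteins, " proteins)")
proteome <- generate_proteome(PARAMS, out_dir = DATA_DIR)
message("  presequence-bearing proteins: ",
        sum(!is.na(proteome$cleavage_pos)), " (",
        sum(proteome$compartment == "plastid"), " plastid, ",
        sum(proteome$compartment == "mitochondrion"), " mitochondrial, ",
        sum(proteome$compartment == "secretory"), " secretory)")

message("Simulating terminome (", PARAMS$n_termini, " N-terminal peptides)")
term <- simulate_terminome(proteome, PARAMS)
write_quant_table(term$quant, file.path(DATA_DIR, "terminome_quant.tsv"),
                  id_name = "terminus")
write_results_tsv(term$truth, file.path(DATA_DIR, "terminome_truth.tsv"),
                  seed = CFG$rng_seed)
message("  acetylated termini: ", sum(term$truth$acetylated),
        "; quantifiable: ", sum(term$truth$quantifiable))

message("Simulating label-free proteome quantification")
prot <- simulate_proteome_quant(proteome, PARAMS)
write_quant_table(prot$quant, file.path(DATA_DIR, "proteome_quant.tsv"),
                  id_name = "accession")
write_results_tsv(prot$truth, file.path(DATA_DIR, "proteome_truth.tsv"),
                  seed = CFG$rng_seed)
message("  missing cells: ",
        sprintf("%.1f%%", 100 * mean(is.na(prot$quant$values))),
        "; proteins with true effects: ",
        sum(prot$truth$diff_class != "null"))

message("Simulating replicated pull-down experiment")
coip <- simulate_coip(proteome, PARAMS)
write_results_tsv(coip$records, file.path(DATA_DIR, "coip_records.tsv"),
                  seed = CFG$rng_seed)
writeLines(coip$truth, file.path(DATA_DIR, "coip_truth.txt"))
message("  true interactors: ", length(coip$truth),
        "; observed proteins: ", nrow(coip$records))
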