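# Stringent pull-down interactor filtering: chloroplast-annotated proteins
# present in every bait replicate and absent from every control are strong
# candidates; single-replicate co-purifiers are reported separately.

source(file.path("analysis", "00_config.R"))

rec <- read.delim(file.path(DATA_DIR, "coip_records.tsv"),
                  comment.char = "#", stringsAsFactors = FALSE)
truth <- readLines(file.path(DATA_DIR, "coip_truth.txt"))

strict <- stringent_subset(rec)
save_tsv(strict, "coip_stringent_candidates.tsv")
message("Stringent candidates (all baits, no control, chloroplast): ",
        nrow(strict))
message("  true interactors recovered: ",
        sum(strict$accession %in% truth), " of ", length(truth),
        "; false positives: ", sum(!strict$accession %in% truth))

relax <- relaxed_subset(rec)
save_tsv(relax, "coip_relaxed_candidates.tsv")
message("Relaxed candidates (>= 1 bait, no control): ", nrow(relax),
        " (", sum(relax$single_replicate), " seen in a single replicate)")
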