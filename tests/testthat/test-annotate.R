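cfg <- analysis_config()

test_that("peptide mapping returns all occurrences, including overlaps", {
  prot <- data.frame(accession = c("P1", "P2"),
                     sequence = c("MASTK", "AAAA"),
                     stringsAsFactors = FALSE)
  expect_equal(map_peptide("AST", prot),
               data.frame(accession = "P1", start_pos = 2L))
  hits <- map_peptide("AA", prot)
  expect_equal(hits$accession, rep("P2", 3))
  expect_equal(hits$start_pos, 1:3)
  expect_equal(nrow(map_peptide("WWW", prot)), 0L)
})

test_that("terminus classification follows the positional precedence rules", {
  prot <- toy_proteome()
  p1 <- prot[1, ]  # plastid, cleavage_pos 50

  expect_equal(classify_terminus(1L, p1, cfg)$category, "POS1")
  expect_equal(classify_terminus(2L, p1, cfg)$category, "POS2")

  at51 <- classify_terminus(51L, p1, cfg)
  expect_equal(at51$category, "CLEAVAGE_WINDOW")
  expect_equal(at51$window_kind, "TP_plastid")
  expect_equal(at51$offset, 0L)
  expect_true(at51$expected)

  at57 <- classify_terminus(57L, p1, cfg)
  expect_equal(at57$category, "UNANNOTATED")
  expect_equal(at57$offset, 6L)
  expect_false(at57$expected)

  expect_equal(classify_terminus(36L, prot[2, ], cfg)$window_kind, "TP_mito")
  expect_equal(classify_terminus(23L, prot[3, ], cfg)$window_kind, "SP")

  expect_error(classify_terminus(0L, p1, cfg), "out of range")
  expect_error(classify_terminus(200L, p1, cfg), "out of range")
})

test_that("POS1/POS2 take precedence over a cleavage window", {
  # crafted protein whose window covers positions 1..2
  prot <- data.frame(accession = "PX", sequence = "MKTAYEAGHKLLMNPQ",
                     compartment = "plastid", cleavage_pos = 3L,
                     plastid_encoded = FALSE, stringsAsFactors = FALSE)
  expect_equal(classify_terminus(1L, prot, cfg)$category, "POS1")
  expect_equal(classify_terminus(2L, prot, cfg)$category, "POS2")
  expect_equal(classify_terminus(3L, prot, cfg)$category, "CLEAVAGE_WINDOW")
  # enumerate the full precedence order over all positions
  for (s in 1:16) {
    got <- classify_terminus(s, prot, cfg)$category
    want <- if (s == 1) "POS1" else if (s == 2) "POS2" else
      if (abs(s - 4L) <= 5L) "CLEAVAGE_WINDOW" else "UNANNOTATED"
    expect_equal(got, want, info = paste("position", s))
  }
})

test_that("the cleavage window is symmetric and inclusive at |offset| = W", {
  p1 <- toy_proteome()[1, ]  # cleavage_pos 50, mature N-terminus 51
  for (d in 0:cfg$window_W) {
    up <- classify_terminus(51L - d, p1, cfg)$category
    down <- classify_terminus(51L + d, p1, cfg)$category
    expect_equal(up == "CLEAVAGE_WINDOW", down == "CLEAVAGE_WINDOW",
                 info = paste("d =", d))
    expect_equal(up, "CLEAVAGE_WINDOW")
  }
  expect_equal(classify_terminus(51L - 6L, p1, cfg)$category, "UNANNOTATED")
  expect_equal(classify_terminus(51L + 6L, p1, cfg)$category, "UNANNOTATED")
})

test_that("every start position receives exactly one category", {
  prot <- toy_proteome()
  cats <- c("POS1", "POS2", "CLEAVAGE_WINDOW", "UNANNOTATED")
  for (r in seq_len(nrow(prot))) {
    for (s in seq_len(nchar(prot$sequence[r]))) {
      got <- classify_terminus(s, prot[r, ], cfg)$category
      expect_true(got %in% cats)
    }
  }
})

test_that("ambiguous peptides map to the smallest accession and are flagged", {
  prot <- data.frame(
    accession = c("B2", "A1"),
    sequence = c("MWWASTKWW", "MASTKGHI"),
    compartment = "other", cleavage_pos = NA_integer_,
    plastid_encoded = FALSE, stringsAsFactors = FALSE
  )
  termini <- data.frame(accession = "B2", start_pos = 4L,
                        peptide_seq = "ASTK", nterm_mod = "free_dimethylated",
                        stringsAsFactors = FALSE)
  ann <- annotate_termini(termini, prot, cfg)
  expect_true(ann$ambiguous)
  expect_equal(ann$accession, "A1")
  expect_equal(ann$start_pos, 2L)
  # ambiguous termini are excluded from tallies by default
  tal <- tally_categories(ann)
  expect_equal(sum(tal$total), 0L)
  tal_inc <- tally_categories(ann, include_ambiguous = TRUE)
  expect_equal(sum(tal_inc$total), 1L)
})

test_that("annotation rejects peptides that contradict the protein sequence", {
  prot <- toy_proteome()
  bad <- data.frame(accession = "P1", start_pos = 1L, peptide_seq = "MXXX",
                    stringsAsFactors = FALSE)
  expect_error(annotate_termini(bad, prot, cfg), "does not match")
  unknown <- data.frame(accession = "NOPE", start_pos = 1L)
  expect_error(annotate_termini(unknown, prot, cfg), "unknown accession")
})

test_that("offset histogram counts plastid termini per signed offset", {
  prot <- toy_proteome()
  termini <- data.frame(
    accession = c("P1", "P1", "P1", "P2", "P4"),
    start_pos = c(51L, 51L, 49L, 36L, 10L),
    stringsAsFactors = FALSE
  )
  ann <- annotate_termini(termini, prot, cfg)
  h <- offset_histogram(ann, prot, compartment = "plastid", cfg = cfg)
  expect_equal(h$offset, c(-2L, 0L))
  expect_equal(h$count, c(1L, 2L))
  expect_true(all(h$in_window))
  expect_equal(sum(h$count), 3L)  # P2 is mito, P4 has no cleavage site

  h_empty <- offset_histogram(ann[ann$accession == "P4", , drop = FALSE],
                              prot, cfg = cfg)
  expect_equal(nrow(h_empty), 0L)
})

test_that("precursor detection matches a brute-force position scan", {
  prot <- toy_proteome()
  # crafted termini across all proteins and positions
  termini <- data.frame(
    accession = c("P1", "P1", "P1", "P1", "P2", "P2", "P3", "P4", "P1",
                  "P2"),
    start_pos = c(1L, 2L, 45L, 51L, 2L, 30L, 10L, 5L, 46L, 31L),
    stringsAsFactors = FALSE
  )
  termini$peptide_seq <- substr(
    prot$sequence[match(termini$accession, prot$accession)],
    termini$start_pos, termini$start_pos + 7L)
  ann <- annotate_termini(termini, prot, cfg, resolve_ambiguous = FALSE)
  cand <- detect_precursors(ann, prot, cfg)
  # oracle: independent scan of the rule
  cpos <- prot$cleavage_pos[match(termini$accession, prot$accession)]
  expected <- which(!is.na(cpos) & termini$start_pos <= cpos - cfg$window_W)
  expect_equal(nrow(cand), length(expected))
  expect_setequal(paste(cand$accession, cand$start_pos),
                  paste(termini$accession[expected],
                        termini$start_pos[expected]))
  # terminus exactly at the mature start is never a candidate
  expect_false(any(cand$start_pos == cpos[match(cand$accession,
                                                termini$accession)] + 1L))
  expect_type(cand$has_quant_lys, "logical")
})

test_that("category tallies are exhaustive, disjoint and conserved", {
  prot <- toy_proteome()
  termini <- data.frame(
    accession = rep("P1", 6),
    start_pos = c(1L, 2L, 51L, 49L, 70L, 20L),
    nterm_mod = c("acetylated", "acetylated", "free_dimethylated",
                  "acetylated", "free_dimethylated", "free_dimethylated"),
    stringsAsFactors = FALSE
  )
  ann <- annotate_termini(termini, prot, cfg)
  tal <- tally_categories(ann)
  expect_equal(sum(tal$total), nrow(termini))
  expect_equal(tal$acetylated + tal$dimethylated, tal$total)
  expect_equal(tal$total[tal$category == "POS1"], 1L)
  expect_equal(tal$total[tal$category == "CLEAVAGE_WINDOW"], 2L)
  expect_equal(tal$total[tal$category == "UNANNOTATED"], 2L)

  tal0 <- tally_categories(ann[0, , drop = FALSE])
  expect_equal(sum(tal0$total), 0L)
})
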