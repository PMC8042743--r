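#' Map a peptide sequence onto a proteome
#'
#' Exact substring matching of a peptide against every protein sequence;
#' all occurrences (including overlapping ones) are returned, sorted by
#' accession then start position.
#'
#' @param peptide_seq amino-acid string.
#' @param proteome proteome data.frame (see [build_proteome()]).
#' @return data.frame with columns `accession`, `start_pos` (1-based);
#'   zero rows when the peptide matches nowhere.
#' @export
map_peptide <- function(peptide_seq, proteome) {
  stopifnot(is.character(peptide_seq), length(peptide_seq) == 1L,
            nzchar(peptide_seq))
  subject <- Biostrings::AAStringSet(proteome$sequence)
  names(subject) <- proteome$accession
  hits <- Biostrings::vmatchPattern(peptide_seq, subject)
  starts <- Biostrings::startIndex(hits)
  n_hit <- lengths(starts)
  out <- data.frame(
    accession = rep(proteome$accession, n_hit),
    start_pos = unlist(starts, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  if (nrow(out) == 0L) return(out)
  out[order(out$accession, out$start_pos), , drop = FALSE]
}

#' Classify one N-terminus by positional rules
#'
#' Positional annotation of an observed protein N-terminus:
#' * `POS1` — the database start site (position 1, initiator Met intact);
#' * `POS2` — position 2 after initiator-Met excision (residue 1 must be Met);
#' * `CLEAVAGE_WINDOW` — within `window_W` residues (two-sided, inclusive)
#'   of the predicted signal/transit-peptide cleavage site: the mature
#'   N-terminus is `cleavage_pos + 1`, so the condition is
#'   `|start_pos - (cleavage_pos + 1)| <= window_W`;
#' * `UNANNOTATED` — anything else (internal proteolysis, alternative
#'   starts, lumenal secondary cleavages).
#'
#' Precedence is POS1 > POS2 > CLEAVAGE_WINDOW > UNANNOTATED: direct
#' start-site evidence outranks a prediction window. The signed offset to
#' the predicted mature N-terminus is reported whenever a cleavage site
#' exists, whatever the category.
#'
#' @param start_pos 1-based observed start within the protein.
#' @param protein one-row slice of a proteome data.frame.
#' @param cfg an [analysis_config()].
#' @return A one-row data.frame: `category`, `window_kind`, `offset`,
#'   `expected`.
#' @export
classify_terminus <- function(start_pos, protein, cfg = analysis_config()) {
  len <- nchar(protein$sequence)
  if (start_pos < 1L || start_pos > len) {
    stop("start_pos ", start_pos, " out of range [1, ", len, "] for ",
         protein$accession)
  }
  cpos <- protein$cleavage_pos
  offset <- if (!is.na(cpos)) as.integer(start_pos - (cpos + 1L)) else NA_integer_
  category <- "UNANNOTATED"
  window_kind <- "none"
  if (start_pos == 1L) {
    category <- "POS1"
  } else if (start_pos == 2L && substr(protein$sequence, 1L, 1L) == "M") {
    category <- "POS2"
  } else if (!is.na(cpos) && abs(offset) <= cfg$window_W) {
    category <- "CLEAVAGE_WINDOW"
    window_kind <- switch(protein$compartment,
                          plastid = "TP_plastid",
                          mitochondrion = "TP_mito",
                          secretory = "SP",
                          "none")
  }
  data.frame(category = category, window_kind = window_kind,
             offset = offset, expected = category != "UNANNOTATED",
             stringsAsFactors = FALSE)
}

#' Annotate a table of N-terminal peptides
#'
#' Applies [classify_terminus()] to every identified terminus. When a
#' peptide sequence is provided it is checked against the protein sequence
#' at the claimed position, and peptides that map to more than one protein
#' are reassigned to the lexicographically smallest accession and flagged
#' `ambiguous`.
#'
#' @param termini data.frame with columns `accession`, `start_pos`, and
#'   optionally `peptide_seq`, `nterm_mod` (one of `free_dimethylated`,
#'   `acetylated`, `pyroGlu_E`, `pyroGlu_Q`).
#' @param proteome proteome data.frame.
#' @param cfg an [analysis_config()].
#' @param resolve_ambiguous map multi-protein peptides to the smallest
#'   accession and flag them (default TRUE; requires `peptide_seq`).
#' @return The input with columns `category`, `window_kind`, `offset`,
#'   `expected`, `acetylated`, `ambiguous` appended.
#' @export
annotate_termini <- function(termini, proteome, cfg = analysis_config(),
                             resolve_ambiguous = TRUE) {
  stopifnot(all(c("accession", "start_pos") %in% names(termini)))
  idx <- match(termini$accession, proteome$accession)
  if (anyNA(idx)) {
    stop("terminus assigned to unknown accession: ",
         termini$accession[is.na(idx)][1])
  }
  out <- termini
  out$ambiguous <- FALSE
  has_seq <- "peptide_seq" %in% names(termini)
  if (has_seq) {
    claimed <- substr(proteome$sequence[idx], termini$start_pos,
                      termini$start_pos + nchar(termini$peptide_seq) - 1L)
    bad <- claimed != termini$peptide_seq
    if (any(bad)) {
      stop("peptide does not match protein sequence at claimed position: ",
           termini$peptide_seq[bad][1], " vs ", termini$accession[bad][1])
    }
    if (resolve_ambiguous) {
      for (i in seq_len(nrow(out))) {
        hits <- map_peptide(out$peptide_seq[i], proteome)
        if (length(unique(hits$accession)) > 1L) {
          out$ambiguous[i] <- TRUE
          first <- hits[hits$accession == min(hits$accession), , drop = FALSE]
          out$accession[i] <- first$accession[1]
          out$start_pos[i] <- first$start_pos[1]
        }
      }
      idx <- match(out$accession, proteome$accession)
    }
  }
  ann <- do.call(rbind, lapply(seq_len(nrow(out)), function(i) {
    classify_terminus(out$start_pos[i], proteome[idx[i], , drop = FALSE], cfg)
  }))
  if (is.null(ann)) {
    ann <- data.frame(category = character(), window_kind = character(),
                      offset = integer(), expected = logical())
  }
  out <- cbind(out, ann)
  out$acetylated <- if ("nterm_mod" %in% names(out)) {
    out$nterm_mod == "acetylated"
  } else FALSE
  rownames(out) <- NULL
  out
}

#' Histogram of observed-vs-predicted cleavage offsets
#'
#' Counts termini per signed offset to the predicted mature N-terminus,
#' restricted to proteins of one compartment (plastid by default). The
#' `in_window` flag marks offsets within the expected-terminus window.
#'
#' @param annotations output of [annotate_termini()].
#' @param proteome proteome data.frame.
#' @param compartment which compartment's proteins to tabulate.
#' @param cfg an [analysis_config()].
#' @return data.frame `offset`, `count`, `in_window`; zero rows when no
#'   terminus has a defined offset.
#' @export
offset_histogram <- function(annotations, proteome, compartment = "plastid",
                             cfg = analysis_config()) {
  comp <- proteome$compartment[match(annotations$accession,
                                     proteome$accession)]
  keep <- comp == compartment & !is.na(annotations$offset)
  offs <- annotations$offset[keep]
  if (length(offs) == 0L) {
    return(data.frame(offset = integer(), count = integer(),
                      in_window = logical()))
  }
  tab <- table(offs)
  out <- data.frame(offset = as.integer(names(tab)),
                    count = as.integer(tab))
  out$in_window <- abs(out$offset) <= cfg$window_W
  out[order(out$offset), , drop = FALSE]
}

#' Detect candidate intact precursor proteins
#'
#' For presequence-bearing proteins, a terminus observed well upstream of
#' the predicted cleavage site (`start_pos <= cleavage_pos - window_W`) —
#' in particular at position 1 or 2 — indicates an unprocessed full-length
#' precursor rather than the imported mature protein. Each candidate is
#' flagged for whether its peptide contains a Lys, which in the dimethyl
#' labeling scheme is what permits quantification of an acetylated
#' (alpha-amine-blocked) terminus.
#'
#' @param annotations output of [annotate_termini()].
#' @param proteome proteome data.frame.
#' @param cfg an [analysis_config()].
#' @return Subset of `annotations` with a `has_quant_lys` column appended.
#' @export
detect_precursors <- function(annotations, proteome,
                              cfg = analysis_config()) {
  idx <- match(annotations$accession, proteome$accession)
  cpos <- proteome$cleavage_pos[idx]
  keep <- !is.na(cpos) &
    annotations$start_pos <= cpos - cfg$window_W
  out <- annotations[keep, , drop = FALSE]
  out$has_quant_lys <- if ("peptide_seq" %in% names(out)) {
    grepl("K", out$peptide_seq, fixed = TRUE)
  } else NA
  rownames(out) <- NULL
  out
}

#' Tally positional categories by N-terminal modification
#'
#' Cross-tabulates the exhaustive, disjoint positional categories against
#' the acetylated/dimethylated state. Ambiguously mapped termini are
#' excluded by default.
#'
#' @param annotations output of [annotate_termini()].
#' @param include_ambiguous include ambiguous termini (default FALSE).
#' @return data.frame `category`, `acetylated`, `dimethylated`, `total`,
#'   with one row per category (all categories always present) plus the
#'   grand total as attribute `n_input`.
#' @export
tally_categories <- function(annotations, include_ambiguous = FALSE) {
  categories <- c("POS1", "POS2", "CLEAVAGE_WINDOW", "UNANNOTATED")
  keep <- if (!include_ambiguous && "ambiguous" %in% names(annotations)) {
    !annotations$ambiguous
  } else rep(TRUE, nrow(annotations))
  ann <- annotations[keep, , drop = FALSE]
  ac <- if ("acetylated" %in% names(ann)) ann$acetylated else
    rep(FALSE, nrow(ann))
  out <- data.frame(category = categories,
                    acetylated = 0L, dimethylated = 0L, total = 0L)
  for (i in seq_along(categories)) {
    in_cat <- ann$category == categories[i]
    out$acetylated[i] <- sum(in_cat & ac)
    out$dimethylated[i] <- sum(in_cat & !ac)
    out$total[i] <- sum(in_cat)
  }
  attr(out, "n_input") <- nrow(ann)
  out
}
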