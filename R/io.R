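#' Read a protein FASTA database
#'
#' Sequences are uppercased and a trailing stop character (`*`) is stripped.
#' The accession is the header token before the first whitespace.
#'
#' @param path path to a FASTA file.
#' @return A data.frame with columns `accession` and `sequence`, one row per
#'   record (zero rows for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) > 0L && !startsWith(trimws(lines[nonempty[1]]), ">")) {
    stop("malformed FASTA record: sequence before any header at line ",
         nonempty[1])
  }
  if (length(nonempty) == 0L) {
    return(data.frame(accession = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  seqs <- Biostrings::readAAStringSet(path)
  acc <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  sq <- toupper(as.character(seqs))
  sq <- sub("\\*$", "", sq)
  data.frame(accession = acc, sequence = unname(sq), stringsAsFactors = FALSE)
}

#' Write protein sequences to FASTA
#'
#' @param proteins data.frame with `accession` and `sequence` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(proteins$sequence)
  names(set) <- proteins$accession
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Read a TargetP-style localization/cleavage prediction table
#'
#' Expects a tab-separated file with a header and (at least) columns for the
#' accession, the predicted class, and the cleavage-site position `CS`
#' (the 1-based position of the LAST presequence residue; the mature
#' N-terminus is `CS + 1`). Classes `cTP`, `mTP`, `SP`, `noTP` map to
#' compartments `plastid`, `mitochondrion`, `secretory`, `other`; unknown
#' labels map to `other` with a warning. An empty/NA cleavage field means no
#' predicted cleavage.
#'
#' @param path path to the TSV file.
#' @param proteins optional protein data.frame (from [read_fasta()]); when
#'   given, each cleavage position is validated against the sequence length.
#' @return A data.frame with columns `accession`, `compartment`,
#'   `cleavage_pos` (NA when absent).
#' @export
read_targetp_table <- function(path, proteins = NULL) {
  if (!file.exists(path)) stop("TargetP table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("", "NA", "-"))
  need <- c("accession", "prediction", "CS")
  if (!all(need %in% names(tab))) {
    stop("TargetP table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(tab$accession)) {
    stop("duplicated accession in TargetP table: ",
         tab$accession[duplicated(tab$accession)][1])
  }
  class_map <- c(cTP = "plastid", mTP = "mitochondrion",
                 SP = "secretory", noTP = "other")
  unknown <- setdiff(unique(tab$prediction), names(class_map))
  if (length(unknown) > 0L) {
    warning("unknown prediction class(es) mapped to 'other': ",
            paste(unknown, collapse = ", "))
  }
  compartment <- unname(class_map[tab$prediction])
  compartment[is.na(compartment)] <- "other"
  cs <- suppressWarnings(as.integer(tab$CS))
  bad <- !is.na(tab$CS) & is.na(cs)
  if (any(bad)) stop("non-integer cleavage position for ",
                     tab$accession[bad][1])
  if (any(!is.na(cs) & cs < 1L)) {
    stop("cleavage position out of range (< 1) for ",
         tab$accession[which(!is.na(cs) & cs < 1L)[1]])
  }
  out <- data.frame(accession = tab$accession, compartment = compartment,
                    cleavage_pos = cs, stringsAsFactors = FALSE)
  if (!is.null(proteins)) {
    len <- stats::setNames(nchar(proteins$sequence), proteins$accession)
    known <- out$accession %in% names(len)
    over <- known & !is.na(out$cleavage_pos) &
      out$cleavage_pos >= len[out$accession]
    if (any(over)) {
      stop("cleavage position >= sequence length for ",
           out$accession[over][1])
    }
  }
  out
}

#' Assemble a proteome table from sequences and predictions
#'
#' Joins FASTA sequences with localization predictions into the per-protein
#' table used by the annotation and simulation stages. Proteins without a
#' prediction row get compartment `other` and no cleavage site.
#'
#' @param proteins data.frame from [read_fasta()].
#' @param targetp data.frame from [read_targetp_table()], or NULL.
#' @param plastid_encoded character vector of accessions that are
#'   plastid-encoded (no transit peptide expected); forces `cleavage_pos` NA.
#' @return A data.frame with columns `accession`, `sequence`, `compartment`,
#'   `cleavage_pos`, `plastid_encoded`.
#' @export
build_proteome <- function(proteins, targetp = NULL,
                           plastid_encoded = character()) {
  stopifnot(all(nzchar(proteins$sequence)))
  out <- proteins
  out$compartment <- "other"
  out$cleavage_pos <- NA_integer_
  if (!is.null(targetp)) {
    idx <- match(out$accession, targetp$accession)
    hit <- !is.na(idx)
    out$compartment[hit] <- targetp$compartment[idx[hit]]
    out$cleavage_pos[hit] <- targetp$cleavage_pos[idx[hit]]
  }
  out$plastid_encoded <- out$accession %in% plastid_encoded
  out$cleavage_pos[out$plastid_encoded] <- NA_integer_
  bad <- !is.na(out$cleavage_pos) &
    out$cleavage_pos >= nchar(out$sequence)
  if (any(bad)) stop("cleavage_pos >= sequence length for ",
                     out$accession[bad][1])
  out
}

#' Construct a quantification table
#'
#' The pipeline's shared container for intensity data: a numeric matrix
#' (features x samples, NA = missing) plus a sample design (genotype,
#' replicate). Mirrors the layout of search-engine protein/peptide exports
#' after column selection.
#'
#' @param values numeric matrix with feature rownames and sample colnames.
#' @param design data.frame with columns `sample`, `genotype`, `replicate`;
#'   `sample` must match `colnames(values)`.
#' @return An object of class `quant_table`.
#' @export
quant_table <- function(values, design) {
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)))
  stopifnot(all(c("sample", "genotype", "replicate") %in% names(design)))
  if (!identical(colnames(values), design$sample)) {
    stop("design$sample must match colnames(values) in order")
  }
  if (anyDuplicated(design$sample)) stop("duplicate sample names in design")
  if (any(is.infinite(values))) stop("intensities must be finite")
  structure(list(values = values, design = design), class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  cat(sprintf("quant_table: %d features x %d samples (%d genotypes)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$design$genotype))))
  cat(sprintf("  missing: %.1f%%\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

#' Read a quantification TSV
#'
#' First column is the feature identifier; remaining columns are intensity
#' columns named `<genotype>_<replicate>`. A zero or empty cell means the
#' feature was not quantified in that sample and becomes NA (intensity zero
#' is the conventional not-quantified sentinel in search-engine exports).
#' Literal `NaN` text is rejected.
#'
#' @param path path to the TSV file.
#' @param require_complete require a full genotype x replicate crossing in
#'   the header (default TRUE).
#' @return A `quant_table`.
#' @export
read_quant_table <- function(path, require_complete = TRUE) {
  if (!file.exists(path)) stop("quant table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 2L) stop("quant table needs an id column plus intensities")
  ids <- tab[[1L]]
  if (anyDuplicated(ids)) stop("duplicated feature id: ",
                               ids[duplicated(ids)][1])
  sample_names <- names(tab)[-1L]
  design <- parse_sample_design(sample_names, require_complete)
  vals <- matrix(NA_real_, nrow = nrow(tab), ncol = length(sample_names),
                 dimnames = list(ids, sample_names))
  for (j in seq_along(sample_names)) {
    raw <- trimws(tab[[j + 1L]])
    if (any(toupper(raw) %in% c("NAN", "INF", "-INF"))) {
      stop("non-finite text in column '", sample_names[j],
           "' row ", which(toupper(raw) %in% c("NAN", "INF", "-INF"))[1])
    }
    num <- suppressWarnings(as.numeric(raw))
    bad <- nzchar(raw) & is.na(num)
    if (any(bad)) {
      stop("non-numeric intensity '", raw[bad][1], "' at row ",
           which(bad)[1], ", column '", sample_names[j], "'")
    }
    num[!nzchar(raw)] <- NA_real_
    num[!is.na(num) & num == 0] <- NA_real_
    if (any(num < 0, na.rm = TRUE)) {
      stop("negative intensity at row ", which(num < 0)[1],
           ", column '", sample_names[j], "'")
    }
    vals[, j] <- num
  }
  quant_table(vals, design)
}

parse_sample_design <- function(sample_names, require_complete = TRUE) {
  m <- regmatches(sample_names,
                  regexec("^(.+)_([^_]+)$", sample_names))
  ok <- lengths(m) == 3L
  if (!all(ok)) {
    stop("intensity column '", sample_names[!ok][1],
         "' is not of the form <genotype>_<replicate>")
  }
  genotype <- vapply(m, `[`, character(1), 2L)
  replicate <- vapply(m, `[`, character(1), 3L)
  if (require_complete) {
    tab <- table(genotype)
    reps_per <- split(replicate, genotype)
    n_rep <- lengths(reps_per)
    if (length(unique(n_rep)) != 1L ||
        length(unique(lapply(reps_per, sort))) != 1L) {
      stop("incomplete design: genotypes do not share the same replicates (",
           paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                 collapse = ", "), ")")
    }
  }
  data.frame(sample = sample_names, genotype = genotype,
             replicate = replicate, stringsAsFactors = FALSE)
}

#' Write a quantification table to TSV
#'
#' Missing values are written as empty cells; present values keep full
#' precision (round-trip safe at 15 significant digits).
#'
#' @param qt a `quant_table`.
#' @param path output path.
#' @param id_name name for the identifier column.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(qt, path, id_name = "id") {
  vals <- qt$values
  txt <- matrix("", nrow = nrow(vals), ncol = ncol(vals))
  present <- !is.na(vals)
  txt[present] <- format(vals[present], digits = 15, trim = TRUE,
                         scientific = FALSE)
  out <- data.frame(rownames(vals), txt, stringsAsFactors = FALSE,
                    check.names = FALSE)
  names(out) <- c(id_name, colnames(vals))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a results table to TSV
#'
#' UTF-8, tab-delimited, `.` decimal separator; an optional comment header
#' records the seed so every output is self-describing.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param seed optional seed recorded as a `# seed: <n>` comment line.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(df, path, seed = NULL) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
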