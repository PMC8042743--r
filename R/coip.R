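# AP-MS candidate-interactor filtering. A pull-down record table has one
# row per observed protein with bait-replicate log2 LFQ intensities
# (columns `bait_*`, NA = not identified), control presence flags
# (columns `control_*`), a `chloroplast_annotated` flag and optional
# `unique_peptides` / `coverage` metadata.

coip_columns <- function(records) {
  bait <- grep("^bait_", names(records), value = TRUE)
  ctrl <- grep("^control_", names(records), value = TRUE)
  if (length(bait) == 0L) stop("record table has no bait_* columns")
  if (length(ctrl) == 0L) stop("record table has no control_* columns")
  list(bait = bait, ctrl = ctrl)
}

#' Stringent candidate-interactor subset
#'
#' Keeps a protein iff it was identified (non-missing LFQ intensity) in
#' ALL bait replicates, is absent from ALL control pull-downs, and is
#' chloroplast-annotated — the strong-candidate rule of replicated
#' co-immunoprecipitation screens. Output is sorted by maximum bait
#' intensity, descending.
#'
#' @param records pull-down record data.frame (see [simulate_coip()]).
#' @param min_unique_peptides optional minimum unique-peptide count
#'   (default 1; ignored when the column is absent).
#' @return The kept rows, sorted, with a `max_bait_intensity` column.
#' @export
stringent_subset <- function(records, min_unique_peptides = 1L) {
  cols <- coip_columns(records)
  bait_present <- !is.na(as.matrix(records[cols$bait]))
  if (ncol(bait_present) < 2L) {
    stop("stringent filtering requires at least 2 bait replicates")
  }
  ctrl_present <- as.matrix(records[cols$ctrl])
  keep <- rowSums(bait_present) == length(cols$bait) &
    rowSums(ctrl_present) == 0L &
    records$chloroplast_annotated
  if ("unique_peptides" %in% names(records)) {
    keep <- keep & records$unique_peptides >= min_unique_peptides
  }
  out <- records[keep, , drop = FALSE]
  out$max_bait_intensity <- suppressWarnings(
    apply(as.matrix(out[cols$bait]), 1L, max, na.rm = TRUE))
  if (nrow(out) == 0L) {
    out$max_bait_intensity <- numeric(0)
    return(out)
  }
  out <- out[order(-out$max_bait_intensity), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relaxed candidate-interactor subset
#'
#' Secondary candidates: chloroplast-annotated proteins identified in at
#' least one bait replicate and absent from every control. Proteins seen
#' in only a subset of bait replicates are flagged `single_replicate` —
#' they co-purified but fail the stringent both-replicates rule.
#'
#' @inheritParams stringent_subset
#' @return The kept rows with `single_replicate` and
#'   `max_bait_intensity` columns, sorted by intensity descending.
#' @export
relaxed_subset <- function(records, min_unique_peptides = 1L) {
  cols <- coip_columns(records)
  bait_present <- !is.na(as.matrix(records[cols$bait]))
  ctrl_present <- as.matrix(records[cols$ctrl])
  keep <- rowSums(bait_present) >= 1L &
    rowSums(ctrl_present) == 0L &
    records$chloroplast_annotated
  if ("unique_peptides" %in% names(records)) {
    keep <- keep & records$unique_peptides >= min_unique_peptides
  }
  out <- records[keep, , drop = FALSE]
  out$single_replicate <- rowSums(bait_present[keep, , drop = FALSE]) <
    length(cols$bait)
  out$max_bait_intensity <- suppressWarnings(
    apply(as.matrix(out[cols$bait]), 1L, max, na.rm = TRUE))
  if (nrow(out) == 0L) return(out)
  out <- out[order(-out$max_bait_intensity), , drop = FALSE]
  rownames(out) <- NULL
  out
}
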