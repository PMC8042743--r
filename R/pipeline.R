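#' Run the full synthetic-data analysis pipeline
#'
#' Orchestrates every stage end to end on simulated data: proteome
#' generation, terminome simulation and positional annotation, moderated
#' t-tests between the overexpressor and knock-down genotypes, label-free
#' proteome differential analysis (filter, log2, imputation, ANOVA + BH,
#' Tukey HSD, clustering, PCA), and pull-down interactor filtering. All
#' stage outputs are written as TSV files under `out_dir` together with a
#' run manifest (config snapshot, seed, output checksums), so a rerun
#' with the same config and seed reproduces identical files.
#'
#' @param cfg an [analysis_config()].
#' @param params a [sim_params()]; its seed is forced to `cfg$rng_seed`.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with every stage's in-memory result and the
#'   manifest.
#' @export
run_pipeline <- function(cfg = analysis_config(),
                         params = sim_params(),
                         out_dir = tempfile("ntermflow_run_"),
                         quiet = FALSE) {
  params$seed <- cfg$rng_seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[ntermflow] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  say("simulate: proteome (", params$n_proteins, " proteins)")
  proteome <- stage("simulate", generate_proteome(params, out_dir = out_dir))

  say("simulate: terminome (", params$n_termini, " termini)")
  term <- stage("simulate", simulate_terminome(proteome, params))
  write_quant_table(term$quant, file.path(out_dir, "terminome_quant.tsv"),
                    id_name = "terminus")

  say("annotate: positional classification")
  ann <- stage("annotate", {
    a <- annotate_termini(term$truth[, c("accession", "start_pos",
                                         "peptide_seq", "nterm_mod")],
                          proteome, cfg, resolve_ambiguous = FALSE)
    a$terminus <- term$truth$terminus
    a
  })
  write_results_tsv(ann, file.path(out_dir, "annotations.tsv"),
                    seed = cfg$rng_seed)
  tallies <- tally_categories(ann)
  write_results_tsv(tallies, file.path(out_dir, "category_tallies.tsv"),
                    seed = cfg$rng_seed)
  offs <- offset_histogram(ann, proteome, cfg = cfg)
  write_results_tsv(offs, file.path(out_dir, "offset_histogram.tsv"),
                    seed = cfg$rng_seed)

  say("term-diff: moderated t-test ", params$genotypes[2], " vs ",
      params$genotypes[3])
  termdiff <- stage("term-diff", {
    lvals <- log2(term$quant$values)
    gA <- term$quant$design$genotype == params$genotypes[2]
    gB <- term$quant$design$genotype == params$genotypes[3]
    xA <- lvals[, gA, drop = FALSE]
    xB <- lvals[, gB, drop = FALSE]
    nA <- rowSums(!is.na(xA)); nB <- rowSums(!is.na(xB))
    usable <- nA >= cfg$min_quant_reps & nB >= cfg$min_quant_reps
    vA <- apply(xA, 1L, stats::var, na.rm = TRUE)
    vB <- apply(xB, 1L, stats::var, na.rm = TRUE)
    d <- pmax(nA + nB - 2L, 0L)
    s2 <- ifelse(d > 0, ((nA - 1L) * ifelse(nA > 1, vA, 0) +
                           (nB - 1L) * ifelse(nB > 1, vB, 0)) / d, NA)
    fit <- fit_moderation(s2[usable], d[usable])
    res <- moderated_t(xA, xB, fit$d0, fit$s02, cfg)
    significance_filter(res, cfg)
  })
  write_results_tsv(termdiff, file.path(out_dir, "terminome_diff.tsv"),
                    seed = cfg$rng_seed)

  say("prot-diff: proteome quantification and ANOVA")
  prot <- stage("prot-diff", simulate_proteome_quant(proteome, params))
  write_quant_table(prot$quant, file.path(out_dir, "proteome_quant.tsv"),
                    id_name = "accession")
  protdiff <- stage("prot-diff", {
    filtered <- filter_quantifiable(prot$quant, cfg)
    completed <- impute_missing(log2_transform(filtered), cfg)
    av <- anova_bh(completed, cfg)
    sig <- av$accession[av$significant]
    tk <- if (length(sig) > 0L) tukey_hsd(completed, sig, cfg) else NULL
    pt <- pairwise_t_flags(completed, cfg)
    list(filtered = filtered, completed = completed, anova = av,
         tukey = tk, pairwise_t = pt, significant = sig)
  })
  write_results_tsv(protdiff$anova, file.path(out_dir, "proteome_anova.tsv"),
                    seed = cfg$rng_seed)
  if (!is.null(protdiff$tukey)) {
    write_results_tsv(protdiff$tukey, file.path(out_dir, "proteome_tukey.tsv"),
                      seed = cfg$rng_seed)
  }

  say("volcano + terminus/protein correlation")
  volcano <- volcano_table(termdiff, ann, proteome)
  write_results_tsv(volcano, file.path(out_dir, "volcano.tsv"),
                    seed = cfg$rng_seed)
  corr <- stage("term-diff", {
    term_fc <- stats::setNames(termdiff$log2FC,
                               ann$accession[match(termdiff$id,
                                                   ann$terminus)])
    lv <- protdiff$completed$values
    gA <- protdiff$completed$design$genotype == params$genotypes[2]
    gB <- protdiff$completed$design$genotype == params$genotypes[3]
    prot_fc <- rowMeans(lv[, gA, drop = FALSE]) -
      rowMeans(lv[, gB, drop = FALSE])
    ok <- !is.na(term_fc) & !is.na(names(term_fc))
    correlate_termini_protein(term_fc[ok], prot_fc)
  })

  say("cluster: z-score profiles, k = ", cfg$n_clusters_k)
  clus <- if (length(protdiff$significant) >= cfg$n_clusters_k) {
    cl <- stage("cluster", zscore_cluster(protdiff$completed,
                                          protdiff$significant, cfg))
    write_results_tsv(cl$clusters, file.path(out_dir, "clusters.tsv"),
                      seed = cfg$rng_seed)
    write_results_tsv(
      data.frame(cluster = rownames(cl$profiles), cl$profiles,
                 check.names = FALSE),
      file.path(out_dir, "cluster_profiles.tsv"), seed = cfg$rng_seed)
    cl
  } else NULL
  # project on the significant proteins when there are enough of them,
  # otherwise on the full quantifiable set
  pca_set <- if (length(protdiff$significant) >= 3L) {
    protdiff$significant
  } else NULL
  pca <- stage("cluster", pca_coordinates(protdiff$completed, pca_set))
  write_results_tsv(pca, file.path(out_dir, "pca_coordinates.tsv"),
                    seed = cfg$rng_seed)

  say("coip: stringent interactor filter")
  coip <- stage("coip", simulate_coip(proteome, params))
  candidates <- stage("coip", stringent_subset(coip$records))
  write_results_tsv(candidates, file.path(out_dir, "coip_candidates.tsv"),
                    seed = cfg$rng_seed)

  manifest <- write_manifest(out_dir, cfg)
  say("done: ", out_dir)
  invisible(list(
    proteome = proteome, terminome = term, annotations = ann,
    tallies = tallies, offset_histogram = offs, terminome_diff = termdiff,
    proteome_quant = prot, proteome_diff = protdiff, volcano = volcano,
    correlation = corr, clustering = clus, pca = pca,
    coip = coip, coip_candidates = candidates,
    manifest = manifest, out_dir = out_dir
  ))
}

# Run manifest: config snapshot, seed and md5 checksums of every output
# file; deterministic stages rerun with the same manifest reproduce the
# same checksums.
write_manifest <- function(out_dir, cfg) {
  files <- sort(setdiff(list.files(out_dir), "manifest.tsv"))
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- data.frame(
    key = c(paste0("config.", names(cfg)), paste0("md5.", files)),
    value = c(vapply(cfg, format, character(1)), unname(sums)),
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}
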