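#' Simulation parameters
#'
#' Defaults emulate the structure of a seedling terminome/proteome study:
#' three genotypes (wild type `wt`, overexpressor `oe`, knock-down `kd`)
#' with four biological replicates, a proteome in which a minority of
#' proteins carries genotype effects, and a terminome whose positional
#' categories and N-terminal acetylation frequencies follow the field's
#' reported rates (89% acetylation at position 1, 78% at position 2, 27%
#' at mature plastid termini, none at signal-peptide-processed termini)
#' with transit-peptide cleavage sites ragged by up to two residues to
#' either side.
#'
#' @param n_proteins number of database proteins.
#' @param frac_plastid_tp,frac_mito_tp,frac_sp fractions of proteins with a
#'   plastid transit peptide, mitochondrial transit peptide, or signal
#'   peptide (exact counts by rounding; the remainder has no presequence).
#' @param seq_length_range protein length range (uniform integer draw).
#' @param cleavage_range presequence length range: the cleavage position
#'   (last presequence residue) is uniform over this range.
#' @param n_termini number of simulated N-terminal peptides.
#' @param category_weights mixture weights over positional categories
#'   (must sum to 1).
#' @param acetyl_prob named acetylation probabilities: `POS1`, `POS2`,
#'   `plastid_mature`, `mito_mature`, `sp_mature`, `unannotated`.
#' @param offset_weights ragged-cleavage offset distribution over -2..+2.
#' @param peptide_length_range simulated peptide length range.
#' @param log2_intensity_mean,log2_intensity_sd per-feature base abundance
#'   distribution (log2 scale).
#' @param replicate_sd within-group replicate noise SD (log2 scale).
#' @param genotypes genotype labels (the second is treated as the
#'   overexpressor, the third as the knock-down for effect assignment).
#' @param n_replicates biological replicates per genotype.
#' @param effect_fraction fraction of proteins carrying a genotype effect
#'   (split evenly between up-in-overexpressor and up-in-knockdown);
#'   N-terminal peptides inherit their parent protein's effect.
#' @param effect_log2 effect size (log2 fold change).
#' @param missing_rate overall expected missing-value fraction.
#' @param miss_steepness steepness of the intensity-dependent
#'   (missing-not-at-random) logistic missingness weight for the proteome.
#' @param n_true_interactors,n_background,bg_prob,n_bait_reps,n_controls
#'   pull-down simulation: number of true (plastid) interactors, number of
#'   sporadic background proteins, per-sample background presence
#'   probability, bait replicates, and control experiments.
#' @param seed integer master seed; each generator derives an independent
#'   stream from it.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_proteins = 600L,
                       frac_plastid_tp = 0.30,
                       frac_mito_tp = 0.10,
                       frac_sp = 0.10,
                       seq_length_range = c(120L, 600L),
                       cleavage_range = c(30L, 80L),
                       n_termini = 1300L,
                       category_weights = c(POS1 = 0.25, POS2 = 0.20,
                                            CLEAVAGE_WINDOW = 0.28,
                                            UNANNOTATED = 0.27),
                       acetyl_prob = c(POS1 = 0.89, POS2 = 0.78,
                                       plastid_mature = 0.27,
                                       mito_mature = 0.05,
                                       sp_mature = 0.0,
                                       unannotated = 0.125),
                       offset_weights = c("-2" = 0.05, "-1" = 0.15,
                                          "0" = 0.60, "1" = 0.15,
                                          "2" = 0.05),
                       peptide_length_range = c(8L, 20L),
                       log2_intensity_mean = 25,
                       log2_intensity_sd = 2,
                       replicate_sd = 0.25,
                       genotypes = c("wt", "oe", "kd"),
                       n_replicates = 4L,
                       effect_fraction = 0.15,
                       effect_log2 = 1.0,
                       missing_rate = 0.2,
                       miss_steepness = 1.0,
                       n_true_interactors = 8L,
                       n_background = 50L,
                       bg_prob = 0.2,
                       n_bait_reps = 2L,
                       n_controls = 2L,
                       seed = 1L) {
  p <- as.list(environment())
  stopifnot(
    p$n_proteins > 0L,
    p$frac_plastid_tp + p$frac_mito_tp + p$frac_sp <= 1,
    abs(sum(p$category_weights) - 1) < 1e-8,
    all(p$acetyl_prob >= 0 & p$acetyl_prob <= 1),
    abs(sum(p$offset_weights) - 1) < 1e-8,
    p$effect_fraction >= 0, p$effect_fraction <= 1,
    p$missing_rate >= 0, p$missing_rate < 1,
    p$n_replicates >= 2L,
    p$seq_length_range[1] > p$cleavage_range[2] + 10L
  )
  structure(p, class = "sim_params")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Generate a synthetic protein database
#'
#' Sequences are i.i.d. uniform over the 20 canonical amino acids with
#' position 1 fixed to Met. Presequence-bearing proteins (plastid/mito
#' transit peptide or signal peptide, in the requested fractions, exact
#' counts by rounding) get a cleavage position uniform over
#' `cleavage_range`. Deterministic given `params$seed`.
#'
#' @param params a [sim_params()] object.
#' @param out_dir optional directory; when given, writes `proteome.fasta`
#'   and `targetp.tsv` there.
#' @return A proteome data.frame (see [build_proteome()]).
#' @export
generate_proteome <- function(params = sim_params(), out_dir = NULL) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(op_seed(params$seed, "generate_proteome"), {
    n <- params$n_proteins
    lens <- sample(params$seq_length_range[1]:params$seq_length_range[2],
                   n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste0("M", paste(sample(AA20, L - 1L, replace = TRUE),
                        collapse = ""))
    }, character(1))
    n_pl <- round(params$frac_plastid_tp * n)
    n_mt <- round(params$frac_mito_tp * n)
    n_sp <- round(params$frac_sp * n)
    compartment <- rep("other", n)
    compartment[seq_len(n_pl)] <- "plastid"
    if (n_mt > 0L) compartment[n_pl + seq_len(n_mt)] <- "mitochondrion"
    if (n_sp > 0L) compartment[n_pl + n_mt + seq_len(n_sp)] <- "secretory"
    cleavage_pos <- rep(NA_integer_, n)
    has_cs <- compartment != "other"
    cleavage_pos[has_cs] <- sample(
      params$cleavage_range[1]:params$cleavage_range[2],
      sum(has_cs), replace = TRUE)
    proteome <- data.frame(
      accession = sprintf("SYN%04d", seq_len(n)),
      sequence = seqs,
      compartment = compartment,
      cleavage_pos = cleavage_pos,
      plastid_encoded = FALSE,
      stringsAsFactors = FALSE
    )
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(proteome, file.path(out_dir, "proteome.fasta"))
    write_targetp_table(proteome, file.path(out_dir, "targetp.tsv"))
  }
  proteome
}

#' Write a proteome's predictions as a TargetP-style TSV
#'
#' @param proteome proteome data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_targetp_table <- function(proteome, path) {
  rev_map <- c(plastid = "cTP", mitochondrion = "mTP",
               secretory = "SP", other = "noTP")
  out <- data.frame(
    accession = proteome$accession,
    prediction = unname(rev_map[proteome$compartment]),
    CS = ifelse(is.na(proteome$cleavage_pos), "",
                as.character(proteome$cleavage_pos)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

sample_design <- function(params) {
  data.frame(
    sample = as.vector(t(outer(params$genotypes, seq_len(params$n_replicates),
                               paste, sep = "_"))),
    genotype = rep(params$genotypes, each = params$n_replicates),
    replicate = as.character(rep(seq_len(params$n_replicates),
                                 length(params$genotypes))),
    stringsAsFactors = FALSE
  )
}

# Per-protein differential class and log2 effect matrix (proteins x
# genotypes). Drawn in its own seed stream so the terminome and proteome
# simulations see the SAME protein-level effects: an N-terminal peptide's
# abundance change mirrors its parent protein's, which is what couples the
# two views in the emulated experiment (terminus fold changes correlate
# with protein fold changes).
draw_protein_effects <- function(proteome, params) {
  withr::with_seed(op_seed(params$seed, "protein_effects"), {
    n <- nrow(proteome)
    classes <- sample(c("null", "up_oe", "up_kd"), n, replace = TRUE,
                      prob = c(1 - params$effect_fraction,
                               params$effect_fraction / 2,
                               params$effect_fraction / 2))
    eff <- matrix(0, nrow = n, ncol = length(params$genotypes),
                  dimnames = list(NULL, params$genotypes))
    eff[classes == "up_oe", params$genotypes[2]] <- params$effect_log2
    eff[classes == "up_kd", params$genotypes[3]] <- params$effect_log2
    list(classes = classes, effects = eff)
  })
}

#' Simulate an N-terminome experiment with ground truth
#'
#' Draws `n_termini` N-terminal peptides over the proteome: start positions
#' consistent with the drawn category (POS1 at 1; POS2 at 2; cleavage-window
#' termini at `cleavage_pos + 1 + offset` with ragged offsets; unannotated
#' termini internal and outside all windows), per-category acetylation,
#' log-normal intensities with genotype effects, and missingness. In the
#' dimethyl labeling chemistry only free amines carry the isotope label, so
#' an acetylated terminus is quantifiable across channels only if its
#' peptide contains a (labelable) Lys; quantifiability is read off the
#' simulated peptide sequence. Non-quantifiable termini are identified but
#' carry no intensities.
#'
#' @param proteome proteome data.frame from [generate_proteome()].
#' @param params a [sim_params()] object.
#' @return List with `quant` (a [quant_table()] over all termini; rows of
#'   non-quantifiable termini are all-NA) and `truth` (per-terminus ground
#'   truth: category, offset, acetylation, quantifiability, and the
#'   differential class / per-genotype log2 effects inherited from the
#'   parent protein, shared with [simulate_proteome_quant()]).
#' @export
simulate_terminome <- function(proteome, params = sim_params()) {
  stopifnot(nrow(proteome) > 0L)
  de_prot <- draw_protein_effects(proteome, params)
  withr::with_seed(op_seed(params$seed, "simulate_terminome"), {
    n <- params$n_termini
    W <- 5L  # category construction window, matches the default config
    cats <- sample(names(params$category_weights), n, replace = TRUE,
                   prob = params$category_weights)
    has_cs <- which(!is.na(proteome$cleavage_pos))
    if (length(has_cs) == 0L && any(cats == "CLEAVAGE_WINDOW")) {
      stop("CLEAVAGE_WINDOW termini requested but no protein has a ",
           "cleavage site")
    }
    offs_support <- as.integer(names(params$offset_weights))
    prot_idx <- integer(n)
    start <- integer(n)
    true_offset <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      if (cats[i] == "CLEAVAGE_WINDOW") {
        prot_idx[i] <- if (length(has_cs) == 1L) has_cs else sample(has_cs, 1L)
        true_offset[i] <- sample(offs_support, 1L,
                                 prob = params$offset_weights)
        start[i] <- proteome$cleavage_pos[prot_idx[i]] + 1L + true_offset[i]
      } else if (cats[i] == "POS1") {
        prot_idx[i] <- sample.int(nrow(proteome), 1L)
        start[i] <- 1L
      } else if (cats[i] == "POS2") {
        prot_idx[i] <- sample.int(nrow(proteome), 1L)
        start[i] <- 2L
      } else {
        repeat {
          j <- sample.int(nrow(proteome), 1L)
          len <- nchar(proteome$sequence[j])
          s <- sample(3L:(len - params$peptide_length_range[1]), 1L)
          cp <- proteome$cleavage_pos[j]
          if (is.na(cp) || abs(s - (cp + 1L)) > W) {
            prot_idx[i] <- j; start[i] <- s; break
          }
        }
      }
    }
    cp_all <- proteome$cleavage_pos[prot_idx]
    observed_offset <- ifelse(is.na(cp_all), NA_integer_,
                              start - (cp_all + 1L))
    plen <- sample(params$peptide_length_range[1]:params$peptide_length_range[2],
                   n, replace = TRUE)
    max_len <- nchar(proteome$sequence[prot_idx]) - start + 1L
    plen <- pmin(plen, max_len)
    peptide <- substr(proteome$sequence[prot_idx], start, start + plen - 1L)
    ap <- params$acetyl_prob
    p_acetyl <- numeric(n)
    comp <- proteome$compartment[prot_idx]
    for (i in seq_len(n)) {
      p_acetyl[i] <- switch(cats[i],
        POS1 = ap[["POS1"]],
        POS2 = ap[["POS2"]],
        CLEAVAGE_WINDOW = switch(comp[i],
                                 plastid = ap[["plastid_mature"]],
                                 mitochondrion = ap[["mito_mature"]],
                                 secretory = ap[["sp_mature"]],
                                 ap[["unannotated"]]),
        UNANNOTATED = ap[["unannotated"]])
    }
    acetylated <- stats::runif(n) < p_acetyl
    has_lys <- grepl("K", peptide, fixed = TRUE)
    quantifiable <- !acetylated | has_lys
    # termini inherit the parent protein's genotype effects
    de <- list(classes = de_prot$classes[prot_idx],
               effects = de_prot$effects[prot_idx, , drop = FALSE])
    design <- sample_design(params)
    base <- stats::rnorm(n, params$log2_intensity_mean,
                         params$log2_intensity_sd)
    log2_mat <- matrix(NA_real_, nrow = n, ncol = nrow(design))
    q <- which(quantifiable)
    for (j in seq_len(nrow(design))) {
      g <- design$genotype[j]
      log2_mat[q, j] <- base[q] + de$effects[q, g] +
        stats::rnorm(length(q), 0, params$replicate_sd)
    }
    if (params$missing_rate > 0) {
      drop <- matrix(stats::runif(n * nrow(design)) < params$missing_rate,
                     nrow = n)
      log2_mat[drop] <- NA_real_
    }
    ids <- sprintf("term%05d", seq_len(n))
    vals <- 2^log2_mat
    dimnames(vals) <- list(ids, design$sample)
    truth <- data.frame(
      terminus = ids,
      accession = proteome$accession[prot_idx],
      start_pos = start,
      peptide_seq = peptide,
      category = cats,
      offset = observed_offset,
      acetylated = acetylated,
      nterm_mod = ifelse(acetylated, "acetylated", "free_dimethylated"),
      has_lys = has_lys,
      quantifiable = quantifiable,
      diff_class = de$classes,
      stringsAsFactors = FALSE
    )
    for (g in params$genotypes) truth[[paste0("eff_", g)]] <- de$effects[, g]
    list(quant = quant_table(vals, design), truth = truth)
  })
}

#' Simulate a label-free quantitative proteome with ground truth
#'
#' Per-protein log-normal abundance over 3 genotypes x `n_replicates`; a
#' fraction `effect_fraction` of proteins carries genotype effects of size
#' `effect_log2`. Missingness is missing-not-at-random: the per-cell
#' missingness probability is a logistic weight decreasing in log2
#' intensity, normalized so the expected overall missing fraction equals
#' `missing_rate`.
#'
#' @param proteome proteome data.frame.
#' @param params a [sim_params()] object.
#' @return List with `quant` (a [quant_table()], raw intensity scale) and
#'   `truth` (per-protein differential class and genotype effects).
#' @export
simulate_proteome_quant <- function(proteome, params = sim_params()) {
  stopifnot(nrow(proteome) > 0L)
  de <- draw_protein_effects(proteome, params)
  withr::with_seed(op_seed(params$seed, "simulate_proteome_quant"), {
    n <- nrow(proteome)
    design <- sample_design(params)
    base <- stats::rnorm(n, params$log2_intensity_mean,
                         params$log2_intensity_sd)
    log2_mat <- matrix(NA_real_, nrow = n, ncol = nrow(design))
    for (j in seq_len(nrow(design))) {
      g <- design$genotype[j]
      log2_mat[, j] <- base + de$effects[, g] +
        stats::rnorm(n, 0, params$replicate_sd)
    }
    if (params$missing_rate > 0) {
      z <- (log2_mat - mean(log2_mat)) / stats::sd(log2_mat)
      w <- stats::plogis(-params$miss_steepness * z)
      p_miss <- pmin(params$missing_rate * w / mean(w), 1)
      log2_mat[stats::runif(length(p_miss)) < p_miss] <- NA_real_
    }
    vals <- 2^log2_mat
    dimnames(vals) <- list(proteome$accession, design$sample)
    truth <- data.frame(
      accession = proteome$accession,
      diff_class = de$classes,
      stringsAsFactors = FALSE
    )
    for (g in params$genotypes) truth[[paste0("eff_", g)]] <- de$effects[, g]
    list(quant = quant_table(vals, design), truth = truth)
  })
}

#' Simulate an affinity-purification pull-down experiment
#'
#' True interactors (drawn from plastid-compartment proteins) are present
#' in every bait replicate and absent from every control; background
#' proteins appear sporadically in any sample (independently with
#' probability `bg_prob` per sample). Per-protein metadata (unique peptide
#' counts, sequence coverage) is drawn to mirror a search-engine protein
#' table.
#'
#' @param proteome proteome data.frame (needs at least
#'   `n_true_interactors` plastid proteins).
#' @param params a [sim_params()] object.
#' @return List with `records` (one row per observed protein: bait log2
#'   intensities `bait_*` with NA = absent, control presence flags
#'   `control_*`, `chloroplast_annotated`, `unique_peptides`, `coverage`)
#'   and `truth` (accessions of the true interactors).
#' @export
simulate_coip <- function(proteome, params = sim_params()) {
  withr::with_seed(op_seed(params$seed, "simulate_coip"), {
    plastid <- proteome$accession[proteome$compartment == "plastid"]
    if (length(plastid) < params$n_true_interactors) {
      stop("not enough plastid proteins for ", params$n_true_interactors,
           " true interactors")
    }
    true_set <- sort(sample(plastid, params$n_true_interactors))
    pool <- setdiff(proteome$accession, true_set)
    n_bg <- min(params$n_background, length(pool))
    bg <- sort(sample(pool, n_bg))
    all_acc <- c(true_set, bg)
    nb <- params$n_bait_reps
    nc <- params$n_controls
    present_bait <- matrix(FALSE, length(all_acc), nb)
    present_ctrl <- matrix(FALSE, length(all_acc), nc)
    present_bait[seq_along(true_set), ] <- TRUE
    is_bg <- seq_along(all_acc) > length(true_set)
    present_bait[is_bg, ] <- stats::runif(sum(is_bg) * nb) < params$bg_prob
    present_ctrl[is_bg, ] <- stats::runif(sum(is_bg) * nc) < params$bg_prob
    inten <- matrix(NA_real_, length(all_acc), nb)
    inten[present_bait] <- stats::rnorm(sum(present_bait),
                                        params$log2_intensity_mean,
                                        params$log2_intensity_sd)
    comp <- proteome$compartment[match(all_acc, proteome$accession)]
    records <- data.frame(accession = all_acc, stringsAsFactors = FALSE)
    for (b in seq_len(nb)) records[[paste0("bait_", b)]] <- inten[, b]
    for (k in seq_len(nc)) records[[paste0("control_", k)]] <- present_ctrl[, k]
    records$chloroplast_annotated <- comp == "plastid"
    records$unique_peptides <- 1L + stats::rpois(length(all_acc), 4)
    records$coverage <- round(stats::runif(length(all_acc), 5, 60), 1)
    keep <- rowSums(present_bait) + rowSums(present_ctrl) > 0
    list(records = records[keep, , drop = FALSE], truth = true_set)
  })
}
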