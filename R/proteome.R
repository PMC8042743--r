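# Label-free proteome differential analysis: quantifiability filter,
# log2 + downshifted-Gaussian imputation, one-way ANOVA with BH FDR and
# Tukey HSD post-hoc, pairwise t-tests, z-score clustering, PCA.

#' Convert a quant table to log2 scale
#'
#' @param qt a [quant_table()] on raw intensity scale.
#' @return A `quant_table` with log2-transformed values.
#' @export
log2_transform <- function(qt) {
  qt$values <- log2(qt$values)
  qt
}

#' Filter for quantifiable features
#'
#' Keeps a feature iff at least one genotype has `min_quant_reps` or more
#' present values (the standard at-least-two-of-four-replicates rule).
#'
#' @param qt a [quant_table()].
#' @param cfg an [analysis_config()].
#' @return The filtered `quant_table`, with attributes `n_kept` and
#'   `n_dropped`.
#' @export
filter_quantifiable <- function(qt, cfg = analysis_config()) {
  genos <- unique(qt$design$genotype)
  reps_per <- table(qt$design$genotype)
  if (any(reps_per < 2L)) {
    stop("design must have at least 2 replicates per genotype")
  }
  present <- !is.na(qt$values)
  keep <- rep(FALSE, nrow(qt$values))
  for (g in genos) {
    cols <- which(qt$design$genotype == g)
    keep <- keep | rowSums(present[, cols, drop = FALSE]) >= cfg$min_quant_reps
  }
  out <- qt
  out$values <- qt$values[keep, , drop = FALSE]
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Impute missing values from a downshifted Gaussian
#'
#' Perseus-style imputation on log2 intensities: missing cells in each
#' sample are drawn from a normal with mean `(sample mean) -
#' impute_downshift * (sample SD)` and SD `impute_width * (sample SD)`,
#' emulating values that fell below the detection limit. Samples with
#' fewer than 3 present values fall back to parameters of the global
#' intensity distribution (with a warning). Deterministic given `seed`.
#'
#' @param qt a `quant_table` of log2 intensities.
#' @param cfg an [analysis_config()].
#' @param seed integer seed (defaults to `cfg$rng_seed`).
#' @return The completed `quant_table`; the logical matrix of imputed
#'   cells is attached as attribute `imputed_mask`.
#' @export
impute_missing <- function(qt, cfg = analysis_config(),
                           seed = cfg$rng_seed) {
  vals <- qt$values
  mask <- is.na(vals)
  if (!any(mask)) {
    attr(qt, "imputed_mask") <- mask
    return(qt)
  }
  g_mean <- mean(vals, na.rm = TRUE)
  g_sd <- stats::sd(vals, na.rm = TRUE)
  withr::with_seed(op_seed(seed, "impute_missing"), {
    for (j in seq_len(ncol(vals))) {
      miss <- which(mask[, j])
      if (length(miss) == 0L) next
      present <- vals[!mask[, j], j]
      if (length(present) < 3L) {
        warning("sample '", colnames(vals)[j], "' has fewer than 3 present ",
                "values; using global imputation parameters")
        m <- g_mean; s <- g_sd
      } else {
        m <- mean(present); s <- stats::sd(present)
      }
      vals[miss, j] <- stats::rnorm(length(miss),
                                    mean = m - cfg$impute_downshift * s,
                                    sd = cfg$impute_width * s)
    }
  })
  qt$values <- vals
  attr(qt, "imputed_mask") <- mask
  qt
}

# Vectorized one-way fixed-effects ANOVA across genotype groups.
# NA-tolerant: per-row group sizes reflect present values. Returns NA for
# rows with < 2 groups having >= 2 values (no within-group df otherwise).
row_anova <- function(vals, genotype) {
  genos <- unique(genotype)
  k <- length(genos)
  n_g <- matrix(0L, nrow(vals), k)
  m_g <- matrix(NA_real_, nrow(vals), k)
  ss_g <- matrix(0, nrow(vals), k)
  for (i in seq_len(k)) {
    cols <- which(genotype == genos[i])
    sub <- vals[, cols, drop = FALSE]
    n_g[, i] <- rowSums(!is.na(sub))
    m_g[, i] <- rowMeans(sub, na.rm = TRUE)
    dev <- sub - m_g[, i]
    ss_g[, i] <- rowSums(dev^2, na.rm = TRUE)
  }
  n_tot <- rowSums(n_g)
  grand <- rowSums(ifelse(n_g > 0, n_g * m_g, 0)) / n_tot
  k_eff <- rowSums(n_g > 0)
  ss_between <- rowSums(ifelse(n_g > 0, n_g * (m_g - grand)^2, 0))
  ss_within <- rowSums(ss_g)
  df1 <- k_eff - 1L
  df2 <- n_tot - k_eff
  msb <- ss_between / df1
  msw <- ss_within / df2
  f <- msb / msw
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  bad <- df1 < 1L | df2 < 1L
  p[bad] <- NA_real_
  f[bad] <- NA_real_
  list(f = f, p = p, df1 = df1, df2 = df2, msw = msw,
       group_means = m_g, group_n = n_g, genotypes = genos)
}

#' Per-protein one-way ANOVA with Benjamini-Hochberg FDR
#'
#' One-way fixed-effects ANOVA of log2 intensity across genotypes for
#' every protein, followed by BH step-up adjustment; the significant set
#' is `{q < fdr_q}`.
#'
#' @param qt a completed (imputed) `quant_table` of log2 intensities.
#' @param cfg an [analysis_config()].
#' @return data.frame `accession`, `anova_p`, `anova_q`, `significant`.
#' @export
anova_bh <- function(qt, cfg = analysis_config()) {
  res <- row_anova(qt$values, qt$design$genotype)
  q <- stats::p.adjust(res$p, method = "BH")
  data.frame(
    accession = rownames(qt$values),
    anova_p = res$p,
    anova_q = q,
    significant = !is.na(q) & q < cfg$fdr_q,
    stringsAsFactors = FALSE
  )
}

#' Tukey HSD post-hoc pairwise comparisons
#'
#' For each protein in the ANOVA-significant set, compares every genotype
#' pair with the studentized-range (Tukey-Kramer) test at family-wise
#' level `alpha`, using the ANOVA within-group mean square.
#'
#' @param qt a completed `quant_table` of log2 intensities.
#' @param significant_accessions accessions to test (typically the
#'   ANOVA-significant set).
#' @param cfg an [analysis_config()].
#' @return data.frame `accession`, `pair` (e.g. `"oe-wt"`), `diff` (log2),
#'   `p_value`, `flag`.
#' @export
tukey_hsd <- function(qt, significant_accessions, cfg = analysis_config()) {
  idx <- match(significant_accessions, rownames(qt$values))
  if (anyNA(idx)) stop("unknown accession: ",
                       significant_accessions[is.na(idx)][1])
  vals <- qt$values[idx, , drop = FALSE]
  res <- row_anova(vals, qt$design$genotype)
  genos <- res$genotypes
  k <- length(genos)
  pairs <- utils::combn(k, 2L)
  out <- list()
  for (pi in seq_len(ncol(pairs))) {
    i <- pairs[1, pi]; j <- pairs[2, pi]
    diff <- res$group_means[, j] - res$group_means[, i]
    se <- sqrt(res$msw / 2 * (1 / res$group_n[, i] + 1 / res$group_n[, j]))
    qstat <- abs(diff) / se
    p <- stats::ptukey(qstat, nmeans = k, df = res$df2, lower.tail = FALSE)
    out[[pi]] <- data.frame(
      accession = significant_accessions,
      pair = paste0(genos[j], "-", genos[i]),
      diff = diff,
      p_value = p,
      flag = !is.na(p) & p < cfg$alpha,
      stringsAsFactors = FALSE
    )
  }
  res_df <- do.call(rbind, out)
  rownames(res_df) <- NULL
  res_df
}

#' Pairwise two-tailed t-tests per genotype pair
#'
#' Per-protein two-sample t-tests for every genotype pair, pooled
#' variance by default (Welch optional), flagged at `alpha`. Mirrors the
#' per-pair "significantly different from wild type" columns of a
#' protein-abundance summary table. With `use_imputed = FALSE` supply an
#' unimputed table: tests then use observed values only and rows with too
#' few present values per group are NA.
#'
#' @param qt a `quant_table` of log2 intensities.
#' @param cfg an [analysis_config()].
#' @param pooled pooled-variance (TRUE, default) or Welch test.
#' @return data.frame `accession`, `pair`, `diff`, `p_value`, `flag`.
#' @export
pairwise_t_flags <- function(qt, cfg = analysis_config(), pooled = TRUE) {
  genos <- unique(qt$design$genotype)
  pairs <- utils::combn(length(genos), 2L)
  out <- list()
  for (pi in seq_len(ncol(pairs))) {
    gi <- genos[pairs[1, pi]]; gj <- genos[pairs[2, pi]]
    xA <- qt$values[, qt$design$genotype == gj, drop = FALSE]
    xB <- qt$values[, qt$design$genotype == gi, drop = FALSE]
    nA <- rowSums(!is.na(xA)); nB <- rowSums(!is.na(xB))
    mA <- rowMeans(xA, na.rm = TRUE); mB <- rowMeans(xB, na.rm = TRUE)
    vA <- apply(xA, 1L, stats::var, na.rm = TRUE)
    vB <- apply(xB, 1L, stats::var, na.rm = TRUE)
    if (pooled) {
      d <- nA + nB - 2L
      s2 <- ((nA - 1L) * vA + (nB - 1L) * vB) / d
      se <- sqrt(s2 * (1 / nA + 1 / nB))
      df <- d
    } else {
      se <- sqrt(vA / nA + vB / nB)
      df <- (vA / nA + vB / nB)^2 /
        ((vA / nA)^2 / (nA - 1L) + (vB / nB)^2 / (nB - 1L))
    }
    tstat <- (mA - mB) / se
    p <- 2 * stats::pt(-abs(tstat), df = df)
    invalid <- nA < cfg$min_quant_reps | nB < cfg$min_quant_reps |
      !is.finite(se) | se == 0
    p[invalid & (mA - mB) != 0] <- NA_real_
    p[!is.na(se) & se == 0 & (mA - mB) == 0] <- 1
    out[[pi]] <- data.frame(
      accession = rownames(qt$values),
      pair = paste0(gj, "-", gi),
      diff = mA - mB,
      p_value = p,
      flag = !is.na(p) & p < cfg$alpha,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Z-score normalize and hierarchically cluster abundance profiles
#'
#' Each protein's log2 profile is standardized to mean 0, SD 1 across all
#' samples; proteins are clustered by agglomerative hierarchical
#' clustering (Euclidean distance, average linkage) and the tree is cut
#' into `n_clusters_k` groups.
#'
#' @param qt a completed `quant_table` of log2 intensities.
#' @param significant_accessions proteins to cluster.
#' @param cfg an [analysis_config()].
#' @return List: `clusters` (data.frame `accession`, `cluster`),
#'   `profiles` (cluster-mean z-score matrix, clusters x samples),
#'   `zscores` (protein z-score matrix), `tree` (the hclust object).
#' @export
zscore_cluster <- function(qt, significant_accessions,
                           cfg = analysis_config()) {
  idx <- match(significant_accessions, rownames(qt$values))
  if (anyNA(idx)) stop("unknown accession: ",
                       significant_accessions[is.na(idx)][1])
  vals <- qt$values[idx, , drop = FALSE]
  if (any(is.na(vals))) stop("clustering requires a completed (imputed) table")
  mu <- rowMeans(vals)
  sdv <- apply(vals, 1L, stats::sd)
  if (any(sdv == 0)) sdv[sdv == 0] <- 1  # flat profile -> all-zero z-scores
  z <- (vals - mu) / sdv
  k <- min(cfg$n_clusters_k, nrow(z))
  tree <- stats::hclust(stats::dist(z, method = "euclidean"),
                        method = "average")
  cl <- stats::cutree(tree, k = k)
  profiles <- do.call(rbind, lapply(seq_len(k), function(ci) {
    colMeans(z[cl == ci, , drop = FALSE])
  }))
  rownames(profiles) <- paste0("cluster_", seq_len(k))
  list(
    clusters = data.frame(accession = significant_accessions,
                          cluster = unname(cl), stringsAsFactors = FALSE),
    profiles = profiles,
    zscores = z,
    tree = tree
  )
}

#' Sample PCA coordinates
#'
#' Projects the samples onto the first two principal components of the
#' (protein-centered) log2 intensity matrix restricted to a protein set —
#' replicates of distinct genotypes with real effects separate into
#' genotype clusters.
#'
#' @param qt a completed `quant_table` of log2 intensities.
#' @param significant_accessions proteins defining the projection
#'   (default: all).
#' @return data.frame `sample`, `genotype`, `PC1`, `PC2`, with the
#'   per-component variance-explained fractions as attribute
#'   `var_explained`.
#' @export
pca_coordinates <- function(qt, significant_accessions = NULL) {
  vals <- qt$values
  if (!is.null(significant_accessions)) {
    idx <- match(significant_accessions, rownames(vals))
    if (anyNA(idx)) stop("unknown accession: ",
                         significant_accessions[is.na(idx)][1])
    vals <- vals[idx, , drop = FALSE]
  }
  if (any(is.na(vals))) stop("PCA requires a completed (imputed) table")
  pc <- stats::prcomp(t(vals), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x
  if (ncol(scores) < 2L) scores <- cbind(scores, PC2 = 0)
  out <- data.frame(
    sample = qt$design$sample,
    genotype = qt$design$genotype,
    PC1 = scores[, 1], PC2 = scores[, 2],
    stringsAsFactors = FALSE
  )
  attr(out, "var_explained") <- ve
  rownames(out) <- NULL
  out
}
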