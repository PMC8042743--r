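# Empirical-Bayes moderated t-statistics for per-terminus differential
# abundance. The per-feature sample variance s2 is shrunk toward a prior
# s0^2 with prior degrees of freedom d0, estimated by moment matching of
# log sample variances against a scaled F distribution: under the model
# s2 ~ s0^2 * F(d, d0), so that
#   E[log s2] = log s0^2 + digamma(d/2) - log(d/2)
#                        - digamma(d0/2) + log(d0/2)
#   Var[log s2] = trigamma(d/2) + trigamma(d0/2).

# Invert trigamma by Newton iteration (monotone decreasing, convex).
trigamma_inverse <- function(x) {
  stopifnot(x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (iter in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Estimate variance-shrinkage hyperparameters
#'
#' Fits the empirical-Bayes prior (d0, s0^2) for the moderated t-test by
#' moment matching of log sample variances against a scaled F
#' distribution. When the dispersion of log variances is at or below its
#' theoretical minimum (all variance is sampling noise), d0 = Inf and
#' every feature shares the pooled variance s0^2.
#'
#' @param s2 per-feature sample variances (finite, positive entries used).
#' @param df residual degrees of freedom: scalar, or vector along `s2`.
#' @return List with elements `d0` (prior df, possibly Inf) and `s02`
#'   (prior variance).
#' @export
fit_moderation <- function(s2, df) {
  if (length(df) == 1L) df <- rep(df, length(s2))
  stopifnot(length(df) == length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (!any(ok)) {
    stop("all variances are zero or undefined; apply a pseudo-variance ",
         "floor before fitting the prior")
  }
  if (sum(ok) < 10L) {
    warning("fewer than 10 usable variances; hyperparameter estimates ",
            "are unstable")
  }
  s2u <- s2[ok]
  dfu <- df[ok]
  e <- log(s2u) - digamma(dfu / 2) + log(dfu / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(dfu / 2))
  if (!is.finite(evar) || evar <= 0) {
    # log-variance dispersion at or below its sampling minimum: all
    # features share one variance; the pooled (mean) variance estimates it
    return(list(d0 = Inf, s02 = mean(s2u)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

#' Moderated two-sample t-tests on log2 intensities
#'
#' For each feature, compares the two groups with a pooled-variance t-test
#' whose variance is shrunk toward the empirical-Bayes prior:
#' `s2_tilde = (d0*s02 + d*s2) / (d0 + d)` with `d` the per-feature
#' residual df (reduced by missing values), and the statistic referred to
#' a t distribution on `d0 + d` df. `d0 = Inf` uses `s02` exactly;
#' `d0 = 0` reduces to the ordinary pooled two-sample t-test. Features
#' with fewer than `min_quant_reps` present values in either group are
#' skipped with a reason code.
#'
#' @param xA,xB numeric matrices of log2 intensities (features x
#'   replicates), NA = missing; equal row counts, shared feature order.
#' @param d0,s02 hyperparameters from [fit_moderation()].
#' @param cfg an [analysis_config()] (uses `min_quant_reps`, `alpha`,
#'   `log2fc_tau`).
#' @param ids optional feature identifiers.
#' @return data.frame with one row per input feature: `id`, `log2FC`
#'   (A - B), `s2`, `s2_tilde`, `t_mod`, `df`, `p_value`, `significant`,
#'   `skipped`, `reason`.
#' @export
moderated_t <- function(xA, xB, d0, s02, cfg = analysis_config(),
                        ids = NULL) {
  xA <- as.matrix(xA); xB <- as.matrix(xB)
  stopifnot(nrow(xA) == nrow(xB))
  if (is.null(ids)) {
    ids <- rownames(xA)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(xA)))
  }
  nA <- rowSums(!is.na(xA))
  nB <- rowSums(!is.na(xB))
  mA <- rowMeans(xA, na.rm = TRUE)
  mB <- rowMeans(xB, na.rm = TRUE)
  vA <- apply(xA, 1L, stats::var, na.rm = TRUE)
  vB <- apply(xB, 1L, stats::var, na.rm = TRUE)
  vA[nA < 2L] <- 0; vB[nB < 2L] <- 0
  d <- nA + nB - 2L
  s2 <- ifelse(d > 0, ((nA - 1L) * vA + (nB - 1L) * vB) / d, NA_real_)
  skipped <- nA < cfg$min_quant_reps | nB < cfg$min_quant_reps
  reason <- ifelse(skipped, "insufficient_replicates", "")
  s2_tilde <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + d * s2) / (d0 + d)
  log2FC <- mA - mB
  se <- sqrt(s2_tilde * (1 / nA + 1 / nB))
  t_mod <- ifelse(log2FC == 0, 0, log2FC / se)
  t_mod[!is.finite(t_mod) & !is.na(log2FC)] <-
    sign(log2FC[!is.finite(t_mod) & !is.na(log2FC)]) * Inf
  df_tot <- d0 + d
  p <- 2 * stats::pt(-abs(t_mod), df = df_tot)
  p[!is.na(t_mod) & t_mod == 0] <- 1
  out <- data.frame(
    id = ids, log2FC = log2FC, s2 = s2, s2_tilde = s2_tilde,
    t_mod = t_mod, df = df_tot, p_value = p,
    significant = NA, skipped = skipped, reason = reason,
    stringsAsFactors = FALSE
  )
  out$log2FC[skipped] <- NA_real_
  out$t_mod[skipped] <- NA_real_
  out$p_value[skipped] <- NA_real_
  out$significant <- !skipped & out$p_value < cfg$alpha &
    abs(out$log2FC) > cfg$log2fc_tau
  rownames(out) <- NULL
  out
}

#' Apply the significance filter to test results
#'
#' A feature is significant iff `p < alpha` AND `|log2FC| > log2fc_tau`
#' (the default tau of 0.58 is the two-decimal log2 equivalent of a 50%
#' abundance change). Optionally substitutes BH-adjusted p-values for the
#' raw ones.
#'
#' @param results data.frame with `p_value` and `log2FC` columns.
#' @param cfg an [analysis_config()].
#' @param use_fdr apply Benjamini-Hochberg adjustment before thresholding
#'   (default FALSE: raw p-values, as in the standard terminome criteria).
#' @return `results` with `significant` recomputed and a `direction`
#'   column (`up`/`down`/`ns`); counts are attached as attribute `counts`.
#' @export
significance_filter <- function(results, cfg = analysis_config(),
                                use_fdr = FALSE) {
  p <- results$p_value
  if (use_fdr) p <- stats::p.adjust(p, method = "BH")
  sig <- !is.na(p) & p < cfg$alpha &
    !is.na(results$log2FC) & abs(results$log2FC) > cfg$log2fc_tau
  results$significant <- sig
  results$direction <- "ns"
  results$direction[sig & results$log2FC > 0] <- "up"
  results$direction[sig & results$log2FC < 0] <- "down"
  attr(results, "counts") <- c(up = sum(results$direction == "up"),
                               down = sum(results$direction == "down"),
                               ns = sum(results$direction == "ns"))
  results
}

#' Correlate terminus and parent-protein fold changes
#'
#' Pearson correlation between N-terminal-peptide log2 fold changes and
#' the corresponding protein-level log2 fold changes, with a 95%
#' confidence interval from the Fisher z transform. A strong correlation
#' indicates that terminus abundance changes track overall protein
#' abundance rather than differential proteolytic processing.
#'
#' @param term_fc named numeric vector of terminus log2 fold changes
#'   (names = parent-protein accessions).
#' @param prot_fc named numeric vector of protein log2 fold changes.
#' @return List: `n` matched pairs, `r`, `ci_lo`, `ci_hi`, `p_value`.
#' @export
correlate_termini_protein <- function(term_fc, prot_fc) {
  stopifnot(!is.null(names(term_fc)), !is.null(names(prot_fc)))
  matched <- names(term_fc) %in% names(prot_fc)
  x <- term_fc[matched]
  y <- prot_fc[names(term_fc)[matched]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 matched pairs, got ", length(x))
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
  list(n = length(x), r = unname(ct$estimate),
       ci_lo = ct$conf.int[1], ci_hi = ct$conf.int[2],
       p_value = ct$p.value)
}

#' Build a volcano table from test results
#'
#' One row per tested (non-skipped) feature: log2 fold change, -log10 p,
#' significance class, and a plastid flag when annotations are supplied.
#'
#' @param results output of [moderated_t()] / [significance_filter()].
#' @param annotations optional [annotate_termini()] output with an
#'   `accession` column matched via `results$id` -> `annotations$terminus`.
#' @param proteome optional proteome data.frame for the plastid flag.
#' @return data.frame `id`, `log2FC`, `neg_log10_p`, `class`, `plastid`.
#' @export
volcano_table <- function(results, annotations = NULL, proteome = NULL) {
  res <- if ("direction" %in% names(results)) results else
    significance_filter(results)
  res <- res[!res$skipped & !is.na(res$p_value), , drop = FALSE]
  out <- data.frame(
    id = res$id,
    log2FC = res$log2FC,
    neg_log10_p = -log10(res$p_value),
    class = res$direction,
    plastid = rep(NA, nrow(res)),
    stringsAsFactors = FALSE
  )
  if (!is.null(annotations) && !is.null(proteome)) {
    acc <- annotations$accession[match(out$id, annotations$terminus)]
    comp <- proteome$compartment[match(acc, proteome$accession)]
    enc <- proteome$plastid_encoded[match(acc, proteome$accession)]
    out$plastid <- comp == "plastid" | (!is.na(enc) & enc)
  }
  rownames(out) <- NULL
  out
}
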