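#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline in one validated object.
#' Defaults reproduce the workflow's standard settings: cleavage-site
#' windows of five residues, significance at P < 0.05 with a fold-change
#' floor of |log2 FC| > 0.58 (a 50% change), BH FDR at 0.05, quantification
#' in at least two of four replicates, seven abundance-profile clusters,
#' and downshifted-Gaussian imputation with width 0.3 and downshift 1.8
#' (in units of the per-sample SD).
#'
#' @param window_W integer; half-width (residues) of the window around a
#'   predicted cleavage site within which a terminus counts as expected.
#' @param alpha p-value threshold for per-test significance.
#' @param fdr_q Benjamini-Hochberg FDR threshold for the proteome ANOVA.
#' @param log2fc_tau absolute log2 fold-change threshold.
#' @param min_quant_reps minimum present values per group for a feature to
#'   count as quantified.
#' @param n_clusters_k number of clusters cut from the abundance-profile tree.
#' @param impute_width imputation SD as a fraction of the sample SD.
#' @param impute_downshift imputation mean downshift in sample SDs.
#' @param rng_seed integer seed controlling all stochastic steps.
#' @return An object of class `analysis_config` (a validated named list).
#' @export
analysis_config <- function(window_W = 5L,
                            alpha = 0.05,
                            fdr_q = 0.05,
                            log2fc_tau = 0.58,
                            min_quant_reps = 2L,
                            n_clusters_k = 7L,
                            impute_width = 0.3,
                            impute_downshift = 1.8,
                            rng_seed = 1L) {
  cfg <- list(
    window_W = as.integer(window_W),
    alpha = as.numeric(alpha),
    fdr_q = as.numeric(fdr_q),
    log2fc_tau = as.numeric(log2fc_tau),
    min_quant_reps = as.integer(min_quant_reps),
    n_clusters_k = as.integer(n_clusters_k),
    impute_width = as.numeric(impute_width),
    impute_downshift = as.numeric(impute_downshift),
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "analysis_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$window_W >= 0L,
    cfg$alpha > 0, cfg$alpha < 1,
    cfg$fdr_q > 0, cfg$fdr_q < 1,
    cfg$log2fc_tau > 0,
    cfg$min_quant_reps >= 1L,
    cfg$n_clusters_k >= 1L,
    cfg$impute_width >= 0,
    cfg$impute_downshift >= 0
  )
  invisible(cfg)
}

#' Read a flat key=value configuration file
#'
#' One `key = value` pair per line; blank lines and lines starting with `#`
#' are ignored. Keys must be parameters of [analysis_config()]; unknown keys
#' are an error, so a typo cannot silently fall back to a default.
#'
#' @param path path to the configuration text file.
#' @return An `analysis_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  defaults <- formals(analysis_config)
  overrides <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed config line: '", ln, "'")
    key <- trimws(parts[1])
    val <- trimws(parts[2])
    if (!key %in% names(defaults)) stop("unknown config key: '", key, "'")
    num <- suppressWarnings(as.numeric(val))
    if (is.na(num)) stop("non-numeric value for config key '", key, "': ", val)
    overrides[[key]] <- num
  }
  do.call(analysis_config, overrides)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("analysis_config:\n")
  for (k in names(x)) cat(sprintf("  %-16s %s\n", k, format(x[[k]])))
  invisible(x)
}

# Deterministic per-operation seed: combines the user seed with a polynomial
# hash of the operation name so independent stages draw from independent,
# reproducible streams. Kept below 2^31 - 1 (R integer range).
op_seed <- function(seed, op) {
  h <- 0
  for (ch in utf8ToInt(op)) h <- (h * 31 + ch) %% 2147483587
  as.integer((as.numeric(seed) %% 2147483587 + h) %% 2147483587)
}
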