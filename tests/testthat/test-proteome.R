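cfg <- analysis_config()

test_that("quantifiability filter keeps >= 2-of-4 in at least one genotype", {
  vals <- matrix(NA_real_, nrow = 4, ncol = 12)
  vals[1, 5:6] <- c(10, 11)          # 2/4 in one genotype only -> kept
  vals[2, c(1, 5, 9)] <- 10          # 1/4 in every genotype -> dropped
  vals[3, ] <- 10                    # complete -> kept
  # row 4 all missing -> dropped
  qt <- toy_quant(vals)
  filt <- filter_quantifiable(qt, cfg)
  expect_equal(rownames(filt$values), c("prot01", "prot03"))
  expect_equal(attr(filt, "n_kept"), 2L)
  expect_equal(attr(filt, "n_dropped"), 2L)
})

test_that("quantifiability filter matches a brute-force per-row scan", {
  withr::with_seed(12, {
    vals <- matrix(rnorm(10 * 12, 20, 2), nrow = 10)
    vals[runif(120) < 0.5] <- NA
  })
  qt <- toy_quant(vals)
  filt <- filter_quantifiable(qt, cfg)
  # oracle: literal restatement of the rule, row by row, group by group
  keep <- vapply(seq_len(10), function(i) {
    any(vapply(split(seq_len(12), qt$design$genotype), function(cols) {
      sum(!is.na(vals[i, cols])) >= 2L
    }, logical(1)))
  }, logical(1))
  expect_equal(rownames(filt$values), rownames(qt$values)[keep])
})

test_that("imputation draws from the downshifted per-sample distribution", {
  withr::with_seed(21, {
    vals <- matrix(rnorm(1000 * 12, 25, 2), nrow = 1000)
    miss <- matrix(runif(12000) < 0.15, nrow = 1000)
    vals[miss] <- NA
  })
  qt <- toy_quant(vals)
  imp <- impute_missing(qt, cfg, seed = 5)
  mask <- attr(imp, "imputed_mask")
  expect_identical(mask, is.na(qt$values))
  expect_false(anyNA(imp$values))
  expect_equal(imp$values[!mask], vals[!mask])
  # imputed values in sample 1 center on mean - 1.8*SD of its observed part
  j <- 1L
  obs <- vals[!mask[, j], j]
  target <- mean(obs) - cfg$impute_downshift * sd(obs)
  got <- imp$values[mask[, j], j]
  se <- cfg$impute_width * sd(obs) / sqrt(length(got))
  expect_lt(abs(mean(got) - target), 3 * se)
  # deterministic given seed
  imp2 <- impute_missing(qt, cfg, seed = 5)
  expect_identical(imp2$values, imp$values)
  # no missing values: identity
  qt_full <- toy_quant(matrix(rnorm(48, 25, 2), nrow = 4))
  imp3 <- impute_missing(qt_full, cfg)
  expect_identical(imp3$values, qt_full$values)
  expect_false(any(attr(imp3, "imputed_mask")))
})

test_that("width 0 imputation is the degenerate point mass at the downshift", {
  vals <- matrix(rnorm(48, 25, 2), nrow = 4)
  vals[1, 1] <- NA
  qt <- toy_quant(vals)
  cfg0 <- analysis_config(impute_width = 0)
  imp <- impute_missing(qt, cfg0, seed = 1)
  obs <- vals[-1, 1]
  expect_equal(imp$values[1, 1], mean(obs) - 1.8 * sd(obs),
               tolerance = 1e-12)
})

test_that("row-wise ANOVA agrees with the lm/anova oracle per protein", {
  withr::with_seed(33, {
    vals <- matrix(rnorm(8 * 12, 20, 1), nrow = 8)
    vals[1:3, 5:8] <- vals[1:3, 5:8] + 2
  })
  qt <- toy_quant(vals)
  res <- anova_bh(qt, cfg)
  g <- factor(qt$design$genotype)
  for (i in seq_len(8)) {
    oracle <- anova(lm(vals[i, ] ~ g))[["Pr(>F)"]][1]
    expect_equal(res$anova_p[i], oracle, tolerance = 1e-10)
  }
  expect_equal(res$anova_q, p.adjust(res$anova_p, "BH"))
  expect_true(all(res$anova_q >= res$anova_p))
})

test_that("BH selection matches brute-force evaluation over all cutoffs", {
  bh_oracle <- function(p, q) {
    # largest k with p_(k) <= k q / m; reject all p <= that cutoff
    m <- length(p)
    ps <- sort(p)
    k <- max(c(0, which(ps <= seq_len(m) * q / m)))
    if (k == 0) rep(FALSE, m) else p <= ps[k]
  }
  p1 <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(p.adjust(p1, "BH") < 0.05, bh_oracle(p1, 0.05))
  expect_true(all(bh_oracle(p1, 0.05)))  # all four pass at m = 4
  p2 <- c(0.3, 0.6)
  expect_equal(sum(bh_oracle(p2, 0.05)), 0L)
  withr::with_seed(9, {
    p3 <- c(runif(15), runif(5, 0, 0.01))
  })
  expect_equal(p.adjust(p3, "BH") < 0.05, bh_oracle(p3, 0.05))
  # q-values are monotone in p
  ord <- order(p3)
  expect_true(all(diff(p.adjust(p3, "BH")[ord]) >= -1e-15))
})

test_that("Tukey HSD flags separated pairs and matches TukeyHSD/ptukey", {
  withr::with_seed(44, {
    vals <- matrix(rnorm(6 * 12, 0, 0.05), nrow = 6)
    vals[1:3, 9:12] <- vals[1:3, 9:12] + 5  # kd shifted for rows 1-3
  })
  qt <- toy_quant(vals)
  res <- tukey_hsd(qt, rownames(qt$values), cfg)
  r1 <- res[res$accession == "prot01", ]
  expect_true(r1$flag[r1$pair %in% c("kd-wt", "kd-oe")] |> all())
  expect_false(r1$flag[r1$pair == "oe-wt"])
  # oracle: base-R TukeyHSD on the same model
  g <- factor(qt$design$genotype, levels = unique(qt$design$genotype))
  for (i in c(1L, 5L)) {
    tk <- TukeyHSD(aov(vals[i, ] ~ g))$g
    ri <- res[res$accession == rownames(qt$values)[i], ]
    for (pr in rownames(tk)) {
      expect_equal(ri$p_value[ri$pair == pr], tk[pr, "p adj"],
                   tolerance = 1e-8, info = pr)
    }
  }
  # studentized-range critical value q(0.05; k=3, df=9) = 3.948 (tables)
  expect_equal(qtukey(0.95, nmeans = 3, df = 9), 3.948, tolerance = 1e-3)
})

test_that("pairwise t-tests match t.test and flag only real separation", {
  withr::with_seed(55, {
    vals <- matrix(rnorm(5 * 12, 10, 0.5), nrow = 5)
    vals[1, 5:8] <- vals[1, 5:8] + 10
  })
  vals[2, ] <- rep(c(7, 8, 7.5, 7.2), 3)  # identical groups
  qt <- toy_quant(vals)
  res <- pairwise_t_flags(qt, cfg, pooled = TRUE)
  expect_true(all(res$flag[res$accession == "prot01" &
                             res$pair %in% c("oe-wt", "kd-oe")]))
  expect_false(any(res$flag[res$accession == "prot02"]))
  g <- qt$design$genotype
  oracle <- t.test(vals[1, g == "oe"], vals[1, g == "wt"],
                   var.equal = TRUE)
  r <- res[res$accession == "prot01" & res$pair == "oe-wt", ]
  expect_equal(r$p_value, oracle$p.value, tolerance = 1e-10)
  expect_equal(r$diff, unname(oracle$estimate[1] - oracle$estimate[2]),
               tolerance = 1e-10)
  # Welch option against t.test default
  res_w <- pairwise_t_flags(qt, cfg, pooled = FALSE)
  oracle_w <- t.test(vals[1, g == "oe"], vals[1, g == "wt"])
  rw <- res_w[res_w$accession == "prot01" & res_w$pair == "oe-wt", ]
  expect_equal(rw$p_value, oracle_w$p.value, tolerance = 1e-10)
})

test_that("two planted profile archetypes are recovered perfectly (ARI = 1)", {
  skip_if_not_installed("mclust")
  withr::with_seed(66, {
    up_in_oe <- rep(c(0, 3, 0), each = 4)
    up_in_kd <- rep(c(0, 0, 3), each = 4)
    vals <- rbind(
      matrix(rep(up_in_oe, 20), nrow = 20, byrow = TRUE),
      matrix(rep(up_in_kd, 15), nrow = 15, byrow = TRUE)
    ) + matrix(rnorm(35 * 12, 20, 0.1), nrow = 35)
  })
  truth <- rep(1:2, c(20, 15))
  qt <- toy_quant(vals)
  cl <- zscore_cluster(qt, rownames(qt$values),
                       analysis_config(n_clusters_k = 2))
  expect_equal(mclust::adjustedRandIndex(cl$clusters$cluster, truth), 1)
  # z-scores are standardized per protein
  expect_equal(unname(rowMeans(cl$zscores)), rep(0, 35), tolerance = 1e-12)
  expect_equal(unname(apply(cl$zscores, 1, sd)), rep(1, 35),
               tolerance = 1e-12)
  # conservation and the k = 1 degenerate case
  expect_equal(nrow(cl$clusters), 35L)
  cl1 <- zscore_cluster(qt, rownames(qt$values),
                        analysis_config(n_clusters_k = 1))
  expect_true(all(cl1$clusters$cluster == 1L))
})

test_that("PCA separates genotypes with effects and degenerates gracefully", {
  withr::with_seed(88, {
    base <- rnorm(40, 20, 2)
    vals <- matrix(base, nrow = 40, ncol = 12)
    vals[1:15, 5:8] <- vals[1:15, 5:8] + 4
    vals[16:30, 9:12] <- vals[16:30, 9:12] + 4
    vals <- vals + matrix(rnorm(480, 0, 0.2), nrow = 40)
  })
  qt <- toy_quant(vals)
  pc <- pca_coordinates(qt)
  # genotype centroids are mutually distant relative to within-group spread
  cent <- aggregate(cbind(PC1, PC2) ~ genotype, pc, mean)
  d <- dist(cent[, c("PC1", "PC2")])
  within <- max(tapply(seq_len(12), pc$genotype, function(i) {
    max(dist(pc[i, c("PC1", "PC2")]))
  }))
  expect_gt(min(d), within)
  ve <- attr(pc, "var_explained")
  expect_true(all(diff(ve) <= 1e-12))  # non-increasing
  # identical samples: all scores equal
  qt0 <- toy_quant(matrix(rep(rnorm(10, 20, 1), 12), nrow = 10))
  pc0 <- pca_coordinates(qt0)
  expect_equal(max(abs(pc0$PC1 - pc0$PC1[1])), 0, tolerance = 1e-10)
})

test_that("the pipeline conserves proteins between filter and tests", {
  params <- fast_sim_params()
  sim <- simulate_proteome_quant(generate_proteome(params), params)
  filt <- filter_quantifiable(sim$quant, cfg)
  expect_equal(attr(filt, "n_kept") + attr(filt, "n_dropped"),
               nrow(sim$quant$values))
  completed <- impute_missing(log2_transform(filt), cfg)
  av <- anova_bh(completed, cfg)
  expect_equal(nrow(av), attr(filt, "n_kept"))
  expect_false(anyNA(av$anova_p))
  expect_false(anyNA(av$anova_q))
})
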