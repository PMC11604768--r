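## small helper: counts/samples/dictionary triple for a hand-built matrix
## whose DNA columns come first
diff_fixture <- function(n_prom = 4, n_bc = 30, seed = 1, effect = 1,
                         n_dna = 3, n_rep = 3, depth = 60, phi = 0.2) {
  cfg <- sim_config(n_promoters = n_prom, n_barcodes = n_bc,
                    dna_depth = depth, rna_depth = depth,
                    nb_dispersion = phi, n_dna_reps = n_dna,
                    n_rna_reps = n_rep,
                    responsive_fraction = if (effect != 1) 1 else 0,
                    effect_size = effect)
  simulate_screen_counts(cfg, seed = seed)
}

test_that("barcode capping keeps the top-DNA barcodes with lexicographic ties", {
  set.seed(2)
  bcs <- sprintf("bc%03d", 1:150)
  dict <- tibble::tibble(barcode = bcs, promoter_id = "P1")
  counts <- tibble::tibble(barcode = bcs, sample_id = "dna1",
                           count = sample(10:500, 150))
  samples <- tibble::tibble(sample_id = "dna1", material = "DNA",
                            condition = "input", batch = "b")
  capped <- cap_barcodes(dict, counts, samples, cap = 100)
  expect_equal(nrow(capped), 100)
  top <- counts$barcode[order(-counts$count, counts$barcode)][1:100]
  expect_setequal(capped$barcode, top)

  ## fewer than the cap: everything kept
  small <- cap_barcodes(dict[1:80, ], counts[1:80, ], samples, cap = 100)
  expect_equal(nrow(small), 80)

  ## tie at the cutoff resolved lexicographically
  tie_counts <- tibble::tibble(barcode = c("bcA", "bcB", "bcC"),
                               sample_id = "dna1", count = c(9L, 5L, 5L))
  tie_dict <- tibble::tibble(barcode = c("bcA", "bcB", "bcC"),
                             promoter_id = "P1")
  kept <- cap_barcodes(tie_dict, tie_counts, samples, cap = 2)
  expect_setequal(kept$barcode, c("bcA", "bcB"))
})

test_that("BH adjustment matches the hand computation", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.2, 0.04, 0.9)
  expect_equal(adjust_fdr(p), p.adjust(p, "BH"))
})

test_that("the vectorized engine agrees with a brute-force NB maximizer", {
  sim <- diff_fixture(n_prom = 3, n_bc = 25, seed = 4, effect = 1.6)
  fit <- mpra_diff_test(sim$counts, sim$samples, sim$dictionary,
                        conditions = c("control", "treated"),
                        recenter = FALSE)
  res <- tidy(fit)

  ## rebuild the per-promoter data exactly as the engine sees it
  samples <- sim$samples
  dna_ids <- samples$sample_id[samples$material == "DNA"]
  rna <- samples[samples$material == "RNA", ]
  wide <- tidyr::pivot_wider(sim$counts, names_from = "sample_id",
                             values_from = "count", values_fill = 0L)
  wide <- dplyr::inner_join(sim$dictionary, wide, by = "barcode")
  dfac <- fit$depth_factors
  for (p in unique(wide$promoter_id)) {
    w <- wide[wide$promoter_id == p, ]
    d_b <- rowMeans(sweep(as.matrix(w[dna_ids]), 2,
                          dfac$depth_factor[match(dna_ids, dfac$sample_id)],
                          "/"))
    keep <- d_b > 0
    y <- as.numeric(as.matrix(w[rna$sample_id])[keep, ])
    offs <- as.numeric(d_b[keep] %o%
                         dfac$depth_factor[match(rna$sample_id,
                                                 dfac$sample_id)])
    cond <- rep(rna$condition, each = sum(keep))
    got <- res[res$promoter_id == p, ]
    ## at the engine's dispersion, the brute-force maximizer must agree on
    ## both model fits and hence the LRT
    size <- 1 / got$dispersion
    full <- oracle_nb_fit(y, offs, cond, shared = FALSE, fixed_size = size)
    red <- oracle_nb_fit(y, offs, cond, shared = TRUE, fixed_size = size)
    lrt_oracle <- max(0, 2 * (full$loglik - red$loglik))
    expect_lt(abs(got$lrt_stat - lrt_oracle), 0.02 * max(1, lrt_oracle))
    ln_fc_oracle <- full$beta[2] - full$beta[1]
    expect_lt(abs(got$log2_fc * log(2) - ln_fc_oracle), 0.01)
    ## and the engine's profiled dispersion is in the vicinity of the
    ## joint-MLE dispersion
    joint <- oracle_nb_fit(y, offs, cond, shared = FALSE)
    expect_lt(abs(log(got$dispersion / max(joint$phi, 1e-4))), log(3))
  }
})

test_that("natural-log contrasts are reported in log2", {
  ## a 2-fold effect on a 30% minority of a mostly-null library lands near
  ## log2_fc = 1 (i.e. ln 0.693 / ln 2) for the affected promoters
  cfg <- sim_config(n_promoters = 60, n_barcodes = 40, dna_depth = 150,
                    rna_depth = 150, responsive_fraction = 0.3,
                    effect_size = 2)
  sim <- simulate_screen_counts(cfg, seed = 6)
  fit <- mpra_diff_test(sim$counts, sim$samples, sim$dictionary,
                        conditions = c("control", "treated"))
  res <- dplyr::inner_join(tidy(fit), sim$truth$promoters,
                           by = "promoter_id")
  expect_lt(abs(median(res$log2_fc[res$responsive]) - 1), 0.1)
  expect_lt(abs(median(res$log2_fc[!res$responsive])), 0.1)
  expect_equal(res$df[1], 1L)
  expect_equal(res$p_value, pchisq(res$lrt_stat, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("relabeling conditions flips the fold change and keeps the statistic", {
  sim <- diff_fixture(n_prom = 25, n_bc = 30, seed = 9, effect = 1.5)
  f1 <- mpra_diff_test(sim$counts, sim$samples, sim$dictionary,
                       conditions = c("control", "treated"))
  f2 <- mpra_diff_test(sim$counts, sim$samples, sim$dictionary,
                       conditions = c("treated", "control"))
  r1 <- tidy(f1); r2 <- tidy(f2)
  expect_equal(r1$lrt_stat, r2$lrt_stat, tolerance = 1e-6)
  expect_equal(r1$log2_fc, -r2$log2_fc, tolerance = 1e-6)
})

test_that("a common factor in all depth factors leaves the test invariant", {
  sim <- diff_fixture(n_prom = 20, n_bc = 25, seed = 12)
  base <- upper_quartile_factors(sim$counts)
  f1 <- mpra_diff_test(sim$counts, sim$samples, sim$dictionary,
                       conditions = c("control", "treated"),
                       depth_factors = base)
  scaled <- dplyr::mutate(base, depth_factor = .data$depth_factor * 3.7)
  f2 <- mpra_diff_test(sim$counts, sim$samples, sim$dictionary,
                       conditions = c("control", "treated"),
                       depth_factors = scaled)
  expect_equal(tidy(f1)$lrt_stat, tidy(f2)$lrt_stat, tolerance = 1e-6)
})

test_that("promoters with no RNA signal are flagged, not tested", {
  sim <- diff_fixture(n_prom = 5, n_bc = 10, seed = 3)
  rna_ids <- sim$samples$sample_id[sim$samples$material == "RNA"]
  dead <- sim$truth$promoters$promoter_id[1]
  dead_bcs <- sim$dictionary$barcode[sim$dictionary$promoter_id == dead]
  counts <- sim$counts[!(sim$counts$barcode %in% dead_bcs &
                           sim$counts$sample_id %in% rna_ids), ]
  fit <- mpra_diff_test(counts, sim$samples, sim$dictionary,
                        conditions = c("control", "treated"))
  res <- tidy(fit)
  row <- res[res$promoter_id == dead, ]
  expect_equal(row$flag, "all_zero_rna")
  expect_equal(row$p_value, 1)
  expect_true(is.na(row$log2_fc))
})

test_that("tidy and glance summarize the fit object", {
  sim <- diff_fixture(n_prom = 6, n_bc = 15, seed = 8)
  fit <- mpra_diff_test(sim$counts, sim$samples, sim$dictionary,
                        conditions = c("control", "treated"))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("promoter_id", "log2_fc", "lrt_stat", "df", "p_value",
                    "fdr", "n_barcodes_used", "flag") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_promoters, 6)
  expect_s3_class(plot_volcano(fit), "ggplot")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_diff_results(fit, path)
  expect_equal(nrow(readr::read_tsv(path, show_col_types = FALSE)), 6)
})

test_that("the engine cross-checks against glm.nb on a single promoter", {
  skip_if_not_installed("MASS")
  sim <- diff_fixture(n_prom = 1, n_bc = 60, seed = 15, effect = 1.8,
                      depth = 100)
  fit <- mpra_diff_test(sim$counts, sim$samples, sim$dictionary,
                        conditions = c("control", "treated"),
                        recenter = FALSE)
  res <- tidy(fit)

  samples <- sim$samples
  dna_ids <- samples$sample_id[samples$material == "DNA"]
  rna <- samples[samples$material == "RNA", ]
  wide <- tidyr::pivot_wider(sim$counts, names_from = "sample_id",
                             values_from = "count", values_fill = 0L)
  dfac <- fit$depth_factors
  d_b <- rowMeans(sweep(as.matrix(wide[dna_ids]), 2,
                        dfac$depth_factor[match(dna_ids, dfac$sample_id)], "/"))
  keep <- d_b > 0
  long <- tibble::tibble(
    y = as.numeric(as.matrix(wide[rna$sample_id])[keep, ]),
    off = log(as.numeric(d_b[keep] %o%
                           dfac$depth_factor[match(rna$sample_id,
                                                   dfac$sample_id)])),
    condition = factor(rep(rna$condition, each = sum(keep)),
                       levels = c("control", "treated"))
  )
  gm <- MASS::glm.nb(y ~ condition + offset(off), data = long)
  ln_fc_ref <- unname(coef(gm)["conditiontreated"])
  expect_lt(abs(res$log2_fc * log(2) - ln_fc_ref), 0.03)
})
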