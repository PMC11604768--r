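test_that("rpm scales each sample to one million and is scale invariant", {
  m <- matrix(c(1, 1, 2), 3, 1, dimnames = list(paste0("b", 1:3), "s1"))
  out <- rpm(toy_counts(m))
  expect_equal(out$rpm, c(250000, 250000, 500000))

  set.seed(5)
  m <- matrix(rpois(60, 40) + 1, 12, 5,
              dimnames = list(paste0("b", 1:12), paste0("s", 1:5)))
  out <- rpm(toy_counts(m))
  sums <- tapply(out$rpm, out$sample_id, sum)
  expect_equal(unname(sums), rep(1e6, 5), ignore_attr = TRUE)

  doubled <- toy_counts(m)
  doubled$count[doubled$sample_id == "s2"] <-
    doubled$count[doubled$sample_id == "s2"] * 2L
  out2 <- rpm(doubled)
  expect_equal(out2$rpm[out2$sample_id == "s2"],
               out$rpm[out$sample_id == "s2"])

  zero <- tibble::tibble(barcode = "b", sample_id = "dead", count = 0L)
  expect_error(rpm(zero), "dead")
})

quant_fixture <- function() {
  dict <- tibble::tibble(barcode = paste0("b", 1:4),
                         promoter_id = c("P1", "P1", "P2", "P2"))
  samples <- tibble::tibble(
    sample_id = c("dna", "rna1"),
    material = c("DNA", "RNA"),
    condition = c("input", "ctrl"),
    batch = "r1"
  )
  list(dict = dict, samples = samples)
}

test_that("aggregate ratios divide promoter RNA RPM sums by DNA RPM sums", {
  fx <- quant_fixture()
  ## equal RNA and DNA columns -> ratio 1 everywhere
  m <- matrix(c(5, 10, 15, 20, 5, 10, 15, 20), 4, 2,
              dimnames = list(paste0("b", 1:4), c("dna", "rna1")))
  out <- aggregate_ratio(toy_counts(m), fx$samples, fx$dict)
  expect_equal(out$ratio, c(1, 1))

  ## hand arithmetic: P1 RNA {10,30} vs DNA {20,20} with equal totals
  m2 <- matrix(c(20, 20, 30, 30, 10, 30, 30, 30), 4, 2,
               dimnames = list(paste0("b", 1:4), c("dna", "rna1")))
  out2 <- aggregate_ratio(toy_counts(m2), fx$samples, fx$dict)
  expect_equal(out2$ratio[out2$promoter_id == "P1"], 1)

  ## zero DNA for P2 -> undefined, flagged
  m3 <- matrix(c(20, 20, 0, 0, 10, 30, 5, 5), 4, 2,
               dimnames = list(paste0("b", 1:4), c("dna", "rna1")))
  out3 <- aggregate_ratio(toy_counts(m3), fx$samples, fx$dict)
  expect_true(out3$undefined[out3$promoter_id == "P2"])
  expect_true(is.na(out3$ratio[out3$promoter_id == "P2"]))
})

test_that("aggregate ratios ignore per-sample scaling and respond only to their promoter", {
  fx <- quant_fixture()
  set.seed(11)
  m <- matrix(rpois(8, 50) + 1, 4, 2,
              dimnames = list(paste0("b", 1:4), c("dna", "rna1")))
  base <- aggregate_ratio(toy_counts(m), fx$samples, fx$dict)
  m_scaled <- m
  m_scaled[, "rna1"] <- m_scaled[, "rna1"] * 7L
  scaled <- aggregate_ratio(toy_counts(m_scaled), fx$samples, fx$dict)
  expect_equal(scaled$ratio, base$ratio)

  ## raising one RNA count of P1 raises only P1's ratio
  m_up <- m
  m_up["b1", "rna1"] <- m_up["b1", "rna1"] + 25L
  up <- aggregate_ratio(toy_counts(m_up), fx$samples, fx$dict)
  expect_gt(up$ratio[up$promoter_id == "P1"],
            base$ratio[base$promoter_id == "P1"])
  ## P2's RPM share drops with the larger column total, but its RNA/DNA
  ## ratio uses the same normalization on both sides of P1's change
  expect_lt(abs(up$ratio[up$promoter_id == "P2"] /
                  base$ratio[base$promoter_id == "P2"] - 1), 0.2)
})

test_that("estimated rates recover simulated ground truth (Spearman >= 0.95)", {
  cfg <- sim_config(n_promoters = 200, n_barcodes = 20, dna_depth = 100,
                    rna_depth = 100, rate_fold_range = 300,
                    nb_dispersion = 0.2)
  sim <- simulate_screen_counts(cfg, seed = 7)
  rates <- aggregate_ratio(sim$counts, sim$samples, sim$dictionary)
  ctrl <- rates[rates$condition == "control", ]
  per_prom <- tapply(ctrl$ratio, ctrl$promoter_id, mean)
  truth <- sim$truth$promoters
  rho <- cor(per_prom[truth$promoter_id], truth$rate, method = "spearman",
             use = "complete.obs")
  expect_gte(rho, 0.95)
})

test_that("barcode fold changes are ratios of arm medians", {
  ## column totals all equal 10, so RPM preserves the raw proportions;
  ## b1 medians: treated [2,4,6] vs control [1,2,3] -> 4/2 = 2
  m <- matrix(c(1, 9, 2, 8, 3, 7,
                2, 8, 4, 6, 6, 4),
              2, 6, dimnames = list(c("b1", "b2"),
                                    c("c1", "c2", "c3", "t1", "t2", "t3")))
  fc <- barcode_fold_changes(toy_counts(m), treated = c("t1", "t2", "t3"),
                             control = c("c1", "c2", "c3"))
  expect_equal(fc$fold_change[fc$barcode == "b1"], 2)
  expect_equal(fc$fold_change[fc$barcode == "b2"], 0.75)
})

test_that("identical arms give fold change one; zero control medians flag undefined", {
  m <- matrix(c(5, 9, 5, 9), 2, 2,
              dimnames = list(c("b1", "b2"), c("c1", "t1")))
  fc <- barcode_fold_changes(toy_counts(m), treated = "t1", control = "c1")
  expect_equal(fc$fold_change, c(1, 1))

  m2 <- matrix(c(0, 9, 4, 9), 2, 2,
               dimnames = list(c("b1", "b2"), c("c1", "t1")))
  fc2 <- barcode_fold_changes(toy_counts(m2), treated = "t1", control = "c1")
  expect_true(fc2$undefined[1])
  expect_true(is.na(fc2$fold_change[1]))
})

test_that("upper-quartile depth factors use interpolated quartiles of nonzero counts", {
  counts <- dplyr::bind_rows(
    tibble::tibble(barcode = paste0("b", 1:50), sample_id = "ref",
                   count = 1:50),
    tibble::tibble(barcode = paste0("b", 1:100), sample_id = "s2",
                   count = 1:100),
    tibble::tibble(barcode = paste0("b", 1:50), sample_id = "s3",
                   count = 2L * (1:50))
  )
  f <- upper_quartile_factors(counts, reference = "ref")
  expect_equal(f$depth_factor[f$sample_id == "ref"], 1)
  expect_equal(f$depth_factor[f$sample_id == "s2"], 75.25 / 37.75)
  expect_equal(f$depth_factor[f$sample_id == "s3"], 2)

  dead <- tibble::tibble(barcode = "b", sample_id = "x", count = 0L)
  expect_error(upper_quartile_factors(dead), "nonzero")
})

test_that("profile summaries cluster with complete linkage and project rank-2 structure", {
  ## two identical columns merge at height zero
  m <- cbind(a = c(1, 5, 9, 2), b = c(1, 5, 9, 2), c = c(9, 1, 2, 8))
  rownames(m) <- paste0("p", 1:4)
  pr <- suppressWarnings(profile_summaries(m))
  merged_first <- pr$col_hclust$height[1]
  expect_equal(merged_first, 0)

  ## rank-1 matrix: second singular value ~ 0 after standardization
  r1 <- outer(c(1, 2, 3, 4, 6), c(1, 2, 4))
  rownames(r1) <- paste0("p", 1:5); colnames(r1) <- paste0("s", 1:3)
  pr1 <- profile_summaries(r1)
  expect_lt(pr1$d[2] / pr1$d[1], 1e-8)

  ## block structure separates as in an independent linkage computation
  set.seed(3)
  blocks <- rbind(matrix(rnorm(20, 0), 4, 5), matrix(rnorm(20, 8), 4, 5))
  rownames(blocks) <- paste0("p", 1:8); colnames(blocks) <- paste0("s", 1:5)
  pr2 <- profile_summaries(blocks)
  ref <- stats::cutree(stats::hclust(stats::dist(blocks), "complete"), 2)
  got <- stats::cutree(pr2$row_hclust, 2)
  expect_equal(got, ref)
  expect_equal(length(pr2$row_order), 8)

  ## constant column dropped with a warning before the biplot
  mc <- cbind(a = c(1, 5, 9, 2), b = rep(3, 4), c = c(9, 1, 2, 8))
  rownames(mc) <- paste0("p", 1:4)
  expect_warning(prc <- profile_summaries(mc), "constant")
  expect_equal(nrow(prc$loadings), 2)
})
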