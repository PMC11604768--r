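pwm_for <- function(seed, weights = NULL) {
  L <- nchar(seed)
  m <- matrix(0.25, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (w in weights) m[w$pos, ] <- w$row
  m
}

seed_tbl <- function(tf, seed, pwm) {
  tibble::tibble(tf_name = tf, species = "synthetic", seed = seed,
                 pwm = list(pwm))
}

test_that("flanking Ns are trimmed and degenerate positions resolved by pwm argmax", {
  out <- resolve_seeds(seed_tbl("a", "NNCACGTGNN", pwm_for("NNCACGTGNN")))
  expect_equal(out$sequence, "CACGTG")

  pwm <- pwm_for("CAWAAAC", list(list(pos = 3, row = c(0.7, 0, 0, 0.3))))
  out <- resolve_seeds(seed_tbl("b", "CAWAAAC", pwm))
  expect_equal(out$sequence, "CAAAAAC")

  ## positions 1 and 3 are N (trimmed); position 2 is R with A dominant
  pwm <- matrix(c(0.25, 0.25, 0.25, 0.25,
                  0.6, 0, 0.4, 0,
                  0.9, 0.033, 0.033, 0.034), 3, 4, byrow = TRUE)
  out <- resolve_seeds(seed_tbl("c", "NRN", pwm))
  expect_equal(out$sequence, oracle_resolve("NRN", pwm))
  expect_equal(out$sequence, "A")
})

test_that("seed resolution errors on all-N seeds and all-zero pwm rows", {
  expect_error(resolve_seeds(seed_tbl("x", "NNNN", pwm_for("NNNN"))),
               "empty motif")
  pwm <- pwm_for("ACRT", list(list(pos = 3, row = c(0, 0, 0, 0))))
  pwm[3, ] <- 0
  expect_error(resolve_seeds(seed_tbl("x", "ACRT", pwm)), "position 3")
})

test_that("resolution matches the independent oracle on random IUPAC seeds", {
  set.seed(41)
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N")
  for (i in 1:40) {
    core <- paste(sample(codes, sample(4:12, 1), replace = TRUE),
                  collapse = "")
    seed <- paste0(strrep("N", sample(0:3, 1)), core,
                   strrep("N", sample(0:3, 1)))
    pwm <- matrix(runif(4 * nchar(seed)), ncol = 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
    expected <- tryCatch(oracle_resolve(seed, pwm), error = function(e) NULL)
    if (is.null(expected)) next
    got <- resolve_seeds(seed_tbl("tf", seed, pwm))$sequence
    expect_equal(got, expected, info = seed)
    ## trimmed length bookkeeping
    n_flank <- nchar(seed) - nchar(sub("N+$", "", sub("^N+", "", seed)))
    expect_equal(nchar(got), nchar(seed) - n_flank)
  }
})

test_that("motifs contained in other motifs are removed, first-wins on duplicates", {
  m <- tibble::tibble(motif_id = c("a", "b"), tf_name = c("a", "b"),
                      sequence = c("CAAAAAC", "AAAAA"),
                      provenance = "experimental")
  expect_equal(dedup_motifs(m)$sequence, "CAAAAAC")

  m <- tibble::tibble(motif_id = c("a", "b"), sequence = c("ACGT", "ACGT"))
  out <- dedup_motifs(m)
  expect_equal(nrow(out), 1)
  expect_equal(out$motif_id, "a")

  m <- tibble::tibble(motif_id = letters[1:3],
                      sequence = c("AAAA", "AAAAA", "AAAAAA"))
  expect_equal(dedup_motifs(m)$sequence, "AAAAAA")
})

test_that("deduplication equals the brute-force filter and is idempotent", {
  set.seed(7)
  for (n in c(40, 500)) {
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C"), sample(4:9, 1), replace = TRUE),
            collapse = "")
    }, character(1))
    m <- tibble::tibble(motif_id = as.character(seq_len(n)), sequence = seqs)
    out <- dedup_motifs(m)
    expect_equal(out$sequence, oracle_dedup(seqs))
    expect_equal(dedup_motifs(out), out)
  }
})

test_that("scrambled controls conserve composition, differ, and are reproducible", {
  m <- tibble::tibble(motif_id = "m1", tf_name = "tf1", sequence = "ACGTTGCA",
                      provenance = "experimental")
  s1 <- scramble_motifs(m, n = 1, seed = 1)
  s2 <- scramble_motifs(m, n = 1, seed = 1)
  expect_equal(s1$sequence, s2$sequence)
  expect_false(s1$sequence == m$sequence)
  expect_equal(sort(strsplit(s1$sequence, "")[[1]]),
               sort(strsplit(m$sequence, "")[[1]]))
  expect_equal(s1$provenance, "negative_control")

  homo <- tibble::tibble(motif_id = "h", tf_name = "h", sequence = "AAAA",
                         provenance = "experimental")
  w <- testthat::capture_warnings(out <- scramble_motifs(homo, n = 1, seed = 1))
  expect_true(any(grepl("homopolymer", w)))
  expect_equal(nrow(out), 0)
})

test_that("catalog pipeline recovers planted motifs and never exceeds seed count", {
  sim <- simulate_catalog(30, seed = 9, n_containments = 5)
  catalog <- build_motif_catalog(sim$seeds)
  expect_setequal(catalog$sequence, sim$expected$sequence)
  expect_lte(nrow(catalog), nrow(sim$seeds))
  expect_true(all(catalog$provenance == "experimental"))

  with_controls <- build_motif_catalog(sim$seeds, n_controls = 10, seed = 2)
  expect_equal(sum(with_controls$provenance == "negative_control"), 10)
})

test_that("seed tables and motif catalogs round-trip through TSV", {
  sim <- simulate_catalog(6, seed = 12)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_seed_table(sim$seeds, path)
  back <- read_seed_table(path)
  expect_equal(back$seed, sim$seeds$seed)
  expect_equal(back$pwm[[3]], unname(sim$seeds$pwm[[3]]), ignore_attr = TRUE)

  catalog <- build_motif_catalog(sim$seeds)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_motif_catalog(catalog, path2)
  expect_equal(read_motif_catalog(path2)$sequence, catalog$sequence)
})
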