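## Synthetic-data generator: ground-truth libraries, dictionary reads,
## sample reads and count matrices with the statistical structure the
## analysis assumes, so every pipeline stage is testable at desk scale.

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a barcoded plasmid screen:
#' per-promoter barcode representation is log-normal calibrated to a mean
#' of about 82 and a median of about 65 barcodes; baseline transcription
#' rates are log-uniform over a 300-fold span; counts are negative binomial
#' with dispersion 0.2 around depth x copy-proportion x rate means.
#'
#' @param n_promoters Number of synthetic promoters.
#' @param n_barcodes Fixed barcodes per promoter; overrides the log-normal
#'   draw when not `NULL`.
#' @param barcode_meanlog,barcode_sdlog Log-normal parameters of the
#'   per-promoter barcode count (defaults target median 65, mean 82).
#' @param dna_depth,rna_depth Mean reads per barcode in DNA / RNA samples.
#' @param nb_dispersion Negative-binomial dispersion of counts.
#' @param dirichlet_concentration Concentration of the within-promoter
#'   Dirichlet copy proportions. The default 1 (flat) gives the skewed
#'   barcode representation of a real plasmid pool; `Inf` gives equal
#'   proportions, so every barcode's count is NB with mean exactly
#'   `dna_depth` (or `rna_depth` x rate).
#' @param rate_fold_range Fold span of the log-uniform baseline rates.
#' @param responsive_fraction Fraction of promoters given a condition
#'   effect.
#' @param effect_size Multiplicative fold change applied to responsive
#'   promoters in the treated arm.
#' @param conditions Condition labels; the first is the control arm.
#' @param n_rna_reps RNA replicates per condition.
#' @param n_dna_reps DNA (plasmid input) replicates.
#' @param sample_depth_sd Log-normal sd of per-sample depth wobble.
#' @param substitution_error Per-base substitution rate in emitted read
#'   barcodes (read-level only; must be in `[0, 0.05]`).
#' @param spike_in_fraction Fraction of sample reads drawn from spike-in
#'   references (read-level only).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_promoters = 2000L,
                       n_barcodes = NULL,
                       barcode_meanlog = log(65),
                       barcode_sdlog = sqrt(2 * log(82 / 65)),
                       dna_depth = 80,
                       rna_depth = 80,
                       nb_dispersion = 0.2,
                       dirichlet_concentration = 1,
                       rate_fold_range = 300,
                       responsive_fraction = 0,
                       effect_size = 1,
                       conditions = c("control", "treated"),
                       n_rna_reps = 3L,
                       n_dna_reps = 4L,
                       sample_depth_sd = 0.1,
                       substitution_error = 0,
                       spike_in_fraction = 0) {
  stopifnot(n_promoters >= 1, dna_depth > 0, rna_depth > 0,
            nb_dispersion > 0, rate_fold_range >= 1,
            responsive_fraction >= 0, responsive_fraction <= 1,
            effect_size > 0, length(conditions) >= 2,
            substitution_error >= 0, substitution_error <= 0.05,
            spike_in_fraction >= 0, spike_in_fraction < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate PWM seeds with a known expected motif catalog
#'
#' Constructs seeds exercising the catalog pipeline: random ACGT motifs are
#' wrapped in flanking `N` runs and sprinkled with internal degenerate
#' codes whose PWM rows have a known argmax, so the expected resolved
#' motif is the planted one. `n_containments` seeds are planted as strict
#' substrings of another motif and are therefore expected to be removed by
#' deduplication. All planted motifs are compatible with the restriction
#' strategy of `config` (no forbidden site inside the motif, at the fixed
#' 5' flank junction, or across a zero-length-spacer motif junction), so
#' the expected catalog is designable.
#'
#' @param n_seeds Number of seeds.
#' @param seed RNG seed.
#' @param motif_len Range of motif lengths (nt).
#' @param n_containments Number of planted substring-containment pairs.
#' @param config [design_config()] used for designability screening.
#' @return A list with `seeds` (input for [resolve_seeds()]) and
#'   `expected` (the expected post-deduplication catalog).
#' @export
simulate_catalog <- function(n_seeds, seed = 1L, motif_len = c(6L, 20L),
                             n_containments = 0L, config = design_config()) {
  stopifnot(n_seeds >= 1, n_containments >= 0,
            n_containments * 2 <= n_seeds, motif_len[1] >= 4)
  with_seed(str_hash("simulate_catalog", seed), {
    n_base <- n_seeds - n_containments
    motifs <- character(n_base)
    for (i in seq_len(n_base)) {
      repeat {
        m <- random_dna(sample(motif_len[1]:motif_len[2], 1))
        existing <- motifs[motifs != ""]
        clash <- length(existing) > 0 &&
          (any(stringr::str_detect(existing, stringr::fixed(m))) ||
             any(stringr::str_detect(m, stringr::fixed(existing))))
        if (!clash && motif_designable(m, config)) {
          motifs[i] <- m
          break
        }
      }
    }
    ## planted containments: strict substrings of the first base motifs
    contained <- character(n_containments)
    for (j in seq_len(n_containments)) {
      host <- motifs[j]
      repeat {
        L <- sample(4:max(4, nchar(host) - 1), 1)
        start <- sample(nchar(host) - L + 1, 1)
        sub <- substr(host, start, start + L - 1)
        others <- c(motifs[-j], contained[contained != ""])
        if (!any(stringr::str_detect(others, stringr::fixed(sub))) &&
            !any(stringr::str_detect(sub, stringr::fixed(others)))) {
          contained[j] <- sub
          break
        }
      }
    }
    all_motifs <- c(motifs, contained)
    seeds <- purrr::map(seq_along(all_motifs), function(i) {
      degenerate_seed(all_motifs[i], tf_name = sprintf("TF%04d", i))
    })
    seeds <- dplyr::bind_rows(seeds)
    expected <- tibble::tibble(
      motif_id = seeds$tf_name[seq_len(n_base)],
      tf_name = seeds$tf_name[seq_len(n_base)],
      sequence = motifs,
      provenance = "experimental"
    )
    list(seeds = seeds, expected = expected)
  })
}

## wrap a plain motif into an IUPAC seed + pwm whose resolution recovers it
degenerate_seed <- function(motif, tf_name) {
  chars <- strsplit(motif, "")[[1]]
  L <- length(chars)
  pwm <- matrix(0, L, 4, dimnames = list(NULL, DNA_BASES))
  seed_chars <- chars
  for (i in seq_len(L)) {
    pwm[i, chars[i]] <- 1
    if (runif(1) < 0.25) {
      ## replace by a degenerate code containing the true base, with the
      ## true base dominant in the pwm row; never N at the motif edges,
      ## where it would extend the flanking-N run and be trimmed
      codes <- names(IUPAC_CODES)[purrr::map_lgl(IUPAC_CODES, function(b) {
        chars[i] %in% b && length(b) > 1
      })]
      if (i == 1L || i == L) codes <- setdiff(codes, "N")
      code <- sample(codes, 1)
      seed_chars[i] <- code
      other <- setdiff(IUPAC_CODES[[code]], chars[i])
      pwm[i, chars[i]] <- 0.7
      pwm[i, other] <- 0.3 / length(other)
    }
  }
  n5 <- sample(0:3, 1)
  n3 <- sample(0:3, 1)
  seed <- paste0(strrep("N", n5), paste(seed_chars, collapse = ""),
                 strrep("N", n3))
  pwm_full <- rbind(matrix(0.25, n5, 4), pwm, matrix(0.25, n3, 4))
  colnames(pwm_full) <- DNA_BASES
  tibble::tibble(tf_name = tf_name, species = "synthetic", seed = seed,
                 pwm = list(pwm_full))
}

#' Can this motif be built into a clean TRE unit?
#'
#' Checks the fixed-fixed junctions a redraw cannot repair: the motif
#' itself, the 5'-flank/motif junction, and (when the phasing spacer has
#' length zero) the motif/motif junction.
#'
#' @param motif Plain ACGT motif sequence.
#' @param config A [design_config()].
#' @return Logical scalar.
#' @export
motif_designable <- function(motif, config = design_config()) {
  sites <- config$forbidden_sites
  if (any(vapply(sites, grepl, logical(1), x = motif, fixed = TRUE))) {
    return(FALSE)
  }
  tail5 <- substr(config$flank_5p, nchar(config$flank_5p) - 4L,
                  nchar(config$flank_5p))
  junction <- paste0(tail5, substr(motif, 1, 5))
  if (any(vapply(sites, grepl, logical(1), x = junction, fixed = TRUE))) {
    return(FALSE)
  }
  if (phasing_spacer_length(nchar(motif), config) == 0) {
    doubled <- paste0(motif, motif)
    if (any(vapply(sites, grepl, logical(1), x = doubled, fixed = TRUE))) {
      return(FALSE)
    }
  }
  TRUE
}

#' Simulate a reporter screen (counts level)
#'
#' Draws a ground-truth library and DNA/RNA count matrices: barcodes per
#' promoter from the configured log-normal (or fixed `n_barcodes`),
#' within-promoter plasmid copy proportions from a flat Dirichlet, DNA
#' counts `NB(mean = dna_depth x n_b x proportion x sample factor,
#' dispersion)`, and RNA counts with the mean additionally multiplied by
#' the promoter's baseline rate (log-uniform over `rate_fold_range`,
#' rescaled so the library-average RNA depth matches `rna_depth`) and its
#' condition effect. A `responsive_fraction` of promoters receives the
#' multiplicative `effect_size` in every non-control arm.
#'
#' @param config A [sim_config()].
#' @param seed Integer RNG seed; same seed, same output.
#' @return A list with `counts` (long tibble: `barcode`, `sample_id`,
#'   `count`), `samples` (metadata), `dictionary` (barcode -> promoter) and
#'   `truth` (list of `promoters` and `barcodes` ground-truth tibbles).
#' @export
simulate_screen_counts <- function(config = sim_config(), seed = 1L) {
  with_seed(str_hash("simulate_screen", seed), {
    P <- config$n_promoters
    n_b <- if (!is.null(config$n_barcodes)) {
      rep(as.integer(config$n_barcodes), P)
    } else {
      pmax(1L, as.integer(round(rlnorm(P, config$barcode_meanlog,
                                       config$barcode_sdlog))))
    }
    promoter_id <- sprintf("prom_%05d", seq_len(P))
    rate <- exp(runif(P, 0, log(config$rate_fold_range)))
    n_resp <- round(config$responsive_fraction * P)
    responsive <- seq_len(P) %in% sample.int(P, n_resp)

    conds <- config$conditions
    K <- length(conds)
    effects <- matrix(1, P, K, dimnames = list(promoter_id, conds))
    effects[responsive, -1] <- config$effect_size

    B <- sum(n_b)
    pid <- rep(seq_len(P), n_b)
    barcode <- sprintf("bc_%07d", seq_len(B))
    ## Dirichlet copy proportions within each promoter
    if (is.finite(config$dirichlet_concentration)) {
      g <- stats::rgamma(B, shape = config$dirichlet_concentration)
      prop <- g / rep(rowsum(g, pid)[, 1], n_b)
    } else {
      prop <- 1 / n_b[pid]
    }

    samples <- dplyr::bind_rows(
      tibble::tibble(sample_id = sprintf("dna_%d", seq_len(config$n_dna_reps)),
                     material = "DNA", condition = "input",
                     batch = sprintf("prep%d", seq_len(config$n_dna_reps))),
      tidyr::expand_grid(condition = conds, rep = seq_len(config$n_rna_reps)) |>
        dplyr::mutate(sample_id = sprintf("rna_%s_%d", .data$condition, .data$rep),
                      material = "RNA", batch = sprintf("rep%d", .data$rep)) |>
        dplyr::select("sample_id", "material", "condition", "batch")
    )
    sdf <- rlnorm(nrow(samples), 0, config$sample_depth_sd)
    names(sdf) <- samples$sample_id

    size <- 1 / config$nb_dispersion
    base_mu <- n_b[pid] * prop  # expected copies, mean 1 per barcode
    rate_scale <- sum(rate[pid] * base_mu) / B

    cols <- purrr::map(seq_len(nrow(samples)), function(j) {
      s <- samples[j, ]
      mu <- if (s$material == "DNA") {
        config$dna_depth * base_mu * sdf[s$sample_id]
      } else {
        k <- match(s$condition, conds)
        config$rna_depth * base_mu * (rate[pid] * effects[pid, k] / rate_scale) *
          sdf[s$sample_id]
      }
      rnbinom(B, mu = mu, size = size)
    })
    counts_mat <- do.call(cbind, cols)
    colnames(counts_mat) <- samples$sample_id

    counts <- tibble::tibble(
      barcode = rep(barcode, nrow(samples)),
      sample_id = rep(samples$sample_id, each = B),
      count = as.integer(counts_mat)
    )
    counts <- counts[counts$count > 0, , drop = FALSE]

    dictionary <- tibble::tibble(barcode = barcode,
                                 promoter_id = promoter_id[pid])
    truth <- list(
      promoters = tibble::tibble(promoter_id = promoter_id, rate = rate,
                                 responsive = responsive,
                                 effect = effects[, K],
                                 n_barcodes = n_b),
      barcodes = tibble::tibble(barcode = barcode,
                                promoter_id = promoter_id[pid],
                                copy_proportion = prop)
    )
    list(counts = counts, samples = samples, dictionary = dictionary,
         truth = truth, seed = seed)
  })
}

#' Simulate a reporter screen down to reads (FASTQ level)
#'
#' Builds a tiny library of real 24-nt barcodes (mutually >= 3 edits apart,
#' so radius-1 sphere clustering is identifiable), emits error-free or
#' error-bearing dictionary read pairs (unit core + barcode read) and
#' per-sample single-end barcode reads with per-base substitution rate
#' `config$substitution_error` in the barcode, plus spike-in reads at
#' `config$spike_in_fraction`. Counts are drawn as in
#' [simulate_screen_counts()] and each read is emitted `count` times, so
#' the read files and the returned count tables agree by construction.
#'
#' @param units Units tibble from [design_library()]; promoters are its
#'   units crossed with one minimal-promoter pool per DNA replicate.
#' @param config A [sim_config()] (use a small `n_barcodes`).
#' @param seed Integer RNG seed.
#' @param design [design_config()] matching `units`.
#' @param out_dir Optional directory; when given, FASTQ/TSV/JSON artifacts
#'   are written there.
#' @param dict_reads_per_barcode Dictionary read pairs emitted per barcode.
#' @param read_length Length of emitted sample reads (barcode + filler).
#' @return As [simulate_screen_counts()], plus `dict_pairs`, `reads` (named
#'   list of per-sample read vectors), `spike_ins`, `pools`, and `layout`.
#' @export
simulate_screen_reads <- function(units, config = sim_config(),
                                  seed = 1L, design = design_config(),
                                  out_dir = NULL,
                                  dict_reads_per_barcode = 3L,
                                  read_length = 40L) {
  pool_min <- MIN_PROMOTERS[1]  # one minimal-promoter pool for compactness
  promoter_id <- paste(units$unit_id, pool_min, sep = "|")
  P <- length(promoter_id)
  cfg <- config
  cfg$n_promoters <- P
  sim <- simulate_screen_counts(cfg, seed)
  ## rename simulated promoters to the real library's promoter ids
  remap <- setNames(promoter_id, sprintf("prom_%05d", seq_len(P)))
  sim$dictionary$promoter_id <- unname(remap[sim$dictionary$promoter_id])
  sim$truth$promoters$promoter_id <- unname(remap[sim$truth$promoters$promoter_id])
  sim$truth$barcodes$promoter_id <- unname(remap[sim$truth$barcodes$promoter_id])

  with_seed(str_hash("simulate_reads", seed), {
    B <- nrow(sim$dictionary)
    bc_seq <- separated_barcodes(B, min_dist = 3L)
    bc_map <- setNames(bc_seq, sim$dictionary$barcode)
    sim$dictionary$barcode <- bc_seq
    sim$truth$barcodes$barcode <- bc_seq
    sim$counts$barcode <- unname(bc_map[sim$counts$barcode])

    cores <- unit_cores(units, design)
    unit_of_bc <- units$unit_id[
      match(sub("\\|[^|]+$", "", sim$dictionary$promoter_id), units$unit_id)]
    sim$dictionary$unit_id <- unit_of_bc
    sim$dictionary$min_promoter <- pool_min

    mutate_reads <- function(x, rate) {
      if (rate <= 0) return(x)
      chars <- strsplit(x, "")
      vapply(chars, function(cc) {
        hit <- runif(length(cc)) < rate
        if (any(hit)) {
          cc[hit] <- vapply(cc[hit], function(b) {
            sample(setdiff(DNA_BASES, b), 1)
          }, character(1))
        }
        paste(cc, collapse = "")
      }, character(1))
    }

    ## dictionary read pairs
    dict_pairs <- tibble::tibble(
      unit_read = mutate_reads(
        rep(unname(cores[unit_of_bc]), each = dict_reads_per_barcode),
        config$substitution_error),
      barcode_read = mutate_reads(
        rep(bc_seq, each = dict_reads_per_barcode),
        config$substitution_error),
      pool_id = "pool1"
    )
    pools <- tibble::tibble(pool_id = "pool1", min_promoter = pool_min)

    spike_ins <- setNames(
      vapply(seq_len(4), function(i) random_dna(read_length), character(1)),
      paste0("spike_", 1:4))

    filler <- strrep("A", max(0, read_length - BARCODE_LEN))
    reads <- purrr::map(unique(sim$counts$sample_id), function(s) {
      cs <- sim$counts[sim$counts$sample_id == s, ]
      tre <- rep(cs$barcode, cs$count)
      tre <- paste0(mutate_reads(tre, config$substitution_error), filler)
      n_spike <- if (config$spike_in_fraction > 0) {
        rnbinom(1, mu = length(tre) * config$spike_in_fraction /
                  (1 - config$spike_in_fraction), size = 1e6)
      } else 0L
      c(tre, sample(spike_ins, n_spike, replace = TRUE))
    })
    names(reads) <- unique(sim$counts$sample_id)

    layout <- list(barcode_start = 1L, barcode_length = BARCODE_LEN,
                   unit_read = "core between flanks",
                   flank_5p_length = nchar(design$flank_5p),
                   flank_3p_length = nchar(design$flank_3p),
                   seed = seed)

    out <- c(sim, list(dict_pairs = dict_pairs, pools = pools,
                       spike_ins = spike_ins, reads = reads, layout = layout))
    if (!is.null(out_dir)) write_simulation(out, units, out_dir)
    out
  })
}

## random 24-mers, greedily filtered to pairwise Levenshtein distance >= 3
separated_barcodes <- function(n, min_dist = 3L, batch = 256L) {
  if (n > 20000) abort("too many barcodes requested for distance-3 separation")
  acc <- character(0)
  guard <- 0L
  while (length(acc) < n) {
    guard <- guard + 1L
    if (guard > 200L) abort("cannot generate enough separated barcodes")
    cand <- unique(vapply(seq_len(batch), function(i) random_dna(BARCODE_LEN),
                          character(1)))
    for (x in cand) {
      if (length(acc) == 0 || min(adist(x, acc)) >= min_dist) {
        acc <- c(acc, x)
        if (length(acc) == n) break
      }
    }
  }
  acc
}

## serialize a read-level simulation: FASTQ, TSV and JSON artifacts
write_simulation <- function(sim, units, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_unit_fasta(units, file.path(out_dir, "units.fasta"))
  write_fastq(sim$dict_pairs$unit_read, file.path(out_dir, "dict_R1.fastq"),
              prefix = "dict")
  write_fastq(sim$dict_pairs$barcode_read, file.path(out_dir, "dict_R2.fastq"),
              prefix = "dict")
  for (s in names(sim$reads)) {
    write_fastq(sim$reads[[s]], file.path(out_dir, paste0(s, ".fastq")),
                prefix = s)
  }
  readr::write_tsv(sim$pools, file.path(out_dir, "pools.tsv"))
  readr::write_tsv(sim$counts, file.path(out_dir, "counts.tsv"))
  readr::write_tsv(sim$samples, file.path(out_dir, "samples.tsv"))
  readr::write_tsv(sim$dictionary, file.path(out_dir, "truth_dictionary.tsv"))
  readr::write_tsv(sim$truth$promoters, file.path(out_dir, "truth_promoters.tsv"))
  readr::write_tsv(sim$truth$barcodes, file.path(out_dir, "truth_barcodes.tsv"))
  spikes <- Biostrings::DNAStringSet(sim$spike_ins)
  Biostrings::writeXStringSet(spikes, file.path(out_dir, "spike_ins.fasta"))
  jsonlite::write_json(sim$layout, file.path(out_dir, "layout.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

#' Write reads as FASTQ
#' @param reads Character vector of read sequences.
#' @param path Output file.
#' @param prefix Read-name prefix.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, prefix = "read") {
  x <- Biostrings::DNAStringSet(setNames(reads,
                                         sprintf("%s_%06d", prefix,
                                                 seq_along(reads))))
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}
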