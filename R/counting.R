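## Sample barcode counting: extract 24-nt barcodes from reads, collapse
## them by greedy sphere clustering at Levenshtein radius 1 (the contract of
## starcode -s), retain clusters consistent with the dictionary, and track
## spike-in reads for per-sample QC.

#' Extract barcodes and spike-in tallies from sample reads
#'
#' The barcode is the first 24 nt of each read. Reads whose first 24 nt
#' exactly match the 24-nt prefix of a spike-in reference are tallied
#' separately (spike-ins are designed distinct, so an exact prefix match
#' suffices and is applied before clustering). Reads shorter than 24 nt or
#' with a non-ACGT character in the first 24 nt are counted as dropped.
#'
#' @param reads A FASTQ file path or a character vector of read sequences.
#' @param spike_ins Optional character vector of spike-in reference
#'   sequences (>= 24 nt), named or not.
#' @param sample_id Sample label attached to the tally.
#' @return A tibble (`sample_id`, `sequence`, `kind`, `count`) where `kind`
#'   is `"barcode"` or `"spike"`; the number of dropped reads is attached
#'   as attribute `"dropped_reads"` and the TRE-read fraction as
#'   `"tre_read_fraction"`.
#' @export
extract_barcodes <- function(reads, spike_ins = NULL, sample_id = "sample") {
  if (length(reads) == 1 && file.exists(reads)) {
    reads <- as.character(Biostrings::readDNAStringSet(reads, format = "fastq"))
  }
  n_total <- length(reads)
  bc <- substr(reads, 1L, BARCODE_LEN)
  ok <- nchar(reads) >= BARCODE_LEN & is_acgt(bc)
  dropped <- n_total - sum(ok)
  bc <- bc[ok]

  spike_prefix <- if (length(spike_ins)) substr(spike_ins, 1L, BARCODE_LEN) else character()
  if (length(spike_prefix) && is.null(names(spike_ins))) {
    names(spike_prefix) <- paste0("spike_", seq_along(spike_prefix))
  } else if (length(spike_prefix)) {
    names(spike_prefix) <- names(spike_ins)
  }
  is_spike <- bc %in% spike_prefix

  tally <- function(x, kind) {
    if (length(x) == 0) {
      return(tibble::tibble(sample_id = character(), sequence = character(),
                            kind = character(), count = integer()))
    }
    tb <- table(x)
    tibble::tibble(sample_id = sample_id, sequence = names(tb),
                   kind = kind, count = as.integer(tb))
  }
  out <- dplyr::bind_rows(tally(bc[!is_spike], "barcode"),
                          tally(bc[is_spike], "spike"))
  n_tre <- sum(!is_spike)
  attr(out, "dropped_reads") <- dropped
  attr(out, "tre_read_fraction") <- if (n_total > 0) n_tre / n_total else NA_real_
  out
}

#' Greedy sphere clustering of barcode tallies
#'
#' Repeatedly selects the highest-count unassigned barcode (ties broken
#' lexicographically) as a centroid and absorbs every unassigned barcode
#' within Levenshtein distance `radius`. Clusters partition the input and
#' the procedure is deterministic. With `radius = 0` every barcode is its
#' own cluster. This reimplements the sphere-clustering (`-s`) contract of
#' starcode.
#'
#' @param tally A tibble with columns `barcode` (or `sequence`) and
#'   `count`; rows with a `kind` column keep only `kind == "barcode"`.
#' @param radius Maximum Levenshtein distance absorbed into a centroid.
#' @return A tibble (`centroid`, `barcode`, `count`), one row per member
#'   barcode (centroids are members of their own cluster).
#' @export
sphere_cluster <- function(tally, radius = 1L) {
  stopifnot(radius >= 0)
  if ("kind" %in% names(tally)) {
    tally <- tally[tally$kind == "barcode", , drop = FALSE]
  }
  if (!"barcode" %in% names(tally) && "sequence" %in% names(tally)) {
    tally$barcode <- tally$sequence
  }
  stopifnot(all(c("barcode", "count") %in% names(tally)))
  if (anyDuplicated(tally$barcode)) abort("duplicate barcodes in tally")
  if (nrow(tally) == 0) {
    return(tibble::tibble(centroid = character(), barcode = character(),
                          count = integer()))
  }
  ord <- order(-tally$count, tally$barcode)
  bc <- tally$barcode[ord]
  ct <- tally$count[ord]
  if (radius == 0) {
    return(tibble::tibble(centroid = bc, barcode = bc, count = ct))
  }
  assigned <- rep(FALSE, length(bc))
  pieces <- list()
  while (!all(assigned)) {
    i <- which(!assigned)[1]
    cand <- which(!assigned)
    d <- adist(bc[i], bc[cand])[1, ]
    members <- cand[d <= radius]
    assigned[members] <- TRUE
    pieces[[length(pieces) + 1L]] <-
      tibble::tibble(centroid = bc[i], barcode = bc[members],
                     count = ct[members])
  }
  dplyr::bind_rows(pieces)
}

#' Retain barcode clusters consistent with the dictionary
#'
#' A cluster is retained if and only if its centroid is a dictionary
#' barcode and every other member that is also in the dictionary maps to
#' the same promoter as the centroid. Each retained cluster contributes the
#' sum of its member counts, keyed by the centroid barcode; all other
#' clusters are discarded.
#'
#' @param clusters Cluster tibble from [sphere_cluster()].
#' @param dictionary Dictionary tibble with `barcode` and `promoter_id`.
#' @param sample_id Optional sample label for the output.
#' @return A tibble (`sample_id`, `barcode`, `promoter_id`, `count`), one
#'   row per retained cluster.
#' @export
retain_clusters <- function(clusters, dictionary, sample_id = NA_character_) {
  map <- setNames(dictionary$promoter_id, dictionary$barcode)
  per <- dplyr::group_by(clusters, .data$centroid)
  per <- dplyr::summarise(
    per,
    total = sum(.data$count),
    centroid_prom = unname(map[.data$centroid[1]]),
    ok = {
      others <- setdiff(.data$barcode, .data$centroid[1])
      in_dict <- others[others %in% names(map)]
      !is.na(unname(map[.data$centroid[1]])) &&
        all(map[in_dict] == unname(map[.data$centroid[1]]))
    },
    .groups = "drop"
  )
  per <- dplyr::filter(per, .data$ok)
  tibble::tibble(sample_id = sample_id, barcode = per$centroid,
                 promoter_id = per$centroid_prom,
                 count = as.integer(per$total))
}

#' Count dictionary barcodes in one sample
#'
#' Convenience wrapper: [extract_barcodes()], [sphere_cluster()],
#' [retain_clusters()], returning accepted counts plus QC metrics.
#'
#' @inheritParams extract_barcodes
#' @param dictionary Dictionary tibble.
#' @param radius Clustering radius (Levenshtein distance).
#' @return A list with `counts` (accepted per-barcode counts),
#'   `spike_in_counts`, and `qc` (a one-row tibble with `sample_id`,
#'   `tre_read_fraction`, `dropped_reads`).
#' @export
count_sample <- function(reads, dictionary, spike_ins = NULL,
                         sample_id = "sample", radius = 1L) {
  tally <- extract_barcodes(reads, spike_ins, sample_id)
  clusters <- sphere_cluster(tally, radius)
  counts <- retain_clusters(clusters, dictionary, sample_id)
  list(
    counts = counts,
    spike_in_counts = tally[tally$kind == "spike", , drop = FALSE],
    qc = tibble::tibble(sample_id = sample_id,
                        tre_read_fraction = attr(tally, "tre_read_fraction"),
                        dropped_reads = attr(tally, "dropped_reads"))
  )
}

#' Flag samples with disproportionately low TRE-read fractions
#'
#' A sample is flagged when its TRE-read fraction falls below
#' `max(rel_mult * cohort median fraction, floor)`. Flag-only: nothing is
#' dropped automatically.
#'
#' @param qc A tibble with columns `sample_id` and `tre_read_fraction`
#'   (one row per cohort sample).
#' @param rel_mult Multiplier on the cohort median (default 0.5).
#' @param floor Absolute floor on the threshold (default 0.5).
#' @return `qc` with `threshold` and logical `flagged` columns added.
#' @export
qc_flag <- function(qc, rel_mult = 0.5, floor = 0.5) {
  stopifnot(nrow(qc) >= 1)
  thr <- max(rel_mult * median(qc$tre_read_fraction), floor)
  dplyr::mutate(qc, threshold = thr,
                flagged = .data$tre_read_fraction < thr)
}

#' Write per-sample accepted counts / QC report TSVs
#' @param x Tibble to write.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_counts_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
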