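## Barcode dictionary: learn the barcode -> promoter map from paired
## dictionary-sequencing reads (one read covering the TRE-unit core, the
## mate carrying the 24-nt barcode), with Levenshtein-<=2 unit matching and
## removal of multi-mapping barcodes.

BARCODE_LEN <- 24L

#' Extract the sequenced core of each unit oligo
#'
#' The dictionary amplicon covers the region between the primer landing
#' sites, i.e. the oligo minus its fixed flanks. For pass-through
#' (commercial) units without a layout, the flank lengths of `config` are
#' trimmed instead.
#'
#' @param units Units tibble from [design_library()].
#' @param config The [design_config()] used for the library.
#' @return A character vector of core sequences named by `unit_id`.
#' @export
unit_cores <- function(units, config = design_config()) {
  n5 <- nchar(config$flank_5p)
  n3 <- nchar(config$flank_3p)
  cores <- substr(units$oligo, n5 + 1L, nchar(units$oligo) - n3)
  setNames(cores, units$unit_id)
}

#' Match observed unit reads against expected unit cores
#'
#' Each observed sequence is assigned to the unique expected unit within
#' Levenshtein distance `max_dist`. If no unit qualifies, or two or more
#' units tie at the minimal qualifying distance, the read is unassigned
#' (`NA`): ambiguity is data, not an error. A strictly nearest unit wins
#' even when others also fall within `max_dist`.
#'
#' @param observed Character vector of observed unit-region sequences.
#' @param cores Named character vector of expected unit cores (pairwise
#'   distinct), as from [unit_cores()].
#' @param max_dist Maximum Levenshtein distance (default 2).
#' @return A tibble with columns `observed`, `unit_id` (`NA` when
#'   unmatched/ambiguous) and `distance`.
#' @export
match_units <- function(observed, cores, max_dist = 2L) {
  stopifnot(!anyDuplicated(cores))
  if (length(observed) == 0) {
    return(tibble::tibble(observed = character(), unit_id = character(),
                          distance = integer()))
  }
  d <- adist(observed, cores)
  best <- apply(d, 1, min)
  n_best <- rowSums(d == best)
  hit <- best <= max_dist & n_best == 1L
  unit <- rep(NA_character_, length(observed))
  unit[hit] <- names(cores)[apply(d[hit, , drop = FALSE], 1, which.min)]
  tibble::tibble(observed = observed, unit_id = unit,
                 distance = as.integer(best))
}

#' Build the barcode dictionary from dictionary read pairs
#'
#' The barcode is the first 24 nt of `barcode_read`. Pairs whose unit read
#' cannot be matched uniquely within distance `max_dist` are dropped, as
#' are pairs with a short or non-ACGT barcode (tallied in the QC
#' attribute). Any barcode observed with two or more distinct matched
#' units -- within or across read pairs -- is discarded entirely, making the
#' resulting map injective barcode -> promoter. The promoter is the matched
#' unit crossed with the minimal promoter of the pool the pair came from.
#'
#' @param pairs Tibble of read pairs: `unit_read`, `barcode_read`,
#'   `pool_id`.
#' @param units Units tibble (or a named character vector of unit cores).
#' @param pools Tibble mapping `pool_id` to `min_promoter`; must cover all
#'   pool ids present in `pairs`.
#' @param config [design_config()] used to derive unit cores when `units`
#'   is a tibble.
#' @param max_dist Maximum unit-matching Levenshtein distance.
#' @return A tibble (`barcode`, `promoter_id`, `unit_id`, `min_promoter`,
#'   `support`) with one row per retained barcode; QC counters are attached
#'   as the `"qc"` attribute.
#' @export
build_dictionary <- function(pairs, units, pools,
                             config = design_config(), max_dist = 2L) {
  stopifnot(all(c("unit_read", "barcode_read", "pool_id") %in% names(pairs)))
  if (!all(unique(pairs$pool_id) %in% pools$pool_id)) {
    abort("pools table does not cover every pool_id in the read pairs")
  }
  cores <- if (is.data.frame(units)) unit_cores(units, config) else units

  barcode <- substr(pairs$barcode_read, 1L, BARCODE_LEN)
  ok_bc <- nchar(pairs$barcode_read) >= BARCODE_LEN & is_acgt(barcode)
  n_bad_barcode <- sum(!ok_bc)

  kept <- tibble::tibble(barcode = barcode[ok_bc],
                         unit_read = pairs$unit_read[ok_bc],
                         pool_id = pairs$pool_id[ok_bc])
  ## match each distinct observed unit sequence once
  uniq <- unique(kept$unit_read)
  matched <- match_units(uniq, cores, max_dist)
  kept$unit_id <- matched$unit_id[match(kept$unit_read, matched$observed)]
  n_unmatched <- sum(is.na(kept$unit_id))
  kept <- kept[!is.na(kept$unit_id), , drop = FALSE]

  kept <- dplyr::left_join(kept, pools[c("pool_id", "min_promoter")],
                           by = "pool_id")
  kept$promoter_id <- paste(kept$unit_id, kept$min_promoter, sep = "|")

  per_bc <- dplyr::summarise(
    dplyr::group_by(kept, .data$barcode),
    n_units = dplyr::n_distinct(.data$unit_id),
    unit_id = .data$unit_id[1],
    min_promoter = .data$min_promoter[1],
    promoter_id = .data$promoter_id[1],
    support = dplyr::n(),
    .groups = "drop"
  )
  n_multi <- sum(per_bc$n_units > 1L)
  out <- dplyr::select(
    dplyr::filter(per_bc, .data$n_units == 1L),
    "barcode", "promoter_id", "unit_id", "min_promoter", "support"
  )
  attr(out, "qc") <- list(n_pairs = nrow(pairs),
                          n_bad_barcode = n_bad_barcode,
                          n_unmatched_unit = n_unmatched,
                          n_multi_unit_barcodes = n_multi)
  out
}

#' Read paired dictionary FASTQ files
#'
#' @param unit_fastq FASTQ whose reads cover the TRE-unit core.
#' @param barcode_fastq FASTQ whose reads carry the barcode in their first
#'   24 nt; records pair with `unit_fastq` by position.
#' @param pool_id Pool label attached to every pair.
#' @return A tibble (`unit_read`, `barcode_read`, `pool_id`) for
#'   [build_dictionary()].
#' @export
read_dictionary_pairs <- function(unit_fastq, barcode_fastq, pool_id) {
  r1 <- Biostrings::readDNAStringSet(unit_fastq, format = "fastq")
  r2 <- Biostrings::readDNAStringSet(barcode_fastq, format = "fastq")
  if (length(r1) != length(r2)) {
    abort("dictionary FASTQ files have different numbers of records")
  }
  tibble::tibble(unit_read = unname(as.character(r1)),
                 barcode_read = unname(as.character(r2)),
                 pool_id = pool_id)
}

#' Read/write a barcode dictionary TSV
#'
#' Columns: `barcode`, `promoter_id`, `unit_id`, `min_promoter`, `support`.
#' @param path File path.
#' @return The reader returns a tibble; the writer returns `path`
#'   invisibly.
#' @export
read_dictionary <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_dictionary
#' @param dictionary Dictionary tibble.
#' @export
write_dictionary <- function(dictionary, path) {
  readr::write_tsv(dictionary, path)
  invisible(path)
}
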