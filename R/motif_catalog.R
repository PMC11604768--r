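## Motif catalog: turn PWM seed sequences into a deduplicated set of plain
## ACGT binding motifs, plus scrambled negative controls.

#' Resolve PWM seed sequences into plain ACGT binding motifs
#'
#' Each seed is processed in two passes: (1) runs of fully degenerate
#' positions (`N`) are trimmed from the 5' and 3' ends; (2) every remaining
#' degenerate IUPAC position is replaced by the predominant base at that
#' position, i.e. the base with maximal PWM weight among the bases the code
#' permits. Ties are broken alphabetically.
#'
#' @param seeds A data frame with columns `tf_name` (character), `species`
#'   (one of `"human"`, `"mouse"`, `"synthetic"`), `seed` (IUPAC string,
#'   length >= 4) and `pwm` (list column of L x 4 matrices of nonnegative
#'   weights, rows matching seed positions, columns ordered A, C, G, T).
#' @return A tibble with columns `motif_id`, `tf_name`, `sequence`,
#'   `provenance` (all `"experimental"`). One row per input seed.
#' @seealso [dedup_motifs()], [build_motif_catalog()]
#' @export
resolve_seeds <- function(seeds) {
  stopifnot(is.data.frame(seeds))
  need <- c("tf_name", "seed", "pwm")
  if (!all(need %in% names(seeds))) {
    abort(paste("`seeds` must have columns:", paste(need, collapse = ", ")))
  }
  sequences <- purrr::map2_chr(seeds$seed, seeds$pwm, resolve_one_seed)
  tibble::tibble(
    motif_id = make.unique(seeds$tf_name, sep = "_"),
    tf_name = seeds$tf_name,
    sequence = sequences,
    provenance = "experimental"
  )
}

## Scalar worker: trim flanking Ns, then argmax-replace remaining degenerate
## positions using the ORIGINAL pwm row indices.
resolve_one_seed <- function(seed, pwm) {
  chars <- strsplit(toupper(seed), "")[[1]]
  L <- length(chars)
  if (!all(chars %in% names(IUPAC_CODES))) {
    abort(paste0("seed '", seed, "' contains non-IUPAC characters"))
  }
  if (!is.matrix(pwm) || nrow(pwm) != L || ncol(pwm) != 4) {
    abort(paste0("pwm for seed '", seed, "' must be a ", L, " x 4 matrix"))
  }
  if (any(pwm < 0)) {
    abort(paste0("pwm for seed '", seed, "' has negative weights"))
  }
  ## all-zero rows surface below, at the degenerate position they affect
  keep <- which(chars != "N")
  if (length(keep) == 0) {
    abort(paste0("seed '", seed, "' is all N: empty motif"))
  }
  idx <- seq(min(keep), max(keep))
  out <- character(length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    code <- chars[i]
    if (code %in% DNA_BASES) {
      out[j] <- code
      next
    }
    allowed <- IUPAC_CODES[[code]]
    w <- pwm[i, match(allowed, DNA_BASES)]
    if (all(w <= 0)) {
      abort(paste0("seed '", seed, "': degenerate position ", i,
                   " has zero pwm weight for all permitted bases"))
    }
    ## alphabetical tie-break: allowed is already in A<C<G<T order
    out[j] <- allowed[which.max(w)]
  }
  paste(out, collapse = "")
}

#' Remove motifs contained within other motifs
#'
#' A motif is dropped when its entire sequence occurs as a contiguous
#' forward-strand substring of another, distinct motif's sequence. Among
#' exact duplicates the first by input order is kept. Input order is
#' preserved. For example, given motifs `CAAAAAC` and `AAAAA`, only
#' `CAAAAAC` is retained.
#'
#' @param motifs A data frame with at least a `sequence` column of plain
#'   ACGT strings (e.g. from [resolve_seeds()]).
#' @return The input tibble restricted to non-contained motifs.
#' @export
dedup_motifs <- function(motifs) {
  stopifnot(is.data.frame(motifs), "sequence" %in% names(motifs))
  seqs <- motifs$sequence
  if (any(!is_acgt(seqs))) {
    abort("dedup_motifs() requires plain ACGT sequences; resolve seeds first")
  }
  n <- length(seqs)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dup_earlier <- i > 1 && seqs[i] %in% seqs[seq_len(i - 1)]
    contained <- any(seqs != seqs[i] &
                       stringr::str_detect(seqs, stringr::fixed(seqs[i])))
    keep[i] <- !dup_earlier && !contained
  }
  tibble::as_tibble(motifs[keep, , drop = FALSE])
}

#' Scramble motifs to create negative-control motifs
#'
#' Draws `n` source motifs (recycled if `n` exceeds the catalog) and
#' permutes each sequence, preserving base composition. The permutation is
#' redrawn (bounded attempts) until it differs from the source and is
#' neither a substring nor a superstring of it. Homopolymer motifs cannot
#' change under permutation and are skipped with a warning.
#'
#' @param motifs A data frame of experimental motifs (columns `motif_id`,
#'   `tf_name`, `sequence`).
#' @param n Number of control motifs to generate.
#' @param seed Integer RNG seed; output is deterministic given the seed.
#' @param max_attempts Redraw bound per motif.
#' @param design A [design_config()]; when supplied, scrambles are also
#'   redrawn until they pass [motif_designable()], so the controls can be
#'   built into clean TRE units.
#' @return A tibble of control motifs, `provenance = "negative_control"`.
#' @export
scramble_motifs <- function(motifs, n = nrow(motifs), seed = 1L,
                            max_attempts = 100L, design = NULL) {
  stopifnot(is.data.frame(motifs), n >= 1)
  src <- motifs
  if (!is.null(motifs$provenance)) {
    src <- motifs[motifs$provenance == "experimental", , drop = FALSE]
  }
  if (nrow(src) == 0) abort("no experimental motifs to scramble")
  rows <- list()
  warned <- character(0)
  draw <- 0L
  while (length(rows) < n && draw < 10L * n) {
    draw <- draw + 1L
    m <- src[(draw - 1L) %% nrow(src) + 1L, ]
    scr <- with_seed(str_hash(seed, m$motif_id, draw), {
      scramble_one(m$sequence, max_attempts, design)
    })
    if (is.na(scr)) {
      if (!m$motif_id %in% warned) {
        warned <- c(warned, m$motif_id)
        reason <- if (length(unique(strsplit(m$sequence, "")[[1]])) == 1L) {
          "is a homopolymer"
        } else {
          "yielded no usable scramble"
        }
        warn(paste0("motif ", m$motif_id, " ", reason, "; control skipped"))
      }
      next
    }
    k <- length(rows) + 1L
    rows[[k]] <- tibble::tibble(
      motif_id = paste0("ctrl_", k, "_", m$motif_id),
      tf_name = paste0("scrambled_", m$tf_name),
      sequence = scr,
      provenance = "negative_control"
    )
  }
  if (length(rows) < n) {
    warn(paste0("only ", length(rows), " of ", n,
                " requested control motifs could be generated"))
  }
  dplyr::bind_rows(rows)
}

scramble_one <- function(sequence, max_attempts, design = NULL) {
  chars <- strsplit(sequence, "")[[1]]
  if (length(unique(chars)) == 1L) return(NA_character_)
  for (attempt in seq_len(max_attempts)) {
    cand <- paste(sample(chars), collapse = "")
    ## equal length: sub/superstring containment reduces to equality,
    ## but keep the full check for safety
    if (cand != sequence &&
        !grepl(cand, sequence, fixed = TRUE) &&
        !grepl(sequence, cand, fixed = TRUE) &&
        (is.null(design) || motif_designable(cand, design))) {
      return(cand)
    }
  }
  NA_character_
}

#' Build a motif catalog from PWM seeds
#'
#' Convenience pipeline: [resolve_seeds()], then [dedup_motifs()], then
#' optionally append `n_controls` scrambled negative-control motifs.
#'
#' @inheritParams resolve_seeds
#' @param n_controls Number of scrambled negative-control motifs to append.
#' @param seed RNG seed for scrambling.
#' @param design Optional [design_config()] forwarded to
#'   [scramble_motifs()] so the controls are designable.
#' @return A tibble of motifs (`motif_id`, `tf_name`, `sequence`,
#'   `provenance`).
#' @export
build_motif_catalog <- function(seeds, n_controls = 0L, seed = 1L,
                                design = NULL) {
  catalog <- dedup_motifs(resolve_seeds(seeds))
  if (n_controls > 0) {
    catalog <- dplyr::bind_rows(
      catalog,
      scramble_motifs(catalog, n = n_controls, seed = seed, design = design)
    )
  }
  catalog
}

#' Read a seed/PWM table from TSV
#'
#' The TSV has columns `tf_name`, `species`, `seed` and `pwm`, the latter a
#' JSON-serialized L x 4 array of row-wise weights (columns A, C, G, T).
#'
#' @param path File path.
#' @return A tibble suitable for [resolve_seeds()].
#' @export
read_seed_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  x$pwm <- purrr::map(x$pwm, function(s) {
    m <- jsonlite::fromJSON(s)
    matrix(as.numeric(m), ncol = 4, dimnames = list(NULL, DNA_BASES))
  })
  tibble::as_tibble(x)
}

#' Write a seed/PWM table to TSV
#' @param seeds Seed tibble with a `pwm` list column.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_seed_table <- function(seeds, path) {
  out <- seeds
  out$pwm <- purrr::map_chr(seeds$pwm, function(m) {
    as.character(jsonlite::toJSON(unname(m), digits = NA))
  })
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read/write a motif catalog TSV
#'
#' Columns: `motif_id`, `tf_name`, `sequence`, `provenance`.
#' @param path File path.
#' @return `read_motif_catalog()` returns a tibble; the writer returns
#'   `path` invisibly.
#' @export
read_motif_catalog <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = "c"))
}

#' @rdname read_motif_catalog
#' @param motifs Motif catalog tibble.
#' @export
write_motif_catalog <- function(motifs, path) {
  readr::write_tsv(motifs, path)
  invisible(path)
}
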