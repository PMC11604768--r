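## TRE-unit / synthetic-promoter design: four helically phased copies of a
## binding motif, random spacers, a rotation segment, 3' filler and fixed
## cloning flanks, synthesized as fixed-length oligos and crossed with three
## minimal promoters.

MIN_PROMOTERS <- c("minTK", "minProm", "minCMV")

#' Design configuration for TRE units
#'
#' @param helical_period DNA helical period in bp per turn (B-DNA, 10.5).
#' @param oligo_length Total synthesized oligo length in nt.
#' @param copies Number of motif copies per unit.
#' @param spacer_sets Integer seeds naming the random spacer sets; two sets
#'   by default.
#' @param rotations Rotation-segment lengths in nt, shifting the TRE block
#'   relative to the downstream minimal promoter (0/4/8 nt is roughly
#'   0/1-3/2-3 of a helical turn).
#' @param forbidden_sites Named character vector of restriction recognition
#'   sequences that must not occur outside their designed flank positions.
#' @param flank_5p,flank_3p Fixed flanking sequences carrying primer landing
#'   sites and the MluI (5') / SpeI (3') cloning sites.
#' @param max_redraws Bound on redraws of random segments when a draw
#'   creates a forbidden site.
#' @return A list of class `design_config`.
#' @export
design_config <- function(helical_period = 10.5,
                          oligo_length = 160L,
                          copies = 4L,
                          spacer_sets = c(1L, 2L),
                          rotations = c(0L, 4L, 8L),
                          forbidden_sites = c(MluI = "ACGCGT", SpeI = "ACTAGT",
                                              KpnI = "GGTACC", XbaI = "TCTAGA"),
                          flank_5p = paste0("CGACGCTCTTCCGATCTCTG", "ACGCGT"),
                          flank_3p = paste0("ACTAGT", "AGATCGGAAGAGCACACGTC"),
                          max_redraws = 1000L) {
  stopifnot(helical_period > 0, oligo_length > 0, copies >= 1,
            length(rotations) >= 1, length(spacer_sets) >= 1)
  cfg <- list(
    helical_period = helical_period, oligo_length = as.integer(oligo_length),
    copies = as.integer(copies), spacer_sets = as.integer(spacer_sets),
    rotations = as.integer(rotations), forbidden_sites = forbidden_sites,
    flank_5p = flank_5p, flank_3p = flank_3p,
    max_redraws = as.integer(max_redraws)
  )
  ## forbidden sites may occur in the flanks only at their cloning spots:
  ## record those designed positions now
  cfg$designed_5p <- site_positions(flank_5p, forbidden_sites)
  cfg$designed_3p <- site_positions(flank_3p, forbidden_sites)
  n_sites <- nrow(cfg$designed_5p) + nrow(cfg$designed_3p)
  if (n_sites > 2) {
    abort("flanks contain forbidden sites beyond the two designed cloning sites")
  }
  structure(cfg, class = "design_config")
}

## 0-based starts of each site within a sequence
site_positions <- function(sequence, sites) {
  hits <- purrr::imap(sites, function(s, nm) {
    loc <- stringr::str_locate_all(sequence, stringr::fixed(s))[[1]]
    if (nrow(loc) == 0) return(NULL)
    tibble::tibble(site = nm, sequence = s, start = loc[, 1] - 1L)
  })
  dplyr::bind_rows(hits)
}

#' Phasing spacer length for a motif
#'
#' Returns the smallest nonnegative spacer length `s` such that the
#' center-to-center spacing of adjacent motif copies (`motif_length + s`)
#' is as close as possible to a half-integer number of helical turns,
#' placing adjacent copies on opposite faces of the double helix. The
#' objective minimized is `min_k |motif_length + s - period * (k + 0.5)|`;
#' for integer lengths and a 10.5 bp period the attained deviation is
#' always 0.25 bp.
#'
#' @param motif_length Motif length(s) in nt (vectorized).
#' @param config A [design_config()].
#' @return Integer spacer length(s), one per input length.
#' @export
phasing_spacer_length <- function(motif_length, config = design_config()) {
  period <- config$helical_period
  vapply(motif_length, function(L) {
    stopifnot(L >= 1)
    s_cand <- 0:as.integer(ceiling(2 * period))
    dev <- vapply(s_cand, function(s) phase_deviation(L + s, period), numeric(1))
    s_cand[which.min(dev)]  # which.min returns the first (smallest s) on ties
  }, integer(1))
}

## circular deviation of a spacing from the nearest half-turn multiple
phase_deviation <- function(spacing, period) {
  k <- max(0, round(spacing / period - 0.5))
  kk <- unique(pmax(0, k + (-1):1))
  min(abs(spacing - period * (kk + 0.5)))
}

#' Generate one TRE unit for a motif
#'
#' Assembles `flank_5p + (motif + spacer) x 3 + motif + rotation segment +
#' 3' filler + flank_3p`, with all random segments drawn from an RNG stream
#' derived deterministically from `(seed, spacer_set, motif_id, rotation)`.
#' Spacer length comes from [phasing_spacer_length()]; the 3' filler length
#' is chosen so the total equals `config$oligo_length`. Any random draw that
#' creates a forbidden restriction site (including across segment
#' junctions) is redrawn, up to `config$max_redraws`.
#'
#' @param motif_id,sequence Motif identifier and plain ACGT sequence.
#' @param spacer_set Spacer-set index (selects an independent random stream).
#' @param rotation Rotation-segment length in nt.
#' @param config A [design_config()].
#' @param seed Integer RNG seed for the whole design run.
#' @return A one-row tibble: `unit_id`, `motif_id`, `spacer_set`,
#'   `rotation`, `oligo`, `length`, and a `layout` list column holding a
#'   tibble of segments with 0-based half-open coordinates.
#' @export
generate_tre_unit <- function(motif_id, sequence, spacer_set, rotation,
                              config = design_config(), seed = 1L) {
  if (!is_acgt(sequence)) abort(paste0("motif ", motif_id, " is not plain ACGT"))
  L <- nchar(sequence)
  for (site in config$forbidden_sites) {
    if (grepl(site, sequence, fixed = TRUE)) {
      abort(paste0("motif ", motif_id, " (", sequence,
                   ") contains forbidden site ", site,
                   "; incompatible with the restriction strategy"))
    }
  }
  s_len <- phasing_spacer_length(L, config)
  n5 <- nchar(config$flank_5p)
  n3 <- nchar(config$flank_3p)
  n_spacers <- config$copies - 1L
  filler_len <- config$oligo_length -
    (n5 + config$copies * L + n_spacers * s_len + rotation + n3)
  if (filler_len < 0) {
    abort(paste0("unit too long for motif ", motif_id, " (", L, " nt motif, ",
                 s_len, " nt spacers, rotation ", rotation, ")"))
  }

  stream_seed <- str_hash(seed, config$spacer_sets[spacer_set], motif_id, rotation)
  oligo <- NULL
  with_seed(stream_seed, {
    for (attempt in seq_len(config$max_redraws)) {
      spacers <- replicate(n_spacers, random_dna(s_len))
      rot_seg <- random_dna(rotation)
      filler <- random_dna(filler_len)
      segs <- c(config$flank_5p,
                as.vector(rbind(rep(sequence, n_spacers), spacers)),
                sequence, rot_seg, filler, config$flank_3p)
      cand <- paste(segs, collapse = "")
      if (nrow(forbidden_site_hits(cand, config, n3)) == 0) {
        oligo <- cand
        break
      }
    }
  })
  if (is.null(oligo)) {
    abort(paste0("redraw budget exhausted for motif ", motif_id,
                 ": cannot avoid forbidden sites"))
  }

  seg_names <- c("flank_5p",
                 as.vector(rbind(paste0("motif", seq_len(n_spacers)),
                                 paste0("spacer", seq_len(n_spacers)))),
                 paste0("motif", config$copies),
                 "rotation", "filler_3p", "flank_3p")
  seg_lens <- c(n5, rep(c(L, s_len), n_spacers), L, rotation, filler_len, n3)
  ends <- cumsum(seg_lens)
  layout <- tibble::tibble(segment = seg_names,
                           start = c(0L, ends[-length(ends)]),
                           end = as.integer(ends))

  tibble::tibble(
    unit_id = sprintf("%s|s%d|r%d", motif_id, spacer_set, rotation),
    motif_id = motif_id,
    spacer_set = as.integer(spacer_set),
    rotation = as.integer(rotation),
    oligo = oligo,
    length = nchar(oligo),
    layout = list(layout)
  )
}

#' Locate forbidden restriction sites outside their designed flank positions
#'
#' @param oligo Oligo sequence.
#' @param config A [design_config()].
#' @param flank_3p_len Length of the 3' flank at the end of this oligo (its
#'   offset is `nchar(oligo) - flank_3p_len`).
#' @return A tibble of off-target hits (`site`, `start` 0-based); zero rows
#'   for a clean oligo.
#' @export
forbidden_site_hits <- function(oligo, config, flank_3p_len = nchar(config$flank_3p)) {
  hits <- site_positions(oligo, config$forbidden_sites)
  if (nrow(hits) == 0) return(hits)
  allowed <- c(config$designed_5p$start,
               nchar(oligo) - flank_3p_len + config$designed_3p$start)
  hits[!(hits$start %in% allowed), , drop = FALSE]
}

#' Design TRE units for a motif catalog
#'
#' Experimental motifs get one unit per spacer-set x rotation combination
#' (six by default); negative-control motifs get a single configuration
#' (spacer set 1, rotation 0).
#'
#' @param motifs Motif catalog tibble (from [build_motif_catalog()]).
#' @param config A [design_config()].
#' @param seed Integer RNG seed.
#' @return A tibble of units with provenance carried over from the catalog.
#' @export
design_tre_units <- function(motifs, config = design_config(), seed = 1L) {
  stopifnot(is.data.frame(motifs))
  prov <- motifs$provenance %||% rep("experimental", nrow(motifs))
  plan <- purrr::map(seq_len(nrow(motifs)), function(i) {
    if (prov[i] == "experimental") {
      grid <- tidyr::expand_grid(spacer_set = seq_along(config$spacer_sets),
                                 rotation = config$rotations)
    } else {
      grid <- tibble::tibble(spacer_set = 1L, rotation = config$rotations[1])
    }
    dplyr::mutate(grid, motif_id = motifs$motif_id[i],
                  sequence = motifs$sequence[i], provenance = prov[i])
  })
  plan <- dplyr::bind_rows(plan)
  units <- purrr::pmap(plan[c("motif_id", "sequence", "spacer_set", "rotation")],
                       generate_tre_unit, config = config, seed = seed)
  dplyr::bind_cols(dplyr::bind_rows(units),
                   plan["provenance"])
}

#' Assemble the full synthetic-promoter library
#'
#' Designs units for the catalog (experimental and negative-control
#' motifs), appends fixed commercial units unmodified (their lengths may
#' exceed the design oligo length), and crosses every unit with the three
#' minimal promoters.
#'
#' @param motifs Motif catalog tibble.
#' @param commercial Optional tibble of pass-through units with columns
#'   `unit_id` and `oligo`.
#' @param config A [design_config()].
#' @param seed Integer RNG seed.
#' @return A list with `units` (one row per TRE unit) and `promoters`
#'   (units crossed with `minTK`, `minProm`, `minCMV`; `promoter_id =
#'   "<unit_id>|<min_promoter>"`).
#' @export
design_library <- function(motifs, commercial = NULL,
                           config = design_config(), seed = 1L) {
  units <- design_tre_units(motifs, config, seed)
  if (!is.null(commercial) && nrow(commercial) > 0) {
    com <- tibble::tibble(
      unit_id = commercial$unit_id,
      motif_id = NA_character_,
      spacer_set = NA_integer_,
      rotation = NA_integer_,
      oligo = commercial$oligo,
      length = nchar(commercial$oligo),
      layout = list(NULL),
      provenance = "commercial"
    )
    units <- dplyr::bind_rows(units, com)
  }
  if (anyDuplicated(units$unit_id)) abort("duplicate unit_id in library")
  promoters <- tidyr::expand_grid(unit_id = units$unit_id,
                                  min_promoter = MIN_PROMOTERS)
  promoters <- dplyr::mutate(promoters,
                             promoter_id = paste(.data$unit_id,
                                                 .data$min_promoter, sep = "|"),
                             .before = 1)
  list(units = units, promoters = promoters)
}

#' Phasing deviation of adjacent motif copies in a unit layout
#'
#' Computes, from a unit's layout, the center-to-center spacing of each
#' adjacent motif-copy pair and its circular deviation from the nearest
#' half-integer number of helical turns.
#'
#' @param layout A layout tibble from [generate_tre_unit()].
#' @param config A [design_config()].
#' @return A numeric vector of deviations in bp, one per adjacent pair.
#' @export
layout_phase_deviation <- function(layout, config = design_config()) {
  m <- layout[grepl("^motif", layout$segment), ]
  spacing <- diff(m$start)
  vapply(spacing, phase_deviation, numeric(1), period = config$helical_period)
}

#' Write unit oligos as FASTA
#' @param units Units tibble; record ids are `unit_id`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_unit_fasta <- function(units, path) {
  x <- Biostrings::DNAStringSet(setNames(units$oligo, units$unit_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write the design manifest TSV
#'
#' One row per unit: identifiers, provenance, configuration, oligo length
#' and the 0-based motif-copy start positions (comma separated).
#'
#' @param units Units tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_design_manifest <- function(units, path) {
  motif_pos <- purrr::map_chr(units$layout, function(lay) {
    if (is.null(lay)) return(NA_character_)
    paste(lay$start[grepl("^motif", lay$segment)], collapse = ",")
  })
  out <- dplyr::select(units, "unit_id", "motif_id", "provenance",
                       "spacer_set", "rotation", "length")
  out$motif_starts <- motif_pos
  readr::write_tsv(out, path)
  invisible(path)
}
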