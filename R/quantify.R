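## Quantification: RPM normalization, aggregate RNA/DNA transcription-rate
## estimates, barcode fold changes, upper-quartile depth factors, and
## clustering/biplot profile summaries.

#' Reads-per-million normalization
#'
#' Scales each sample to one million reads: `count * 1e6 / sample total`.
#'
#' @param counts Long tibble with columns `barcode`, `sample_id`, `count`.
#' @return The input with an `rpm` column added; each sample's `rpm` sums
#'   to 1e6.
#' @export
rpm <- function(counts) {
  stopifnot(all(c("barcode", "sample_id", "count") %in% names(counts)))
  totals <- dplyr::summarise(dplyr::group_by(counts, .data$sample_id),
                             total = sum(.data$count), .groups = "drop")
  zero <- totals$sample_id[totals$total == 0]
  if (length(zero)) {
    abort(paste0("sample(s) with zero total counts: ",
                 paste(zero, collapse = ", ")))
  }
  counts <- dplyr::left_join(counts, totals, by = "sample_id")
  counts <- dplyr::mutate(counts, rpm = .data$count * 1e6 / .data$total)
  dplyr::select(counts, -"total")
}

#' Aggregate RNA/DNA ratio transcription-rate estimates
#'
#' For each promoter and RNA sample: the sum of RNA reads-per-million over
#' the promoter's dictionary barcodes divided by the sum of DNA
#' reads-per-million over the same barcodes in the plasmid input. When
#' several DNA input samples are present their RPM values are averaged per
#' barcode before summing. A promoter whose summed DNA RPM is zero gets an
#' undefined (NA) ratio with `undefined = TRUE`; promoters with no
#' dictionary barcodes are absent from the output.
#'
#' @param counts Long tibble (`barcode`, `sample_id`, `count`).
#' @param samples Sample metadata tibble: `sample_id`, `material` ("DNA" or
#'   "RNA"), `condition`, `batch`.
#' @param dictionary Dictionary tibble (`barcode`, `promoter_id`).
#' @return A tibble (`promoter_id`, `sample_id`, `condition`, `ratio`,
#'   `undefined`), one row per promoter x RNA sample.
#' @export
aggregate_ratio <- function(counts, samples, dictionary) {
  stopifnot(all(c("sample_id", "material") %in% names(samples)))
  norm <- rpm(counts)
  norm <- dplyr::inner_join(norm, dictionary[c("barcode", "promoter_id")],
                            by = "barcode")
  norm <- dplyr::left_join(norm,
                           samples[c("sample_id", "material", "condition")],
                           by = "sample_id")

  dna <- dplyr::filter(norm, .data$material == "DNA")
  if (nrow(dna) == 0) abort("no DNA samples in `samples`")
  ## mean RPM across DNA replicates, then sum over the promoter's barcodes
  dna_bc <- dplyr::summarise(dplyr::group_by(dna, .data$promoter_id, .data$barcode),
                             dna_rpm = sum(.data$rpm) / dplyr::n_distinct(dna$sample_id),
                             .groups = "drop")
  dna_sum <- dplyr::summarise(dplyr::group_by(dna_bc, .data$promoter_id),
                              dna_rpm = sum(.data$dna_rpm), .groups = "drop")

  rna <- dplyr::filter(norm, .data$material == "RNA")
  rna_sum <- dplyr::summarise(
    dplyr::group_by(rna, .data$promoter_id, .data$sample_id, .data$condition),
    rna_rpm = sum(.data$rpm), .groups = "drop"
  )
  out <- dplyr::left_join(rna_sum, dna_sum, by = "promoter_id")
  out$dna_rpm[is.na(out$dna_rpm)] <- 0
  dplyr::transmute(out,
                   promoter_id = .data$promoter_id,
                   sample_id = .data$sample_id,
                   condition = .data$condition,
                   ratio = ifelse(.data$dna_rpm > 0,
                                  .data$rna_rpm / .data$dna_rpm, NA_real_),
                   undefined = .data$dna_rpm == 0)
}

#' Per-barcode fold changes between treatment arms
#'
#' For each barcode: the median RPM across treated replicates divided by
#' the median RPM across control replicates. Barcodes whose control median
#' is zero are flagged undefined.
#'
#' @param counts Long tibble (`barcode`, `sample_id`, `count`).
#' @param treated,control Character vectors of sample ids in each arm
#'   (at least one each).
#' @return A tibble (`barcode`, `treated_median`, `control_median`,
#'   `fold_change`, `undefined`).
#' @export
barcode_fold_changes <- function(counts, treated, control) {
  stopifnot(length(treated) >= 1, length(control) >= 1)
  norm <- rpm(counts[counts$sample_id %in% c(treated, control), , drop = FALSE])
  wide <- tidyr::pivot_wider(norm[c("barcode", "sample_id", "rpm")],
                             names_from = "sample_id", values_from = "rpm",
                             values_fill = 0)
  med <- function(cols) apply(as.matrix(wide[cols]), 1, median)
  t_med <- med(treated)
  c_med <- med(control)
  tibble::tibble(barcode = wide$barcode,
                 treated_median = t_med,
                 control_median = c_med,
                 fold_change = ifelse(c_med > 0, t_med / c_med, NA_real_),
                 undefined = c_med == 0)
}

#' Upper-quartile sequencing-depth factors
#'
#' Scales each sample by the upper quartile of its nonzero raw counts
#' relative to a reference sample: `Q75(nonzero counts of s) / Q75(nonzero
#' counts of reference)`. Quartiles use linear interpolation
#' ([stats::quantile()] type 7). The reference factor is exactly 1.
#'
#' @param counts Long tibble (`barcode`, `sample_id`, `count`).
#' @param reference Reference `sample_id`; defaults to the first sample.
#' @return A tibble (`sample_id`, `depth_factor`).
#' @export
upper_quartile_factors <- function(counts, reference = NULL) {
  ids <- unique(counts$sample_id)
  reference <- reference %||% ids[1]
  if (!reference %in% ids) abort("reference sample not present in counts")
  uq <- vapply(ids, function(s) {
    x <- counts$count[counts$sample_id == s]
    x <- x[x > 0]
    if (length(x) == 0) abort(paste0("sample ", s, " has no nonzero counts"))
    quantile(x, 0.75, names = FALSE)
  }, numeric(1))
  tibble::tibble(sample_id = ids,
                 depth_factor = unname(uq / uq[match(reference, ids)]))
}

#' Clustering and biplot summaries of an activity-profile matrix
#'
#' Rows with any undefined (NA) value are dropped. Hierarchical clustering
#' uses Euclidean distance with complete linkage on rows and columns of the
#' matrix as given. For the biplot, columns are standardized (mean 0, sd 1;
#' constant columns are dropped with a warning) and a rank-2 SVD taken:
#' row (promoter) coordinates are `U[,1:2] * d[1:2]`, column (sample)
#' coordinates are `V[,1:2]`.
#'
#' @param mat A numeric matrix with promoter rownames and sample colnames,
#'   or a tibble whose first column is `promoter_id`.
#' @return An object of class `mpra_profiles`: list with `row_hclust`,
#'   `col_hclust`, `row_order`, `col_order`, `scores` (promoter
#'   coordinates), `loadings` (sample coordinates) and `d` (singular
#'   values of the standardized matrix).
#' @export
profile_summaries <- function(mat) {
  if (is.data.frame(mat)) {
    m <- as.matrix(mat[, -1, drop = FALSE])
    rownames(m) <- mat[[1]]
    mat <- m
  }
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    abort("profile matrix needs at least 2 defined rows and 2 columns")
  }
  row_hc <- hclust(dist(mat, method = "euclidean"), method = "complete")
  col_hc <- hclust(dist(t(mat), method = "euclidean"), method = "complete")

  sds <- apply(mat, 2, sd)
  if (any(sds == 0)) {
    warn(paste0("dropping constant column(s) before biplot: ",
                paste(colnames(mat)[sds == 0], collapse = ", ")))
  }
  std <- scale(mat[, sds > 0, drop = FALSE])
  sv <- svd(std, nu = 2, nv = 2)
  scores <- sv$u %*% diag(sv$d[1:2], 2)
  dimnames(scores) <- list(rownames(mat), c("dim1", "dim2"))
  loadings <- sv$v
  dimnames(loadings) <- list(colnames(std), c("dim1", "dim2"))

  structure(list(row_hclust = row_hc, col_hclust = col_hc,
                 row_order = row_hc$order, col_order = col_hc$order,
                 scores = scores, loadings = loadings, d = sv$d),
            class = "mpra_profiles")
}

#' @export
print.mpra_profiles <- function(x, ...) {
  cat("MPRA profile summary:", nrow(x$scores), "promoters x",
      nrow(x$loadings), "samples\n")
  cat("Leading singular values:",
      paste(signif(head(x$d, 4), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Write a transcription-rate table to TSV (wide, promoters x samples)
#' @param rates Output of [aggregate_ratio()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(rates, path) {
  wide <- tidyr::pivot_wider(rates[c("promoter_id", "sample_id", "ratio")],
                             names_from = "sample_id", values_from = "ratio")
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Write biplot coordinates to TSV
#' @param profiles An `mpra_profiles` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_biplot_coords <- function(profiles, path) {
  rows <- tibble::tibble(id = rownames(profiles$scores), role = "promoter",
                         dim1 = profiles$scores[, 1], dim2 = profiles$scores[, 2])
  cols <- tibble::tibble(id = rownames(profiles$loadings), role = "sample",
                         dim1 = profiles$loadings[, 1], dim2 = profiles$loadings[, 2])
  readr::write_tsv(dplyr::bind_rows(rows, cols), path)
  invisible(path)
}
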