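## ggplot2 helpers for the main result types.

#' Volcano plot of differential promoter activity
#'
#' Displays the LRT statistic (which stays informative when p-values
#' underflow) against the log2 fold change, with promoters passing the FDR
#' threshold highlighted.
#'
#' @param x An `mpra_diff` object or its [tidy()] tibble.
#' @param fdr_threshold Significance threshold (default 0.05).
#' @return A ggplot object.
#' @export
plot_volcano <- function(x, fdr_threshold = 0.05) {
  if (inherits(x, "mpra_diff")) x <- tidy(x)
  d <- x[!is.na(x$log2_fc), , drop = FALSE]
  d$significant <- !is.na(d$fdr) & d$fdr < fdr_threshold
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_fc, y = .data$lrt_stat,
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick"),
                                 name = paste0("FDR < ", fdr_threshold)) +
    ggplot2::labs(x = "log2 fold change", y = "LRT statistic") +
    ggplot2::theme_minimal()
}

#' @method autoplot mpra_diff
#' @export
autoplot.mpra_diff <- function(object, ...) {
  plot_volcano(object, ...)
}

#' Biplot of promoter and sample projections
#'
#' Promoters are drawn as points on the first two singular dimensions of
#' the column-standardized profile matrix; samples as labelled segments
#' from the origin.
#'
#' @param object An `mpra_profiles` object from [profile_summaries()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mpra_profiles
#' @export
autoplot.mpra_profiles <- function(object, ...) {
  pr <- tibble::tibble(dim1 = object$scores[, 1], dim2 = object$scores[, 2])
  sc <- max(abs(pr$dim1), abs(pr$dim2))
  ld <- tibble::tibble(id = rownames(object$loadings),
                       dim1 = object$loadings[, 1] * sc,
                       dim2 = object$loadings[, 2] * sc)
  ggplot2::ggplot() +
    ggplot2::geom_point(data = pr, ggplot2::aes(.data$dim1, .data$dim2),
                        alpha = 0.4, size = 0.8, colour = "grey40") +
    ggplot2::geom_segment(data = ld,
                          ggplot2::aes(x = 0, y = 0, xend = .data$dim1,
                                       yend = .data$dim2),
                          colour = "darkorange", linewidth = 0.7) +
    ggplot2::geom_text(data = ld,
                       ggplot2::aes(.data$dim1, .data$dim2, label = .data$id),
                       vjust = -0.5, size = 3) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2") +
    ggplot2::theme_minimal()
}

#' Per-barcode fold-change strip plot
#'
#' Compares the distribution of barcode fold changes of selected promoters
#' against the remaining (e.g. negative-control) barcodes.
#'
#' @param fc Output of [barcode_fold_changes()] joined with a `group`
#'   column (e.g. motif or promoter label).
#' @return A ggplot object.
#' @export
plot_barcode_fc <- function(fc) {
  stopifnot("group" %in% names(fc))
  d <- fc[!is.na(fc$fold_change), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group,
                                  y = log2(.data$fold_change))) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.4, size = 0.7) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = NA) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "log2 barcode fold change") +
    ggplot2::theme_minimal()
}
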