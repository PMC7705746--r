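# ggplot2 visualisations of the result objects.

#' Plot a divergence-distance distribution with its detected peaks
#'
#' Histogram of the scanned distances at the fit's bin width, with detected
#' peak locations marked — the way 4DTv distributions are usually shown
#' when reading off duplication events.
#'
#' @param object A `peak_fit` from [detect_peaks()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.peak_fit <- function(object, ...) {
  df <- tibble(v = object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$v)) +
    ggplot2::geom_histogram(
      binwidth = object$bin_width, boundary = 0,
      fill = "grey70", colour = "grey35", linewidth = 0.2
    ) +
    ggplot2::geom_vline(
      data = object$peaks,
      ggplot2::aes(xintercept = .data$location),
      colour = "firebrick", linetype = 2
    ) +
    ggplot2::labs(
      x = "distance", y = "gene pairs",
      title = "Divergence distribution",
      subtitle = sprintf("%d pair(s), %d peak(s)",
                         length(object$values), nrow(object$peaks))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a subgenome partition as an identity boxplot
#'
#' One box per chromosome, ordered by median identity and coloured by
#' assigned subgenome — the visual on which A/B assignment of an
#' allopolyploid's chromosomes is classically read.
#'
#' @param object A `subgenome_partition` from [partition_subgenomes()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.subgenome_partition <- function(object, ...) {
  df <- object$profiles |>
    dplyr::mutate(chrom = factor(.data$chrom, levels = .data$chrom)) |>
    dplyr::select("chrom", "subgenome", "identities") |>
    tidyr::unnest_longer("identities", values_to = "identity_pct")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chrom, y = .data$identity_pct,
                                   fill = .data$subgenome)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "best-hit identity (%)", fill = "subgenome") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot an LTR insertion-age distribution
#'
#' @param ages Result tibble of [ltr_insertion_age()] or numeric ages in
#'   MY.
#' @param bin_my Bin width in MY.
#' @return A ggplot of element counts per age bin.
#' @export
plot_ltr_ages <- function(ages, bin_my = 0.5) {
  hist <- ltr_age_distribution(ages, bin_my = bin_my)
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$bin_mid_my, y = .data$count)) +
    ggplot2::geom_col(width = bin_my * 0.92, fill = "steelblue") +
    ggplot2::labs(x = "age of LTRs (MY)", y = "number of elements") +
    ggplot2::theme_minimal()
}
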