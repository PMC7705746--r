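# broom-style verbs for the package's fitted objects.

#' Tidy a peak fit
#'
#' @param x A `peak_fit` from [detect_peaks()].
#' @param ... Unused.
#' @return The peak table: `location`, `height` (fraction of observations
#'   in the peak bin), `bin_mid`, `count`, sorted by height descending.
#' @export
tidy.peak_fit <- function(x, ...) x$peaks

#' Glance at a peak fit
#'
#' @param x A `peak_fit` from [detect_peaks()].
#' @param ... Unused.
#' @return One-row tibble: `n`, `n_peaks`, `bin_width`, `min_fraction`.
#' @export
glance.peak_fit <- function(x, ...) {
  tibble(
    n = length(x$values),
    n_peaks = nrow(x$peaks),
    bin_width = x$bin_width,
    min_fraction = x$min_fraction
  )
}

#' Tidy a subgenome partition
#'
#' @param x A `subgenome_partition` from [partition_subgenomes()].
#' @param ... Unused.
#' @return Per-chromosome assignment: `chrom`, `subgenome`,
#'   `median_identity`, `mean_identity`, `n_genes`.
#' @export
tidy.subgenome_partition <- function(x, ...) x$assignment

#' Glance at a subgenome partition
#'
#' @param x A `subgenome_partition` from [partition_subgenomes()].
#' @param ... Unused.
#' @return One-row tibble: `n_chrom_a`, `n_chrom_b`, `separation` (gap in
#'   identity percent between the lowest A median and the highest B
#'   median).
#' @export
glance.subgenome_partition <- function(x, ...) {
  tibble(
    n_chrom_a = unname(x$sizes[["A"]]),
    n_chrom_b = unname(x$sizes[["B"]]),
    separation = x$separation
  )
}
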