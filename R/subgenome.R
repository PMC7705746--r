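# Partitioning an allopolyploid's chromosomes into A/B subgenomes by
# best-hit identity of their genes against a diploid reference. The group
# with the higher median identity to the reference is labelled A, mirroring
# how identity boxplots are read when one parental lineage is close to a
# sequenced relative.

#' Group per-gene identity values into per-chromosome profiles
#'
#' @param gene_hits Data frame with columns `chrom`, `gene_id`,
#'   `identity_pct` — the percent identity of each gene's best hit against
#'   the reference genome. Identities must lie in `[0, 100]`.
#' @return A nested tibble with one row per chromosome: `chrom`, `n_genes`,
#'   `identities` (list-column of numeric vectors, input order preserved).
#'   Chromosomes with no usable identity value are excluded with a warning.
#' @export
identity_profile <- function(gene_hits) {
  stopifnot(is.data.frame(gene_hits))
  need <- c("chrom", "gene_id", "identity_pct")
  if (!all(need %in% names(gene_hits))) {
    abort(paste0("`gene_hits` needs columns: ", paste(need, collapse = ", ")))
  }
  if (nrow(gene_hits) == 0L) abort("empty identity table")
  bad <- !is.na(gene_hits$identity_pct) &
    (gene_hits$identity_pct < 0 | gene_hits$identity_pct > 100)
  if (any(bad)) {
    abort(sprintf("identity values outside [0, 100] (e.g. %g)",
                  gene_hits$identity_pct[bad][1L]))
  }
  empty_chroms <- gene_hits |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(n = sum(!is.na(.data$identity_pct))) |>
    dplyr::filter(.data$n == 0L)
  if (nrow(empty_chroms) > 0L) {
    warn(paste0("excluding chromosome(s) with no identity values: ",
                paste(empty_chroms$chrom, collapse = ", ")))
  }
  gene_hits |>
    dplyr::filter(!is.na(.data$identity_pct)) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      identities = list(.data$identity_pct),
      .groups = "drop"
    )
}

#' Partition chromosomes into A and B subgenomes
#'
#' @description
#' Ranks chromosomes by the median identity of their genes to the
#' reference and splits the ranking at the largest gap between adjacent
#' medians; the higher-identity group is labelled `A` (the subgenome
#' closer to the reference lineage), the rest `B`. Ranking ties are broken
#' by mean identity and then by chromosome name; the split is deterministic
#' and seed-free. Group sizes are reported, never constrained — an even
#' split is an empirical outcome, not a rule. When all medians are equal no
#' gap exists and an ambiguity error is raised.
#'
#' @param profiles Output of [identity_profile()], or a raw identity table
#'   (columns `chrom`, `gene_id`, `identity_pct`), with at least two
#'   chromosomes.
#' @return A `subgenome_partition` object. [tidy()] gives the
#'   per-chromosome table (`chrom`, `subgenome`, `median_identity`,
#'   `mean_identity`, `n_genes`), [glance()] group sizes and the
#'   `separation` (gap between `min` A median and `max` B median),
#'   [autoplot()] the identity boxplot coloured by subgenome.
#' @examples
#' sim <- simulate_allopolyploid(seed = 1)
#' partition_subgenomes(identity_profile(sim$identities))
#' @export
partition_subgenomes <- function(profiles) {
  if (is.data.frame(profiles) && "identity_pct" %in% names(profiles)) {
    profiles <- identity_profile(profiles)
  }
  stopifnot(is.data.frame(profiles),
            all(c("chrom", "identities") %in% names(profiles)))
  if (nrow(profiles) < 2L) abort("need at least two chromosomes to partition")
  if (!"n_genes" %in% names(profiles)) {
    profiles$n_genes <- lengths(profiles$identities)
  }
  tab <- profiles |>
    dplyr::mutate(
      median_identity = purrr::map_dbl(.data$identities, median),
      mean_identity = purrr::map_dbl(.data$identities, mean)
    ) |>
    dplyr::arrange(dplyr::desc(.data$median_identity),
                   dplyr::desc(.data$mean_identity), .data$chrom)
  meds <- tab$median_identity
  if (max(meds) == min(meds)) {
    abort("all chromosome medians are equal: subgenome partition is ambiguous")
  }
  gaps <- meds[-length(meds)] - meds[-1L]
  cut <- which.max(gaps) # A = ranks 1..cut
  tab$subgenome <- c(rep("A", cut), rep("B", nrow(tab) - cut))
  assignment <- tab |>
    dplyr::select("chrom", "subgenome", "median_identity", "mean_identity",
                  "n_genes") |>
    dplyr::arrange(.data$chrom)
  structure(
    list(
      assignment = assignment,
      separation = meds[cut] - meds[cut + 1L],
      sizes = c(A = cut, B = nrow(tab) - cut),
      profiles = tab
    ),
    class = "subgenome_partition"
  )
}

#' @export
print.subgenome_partition <- function(x, ...) {
  cat(sprintf(
    "<subgenome partition: A = %d chromosome(s), B = %d, separation %.2f%%>\n",
    x$sizes[["A"]], x$sizes[["B"]], x$separation
  ))
  print(x$assignment)
  invisible(x)
}
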