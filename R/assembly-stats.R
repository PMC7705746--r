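# Assembly and annotation summary statistics: Nxx lengths, GC content,
# gap totals, gene densities and between-genome count ratios.

#' Nxx length statistic of a set of sequence lengths
#'
#' Returns the length `L` — always a member of `lengths` — such that
#' sequences of length `>= L` together cover at least `x` percent of the
#' total: sort descending, cumulate, take the first length reaching the
#' threshold (`>=` comparison, so ties are handled deterministically).
#' `nxx_statistic(lengths, 50)` is the usual N50, `x = 90` the N90.
#'
#' @param lengths Vector of positive sequence lengths (bp).
#' @param x Percent threshold in `(0, 100)`.
#' @return The Nxx length in bp.
#' @examples
#' nxx_statistic(c(10, 20, 30, 40), 50) # 30
#' @export
nxx_statistic <- function(lengths, x) {
  if (length(lengths) == 0L) abort("`lengths` must be nonempty")
  stopifnot(is.numeric(lengths), all(lengths > 0))
  if (!is.numeric(x) || length(x) != 1L || x <= 0 || x >= 100) {
    abort("`x` must be a single percent in (0, 100)")
  }
  sorted <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(sorted)
  sorted[which(cum >= x / 100 * sum(sorted))[1L]]
}

#' Assembly summary statistics
#'
#' @description
#' Summarises a set of nucleotide sequences the way genome reports tabulate
#' contig/scaffold statistics: only sequences of at least `min_len_bp`
#' (default 1 kb) are counted; `gap_length_bp` is the total number of `N`
#' residues; `gc_fraction` is `(G + C) / (A + C + G + T)` over the counted
#' sequences, so `N`s and ambiguity codes never enter the GC denominator.
#'
#' @param records Tibble of nucleotide records as returned by
#'   [read_fasta()] (columns `id`, `residues`).
#' @param min_len_bp Minimum sequence length to count, default 1000.
#' @return A one-row tibble with columns `seq_count`, `total_length_bp`,
#'   `n50_bp`, `n90_bp`, `max_bp`, `gc_fraction`, `gap_length_bp`.
#' @examples
#' recs <- tibble::tibble(
#'   id = c("s1", "s2"),
#'   residues = c(strrep("ACGT", 300), "AC")
#' )
#' assembly_summary(recs)
#' @export
assembly_summary <- function(records, min_len_bp = 1000) {
  stopifnot(is.data.frame(records),
            all(c("id", "residues") %in% names(records)))
  lens <- nchar(records$residues)
  keep <- lens >= min_len_bp
  if (!any(keep)) {
    abort(sprintf("no sequence of length >= %d bp", as.integer(min_len_bp)))
  }
  seqs <- Biostrings::DNAStringSet(records$residues[keep])
  counts <- Biostrings::letterFrequency(seqs, letters = c("A", "C", "G", "T", "N"))
  totals <- colSums(counts)
  lens <- lens[keep]
  tibble(
    seq_count = as.integer(sum(keep)),
    total_length_bp = sum(lens),
    n50_bp = nxx_statistic(lens, 50),
    n90_bp = nxx_statistic(lens, 90),
    max_bp = max(lens),
    gc_fraction = unname((totals["G"] + totals["C"]) /
                           sum(totals[c("A", "C", "G", "T")])),
    gap_length_bp = unname(totals["N"])
  )
}

#' Gene density in genes per megabase
#'
#' @param gene_count Number of genes (non-negative integer).
#' @param span_mb Sequence span in megabases, `> 0`.
#' @return Genes per Mb at full precision; round at the reporting layer.
#' @examples
#' gene_density(23985, 252.68) # ~ 95 genes per Mb
#' @export
gene_density <- function(gene_count, span_mb) {
  stopifnot(is.numeric(gene_count), all(gene_count >= 0))
  if (!is.numeric(span_mb) || any(span_mb <= 0)) {
    abort("`span_mb` must be > 0")
  }
  gene_count / span_mb
}

#' Ratio of gene (or feature) counts between two genomes
#'
#' @param count_a,count_b Counts; `count_b` must be positive.
#' @return `count_a / count_b`.
#' @examples
#' genome_count_ratio(57841, 37865) # ~ 1.53
#' @export
genome_count_ratio <- function(count_a, count_b) {
  stopifnot(is.numeric(count_a), is.numeric(count_b))
  if (any(count_b <= 0)) abort("`count_b` must be > 0")
  count_a / count_b
}
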