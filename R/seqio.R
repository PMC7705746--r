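# FASTA / GFF3 ingestion. Sequences travel through the package as plain
# tibbles (id, residues, kind) so every downstream verb is data-frame-first;
# Biostrings does the actual parsing and letter counting.

#' Read a FASTA file into a tibble of sequence records
#'
#' @param path Path to a FASTA file (multi-record, wrapped or unwrapped).
#' @param kind `"auto"` (default) guesses nucleotide vs protein from the
#'   residue alphabet per record; `"nucleotide"` or `"protein"` force the
#'   kind for all records.
#' @return A tibble with columns `id`, `residues` (uppercased), `kind`.
#'   Record order is preserved.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgt"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, kind = c("auto", "nucleotide", "protein")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("malformed FASTA '%s': %s", path,
                                      conditionMessage(e)))
  )
  if (length(set) == 0L) abort(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) abort(sprintf("FASTA '%s' has an empty header", path))
  residues <- unname(toupper(as.character(set)))
  kinds <- if (kind == "auto") {
    vapply(residues, .guess_kind, character(1), USE.NAMES = FALSE)
  } else {
    rep(kind, length(residues))
  }
  tibble(id = ids, residues = residues, kind = kinds)
}

.guess_kind <- function(x) {
  if (!nzchar(x)) return("nucleotide")
  nuc <- nchar(gsub("[^ACGTUN]", "", x))
  if (nuc / nchar(x) >= 0.9) "nucleotide" else "protein"
}

#' Write a tibble of sequence records to FASTA
#'
#' @param records Tibble with columns `id` and `residues`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "residues") %in% names(records)))
  set <- Biostrings::BStringSet(setNames(records$residues, records$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Extracts `type = gene` records and assigns each gene its ordinal rank
#' along its chromosome (1-based, by start coordinate). Ranks, not base-pair
#' coordinates, are what the collinearity chainer consumes, which keeps
#' chaining scale-free. Coordinates are kept 1-based inclusive as in GFF3.
#'
#' @param path Path to a GFF3 file. Each gene record must carry an `ID`
#'   attribute.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `rank`.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_gene_models() requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (length(gr) == 0L) abort(sprintf("no type=gene records in '%s'", path))
  ids <- gr$ID
  if (is.null(ids) || any(is.na(ids))) {
    abort(sprintf("gene record without ID attribute in '%s'", path))
  }
  genes <- tibble(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
  genes |>
    dplyr::group_by(.data$chrom) |>
    dplyr::arrange(.data$start, .data$end, .data$gene_id, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}
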