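# Genetic-code degeneracy. The standard code is taken from
# Biostrings::GENETIC_CODE; everything else (fourfold families, purine /
# pyrimidine classes) is derived from it at load time, never hard-coded.

.codon_cache <- new.env(parent = emptyenv())

.purines <- c("A", "G")
.pyrimidines <- c("C", "T")

#' The standard genetic code as a tibble
#'
#' @description
#' Returns the standard (nuclear) genetic code with, for each of the 64
#' codons, the encoded amino acid (`*` for stop) and whether the codon's
#' third position is fourfold degenerate, i.e. whether all four
#' third-position variants encode the same amino acid. Degeneracy is derived
#' from the code table rather than enumerated by hand; under the standard
#' code exactly 32 codons (8 codon families) are fourfold degenerate.
#'
#' @return A tibble with columns `codon`, `aa`, `fourfold`.
#' @examples
#' genetic_code()
#' sum(genetic_code()$fourfold) # 32
#' @export
genetic_code <- function() {
  if (!is.null(.codon_cache$table)) {
    return(.codon_cache$table)
  }
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  stopifnot(length(codons) == 64L)
  prefix <- substr(codons, 1L, 2L)
  fourfold_prefix <- vapply(
    split(unname(code), prefix),
    function(aas) length(unique(aas)) == 1L && !any(aas == "*"),
    logical(1)
  )
  tab <- tibble(
    codon = codons,
    aa = unname(code),
    fourfold = unname(fourfold_prefix[prefix])
  )
  .codon_cache$table <- tab
  .codon_cache$fourfold_prefix <- names(fourfold_prefix)[fourfold_prefix]
  tab
}

# Character vector of the 2-base prefixes whose codon family is fourfold
# degenerate (8 families under the standard code).
.fourfold_prefixes <- function() {
  if (is.null(.codon_cache$fourfold_prefix)) genetic_code()
  .codon_cache$fourfold_prefix
}

#' Is a codon fourfold degenerate at its third position?
#'
#' A codon is fourfold degenerate (4D) when substituting any nucleotide at
#' its third position leaves the encoded amino acid unchanged. Only such
#' sites are strictly synonymous for any third-position change, which is why
#' transversions measured there (the 4DTv statistic) behave as a near-neutral
#' divergence clock.
#'
#' @param codon Character vector of 3-letter codons over `A`, `C`, `G`, `T`.
#'   Codons containing any other character (ambiguity codes, gaps) are not
#'   scored and return `FALSE`.
#' @return Logical vector, one element per codon.
#' @examples
#' fourfold_codon(c("GGA", "ATG", "CTN"))
#' @export
fourfold_codon <- function(codon) {
  codon <- toupper(codon)
  ok <- nchar(codon) == 3L & !is.na(codon) &
    !grepl("[^ACGT]", codon)
  out <- logical(length(codon))
  out[ok] <- substr(codon[ok], 1L, 2L) %in% .fourfold_prefixes()
  out
}

#' Classify a pair of aligned bases
#'
#' Classifies an aligned base pair as `identity`, `transition`
#' (purine–purine or pyrimidine–pyrimidine change), `transversion`
#' (purine–pyrimidine change), or `unscored` (either base is a gap,
#' ambiguity code or missing).
#'
#' @param base_x,base_y Character vectors of single bases, recycled to a
#'   common length.
#' @return Character vector over
#'   `c("identity", "transition", "transversion", "unscored")`.
#' @examples
#' classify_substitution(c("A", "A", "T", "N"), c("G", "C", "T", "A"))
#' @export
classify_substitution <- function(base_x, base_y) {
  n <- max(length(base_x), length(base_y))
  x <- toupper(rep_len(as.character(base_x), n))
  y <- toupper(rep_len(as.character(base_y), n))
  valid <- x %in% c(.purines, .pyrimidines) & y %in% c(.purines, .pyrimidines)
  out <- rep("unscored", n)
  same <- valid & x == y
  out[same] <- "identity"
  xp <- x %in% .purines
  yp <- y %in% .purines
  out[valid & !same & (xp == yp)] <- "transition"
  out[valid & !same & (xp != yp)] <- "transversion"
  out
}
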