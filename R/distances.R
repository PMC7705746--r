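# 4DTv and Kimura two-parameter distances on aligned sequence pairs.
#
# Input convention for the table-level verbs: a data frame with one aligned
# pair per row, columns `pair_id`, `aligned_a`, `aligned_b` (gap character
# "-"). All engines are symmetric in the two sequences.

.split_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

# Validate an in-frame codon pair alignment: equal lengths, length a
# multiple of 3, and gaps covering whole codons only (frame integrity).
.check_codon_pair <- function(a, b, pair_id = "<pair>") {
  if (nchar(a) != nchar(b)) {
    abort(sprintf("pair '%s': aligned sequences differ in length", pair_id))
  }
  if (nchar(a) %% 3L != 0L) {
    abort(sprintf("pair '%s': alignment length not a multiple of 3", pair_id))
  }
  for (s in list(a, b)) {
    cod <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    ngap <- nchar(gsub("[^-]", "", cod))
    if (any(ngap != 0L & ngap != 3L)) {
      abort(sprintf(
        "pair '%s': gaps must cover whole codons (frame broken)", pair_id
      ))
    }
  }
  invisible(TRUE)
}

# Single-pair 4DTv engine. A column is a comparable fourfold-degenerate
# site iff both codons are gap-free and unambiguous, the two codons share
# their first two positions, and that shared 2-base prefix heads a fourfold
# codon family.
.four_dtv_one <- function(a, b) {
  ca <- .split_chars(a)
  cb <- .split_chars(b)
  n_codon <- length(ca) %/% 3L
  i1 <- seq(1L, by = 3L, length.out = n_codon)
  acgt <- c("A", "C", "G", "T")
  clean <- ca[i1] %in% acgt & ca[i1 + 1L] %in% acgt & ca[i1 + 2L] %in% acgt &
    cb[i1] %in% acgt & cb[i1 + 1L] %in% acgt & cb[i1 + 2L] %in% acgt
  same12 <- ca[i1] == cb[i1] & ca[i1 + 1L] == cb[i1 + 1L]
  prefix <- paste0(ca[i1], ca[i1 + 1L])
  usable <- clean & same12 & prefix %in% .fourfold_prefixes()
  cls <- classify_substitution(ca[i1 + 2L][usable], cb[i1 + 2L][usable])
  sites <- sum(usable)
  tv <- sum(cls == "transversion")
  list(
    sites_4d = sites,
    transversions = tv,
    v = if (sites > 0L) tv / sites else NA_real_
  )
}

#' 4DTv distance of aligned coding-sequence pairs
#'
#' @description
#' Computes, for each aligned coding-sequence pair, the transversion rate at
#' fourfold-degenerate third codon positions (the 4DTv distance). A column
#' contributes a comparable 4D site only when both codons are gap-free and
#' unambiguous, the first two codon positions are identical in the two
#' sequences, and that codon family is fourfold degenerate — a conservative
#' rule that guarantees any third-position change is synonymous in both
#' sequences. `v` is the fraction of those sites carrying a transversion.
#'
#' Pairs with no comparable 4D site are retained with `sites_4d = 0` and
#' `v = NA`. With `correct = TRUE` a multiple-hit correction of `v`
#' (transversion-only distance under observed third-position base
#' composition, see [hky_correct_4dtv()]) is added as `corrected_v`; the
#' default output is the raw proportion.
#'
#' @param pairs Data frame with columns `pair_id`, `aligned_a`, `aligned_b`
#'   (equal-length in-frame alignments, gap character `-`, gaps covering
#'   whole codons).
#' @param correct Add a `corrected_v` column? Default `FALSE`.
#' @return A tibble with columns `pair_id`, `sites_4d`, `transversions`,
#'   `v` (and `corrected_v` if requested).
#' @examples
#' four_dtv(tibble::tibble(
#'   pair_id = "p1", aligned_a = "GGTCCA", aligned_b = "GGGCCA"
#' ))
#' @seealso [kimura_distance()], [detect_peaks()]
#' @export
four_dtv <- function(pairs, correct = FALSE) {
  pairs <- .as_pair_table(pairs)
  res <- purrr::pmap(
    list(pairs$pair_id, pairs$aligned_a, pairs$aligned_b),
    function(id, a, b) {
      .check_codon_pair(a, b, id)
      .four_dtv_one(a, b)
    }
  )
  out <- tibble(
    pair_id = pairs$pair_id,
    sites_4d = purrr::map_int(res, ~ as.integer(.x$sites_4d)),
    transversions = purrr::map_int(res, ~ as.integer(.x$transversions)),
    v = purrr::map_dbl(res, "v")
  )
  if (correct) {
    freqs <- purrr::map2(
      pairs$aligned_a, pairs$aligned_b, .third_position_freqs
    )
    out$corrected_v <- purrr::map2_dbl(out$v, freqs, function(v, f) {
      if (is.na(v)) return(NA_real_)
      tryCatch(hky_correct_4dtv(v, f), error = function(e) NA_real_)
    })
  }
  out
}

# Pooled base composition at comparable third positions of one pair;
# falls back to uniform when too few sites.
.third_position_freqs <- function(a, b) {
  ca <- .split_chars(a)
  cb <- .split_chars(b)
  i3 <- seq(3L, length(ca), by = 3L)
  bases <- c(ca[i3], cb[i3])
  bases <- bases[bases %in% c("A", "C", "G", "T")]
  if (length(bases) < 8L) {
    return(c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  }
  tab <- table(factor(bases, levels = c("A", "C", "G", "T")))
  setNames(as.vector(tab) / sum(tab), c("A", "C", "G", "T"))
}

#' Multiple-hit correction of a 4DTv distance
#'
#' Corrects an observed transversion proportion `v` for multiple
#' substitutions using the transversion-only distance with arbitrary
#' purine/pyrimidine composition:
#' \deqn{v' = -2\pi_R\pi_Y \log(1 - v / (2\pi_R\pi_Y))}
#' where \eqn{\pi_R, \pi_Y} are the purine and pyrimidine frequencies. With
#' equal base frequencies this reduces to \eqn{-\tfrac12\log(1-2v)}, whose
#' series expansion equals `v` to first order, so small distances are barely
#' changed. Raw (uncorrected) `v` remains the default everywhere; the
#' correction is an explicit opt-in.
#'
#' @param v Observed transversion proportion(s) at 4D sites, in `[0, 1)`.
#' @param base_freq Named numeric vector of `A`, `C`, `G`, `T` frequencies
#'   (normalised internally). Default uniform.
#' @return Corrected distance(s); errors when `v` is at or beyond the
#'   saturation boundary \eqn{2\pi_R\pi_Y}.
#' @examples
#' hky_correct_4dtv(0.05)
#' @export
hky_correct_4dtv <- function(v,
                             base_freq = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(is.numeric(v), all(!is.na(v)), all(v >= 0))
  f <- base_freq[c("A", "C", "G", "T")]
  if (any(is.na(f))) abort("base_freq must name A, C, G and T")
  f <- f / sum(f)
  pr <- f[["A"]] + f[["G"]]
  py <- f[["C"]] + f[["T"]]
  cap <- 2 * pr * py
  if (any(1 - v / cap <= 0)) {
    abort(sprintf(
      "transversion proportion at/beyond saturation boundary (%.3f)", cap
    ))
  }
  -cap * log(1 - v / cap)
}

# Shared P/Q counting over comparable (both unambiguous A/C/G/T) columns.
.k2p_counts <- function(a, b) {
  cls <- classify_substitution(.split_chars(a), .split_chars(b))
  sites <- sum(cls != "unscored")
  list(
    sites = sites,
    P = if (sites > 0L) sum(cls == "transition") / sites else NA_real_,
    Q = if (sites > 0L) sum(cls == "transversion") / sites else NA_real_
  )
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' @description
#' Computes the transition proportion `P`, transversion proportion `Q` and
#' the Kimura two-parameter distance
#' \deqn{d = -\tfrac12 \log\big((1 - 2P - Q)\sqrt{1 - 2Q}\big)}
#' over the comparable columns (both bases unambiguous `A`/`C`/`G`/`T`) of
#' one aligned pair. Saturated pairs — where `1 - 2P - Q` or `1 - 2Q` is not
#' positive, so the log-correction is undefined — raise an error.
#'
#' @param seq_a,seq_b Aligned sequences of equal length (gap character `-`).
#' @return A one-row tibble with columns `sites`, `P`, `Q`, `d`.
#' @examples
#' k2p_distance("ACGTACGTAC", "ACGTACGTAT")
#' @seealso [kimura_distance()] for the table-level verb.
#' @export
k2p_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) {
    abort("aligned sequences differ in length")
  }
  cnt <- .k2p_counts(seq_a, seq_b)
  if (cnt$sites < 1L) abort("no comparable sites")
  w1 <- 1 - 2 * cnt$P - cnt$Q
  w2 <- 1 - 2 * cnt$Q
  if (w1 <= 0 || w2 <= 0) {
    abort("substitution saturation: Kimura distance incalculable")
  }
  tibble(
    sites = as.integer(cnt$sites),
    P = cnt$P, Q = cnt$Q,
    d = -0.5 * log(w1 * sqrt(w2))
  )
}

#' Kimura two-parameter distances for a table of aligned pairs
#'
#' Table-level companion of [k2p_distance()]: one aligned pair per row,
#' one result row per pair. Saturated pairs are retained with `d = NA` and
#' `saturated = TRUE` rather than dropped, so downstream reports can audit
#' them.
#'
#' @param pairs Data frame with columns `pair_id`, `aligned_a`, `aligned_b`.
#' @return A tibble with columns `pair_id`, `sites`, `P`, `Q`, `d`,
#'   `saturated`.
#' @export
kimura_distance <- function(pairs) {
  pairs <- .as_pair_table(pairs)
  res <- purrr::pmap(
    list(pairs$pair_id, pairs$aligned_a, pairs$aligned_b),
    function(id, a, b) {
      if (nchar(a) != nchar(b)) {
        abort(sprintf("pair '%s': aligned sequences differ in length", id))
      }
      cnt <- .k2p_counts(a, b)
      if (cnt$sites < 1L) {
        return(list(sites = 0L, P = NA_real_, Q = NA_real_,
                    d = NA_real_, saturated = FALSE))
      }
      w1 <- 1 - 2 * cnt$P - cnt$Q
      w2 <- 1 - 2 * cnt$Q
      if (w1 <= 0 || w2 <= 0) {
        return(list(sites = cnt$sites, P = cnt$P, Q = cnt$Q,
                    d = NA_real_, saturated = TRUE))
      }
      list(sites = cnt$sites, P = cnt$P, Q = cnt$Q,
           d = -0.5 * log(w1 * sqrt(w2)), saturated = FALSE)
    }
  )
  tibble(
    pair_id = pairs$pair_id,
    sites = purrr::map_int(res, ~ as.integer(.x$sites)),
    P = purrr::map_dbl(res, "P"),
    Q = purrr::map_dbl(res, "Q"),
    d = purrr::map_dbl(res, "d"),
    saturated = purrr::map_lgl(res, "saturated")
  )
}

.as_pair_table <- function(pairs) {
  if (!is.data.frame(pairs)) {
    abort("`pairs` must be a data frame of aligned sequence pairs")
  }
  need <- c("pair_id", "aligned_a", "aligned_b")
  missing <- setdiff(need, names(pairs))
  if (length(missing)) {
    abort(paste0("`pairs` lacks column(s): ", paste(missing, collapse = ", ")))
  }
  as_tibble(pairs[need])
}
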