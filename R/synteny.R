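# Which gene pairs enter the divergence distribution: candidate protein
# pairs found by shared k-mer screening, scored by BLOSUM62 local alignment,
# filtered on the C-score (score normalised by the best score involving
# either gene), and chained into collinear blocks by dynamic programming
# over gene ranks.

#' Score candidate homologous protein pairs between two proteomes
#'
#' @description
#' Finds candidate pairs by exact shared k-mer screening (default `k = 5`)
#' and scores every candidate with a Smith–Waterman local alignment under
#' BLOSUM62 and affine gap penalties. Each retained hit carries its
#' C-score: the hit score divided by the best score involving either of its
#' two genes, so a reciprocal best pair has `c_score = 1`. Hits scoring
#' below `min_score` are dropped after C-score computation; duplicated genes
#' yield one hit per copy.
#'
#' @param proteome_a,proteome_b Tibbles of protein records (columns `id`,
#'   `residues`), e.g. from [read_fasta()].
#' @param min_score Minimum local-alignment score to keep a hit. The raw
#'   score threshold plays the role a database-size-dependent E-value cutoff
#'   plays in search engines; the C-score filter is the discriminating step.
#' @param k Word size of the shared k-mer screen.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return A tibble with columns `gene_a`, `gene_b`, `score`, `c_score`,
#'   sorted by decreasing score.
#' @seealso [c_score_filter()], [chain_anchors()]
#' @export
score_protein_pairs <- function(proteome_a, proteome_b, min_score = 100,
                                k = 5, gap_opening = 11, gap_extension = 1) {
  for (p in list(proteome_a, proteome_b)) {
    if (!is.data.frame(p) || nrow(p) == 0L ||
        !all(c("id", "residues") %in% names(p))) {
      abort("proteomes must be nonempty tibbles with columns id, residues")
    }
  }
  kmers <- function(x) {
    if (nchar(x) < k) return(character(0))
    unique(substring(x, 1:(nchar(x) - k + 1L), k:nchar(x)))
  }
  km_b <- lapply(proteome_b$residues, kmers)
  index_b <- split(
    rep(seq_len(nrow(proteome_b)), lengths(km_b)),
    unlist(km_b)
  )
  subj_b <- Biostrings::AAStringSet(setNames(proteome_b$residues,
                                             proteome_b$id))
  hits <- purrr::map(seq_len(nrow(proteome_a)), function(i) {
    cand <- unique(unlist(index_b[kmers(proteome_a$residues[i])],
                          use.names = FALSE))
    if (is.null(cand) || length(cand) == 0L) return(NULL)
    cand <- sort(cand)
    scores <- Biostrings::pairwiseAlignment(
      pattern = subj_b[cand],
      subject = Biostrings::AAString(proteome_a$residues[i]),
      type = "local",
      substitutionMatrix = "BLOSUM62",
      gapOpening = gap_opening,
      gapExtension = gap_extension,
      scoreOnly = TRUE
    )
    tibble(
      gene_a = proteome_a$id[i],
      gene_b = proteome_b$id[cand],
      score = as.numeric(scores)
    )
  })
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0L) {
    return(tibble(gene_a = character(), gene_b = character(),
                  score = numeric(), c_score = numeric()))
  }
  hits <- hits[hits$score > 0, , drop = FALSE]
  hits <- add_c_scores(hits)
  hits <- hits[hits$score >= min_score, , drop = FALSE]
  dplyr::arrange(hits, dplyr::desc(.data$score), .data$gene_a, .data$gene_b)
}

#' Attach C-scores to a scored hit table
#'
#' `c_score = score / max(best score of gene_a, best score of gene_b)`,
#' bests taken over the whole table.
#'
#' @param hits Tibble with columns `gene_a`, `gene_b`, `score`.
#' @return `hits` with a `c_score` column (replaced if already present).
#' @export
add_c_scores <- function(hits) {
  stopifnot(all(c("gene_a", "gene_b", "score") %in% names(hits)))
  best_a <- tapply(hits$score, hits$gene_a, max)
  best_b <- tapply(hits$score, hits$gene_b, max)
  hits$c_score <- as.vector(hits$score /
    pmax(best_a[hits$gene_a], best_b[hits$gene_b]))
  as_tibble(hits)
}

#' Filter anchor hits on the C-score
#'
#' Keeps hits whose C-score strictly exceeds `threshold` (default 0.5,
#' the conventional cutoff for anchor candidates). Idempotent; an empty
#' table passes through.
#'
#' @param hits Tibble with a `c_score` column (see [add_c_scores()]).
#' @param threshold Keep hits with `c_score > threshold`.
#' @return The filtered tibble.
#' @export
c_score_filter <- function(hits, threshold = 0.5) {
  stopifnot("c_score" %in% names(hits))
  hits[hits$c_score > threshold, , drop = FALSE]
}

#' Join chromosome and rank information onto anchor hits
#'
#' @param hits Tibble with columns `gene_a`, `gene_b` (and optionally
#'   `score`).
#' @param genes_a,genes_b Gene-model tibbles (from [read_gene_models()] or
#'   the simulator) with columns `gene_id`, `chrom`, `rank`.
#' @return `hits` with columns `chrom_a`, `rank_a`, `chrom_b`, `rank_b`
#'   added; hits whose genes lack a model are dropped.
#' @export
add_gene_ranks <- function(hits, genes_a, genes_b) {
  ga <- dplyr::select(genes_a, gene_a = "gene_id", chrom_a = "chrom",
                      rank_a = "rank")
  gb <- dplyr::select(genes_b, gene_b = "gene_id", chrom_b = "chrom",
                      rank_b = "rank")
  hits |>
    dplyr::inner_join(ga, by = "gene_a") |>
    dplyr::inner_join(gb, by = "gene_b")
}

# Best monotone chain under the gap constraint, by quadratic DP.
# Chains maximise anchor count; ties broken by total anchor score, then by
# earliest end index, so extraction is deterministic.
.best_chain <- function(ra, rb, sc, max_gap) {
  n <- length(ra)
  ord <- order(ra, rb)
  ra <- ra[ord]; rb <- rb[ord]; sc <- sc[ord]
  best <- list(size = 0L, score = -Inf, idx = integer(0),
               orientation = NA_character_)
  for (orientation in c("parallel", "antiparallel")) {
    size <- rep(1L, n); total <- sc; prev <- rep(0L, n)
    for (i in seq_len(n)) {
      js <- which(ra < ra[i] & ra >= ra[i] - max_gap)
      if (orientation == "parallel") {
        js <- js[rb[js] < rb[i] & rb[js] >= rb[i] - max_gap]
      } else {
        js <- js[rb[js] > rb[i] & rb[js] <= rb[i] + max_gap]
      }
      for (j in js) {
        cand_size <- size[j] + 1L
        cand_total <- total[j] + sc[i]
        if (cand_size > size[i] ||
            (cand_size == size[i] && cand_total > total[i])) {
          size[i] <- cand_size; total[i] <- cand_total; prev[i] <- j
        }
      }
    }
    if (n > 0L) {
      end <- which(size == max(size))
      end <- end[which.max(total[end])]
      if (size[end] > best$size ||
          (size[end] == best$size && total[end] > best$score)) {
        chain <- integer(0); i <- end
        while (i != 0L) { chain <- c(i, chain); i <- prev[i] }
        best <- list(size = size[end], score = total[end],
                     idx = ord[chain], orientation = orientation)
      }
    }
  }
  best
}

#' Chain anchors into collinear blocks
#'
#' @description
#' Runs dynamic programming over anchors sorted by gene rank to find
#' maximal chains in which both ranks advance monotonically — `rank_b`
#' increasing for parallel blocks, decreasing for antiparallel (inverted)
#' blocks — with consecutive rank gaps of at most `max_gap` on both
#' chromosomes. Blocks are extracted greedily in order of decreasing chain
#' size (ties by total anchor score), each anchor assigned to at most one
#' block; chains smaller than `min_block` are discarded. Gaps are measured
#' in gene-rank units, not base pairs, so the procedure is scale-free.
#'
#' @param anchors Tibble with columns `rank_a`, `rank_b` and optionally
#'   `gene_a`, `gene_b`, `chrom_a`, `chrom_b`, `score` (see
#'   [add_gene_ranks()]). Chromosome pairs are chained independently.
#' @param max_gap Maximum rank gap between consecutive anchors of a chain.
#' @param min_block Minimum anchors per reported block.
#' @return A tibble with one row per block: `block_id`, `chrom_a`,
#'   `chrom_b`, `orientation` (`parallel`/`antiparallel`), `size`, and a
#'   list-column `anchors` holding that block's anchor rows.
#' @examples
#' chain_anchors(tibble::tibble(rank_a = 1:6, rank_b = 1:6), min_block = 5)
#' @export
chain_anchors <- function(anchors, max_gap = 25, min_block = 5) {
  stopifnot(is.data.frame(anchors),
            all(c("rank_a", "rank_b") %in% names(anchors)))
  anchors <- as_tibble(anchors)
  if (!"chrom_a" %in% names(anchors)) anchors$chrom_a <- "chrA"
  if (!"chrom_b" %in% names(anchors)) anchors$chrom_b <- "chrB"
  if (!"score" %in% names(anchors)) anchors$score <- 1
  if (!"gene_a" %in% names(anchors)) {
    anchors$gene_a <- paste0(anchors$chrom_a, ":", anchors$rank_a)
  }
  if (!"gene_b" %in% names(anchors)) {
    anchors$gene_b <- paste0(anchors$chrom_b, ":", anchors$rank_b)
  }
  empty <- tibble(
    block_id = character(), chrom_a = character(), chrom_b = character(),
    orientation = character(), size = integer(), anchors = list()
  )
  if (nrow(anchors) == 0L) return(empty)
  groups <- split(anchors, paste(anchors$chrom_a, anchors$chrom_b, sep = "\r"))
  blocks <- purrr::map(groups[order(names(groups))], function(g) {
    out <- list()
    while (nrow(g) >= min_block) {
      ch <- .best_chain(g$rank_a, g$rank_b, g$score, max_gap)
      if (ch$size < min_block) break
      out[[length(out) + 1L]] <- tibble(
        chrom_a = g$chrom_a[1L], chrom_b = g$chrom_b[1L],
        orientation = ch$orientation, size = as.integer(ch$size),
        anchors = list(g[sort(ch$idx), , drop = FALSE])
      )
      g <- g[-ch$idx, , drop = FALSE]
    }
    dplyr::bind_rows(out)
  })
  blocks <- dplyr::bind_rows(blocks)
  if (nrow(blocks) == 0L) return(empty)
  blocks <- dplyr::arrange(blocks, dplyr::desc(.data$size),
                           .data$chrom_a, .data$chrom_b)
  blocks$block_id <- sprintf("block_%03d", seq_len(nrow(blocks)))
  dplyr::select(blocks, "block_id", "chrom_a", "chrom_b", "orientation",
                "size", "anchors")
}

#' Flatten collinear blocks into the gene pairs they contain
#'
#' @param blocks Block tibble from [chain_anchors()].
#' @return A deduplicated tibble with columns `gene_a`, `gene_b`.
#' @export
blocks_to_pairs <- function(blocks) {
  if (!is.data.frame(blocks) || nrow(blocks) == 0L) {
    return(tibble(gene_a = character(), gene_b = character()))
  }
  blocks |>
    dplyr::select("anchors") |>
    tidyr::unnest("anchors") |>
    dplyr::distinct(.data$gene_a, .data$gene_b)
}
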