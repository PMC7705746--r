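# Sequence-evolution simulators with planted truth. Each generator draws
# data with the statistical structure the corresponding estimator assumes —
# two-rate substitution at planted divergence times, LTR copies diverging
# since insertion, subgenomes at distinct identity levels, planted collinear
# blocks, scaffold sets with planted gap runs — and returns the truth table
# alongside, so parameter recovery can be tested end to end.
#
# All generators are bit-reproducible given `seed`. A single run seed can be
# expanded into independent per-component seeds with derive_seed().

.DNA <- c("A", "C", "G", "T")
.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Derive a component sub-seed from a run seed
#'
#' Expands one global seed into per-component seeds by a fixed integer
#' mixing step, so components are reproducible independently without
#' sharing an RNG stream. Results stay below `2^31`.
#'
#' @param seed Integer run seed.
#' @param offset Small non-negative integer identifying the component.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, offset = 0) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(offset), length(offset) == 1L, offset >= 0)
  as.integer((abs(seed) + offset * 1013904223) %% 2147483629) + 1L
}

.local_seed <- function(seed, env = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(as.integer(seed), .local_envir = env)
}

# One branch of the two-rate (Kimura) substitution process, site-wise exact:
# transition rate alpha to the partner purine/pyrimidine, rate beta to each
# of the two transversion targets. `code` is the sequence as integers 1..4
# (A,C,G,T); `scale` is a per-site rate multiplier.
.evolve_branch <- function(code, time_years, alpha, beta, scale = 1) {
  n <- length(code)
  scale <- rep_len(scale, n)
  e4 <- exp(-4 * beta * time_years * scale)
  e2 <- exp(-2 * (alpha + beta) * time_years * scale)
  p_same <- 0.25 + 0.25 * e4 + 0.5 * e2
  p_ts <- 0.25 + 0.25 * e4 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e4 # each of two targets
  u <- stats::runif(n)
  partner <- c(3L, 4L, 1L, 2L) # A<->G, C<->T
  tv1 <- c(2L, 1L, 2L, 1L) # first transversion target
  tv2 <- c(4L, 3L, 4L, 3L)
  out <- code
  is_ts <- u >= p_same & u < p_same + p_ts
  is_tv1 <- u >= p_same + p_ts & u < p_same + p_ts + p_tv
  is_tv2 <- u >= p_same + p_ts + p_tv
  out[is_ts] <- partner[code[is_ts]]
  out[is_tv1] <- tv1[code[is_tv1]]
  out[is_tv2] <- tv2[code[is_tv2]]
  out
}

.seq_to_code <- function(x) {
  code <- match(.split_chars(x), .DNA)
  if (any(is.na(code))) abort("sequence must be over A/C/G/T")
  code
}

.code_to_seq <- function(code) paste(.DNA[code], collapse = "")

#' Evolve an ancestral sequence into a diverged pair
#'
#' Produces two independent descendants of `ancestor` by running a
#' continuous-time two-rate substitution process — transition rate `alpha`
#' per site per year, rate `beta` to each of the two transversion targets —
#' for `time_years` along each branch, using the exact site-wise transition
#' probabilities of the process. The expected Kimura distance between the
#' descendants is `2 * time_years * (alpha + 2 * beta)`.
#'
#' @param ancestor Nucleotide string over `A`/`C`/`G`/`T`.
#' @param time_years Branch length in years (each descendant evolves this
#'   long).
#' @param alpha Transition rate, substitutions/site/year.
#' @param beta Rate to each transversion target, substitutions/site/year.
#' @param seed Optional integer seed for reproducibility.
#' @param rate_scale Optional per-site rate multiplier (recycled), e.g. to
#'   slow evolution at constrained codon positions.
#' @return Character vector of the two descendant sequences.
#' @examples
#' evolve_sequence_pair(strrep("ACGT", 10), 0, 1e-9, 5e-10, seed = 1)
#' @export
evolve_sequence_pair <- function(ancestor, time_years, alpha, beta,
                                 seed = NULL, rate_scale = 1) {
  stopifnot(time_years >= 0, alpha >= 0, beta >= 0)
  code <- .seq_to_code(ancestor)
  .local_seed(seed)
  c(
    .code_to_seq(.evolve_branch(code, time_years, alpha, beta, rate_scale)),
    .code_to_seq(.evolve_branch(code, time_years, alpha, beta, rate_scale))
  )
}

# Ancestral coding sequence: codons drawn uniformly from the 61 sense
# codons, so the frame is valid and no internal stops are planted.
.sample_cds <- function(n_codons) {
  sense <- genetic_code()$codon[genetic_code()$aa != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

#' Simulate coding-sequence pairs from planted divergence cohorts
#'
#' @description
#' Emulates the paralog structure behind a 4DTv distribution: gene pairs
#' fall into divergence cohorts (duplication events), every pair of a
#' cohort separating at the same planted time. Cohorts may be given as
#' expected 4DTv values — inverted internally to times through the
#' transversion saturation curve `q = (1 - exp(-8 * beta * t)) / 2` — or as
#' times in years. Codon third positions evolve at the full rates;
#' positions 1–2 are slowed by `pos12_scale`, emulating purifying selection
#' on nonsynonymous sites (without which deep cohorts would retain almost
#' no comparable 4D sites, as in real proteins they do).
#'
#' @param n_pairs Total number of pairs.
#' @param seq_len Alignment length in nucleotides (multiple of 3).
#' @param expected_4dtv Planted cohort locations on the 4DTv scale; the
#'   default `c(0.01, 0.08, 0.48)` mirrors the three divergence cohorts
#'   typically visible in a Salicaceae-style paralog distribution.
#' @param weights Cohort mixture weights (recycled, normalised).
#' @param times Optional cohort times in years, overriding
#'   `expected_4dtv`.
#' @param alpha,beta Substitution rates per site per year (transition; each
#'   transversion target). Defaults follow a synonymous rate of
#'   `alpha + 2 * beta = 0.88e-9`/site/year with transition bias
#'   `kappa = 2`.
#' @param pos12_scale Rate multiplier at codon positions 1–2.
#' @param seed Optional integer seed.
#' @return A list: `pairs` (tibble `pair_id`, `aligned_a`, `aligned_b`) and
#'   `truth` (tibble `pair_id`, `cohort`, `time_years`, `expected_v`).
#' @examples
#' sim <- simulate_wgd_pairs(n_pairs = 4, seq_len = 300, seed = 1)
#' four_dtv(sim$pairs)
#' @export
simulate_wgd_pairs <- function(n_pairs = 600, seq_len = 3000,
                               expected_4dtv = c(0.01, 0.08, 0.48),
                               weights = NULL, times = NULL,
                               alpha = 0.44e-9, beta = 0.22e-9,
                               pos12_scale = 0.2, seed = NULL) {
  stopifnot(n_pairs >= 0, seq_len %% 3 == 0, seq_len > 0)
  if (is.null(times)) {
    stopifnot(all(expected_4dtv >= 0), all(expected_4dtv < 0.5))
    times <- -log(1 - 2 * expected_4dtv) / (8 * beta)
  } else {
    expected_4dtv <- (1 - exp(-8 * beta * times)) / 2
  }
  k <- length(times)
  weights <- if (is.null(weights)) rep(1, k) else rep_len(weights, k)
  weights <- weights / sum(weights)
  empty <- list(
    pairs = tibble(pair_id = character(), aligned_a = character(),
                   aligned_b = character()),
    truth = tibble(pair_id = character(), cohort = integer(),
                   time_years = numeric(), expected_v = numeric())
  )
  if (n_pairs == 0L) return(empty)
  .local_seed(seed)
  cohort <- sample.int(k, n_pairs, replace = TRUE, prob = weights)
  scale <- rep(c(pos12_scale, pos12_scale, 1), seq_len %/% 3L)
  descendants <- purrr::map(cohort, function(co) {
    anc <- .sample_cds(seq_len %/% 3L)
    evolve_sequence_pair(anc, times[co], alpha, beta, rate_scale = scale)
  })
  ids <- sprintf("pair_%05d", seq_len(n_pairs))
  list(
    pairs = tibble(
      pair_id = ids,
      aligned_a = purrr::map_chr(descendants, 1L),
      aligned_b = purrr::map_chr(descendants, 2L)
    ),
    truth = tibble(
      pair_id = ids,
      cohort = cohort,
      time_years = times[cohort],
      expected_v = expected_4dtv[cohort]
    )
  )
}

#' Simulate LTR retrotransposon pairs at planted insertion ages
#'
#' Each element's two LTRs descend from one ancestral LTR sequence and
#' diverge for the planted age along both copies under the two-rate
#' process, calibrated so that the total substitution rate per copy equals
#' `clock_rate` — the same clock the estimator assumes.
#'
#' @param ages_my Planted insertion ages in MY (recycled over elements).
#' @param clock_rate Substitutions/site/year per LTR copy, default
#'   `7.3e-9`.
#' @param n_per_age Elements per planted age.
#' @param ltr_len LTR length in bp.
#' @param kappa Transition/transversion rate ratio `alpha / beta`.
#' @param seed Optional integer seed.
#' @return A list: `pairs` (tibble `element_id`, `ltr5_seq`, `ltr3_seq`)
#'   and `truth` (tibble `element_id`, `age_my`).
#' @examples
#' sim <- simulate_ltr_elements(ages_my = 4, n_per_age = 2, ltr_len = 200,
#'                              seed = 1)
#' ltr_insertion_age(sim$pairs)
#' @export
simulate_ltr_elements <- function(ages_my = c(1, 4, 6), clock_rate = 7.3e-9,
                                  n_per_age = 100, ltr_len = 600, kappa = 2,
                                  seed = NULL) {
  stopifnot(all(ages_my >= 0), clock_rate > 0, n_per_age >= 1, ltr_len >= 1)
  beta <- clock_rate / (kappa + 2)
  alpha <- kappa * beta
  .local_seed(seed)
  ages <- rep(ages_my, each = n_per_age)
  pairs <- purrr::map(ages, function(age) {
    anc <- paste(sample(.DNA, ltr_len, replace = TRUE), collapse = "")
    evolve_sequence_pair(anc, age * 1e6, alpha, beta)
  })
  ids <- sprintf("ltr_%05d", seq_along(ages))
  list(
    pairs = tibble(
      element_id = ids,
      ltr5_seq = purrr::map_chr(pairs, 1L),
      ltr3_seq = purrr::map_chr(pairs, 2L)
    ),
    truth = tibble(element_id = ids, age_my = ages)
  )
}

#' Simulate an allopolyploid identity table with planted subgenome labels
#'
#' Draws per-gene best-hit identities for two chromosome sets around
#' distinct identity levels versus a reference — the input structure the
#' subgenome partitioner assumes. Chromosome names carry no label
#' information; the planted assignment is returned separately.
#'
#' @param ident_a,ident_b Mean identity (percent) of the two subgenomes to
#'   the reference; defaults 92 and 85.
#' @param sd_within Within-chromosome standard deviation of gene
#'   identities (percent).
#' @param n_chrom_per_subgenome Chromosomes per subgenome (default 19, a
#'   Salicaceae-style karyotype).
#' @param genes_per_chrom Genes per chromosome.
#' @param seed Optional integer seed.
#' @return A list: `identities` (tibble `chrom`, `gene_id`,
#'   `identity_pct`), `truth` (tibble `chrom`, `subgenome`), and
#'   `separable` (`FALSE` when `ident_a == ident_b`, in which case no
#'   partition can recover the labels).
#' @export
simulate_allopolyploid <- function(ident_a = 92, ident_b = 85, sd_within = 1,
                                   n_chrom_per_subgenome = 19,
                                   genes_per_chrom = 50, seed = NULL) {
  stopifnot(ident_a >= 0, ident_a < 100, ident_b >= 0, ident_b < 100,
            n_chrom_per_subgenome >= 1, genes_per_chrom >= 1)
  .local_seed(seed)
  n_chrom <- 2L * n_chrom_per_subgenome
  chroms <- sprintf("chr%02d", seq_len(n_chrom))
  labels <- sample(rep(c("A", "B"), each = n_chrom_per_subgenome))
  means <- ifelse(labels == "A", ident_a, ident_b)
  identities <- purrr::map2(chroms, means, function(ch, mu) {
    tibble(
      chrom = ch,
      gene_id = sprintf("%s_g%03d", ch, seq_len(genes_per_chrom)),
      identity_pct = pmin(100, pmax(0, stats::rnorm(genes_per_chrom, mu,
                                                    sd_within)))
    )
  })
  if (ident_a == ident_b) {
    warn("ident_a == ident_b: generated set is not separable")
  }
  list(
    identities = dplyr::bind_rows(identities),
    truth = tibble(chrom = chroms, subgenome = labels),
    separable = ident_a != ident_b
  )
}

.sample_protein <- function(len) {
  paste(sample(.AA20, len, replace = TRUE), collapse = "")
}

.mutate_protein <- function(x, divergence) {
  chars <- .split_chars(x)
  hit <- stats::runif(length(chars)) < divergence
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(a) {
      sample(setdiff(.AA20, a), 1L)
    }, character(1))
  }
  paste(chars, collapse = "")
}

#' Simulate a genome pair with planted duplicated (collinear) blocks
#'
#' @description
#' Builds two proteomes with gene models in which genome B carries, per
#' chromosome, one parallel and one inverted (antiparallel) copy of blocks
#' of genome A's genes — diverged copies, at `divergence` amino-acid
#' replacement probability per site — embedded among unrelated background
#' genes. The layout per chromosome (ranks on B): background 1–10, a
#' parallel copy of A genes 11–40 at 11–40, background 41–50, an inverted
#' copy of A genes 41–60 at 51–70. The planted anchors are returned so
#' anchor recovery through scoring, C-score filtering and chaining can be
#' measured.
#'
#' @param n_chrom Chromosomes per genome.
#' @param genes_per_chrom Genes per A chromosome (minimum 60 layout slots).
#' @param prot_len Protein length (amino acids).
#' @param divergence Per-site amino-acid replacement probability in copied
#'   genes.
#' @param seed Optional integer seed.
#' @return A list with `proteome_a`, `proteome_b` (record tibbles),
#'   `genes_a`, `genes_b` (gene-model tibbles with ranks) and
#'   `truth_anchors` (tibble `gene_a`, `gene_b`, `orientation`).
#' @export
simulate_synteny_genomes <- function(n_chrom = 2, genes_per_chrom = 60,
                                     prot_len = 150, divergence = 0.1,
                                     seed = NULL) {
  stopifnot(n_chrom >= 1, genes_per_chrom >= 60, prot_len >= 20,
            divergence >= 0, divergence < 1)
  .local_seed(seed)
  prot_a <- list(); prot_b <- list(); truth <- list()
  for (ci in seq_len(n_chrom)) {
    cha <- sprintf("A%02d", ci)
    chb <- sprintf("B%02d", ci)
    ids_a <- sprintf("%s_g%03d", cha, seq_len(genes_per_chrom))
    seqs_a <- vapply(seq_len(genes_per_chrom), function(i) {
      .sample_protein(prot_len)
    }, character(1))
    par_src <- 11:40 # parallel block
    inv_src <- 41:60 # inverted block
    n_b <- 10L + length(par_src) + 10L + length(inv_src)
    ids_b <- sprintf("%s_g%03d", chb, seq_len(n_b))
    seqs_b <- character(n_b)
    seqs_b[1:10] <- vapply(1:10, function(i) .sample_protein(prot_len),
                           character(1))
    seqs_b[11:40] <- vapply(seqs_a[par_src], .mutate_protein, character(1),
                            divergence = divergence, USE.NAMES = FALSE)
    seqs_b[41:50] <- vapply(1:10, function(i) .sample_protein(prot_len),
                            character(1))
    seqs_b[51:70] <- vapply(seqs_a[rev(inv_src)], .mutate_protein,
                            character(1), divergence = divergence,
                            USE.NAMES = FALSE)
    prot_a[[ci]] <- tibble(id = ids_a, residues = seqs_a, chrom = cha,
                           rank = seq_along(ids_a))
    prot_b[[ci]] <- tibble(id = ids_b, residues = seqs_b, chrom = chb,
                           rank = seq_along(ids_b))
    truth[[ci]] <- tibble(
      gene_a = c(ids_a[par_src], ids_a[inv_src]),
      gene_b = c(ids_b[11:40], ids_b[rev(51:70)]),
      orientation = rep(c("parallel", "antiparallel"),
                        c(length(par_src), length(inv_src)))
    )
  }
  prot_a <- dplyr::bind_rows(prot_a)
  prot_b <- dplyr::bind_rows(prot_b)
  gene_model <- function(p) {
    tibble(
      gene_id = p$id, chrom = p$chrom,
      start = (p$rank - 1L) * 1000L + 1L,
      end = (p$rank - 1L) * 1000L + 500L,
      strand = "+", rank = p$rank
    )
  }
  list(
    proteome_a = tibble(id = prot_a$id, residues = prot_a$residues,
                        kind = "protein"),
    proteome_b = tibble(id = prot_b$id, residues = prot_b$residues,
                        kind = "protein"),
    genes_a = gene_model(prot_a),
    genes_b = gene_model(prot_b),
    truth_anchors = dplyr::bind_rows(truth)
  )
}

#' Simulate a scaffold set with planted lengths and gap runs
#'
#' @param lengths Optional explicit scaffold lengths (bp); otherwise `n`
#'   lengths are drawn log-normally around `mean_len_bp`.
#' @param n Number of scaffolds when `lengths` is not given.
#' @param mean_len_bp Target mean scaffold length.
#' @param gap_rate Expected fraction of positions inside N-gap runs (runs
#'   of geometric length, mean 10 bp).
#' @param gc GC content of the non-gap sequence.
#' @param seed Optional integer seed.
#' @return A list: `records` (tibble `id`, `residues`, `kind`) and `truth`
#'   (tibble `id`, `length_bp`, `gap_bp`).
#' @examples
#' sim <- simulate_scaffold_set(lengths = c(4000, 3000, 2000, 1000), seed = 1)
#' assembly_summary(sim$records)
#' @export
simulate_scaffold_set <- function(lengths = NULL, n = 20, mean_len_bp = 5000,
                                  gap_rate = 0, gc = 0.4, seed = NULL) {
  stopifnot(gap_rate >= 0, gap_rate < 1, gc > 0, gc < 1)
  .local_seed(seed)
  if (is.null(lengths)) {
    stopifnot(n >= 1)
    lengths <- pmax(200L, round(stats::rlnorm(n, log(mean_len_bp), 0.7)))
  }
  stopifnot(all(lengths >= 1))
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  records <- purrr::map(seq_along(lengths), function(i) {
    len <- as.integer(lengths[i])
    chars <- sample(.DNA, len, replace = TRUE, prob = probs)
    if (gap_rate > 0) {
      n_runs <- stats::rpois(1L, len * gap_rate / 10)
      for (r in seq_len(n_runs)) {
        run <- 1L + stats::rgeom(1L, 1 / 10)
        at <- sample.int(len, 1L)
        chars[at:min(len, at + run - 1L)] <- "N"
      }
    }
    paste(chars, collapse = "")
  })
  ids <- sprintf("scaffold_%03d", seq_along(lengths))
  residues <- unlist(records)
  list(
    records = tibble(id = ids, residues = residues, kind = "nucleotide"),
    truth = tibble(
      id = ids,
      length_bp = nchar(residues),
      gap_bp = nchar(gsub("[^N]", "", residues))
    )
  )
}
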