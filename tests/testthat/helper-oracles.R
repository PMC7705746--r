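# Independent oracles and small generators used across the suite. The
# oracles deliberately avoid the package's own code paths: translation goes
# through seqinr, chain search is exhaustive, Nxx is a plain cumulative
# loop.

DNA4 <- c("A", "C", "G", "T")

# Fourfold degeneracy decided by translating all four third-position
# variants with seqinr (independent of the package's code table). The
# 64-entry answer table is computed once per run and cached for speed.
.oracle_env <- new.env()

oracle_is_fourfold <- function(codon) {
  if (is.null(.oracle_env$four)) {
    all_codons <- apply(expand.grid(DNA4, DNA4, DNA4), 1, paste,
                        collapse = "")
    .oracle_env$four <- vapply(all_codons, function(cd) {
      variants <- paste0(substr(cd, 1, 2), DNA4)
      aas <- vapply(variants, function(v) {
        seqinr::translate(strsplit(v, "")[[1]])
      }, character(1))
      length(unique(aas)) == 1L && !any(aas == "*")
    }, logical(1))
  }
  unname(.oracle_env$four[codon])
}

# Per-column 4DTv count oracle: explicit loop over codons.
oracle_4dtv <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  sites <- 0L
  tv <- 0L
  purine <- c("A", "G")
  for (i in seq(1, length(ca), by = 3)) {
    cod_a <- paste(ca[i:(i + 2)], collapse = "")
    cod_b <- paste(cb[i:(i + 2)], collapse = "")
    if (grepl("[^ACGT]", cod_a) || grepl("[^ACGT]", cod_b)) next
    if (substr(cod_a, 1, 2) != substr(cod_b, 1, 2)) next
    if (!oracle_is_fourfold(cod_a) || !oracle_is_fourfold(cod_b)) next
    sites <- sites + 1L
    x <- ca[i + 2]; y <- cb[i + 2]
    if (x != y && ((x %in% purine) != (y %in% purine))) tv <- tv + 1L
  }
  list(sites = sites, tv = tv)
}

# Brute-force Nxx: descending sort, explicit cumulative loop.
oracle_nxx <- function(lengths, x) {
  s <- sort(lengths, decreasing = TRUE)
  need <- x / 100 * sum(s)
  acc <- 0
  for (l in s) {
    acc <- acc + l
    if (acc >= need) return(l)
  }
}

# Exhaustive maximal chain size over all monotone chains under the gap
# constraint, for one orientation.
oracle_chain_size <- function(ra, rb, max_gap, orientation) {
  n <- length(ra)
  if (n == 0L) return(0L)
  ok_step <- function(j, i) {
    da <- ra[i] - ra[j]
    db <- if (orientation == "parallel") rb[i] - rb[j] else rb[j] - rb[i]
    da >= 1 && da <= max_gap && db >= 1 && db <= max_gap
  }
  best <- 0L
  extend <- function(last, len) {
    best <<- max(best, len)
    for (i in seq_len(n)) {
      if (ok_step(last, i)) extend(i, len + 1L)
    }
  }
  for (s in seq_len(n)) extend(s, 1L)
  best
}

oracle_best_chain_size <- function(ra, rb, max_gap) {
  max(oracle_chain_size(ra, rb, max_gap, "parallel"),
      oracle_chain_size(ra, rb, max_gap, "antiparallel"))
}

# Random in-frame CDS (sense codons only), via seqinr's codon universe.
random_cds <- function(n_codons) {
  all_codons <- apply(expand.grid(DNA4, DNA4, DNA4), 1, paste, collapse = "")
  sense <- all_codons[vapply(all_codons, function(cd) {
    seqinr::translate(strsplit(cd, "")[[1]]) != "*"
  }, logical(1))]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# Random point-mutated copy (no indels), for pair generators.
mutate_dna <- function(x, p) {
  ch <- strsplit(x, "")[[1]]
  hit <- stats::runif(length(ch)) < p
  ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(DNA4, b), 1),
                    character(1))
  paste(ch, collapse = "")
}

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
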