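# The sequence-evolution simulators: determinism, process calibration,
# and end-to-end estimator consistency at small scale.

test_that("simulators are bit-reproducible given a seed", {
  expect_identical(simulate_wgd_pairs(5, 300, seed = 601),
                   simulate_wgd_pairs(5, 300, seed = 601))
  expect_identical(simulate_ltr_elements(ages_my = 2, n_per_age = 3,
                                         ltr_len = 100, seed = 602),
                   simulate_ltr_elements(ages_my = 2, n_per_age = 3,
                                         ltr_len = 100, seed = 602))
  expect_identical(simulate_scaffold_set(n = 5, seed = 603),
                   simulate_scaffold_set(n = 5, seed = 603))
  expect_identical(simulate_allopolyploid(n_chrom_per_subgenome = 2,
                                          seed = 604),
                   simulate_allopolyploid(n_chrom_per_subgenome = 2,
                                          seed = 604))
  # different seeds diverge
  expect_false(identical(simulate_wgd_pairs(5, 300, seed = 601)$pairs,
                         simulate_wgd_pairs(5, 300, seed = 605)$pairs))
})

test_that("derived sub-seeds are valid integers and distinct by component", {
  s <- vapply(0:10, function(k) derive_seed(77, k), integer(1))
  expect_true(all(s > 0))
  expect_true(all(s < 2^31))
  expect_equal(anyDuplicated(s), 0L)
})

test_that("zero elapsed time leaves descendants identical to the ancestor", {
  anc <- strrep("ACGT", 25)
  pair <- evolve_sequence_pair(anc, 0, 1e-9, 1e-9, seed = 606)
  expect_equal(pair, c(anc, anc))
  expect_error(evolve_sequence_pair("ACGX", 1, 1e-9, 1e-9), "A/C/G/T")
})

test_that("equal rates give a 1:2 transition:transversion count ratio", {
  # each site has one transition target and two transversion targets
  pair <- evolve_sequence_pair(strrep("ACGT", 25000), 3e7, 1e-9, 1e-9,
                               seed = 607)
  cls <- classify_substitution(strsplit(pair[1], "")[[1]],
                               strsplit(pair[2], "")[[1]])
  ratio <- sum(cls == "transition") / sum(cls == "transversion")
  expect_equal(ratio, 0.5, tolerance = 0.08)
})

test_that("estimated K2P distance recovers 2 mu t within 3 standard errors", {
  alpha <- 1e-9; beta <- 5e-10; t_years <- 5e7
  n_sites <- 1e5
  pair <- evolve_sequence_pair(paste(rep(c("A", "C", "G", "T"),
                                         length.out = n_sites),
                                     collapse = ""),
                               t_years, alpha, beta, seed = 608)
  d_hat <- k2p_distance(pair[1], pair[2])$d
  d_true <- 2 * t_years * (alpha + 2 * beta)
  se <- sqrt(d_true / n_sites) # binomial-scale error bound
  expect_lt(abs(d_hat - d_true), 3 * se)
})

test_that("WGD cohorts land where the saturation inverse plants them", {
  sim <- simulate_wgd_pairs(n_pairs = 60, seq_len = 3000,
                            expected_4dtv = 0.08, seed = 609)
  v <- four_dtv(sim$pairs)$v
  expect_lt(abs(mean(v) - 0.08), 0.01)
  expect_equal(unique(sim$truth$expected_v), 0.08)
  # empty request degenerates cleanly
  none <- simulate_wgd_pairs(n_pairs = 0, seq_len = 300)
  expect_equal(nrow(none$pairs), 0L)
})

test_that("planted LTR ages are recovered on average", {
  sim <- simulate_ltr_elements(ages_my = 4, n_per_age = 40, ltr_len = 500,
                               seed = 610)
  ages <- ltr_insertion_age(sim$pairs)
  expect_equal(mean(ages$age_my), 4, tolerance = 0.1)
  # age 0 gives identical copies
  zero <- simulate_ltr_elements(ages_my = 0, n_per_age = 2, ltr_len = 50,
                                seed = 611)
  expect_equal(zero$pairs$ltr5_seq, zero$pairs$ltr3_seq)
})

test_that("single short LTR estimates scatter widely (1/length variance)", {
  withr::local_seed(612)
  est <- function(len, n) {
    sim <- simulate_ltr_elements(ages_my = 4, n_per_age = n, ltr_len = len)
    ltr_insertion_age(sim$pairs)$age_my
  }
  sd_short <- stats::sd(est(100, 40))
  sd_long <- stats::sd(est(1600, 40))
  expect_gt(sd_short, 2 * sd_long) # expected factor 4 in SD
})

test_that("scaffold sets carry their planted lengths and gaps", {
  sim <- simulate_scaffold_set(lengths = c(4000, 3000, 2000, 1000),
                               gap_rate = 0, seed = 613)
  expect_equal(nchar(sim$records$residues), c(4000, 3000, 2000, 1000))
  expect_equal(sum(sim$truth$gap_bp), 0)
  s <- assembly_summary(sim$records)
  expect_equal(s$n50_bp, 3000)
  expect_equal(s$gap_length_bp, 0)
})

test_that("simulated CDS ancestors contain no internal stop codons", {
  sim <- simulate_wgd_pairs(n_pairs = 3, seq_len = 999,
                            expected_4dtv = 0, seed = 614)
  for (s in sim$pairs$aligned_a) {
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    aas <- vapply(codons, function(cd) {
      seqinr::translate(strsplit(cd, "")[[1]])
    }, character(1))
    expect_false(any(aas == "*"))
  }
})

test_that("synteny genomes plant recoverable duplicated blocks", {
  sim <- simulate_synteny_genomes(n_chrom = 1, seed = 615)
  expect_equal(nrow(sim$truth_anchors), 50L)
  expect_equal(max(sim$genes_a$rank), 60L)
  expect_equal(max(sim$genes_b$rank), 70L)
  # planted copies are recognisably similar, background is not
  a1 <- sim$proteome_a$residues[sim$proteome_a$id == sim$truth_anchors$gene_a[1]]
  b1 <- sim$proteome_b$residues[sim$proteome_b$id == sim$truth_anchors$gene_b[1]]
  ident <- mean(strsplit(a1, "")[[1]] == strsplit(b1, "")[[1]])
  expect_gt(ident, 0.8)
})
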