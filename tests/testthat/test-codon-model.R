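# Genetic-code degeneracy, substitution classification, 4DTv and K2P.

test_that("fourfold degeneracy matches a translation oracle over all codons", {
  all_codons <- apply(expand.grid(DNA4, DNA4, DNA4), 1, paste, collapse = "")
  mine <- fourfold_codon(all_codons)
  oracle <- vapply(all_codons, oracle_is_fourfold, logical(1))
  expect_identical(mine, unname(oracle))
  expect_identical(sum(mine), 32L)
  expect_true(fourfold_codon("GGA"))
  expect_false(fourfold_codon("ATG"))
  expect_false(fourfold_codon("GGN")) # ambiguity: unscored, not an error
})

test_that("substitutions are classified by purine/pyrimidine class", {
  expect_identical(
    classify_substitution(c("A", "A", "T", "C", "N", "-"),
                          c("G", "C", "T", "T", "A", "A")),
    c("transition", "transversion", "identity", "transition",
      "unscored", "unscored")
  )
})

test_that("four_dtv scores hand-checked alignments", {
  res <- four_dtv(tibble::tibble(
    pair_id = c("tv", "none", "same"),
    aligned_a = c("GGTCCA", "ATGTGG", "GGACCTACG"),
    aligned_b = c("GGGCCA", "ATGTGG", "GGACCTACG")
  ))
  # GGT/GGG: glycine family, T<->G transversion; CCA/CCA identical 4D site;
  # GGA+CCT+ACG: three identical 4D codons
  expect_equal(res$sites_4d, c(2L, 0L, 3L))
  expect_equal(res$transversions, c(1L, 0L, 0L))
  expect_equal(res$v, c(0.5, NA_real_, 0))
})

test_that("four_dtv rejects frame-breaking alignments", {
  expect_error(
    four_dtv(tibble::tibble(pair_id = "x", aligned_a = "GG-CCA",
                            aligned_b = "GGGCCA")),
    "whole codons"
  )
  expect_error(
    four_dtv(tibble::tibble(pair_id = "x", aligned_a = "GGGC",
                            aligned_b = "GGGC")),
    "multiple of 3"
  )
  expect_error(
    four_dtv(tibble::tibble(pair_id = "x", aligned_a = "GGGCCA",
                            aligned_b = "GGG")),
    "length"
  )
  # whole-codon gaps are fine and simply not comparable
  res <- four_dtv(tibble::tibble(pair_id = "ok", aligned_a = "---CCA",
                                 aligned_b = "GGGCCA"))
  expect_equal(res$sites_4d, 1L)
})

test_that("four_dtv agrees with the per-column oracle and is symmetric", {
  withr::local_seed(401)
  for (i in 1:200) {
    a <- random_cds(30)
    b <- mutate_dna(a, stats::runif(1, 0, 0.3))
    res <- four_dtv(tibble::tibble(pair_id = "p", aligned_a = a,
                                   aligned_b = b))
    orc <- oracle_4dtv(a, b)
    expect_identical(res$sites_4d, orc$sites)
    expect_identical(res$transversions, orc$tv)
    flip <- four_dtv(tibble::tibble(pair_id = "p", aligned_a = b,
                                    aligned_b = a))
    expect_identical(res$v, flip$v)
  }
})

test_that("K2P distance matches the closed form and its domain", {
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))
  res <- k2p_distance(a, b)
  expect_equal(res$P, 0.1)
  expect_equal(res$Q, 0.05)
  expect_equal(res$d, -0.5 * log((1 - 0.2 - 0.05) * sqrt(1 - 0.1)))
  expect_equal(round(res$d, 4), 0.1702)

  ident <- k2p_distance("ACGTACGT", "ACGTACGT")
  expect_equal(ident$d, 0)
  expect_equal(ident$P, 0)

  # P = 0.4, Q = 0.3 puts 1 - 2P - Q below zero
  sat_b <- paste0(strrep("G", 40), strrep("C", 30), strrep("A", 30))
  expect_error(k2p_distance(strrep("A", 100), sat_b), "saturation")
})

test_that("K2P agrees with ape's K80 estimator on random pairs", {
  skip_if_not_installed("ape")
  withr::local_seed(402)
  for (i in 1:20) {
    a <- paste(sample(DNA4, 500, replace = TRUE), collapse = "")
    b <- mutate_dna(a, stats::runif(1, 0.01, 0.2))
    mine <- k2p_distance(a, b)$d
    bin <- ape::as.DNAbin(rbind(strsplit(a, "")[[1]], strsplit(b, "")[[1]]))
    ref <- as.numeric(ape::dist.dna(bin, model = "K80"))
    expect_equal(mine, ref, tolerance = 1e-8)
  }
})

test_that("K2P distance increases in P at fixed Q and in Q at fixed P", {
  d_of <- function(P, Q) -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
  n <- 200
  mk <- function(nts, ntv) {
    paste0(strrep("G", nts), strrep("C", ntv), strrep("A", n - nts - ntv))
  }
  a <- strrep("A", n)
  grid <- expand.grid(ts = seq(0, 40, by = 10), tv = seq(0, 40, by = 10))
  d <- mapply(function(ts, tv) k2p_distance(a, mk(ts, tv))$d,
              grid$ts, grid$tv)
  for (tv in unique(grid$tv)) {
    expect_true(all(diff(d[grid$tv == tv]) > 0))
  }
  for (ts in unique(grid$ts)) {
    expect_true(all(diff(d[grid$ts == ts]) > 0))
  }
  # and the closed form evaluated directly agrees
  expect_equal(d[grid$ts == 20 & grid$tv == 30],
               d_of(0.1, 0.15))
})

test_that("kimura_distance keeps saturated pairs flagged, not dropped", {
  tab <- kimura_distance(tibble::tibble(
    pair_id = c("ok", "sat"),
    aligned_a = c(strrep("A", 50), strrep("A", 100)),
    aligned_b = c(strrep("A", 50),
                  paste0(strrep("G", 40), strrep("C", 30), strrep("A", 30)))
  ))
  expect_equal(nrow(tab), 2L)
  expect_false(tab$saturated[1])
  expect_true(tab$saturated[2])
  expect_true(is.na(tab$d[2]))
})

test_that("the multiple-hit correction of v is gentle at small v", {
  expect_equal(hky_correct_4dtv(0), 0)
  # equal base frequencies: closed form -log(1 - 2v)/2
  for (v in c(0.01, 0.02, 0.04)) {
    expect_equal(hky_correct_4dtv(v), -0.5 * log(1 - 2 * v))
    expect_lt(abs(hky_correct_4dtv(v) - v) / v, 0.05)
  }
  expect_error(hky_correct_4dtv(0.5), "saturation")
  # skewed composition lowers the saturation ceiling below 1/2
  skew <- c(A = 0.4, C = 0.1, G = 0.4, T = 0.1)
  expect_error(hky_correct_4dtv(0.4, skew), "saturation")
  expect_gt(hky_correct_4dtv(0.1, skew), hky_correct_4dtv(0.1))
})

test_that("corrected 4DTv is emitted only on request", {
  pair <- tibble::tibble(
    pair_id = "p",
    aligned_a = strrep("GGTCCA", 10),
    aligned_b = paste0("GGGCCA", strrep("GGTCCA", 9)) # 1 tv in 20 4D sites
  )
  expect_false("corrected_v" %in% names(four_dtv(pair)))
  res <- four_dtv(pair, correct = TRUE)
  expect_true("corrected_v" %in% names(res))
  expect_gte(res$corrected_v, res$v)
  # a fully saturated pair is kept with NA correction, not dropped
  sat <- four_dtv(tibble::tibble(pair_id = "s", aligned_a = "GGTCCT",
                                 aligned_b = "GGGCCG"), correct = TRUE)
  expect_true(is.na(sat$corrected_v))
})
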