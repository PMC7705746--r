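# Distance-to-time conversion, peak detection, LTR insertion ages.

test_that("divergence times follow T = d / (2 rate)", {
  expect_equal(divergence_time(0.48, 1.09e-9), 0.48 / (2 * 1.09e-9) / 1e6)
  expect_equal(format_my(divergence_time(0.48, 1.09e-9)), "220")
  expect_equal(divergence_time(0, 1e-9), 0)
  expect_equal(divergence_time(0.0584, 7.3e-9), 4, tolerance = 1e-6)
  expect_error(divergence_time(-0.1, 1e-9), "non-negative")
  expect_error(divergence_time(0.1, molecular_clock(rate_low = 1e-9,
                                                    rate_high = 2e-9)),
               "point rate")
})

test_that("rate intervals map to ordered time intervals", {
  clock <- molecular_clock(rate_low = 0.67e-9, rate_high = 1.09e-9)
  rng <- divergence_time_range(c(0.48, 0.08, 0.01, 0), clock)
  expect_true(all(rng$t_min_my <= rng$t_max_my))
  expect_equal(rng$t_min_my[4], 0)
  expect_equal(rng$t_max_my[4], 0)
  expect_equal(format_my(rng$t_min_my[1:3]), c("220", "36.7", "4.6"))
  expect_equal(format_my(rng$t_max_my[1:3]), c("358", "59.7", "7.5"))
  expect_error(divergence_time_range(0.1, molecular_clock(rate = 1e-9)),
               "interval")
  # degenerate interval: bounds coincide
  flat <- molecular_clock(rate_low = 1e-9, rate_high = 1e-9)
  r <- divergence_time_range(0.2, flat)
  expect_equal(r$t_min_my, r$t_max_my)
})

test_that("time conversion is linear in distance, inverse in rate", {
  withr::local_seed(301)
  d <- stats::runif(20, 0, 0.5)
  r <- stats::runif(20, 1e-10, 1e-8)
  for (i in 1:20) {
    expect_equal(divergence_time(2 * d[i], r[i]),
                 2 * divergence_time(d[i], r[i]))
    expect_equal(divergence_time(d[i], 2 * r[i]),
                 divergence_time(d[i], r[i]) / 2)
  }
})

test_that("detect_peaks recovers planted modes", {
  withr::local_seed(302)
  one <- detect_peaks(stats::rnorm(2000, 0.08, 0.01))
  expect_equal(tidy(one)$location[1], 0.08, tolerance = 0.15)
  expect_lt(abs(tidy(one)$location[1] - 0.08), 0.01)

  mix <- c(stats::rnorm(1500, 0.08, 0.01), stats::rnorm(1500, 0.48, 0.03))
  fit <- detect_peaks(mix[mix >= 0])
  locs <- tidy(fit)$location
  expect_lt(min(abs(locs - 0.08)), 0.01)
  expect_lt(min(abs(locs - 0.48)), 0.01)

  expect_error(detect_peaks(numeric(0)), "no distance")
  expect_error(detect_peaks(c(0.1, -0.2)), ">= 0")
})

test_that("detect_peaks is invariant to shuffling and reports a summary", {
  withr::local_seed(303)
  v <- stats::rnorm(1000, 0.2, 0.02)
  f1 <- detect_peaks(v)
  f2 <- detect_peaks(sample(v))
  expect_equal(tidy(f1), tidy(f2))
  g <- glance(f1)
  expect_equal(g$n, 1000L)
  expect_equal(g$bin_width, 0.01)
  # data-frame-first interface with a tidy column selector
  f3 <- detect_peaks(tibble::tibble(dist = v), value = dist)
  expect_equal(tidy(f3), tidy(f1))
})

test_that("date_peaks appends time columns to the peak table", {
  clock <- molecular_clock(rate_low = 0.67e-9, rate_high = 1.09e-9)
  tab <- date_peaks(tibble::tibble(location = c(0.48, 0.08)), clock)
  expect_equal(format_my(tab$t_min_my), c("220", "36.7"))
  tab2 <- date_peaks(tibble::tibble(location = 0.0584),
                     molecular_clock(rate = 7.3e-9))
  expect_equal(tab2$t_my, 4, tolerance = 1e-6)
})

test_that("LTR insertion ages follow age = d / (2 r)", {
  same <- ltr_insertion_age(tibble::tibble(
    element_id = "e0", ltr5_seq = strrep("ACGT", 50),
    ltr3_seq = strrep("ACGT", 50)
  ))
  expect_equal(same$age_my, 0)
  expect_false(same$saturated)

  # planted counts: 1000 sites, 40 transitions, 15 transversions
  l5 <- strrep("A", 1000)
  l3 <- paste0(strrep("G", 40), strrep("C", 15), strrep("A", 945))
  d_expect <- -0.5 * log((1 - 2 * 0.04 - 0.015) * sqrt(1 - 2 * 0.015))
  res <- ltr_insertion_age(tibble::tibble(element_id = "e1", ltr5_seq = l5,
                                          ltr3_seq = l3))
  expect_equal(res$d, d_expect, tolerance = 1e-9)
  expect_equal(res$age_my, d_expect / (2 * 7.3e-9) / 1e6, tolerance = 1e-9)

  # saturated element kept with NA age and flagged
  sat <- ltr_insertion_age(tibble::tibble(
    element_id = "sat", ltr5_seq = strrep("A", 100),
    ltr3_seq = paste0(strrep("G", 40), strrep("C", 30), strrep("A", 30))
  ))
  expect_true(sat$saturated)
  expect_true(is.na(sat$age_my))

  expect_error(ltr_insertion_age(tibble::tibble(
    element_id = "x", ltr5_seq = "", ltr3_seq = "ACGT"
  )), "nonempty")
})

test_that("LTR ages survive indels through global alignment", {
  withr::local_seed(304)
  base <- paste(sample(DNA4, 400, replace = TRUE), collapse = "")
  with_del <- paste0(substr(base, 1, 150), substr(base, 161, 400))
  res <- ltr_insertion_age(tibble::tibble(
    element_id = "indel", ltr5_seq = base, ltr3_seq = with_del
  ))
  expect_lt(res$d, 0.02) # deletion columns excluded, few mismatches remain
})

test_that("age histograms bin [k b, (k+1) b) and conserve counts", {
  h <- ltr_age_distribution(c(0.1, 0.2, 3.9), bin_my = 0.5)
  expect_equal(h$count[1], 2L)
  expect_equal(h$count[8], 1L) # 3.9 in [3.5, 4.0)
  expect_equal(sum(h$count), 3L)
  expect_equal(nrow(ltr_age_distribution(numeric(0))), 0L)
  # NA ages (saturated elements) are excluded from the histogram
  h2 <- ltr_age_distribution(c(0.1, NA, 0.6))
  expect_equal(sum(h2$count), 2L)
})

test_that("dating reports carry formatted intervals", {
  rep <- dating_report(0.48, molecular_clock(rate_low = 0.67e-9,
                                             rate_high = 1.09e-9))
  expect_equal(rep$interval_my, "220-358")
  expect_equal(rep$peak, 0.48)
})

test_that("clock construction is validated", {
  expect_error(molecular_clock(), "provide")
  expect_error(molecular_clock(rate = -1), "positive")
  expect_error(molecular_clock(rate_low = 2e-9, rate_high = 1e-9),
               "exceed")
})
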