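# Distance-to-time conversion, peak detection in divergence distributions,
# and LTR retrotransposon insertion ages.
#
# Time conversion is T = d / (2 * rate): divergence accumulates on both
# lineages (or both LTR copies), so a distance d between them corresponds
# to d / 2 substitutions per site per lineage.

#' Construct a molecular clock
#'
#' A molecular clock is a substitution rate in substitutions per site per
#' year, optionally with a bounding interval `[rate_low, rate_high]` when
#' the literature reports a rate range rather than a point value. Typical
#' values: the Salicaceae synonymous-rate interval
#' `0.67e-9`–`1.09e-9`/site/year used for dating whole-genome duplication
#' peaks, and the `7.3e-9`/site/year clock used for LTR insertion ages.
#'
#' @param rate Point rate, substitutions/site/year.
#' @param rate_low,rate_high Optional interval bounds.
#' @return An object of class `molecular_clock`.
#' @examples
#' molecular_clock(rate_low = 0.67e-9, rate_high = 1.09e-9)
#' molecular_clock(rate = 7.3e-9)
#' @export
molecular_clock <- function(rate = NULL, rate_low = NULL, rate_high = NULL) {
  if (is.null(rate) && (is.null(rate_low) || is.null(rate_high))) {
    abort("provide `rate`, or both `rate_low` and `rate_high`")
  }
  for (r in list(rate, rate_low, rate_high)) {
    if (!is.null(r) && (!is.numeric(r) || length(r) != 1L || r <= 0)) {
      abort("clock rates must be single positive numbers")
    }
  }
  if (!is.null(rate_low) && !is.null(rate_high) && rate_low > rate_high) {
    abort("`rate_low` must not exceed `rate_high`")
  }
  structure(
    list(rate = rate, rate_low = rate_low, rate_high = rate_high),
    class = "molecular_clock"
  )
}

#' @export
print.molecular_clock <- function(x, ...) {
  cat("<molecular clock>\n")
  if (!is.null(x$rate)) cat(sprintf("  rate: %g /site/year\n", x$rate))
  if (!is.null(x$rate_low)) {
    cat(sprintf("  interval: [%g, %g] /site/year\n", x$rate_low, x$rate_high))
  }
  invisible(x)
}

.clock_rate <- function(clock) {
  if (inherits(clock, "molecular_clock")) {
    if (is.null(clock$rate)) abort("clock has no point rate; use divergence_time_range()")
    clock$rate
  } else if (is.numeric(clock) && length(clock) == 1L) {
    if (clock <= 0) abort("rate must be > 0")
    clock
  } else {
    abort("`clock` must be a molecular_clock or a single positive rate")
  }
}

#' Convert a divergence distance to a time in million years
#'
#' `T = d / (2 * rate)`, returned in million years: the distance between two
#' diverged copies accumulates along both lineages, so each lineage carries
#' `d / 2` substitutions per site.
#'
#' @param distance Divergence distance(s) per site, `>= 0` (a 4DTv value, a
#'   K2P distance, ...).
#' @param clock A [molecular_clock()] with a point rate, or a bare rate in
#'   substitutions/site/year.
#' @return Time(s) in million years (MY).
#' @examples
#' divergence_time(0.48, 1.09e-9) # ~ 220 MY
#' @export
divergence_time <- function(distance, clock) {
  if (!is.numeric(distance) || any(is.na(distance)) || any(distance < 0)) {
    abort("`distance` must be non-negative")
  }
  rate <- .clock_rate(clock)
  distance / (2 * rate) / 1e6
}

#' Convert a distance to a time interval under a clock-rate interval
#'
#' The faster bound of the rate interval gives the younger time bound and
#' vice versa: `t_min = d / (2 * rate_high)`, `t_max = d / (2 * rate_low)`.
#'
#' @param distance Divergence distance(s) per site, `>= 0`.
#' @param clock A [molecular_clock()] carrying `rate_low` and `rate_high`.
#' @return A tibble with columns `distance`, `t_min_my`, `t_max_my`.
#' @examples
#' clock <- molecular_clock(rate_low = 0.67e-9, rate_high = 1.09e-9)
#' divergence_time_range(c(0.48, 0.08, 0.01), clock)
#' @export
divergence_time_range <- function(distance, clock) {
  if (!inherits(clock, "molecular_clock") ||
      is.null(clock$rate_low) || is.null(clock$rate_high)) {
    abort("`clock` must be a molecular_clock with a rate interval")
  }
  if (!is.numeric(distance) || any(is.na(distance)) || any(distance < 0)) {
    abort("`distance` must be non-negative")
  }
  tibble(
    distance = distance,
    t_min_my = distance / (2 * clock$rate_high) / 1e6,
    t_max_my = distance / (2 * clock$rate_low) / 1e6
  )
}

#' Format a time in MY the way dating reports print it
#'
#' One decimal below 100 MY, whole numbers above (so 4.587 prints as
#' `"4.6"`, 220.18 as `"220"`).
#'
#' @param my Numeric times in million years.
#' @return Character vector.
#' @export
format_my <- function(my) {
  ifelse(my < 100, sprintf("%.1f", my), sprintf("%.0f", round(my)))
}

#' Detect peaks in a divergence-distance distribution
#'
#' @description
#' Histogram-first peak detection: values are binned at `bin_width` over
#' `[0, max]`; candidate peaks are bins that are strict local maxima with a
#' count of at least `min_fraction * n`; each peak location is the bin
#' midpoint refined to the kernel-density mode within one bin width. The
#' default bin width of 0.01 matches the resolution at which
#' whole-genome-duplication peaks are conventionally read off 4DTv
#' distributions.
#'
#' @param data A data frame (then `value` names the distance column) or a
#'   bare numeric vector of distances, all `>= 0`.
#' @param value Column of `data` holding the distances (tidy evaluation);
#'   ignored when `data` is a vector. Defaults to a column named `v`.
#' @param bin_width Histogram bin width.
#' @param min_fraction Minimum fraction of all observations a peak bin must
#'   hold.
#' @return A `peak_fit` object; [tidy()] returns the peak table (columns
#'   `location`, `height`, `bin_mid`, `count`, sorted by height descending),
#'   [glance()] a one-row summary and [autoplot()] the annotated histogram.
#' @examples
#' fit <- detect_peaks(c(rnorm(500, 0.08, 0.01)))
#' tidy(fit)
#' @export
detect_peaks <- function(data, value = NULL, bin_width = 0.01,
                         min_fraction = 0.01) {
  if (is.data.frame(data)) {
    qv <- enquo(value)
    values <- if (quo_is_null(qv)) {
      if (!"v" %in% names(data)) {
        abort("specify `value` or provide a column named `v`")
      }
      data$v
    } else {
      eval_tidy(qv, data)
    }
  } else {
    values <- data
  }
  values <- values[!is.na(values)]
  if (length(values) == 0L) abort("no distance values to scan")
  if (any(values < 0)) abort("distances must be >= 0")
  stopifnot(bin_width > 0, min_fraction >= 0)

  n_bins <- max(1L, ceiling(max(values) / bin_width + 1e-12))
  idx <- pmin(floor(values / bin_width) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  mids <- (seq_len(n_bins) - 0.5) * bin_width

  left <- c(-Inf, counts[-n_bins])
  right <- c(counts[-1L], -Inf)
  is_peak <- counts > left & counts > right &
    counts >= min_fraction * length(values)
  peak_idx <- which(is_peak)

  dens <- if (length(values) >= 2L && stats::sd(values) > 0) {
    stats::density(values, bw = bin_width / 2, n = 2048,
                   from = 0, to = n_bins * bin_width)
  } else {
    NULL
  }
  refine <- function(mid) {
    if (is.null(dens)) return(mid)
    win <- dens$x >= mid - bin_width & dens$x <= mid + bin_width
    if (!any(win)) return(mid)
    dens$x[win][which.max(dens$y[win])]
  }
  peaks <- tibble(
    bin_mid = mids[peak_idx],
    count = counts[peak_idx],
    height = counts[peak_idx] / length(values),
    location = vapply(mids[peak_idx], refine, numeric(1))
  )
  peaks <- dplyr::arrange(peaks, dplyr::desc(.data$count), .data$location)
  structure(
    list(
      peaks = dplyr::select(peaks, "location", "height", "bin_mid", "count"),
      values = values,
      bin_width = bin_width,
      min_fraction = min_fraction
    ),
    class = "peak_fit"
  )
}

#' @export
print.peak_fit <- function(x, ...) {
  cat(sprintf("<peak_fit: %d values, bin width %g, %d peak(s)>\n",
              length(x$values), x$bin_width, nrow(x$peaks)))
  print(x$peaks)
  invisible(x)
}

#' Date the peaks of a divergence distribution
#'
#' Converts peak locations to divergence times under a molecular clock:
#' with an interval clock each peak gets `t_min_my`/`t_max_my`, with a
#' point clock a single `t_my`.
#'
#' @param peaks A `peak_fit` from [detect_peaks()], or a data frame with a
#'   `location` column.
#' @param clock A [molecular_clock()].
#' @return The peak table with time columns appended (times in MY).
#' @export
date_peaks <- function(peaks, clock) {
  tab <- if (inherits(peaks, "peak_fit")) peaks$peaks else as_tibble(peaks)
  if (!"location" %in% names(tab)) abort("`peaks` needs a `location` column")
  if (inherits(clock, "molecular_clock") && !is.null(clock$rate_low)) {
    rng <- divergence_time_range(tab$location, clock)
    tab$t_min_my <- rng$t_min_my
    tab$t_max_my <- rng$t_max_my
  } else {
    tab$t_my <- divergence_time(tab$location, clock)
  }
  tab
}

#' Estimate LTR retrotransposon insertion ages
#'
#' @description
#' The two long terminal repeats of a retrotransposon are identical at the
#' moment of insertion and then diverge independently, so their Kimura
#' two-parameter distance `d`, divided by twice a molecular clock rate,
#' dates the insertion: `age = d / (2 * rate)`. For each element the 5'
#' and 3' LTR sequences are globally aligned (Needleman–Wunsch, affine
#' gaps) and `d` is computed over the ungapped columns. Elements whose
#' divergence is saturated are retained with `age_my = NA` and flagged,
#' never silently dropped.
#'
#' @param ltr_pairs Tibble with columns `element_id`, `ltr5_seq`,
#'   `ltr3_seq`.
#' @param clock Clock rate for LTR divergence, substitutions/site/year
#'   (default `7.3e-9`), or a [molecular_clock()].
#' @return A tibble with columns `element_id`, `sites`, `d`, `age_years`,
#'   `age_my`, `saturated`.
#' @examples
#' ltr_insertion_age(tibble::tibble(
#'   element_id = "e1",
#'   ltr5_seq = "ACGTACGTACGT", ltr3_seq = "ACGTACGTACGT"
#' ))
#' @export
ltr_insertion_age <- function(ltr_pairs, clock = 7.3e-9) {
  stopifnot(is.data.frame(ltr_pairs),
            all(c("element_id", "ltr5_seq", "ltr3_seq") %in% names(ltr_pairs)))
  if (any(!nzchar(ltr_pairs$ltr5_seq)) || any(!nzchar(ltr_pairs$ltr3_seq))) {
    abort("LTR sequences must be nonempty")
  }
  rate <- .clock_rate(clock)
  aligned <- purrr::map2(ltr_pairs$ltr5_seq, ltr_pairs$ltr3_seq, .align_global)
  dist <- kimura_distance(tibble(
    pair_id = ltr_pairs$element_id,
    aligned_a = purrr::map_chr(aligned, 1L),
    aligned_b = purrr::map_chr(aligned, 2L)
  ))
  tibble(
    element_id = ltr_pairs$element_id,
    sites = dist$sites,
    d = dist$d,
    age_years = dist$d / (2 * rate),
    age_my = dist$d / (2 * rate) / 1e6,
    saturated = dist$saturated
  )
}

# Global (Needleman-Wunsch) nucleotide alignment of one LTR pair.
.align_global <- function(a, b) {
  if (identical(a, b)) return(c(a, b))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(a),
    subject = Biostrings::DNAString(b),
    type = "global",
    substitutionMatrix = mat,
    gapOpening = 10, gapExtension = 0.5
  )
  c(as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln)))
}

#' Histogram of LTR insertion ages
#'
#' Bins ages into `[k * bin_my, (k + 1) * bin_my)` intervals; the counts
#' total the number of elements with a finite age.
#'
#' @param ages Numeric ages in MY, or the result tibble of
#'   [ltr_insertion_age()] (its `age_my` column is used; `NA` ages are
#'   dropped).
#' @param bin_my Bin width in MY, default 0.5.
#' @return A tibble with columns `bin_start_my`, `bin_mid_my`, `count`
#'   (empty bins included up to the oldest element).
#' @export
ltr_age_distribution <- function(ages, bin_my = 0.5) {
  if (is.data.frame(ages)) ages <- ages$age_my
  ages <- ages[!is.na(ages)]
  stopifnot(bin_my > 0)
  if (length(ages) == 0L) {
    return(tibble(bin_start_my = numeric(), bin_mid_my = numeric(),
                  count = integer()))
  }
  if (any(!is.finite(ages)) || any(ages < 0)) abort("ages must be finite and >= 0")
  n_bins <- max(1L, floor(max(ages) / bin_my) + 1L)
  idx <- pmin(floor(ages / bin_my) + 1L, n_bins)
  tibble(
    bin_start_my = (seq_len(n_bins) - 1L) * bin_my,
    bin_mid_my = (seq_len(n_bins) - 0.5) * bin_my,
    count = tabulate(idx, nbins = n_bins)
  )
}

#' Assemble a dating report for one divergence peak
#'
#' @param peak Peak location (distance).
#' @param clock A [molecular_clock()] with a rate interval.
#' @return A list (JSON-ready) with the peak, the rate interval and the
#'   formatted time interval in MY.
#' @examples
#' dating_report(0.48, molecular_clock(rate_low = 0.67e-9, rate_high = 1.09e-9))
#' @export
dating_report <- function(peak, clock) {
  rng <- divergence_time_range(peak, clock)
  list(
    peak = peak,
    rate_low = clock$rate_low,
    rate_high = clock$rate_high,
    t_min_my = rng$t_min_my,
    t_max_my = rng$t_max_my,
    interval_my = paste0(format_my(rng$t_min_my), "-", format_my(rng$t_max_my))
  )
}
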