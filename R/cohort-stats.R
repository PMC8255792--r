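# Registry and population-genetic summaries.

#' Construct an allele length frequency spectrum
#'
#' Maps allele length (bp) to the number of chromosomes carrying it.
#' Tract arithmetic (`2v + 4(w+x+y+z)`) makes every length even.
#'
#' @param length_bp Integer vector of distinct allele lengths (bp, even).
#' @param count Integer vector of chromosome counts (>= 0), same length.
#' @return An object of class `frequency_spectrum`: a data frame with
#'   columns `length_bp`, `count`, sorted by length, with the total
#'   chromosome count in `attr(, "total")`.
#' @export
#' @examples
#' frequency_spectrum(c(138, 134), c(3, 1))
frequency_spectrum <- function(length_bp, count) {
  if (length(length_bp) != length(count) || !length(length_bp)) {
    stop("length_bp and count must be non-empty vectors of equal length", call. = FALSE)
  }
  length_bp <- vapply(length_bp, as_count, 0L, name = "length_bp")
  count <- vapply(count, as_count, 0L, name = "count")
  if (any(length_bp %% 2L != 0L)) {
    stop("allele lengths must be even (tract arithmetic yields even bp)", call. = FALSE)
  }
  if (anyDuplicated(length_bp)) stop("duplicated allele length", call. = FALSE)
  o <- order(length_bp)
  s <- data.frame(length_bp = length_bp[o], count = count[o])
  s <- s[s$count > 0L, , drop = FALSE]
  if (!nrow(s)) stop("spectrum has no chromosomes", call. = FALSE)
  rownames(s) <- NULL
  structure(s, total = sum(s$count), class = c("frequency_spectrum", "data.frame"))
}

#' @export
print.frequency_spectrum <- function(x, ...) {
  cat(sprintf("<frequency_spectrum> %d distinct lengths, %d chromosomes\n",
              nrow(x), attr(x, "total")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Summary statistics of an allele length spectrum
#'
#' Distinct allele count, length range, modal length (ties broken towards
#' the smaller length and flagged), per-length frequencies rounded half-up
#' to one decimal, and a unimodality flag. Unimodality is assessed after
#' pooling the sorted observed lengths into consecutive pairs (4-bp bins),
#' which smooths single-length sampling noise: the pooled counts must rise
#' to a single peak and then fall.
#'
#' @param s A [frequency_spectrum()].
#' @return A list with `distinct_alleles`, `min_bp`, `max_bp`, `mode_bp`,
#'   `mode_tied`, `mode_pct`, `unimodal`, `total`, and `freq` (data frame
#'   `length_bp`, `count`, `pct`).
#' @export
spectrum_stats <- function(s) {
  if (!inherits(s, "frequency_spectrum")) stop("expected a 'frequency_spectrum'", call. = FALSE)
  total <- attr(s, "total")
  pct <- round_half_up(100 * s$count / total, 1)
  mx <- max(s$count)
  tied <- sum(s$count == mx) > 1L
  mode_bp <- min(s$length_bp[s$count == mx])
  bins <- (seq_len(nrow(s)) - 1L) %/% 2L
  pooled <- tapply(s$count, bins, sum)
  peak <- which.max(pooled)
  unimodal <- all(diff(pooled[seq_len(peak)]) >= 0) &&
    all(diff(pooled[peak:length(pooled)]) <= 0)
  list(distinct_alleles = nrow(s), min_bp = min(s$length_bp),
       max_bp = max(s$length_bp), mode_bp = mode_bp, mode_tied = tied,
       mode_pct = pct[s$length_bp == mode_bp], unimodal = unname(unimodal),
       total = total,
       freq = data.frame(length_bp = s$length_bp, count = s$count, pct = pct))
}

#' Expected heterozygosity of a length spectrum
#'
#' `1 - sum(p_i^2)` over allele-length frequencies, the probability that
#' two chromosomes drawn at random carry different allele lengths.
#'
#' @param s A [frequency_spectrum()].
#' @return A fraction in `[0, 1)`.
#' @export
#' @examples
#' expected_heterozygosity(frequency_spectrum(c(110, 112), c(1, 1)))  # 0.5
expected_heterozygosity <- function(s) {
  if (!inherits(s, "frequency_spectrum")) stop("expected a 'frequency_spectrum'", call. = FALSE)
  p <- s$count / attr(s, "total")
  1 - sum(p^2)
}

# tract bp of an allele, NA when only a count range is known
allele_length_bp <- function(a) {
  if (!is.null(a$decomposition)) tract_length(a$decomposition) else NA_integer_
}

#' Observed heterozygosity of a cohort
#'
#' Fraction of individuals whose two alleles have distinct tract lengths.
#' Only genotypes where both alleles carry a decomposition (hence an exact
#' bp size) enter the denominator; expanded count-only alleles have no
#' exact size.
#'
#' @param genotypes List of [genotype_record()] objects.
#' @return A fraction in `[0, 1]`.
#' @export
observed_heterozygosity <- function(genotypes) {
  sizes <- vapply(genotypes, function(g) {
    c(allele_length_bp(g$allele1), allele_length_bp(g$allele2))
  }, integer(2))
  ok <- !is.na(sizes[1, ]) & !is.na(sizes[2, ])
  if (!any(ok)) stop("no genotype with two sized alleles", call. = FALSE)
  mean(sizes[1, ok] != sizes[2, ok])
}

#' Aggregate a testing registry
#'
#' Sums the yearly registry rows (year, cohort size, males, females,
#' positives) and computes the positivity rate as a percentage rounded
#' half-up to one decimal. Rows where `males + females != cohort` or
#' `positives > cohort` raise a validation error naming the year.
#'
#' @param r Data frame with columns `year`, `cohort`, `males`, `females`,
#'   `positives`.
#' @return A list with `cohort`, `males`, `females`, `positives`,
#'   `positivity_rate` (percent, one decimal).
#' @export
#' @examples
#' registry_totals(dm2_registry())
registry_totals <- function(r) {
  need <- c("year", "cohort", "males", "females", "positives")
  if (!is.data.frame(r) || !all(need %in% names(r))) {
    stop(sprintf("registry must be a data frame with columns %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  if (!nrow(r)) stop("registry table is empty", call. = FALSE)
  bad <- r$males + r$females != r$cohort
  if (any(bad)) {
    stop(sprintf("inconsistent registry row for year %s: males + females != cohort",
                 r$year[which(bad)[1]]), call. = FALSE)
  }
  bad <- r$positives > r$cohort
  if (any(bad)) {
    stop(sprintf("inconsistent registry row for year %s: positives > cohort",
                 r$year[which(bad)[1]]), call. = FALSE)
  }
  list(cohort = sum(r$cohort), males = sum(r$males), females = sum(r$females),
       positives = sum(r$positives),
       positivity_rate = round_half_up(100 * sum(r$positives) / sum(r$cohort), 1))
}

#' Interruption-motif composition frequencies
#'
#' Tabulates, over a catalogue of sequenced alleles:
#' * the `(CCTG)x(NCTG)y(CCTG)z` core of every allele (uninterrupted
#'   alleles reported as `(CCTG)x`), as a percentage of all alleles;
#' * the interruption-window size split (`y = 3` vs `y = 5` vs other)
#'   over interrupted alleles only;
#' * the full five-part motif, as a percentage of all alleles.
#'
#' Denominators are reported explicitly; percentages are rounded half-up
#' to one decimal.
#'
#' @param decompositions List of [motif_decomposition()] objects (or of
#'   [allele_record()]s carrying decompositions).
#' @return A list with data frames `core`, `interruption`, `full_motif`,
#'   and `denominators` (`all`, `interrupted`).
#' @export
motif_frequencies <- function(decompositions) {
  decompositions <- lapply(decompositions, function(d) {
    if (inherits(d, "allele_record")) d <- d$decomposition
    if (!is_decomposition(d)) {
      stop("every allele must carry a motif_decomposition", call. = FALSE)
    }
    d
  })
  if (!length(decompositions)) stop("no alleles", call. = FALSE)
  n_all <- length(decompositions)
  ys <- vapply(decompositions, interruption_count, 0L)
  n_int <- sum(ys > 0L)
  freq_table <- function(keys, denom, key_name) {
    counts <- sort(table(keys), decreasing = TRUE)
    df <- data.frame(key = names(counts), count = as.integer(counts),
                     pct = round_half_up(100 * as.integer(counts) / denom, 1),
                     row.names = NULL, stringsAsFactors = FALSE)
    names(df)[1] <- key_name
    df
  }
  cores <- vapply(decompositions, core_notation, "")
  fulls <- vapply(decompositions, repeat_notation, "")
  interruption <- if (n_int) {
    freq_table(sprintf("y=%d", ys[ys > 0L]), n_int, "window")
  } else {
    data.frame(window = character(), count = integer(), pct = numeric())
  }
  list(core = freq_table(cores, n_all, "core"),
       interruption = interruption,
       full_motif = freq_table(fulls, n_all, "motif"),
       denominators = list(all = n_all, interrupted = n_int))
}

#' Clinical indication profile of a cohort
#'
#' Per-label percentages among true positives and among all requests.
#' Labels are non-exclusive (one individual may carry several), so
#' columns need not sum to 100.
#'
#' @param genotypes List of [genotype_record()] objects.
#' @return A data frame with columns `label`, `pct_positives`, `pct_all`
#'   (percentages, one decimal), plus `n_positives` and `n_all` as
#'   attributes. Warns when the positive subset is empty.
#' @export
indication_profile <- function(genotypes) {
  if (!length(genotypes)) stop("empty cohort", call. = FALSE)
  labs <- indication_labels()
  has <- vapply(genotypes, function(g) labs %in% g$indications, logical(length(labs)))
  pos <- vapply(genotypes, function(g) g$true_status == "DM2_positive", TRUE)
  n_pos <- sum(pos)
  if (!n_pos) warning("no DM2-positive individuals in cohort", call. = FALSE)
  pct_pos <- if (n_pos) round_half_up(100 * rowSums(has[, pos, drop = FALSE]) / n_pos, 1)
             else rep(NA_real_, length(labs))
  out <- data.frame(label = labs,
                    pct_positives = pct_pos,
                    pct_all = round_half_up(100 * rowSums(has) / length(genotypes), 1),
                    stringsAsFactors = FALSE)
  attr(out, "n_positives") <- n_pos
  attr(out, "n_all") <- length(genotypes)
  out
}
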