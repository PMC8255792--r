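# Structural classes and diagnostic categories of CNBP alleles.

#' Diagnostic thresholds on the uninterrupted CCTG count
#'
#' Default bounds follow the consensus guideline reading: normal up to 26
#' CCTG units, gray-zone premutation 27--74, pathogenic expansion >= 75
#' (expansions range up to ~11,000 units). The literature also contains a
#' "<25 copies" phrasing of the normal bound; the upper normal bound is
#' therefore configurable.
#'
#' @param normal_max Largest uninterrupted CCTG count still normal (default 26).
#' @param gray_lo,gray_hi Bounds of the gray / premutation zone (27, 74).
#' @param pathogenic_min Smallest pathogenic count (75).
#' @return An object of class `class_thresholds`.
#' @export
#' @examples
#' class_thresholds()
class_thresholds <- function(normal_max = 26L, gray_lo = 27L, gray_hi = 74L,
                             pathogenic_min = 75L) {
  normal_max <- as_count(normal_max, "normal_max", 1)
  gray_lo <- as_count(gray_lo, "gray_lo", 1)
  gray_hi <- as_count(gray_hi, "gray_hi", 1)
  pathogenic_min <- as_count(pathogenic_min, "pathogenic_min", 1)
  if (!(normal_max < gray_lo && gray_lo <= gray_hi && gray_hi < pathogenic_min)) {
    stop("thresholds must satisfy normal_max < gray_lo <= gray_hi < pathogenic_min",
         call. = FALSE)
  }
  structure(list(normal_max = normal_max, gray_lo = gray_lo,
                 gray_hi = gray_hi, pathogenic_min = pathogenic_min),
            class = "class_thresholds")
}

#' @export
print.class_thresholds <- function(x, ...) {
  cat(sprintf("<class_thresholds> normal <= %d | gray %d-%d | pathogenic >= %d (CCTG units)\n",
              x$normal_max, x$gray_lo, x$gray_hi, x$pathogenic_min))
  invisible(x)
}

.MAX_EXPANSION <- 11000L

.STRUCTURAL_CLASSES <- c("short_uninterrupted", "short_interrupted",
                         "long_interrupted", "long_uninterrupted",
                         "expanded", "unclassified")
.DIAGNOSTIC_CATEGORIES <- c("normal", "gray_premutation", "pathogenic")

#' Structural class of a healthy-range allele
#'
#' Sequenced healthy-range alleles fall into four structural classes,
#' keyed on the interruption-window size `y` and, for uninterrupted
#' alleles, the total CCTG count:
#'
#' * `short_uninterrupted`: `y = 0`, total CCTG <= 12 (rare, ~2% of
#'   chromosomes);
#' * `short_interrupted`: `y = 3` (three-tetramer window, CCTG total 9--15);
#' * `long_interrupted`: `y = 5` (five-tetramer window);
#' * `long_uninterrupted`: `y = 0`, total CCTG >= 22 (includes gray-zone
#'   premutations).
#'
#' Any other combination is `unclassified`. Class assignment keys on `y`,
#' not on the CCTG total, because the printed CCTG ranges of the two
#' interrupted classes overlap.
#'
#' @param d A [motif_decomposition()].
#' @return A single string, one of
#'   `"short_uninterrupted"`, `"short_interrupted"`, `"long_interrupted"`,
#'   `"long_uninterrupted"`, `"unclassified"`.
#' @export
#' @examples
#' structural_class(motif_decomposition(18, 10, 23))  # long_uninterrupted
structural_class <- function(d) {
  stop_if_not_decomposition(d)
  y <- length(d$block)
  tot <- total_cctg(d)
  if (y == 3L) return("short_interrupted")
  if (y == 5L) return("long_interrupted")
  if (y == 0L) {
    if (tot <= 12L) return("short_uninterrupted")
    if (tot >= 22L) return("long_uninterrupted")
  }
  "unclassified"
}

#' Construct an allele record
#'
#' One allele: either a full [motif_decomposition()] (sequenced alleles)
#' or a CCTG repeat-count range (fragment-only or somatically mosaic
#' expanded alleles, for which `lo < hi` captures the mosaic spread;
#' count-only alleles are assumed uninterrupted). The structural class and
#' the effective uninterrupted CCTG count are derived on construction.
#'
#' @param id Allele identifier.
#' @param decomposition Optional [motif_decomposition()].
#' @param count_range Optional integer vector `c(lo, hi)` of CCTG copies
#'   (`lo == hi` for a single count); `hi` must not exceed 11000.
#' @param thresholds A [class_thresholds()] used to derive the diagnostic
#'   category.
#' @return An object of class `allele_record` with fields `id`,
#'   `decomposition`, `count_range`, `structural_class`, `effective_count`
#'   and `diagnostic_category`.
#' @export
#' @examples
#' allele_record("a1", motif_decomposition(21, 9, 5, c("TCTG", "CCTG", "TCTG"), 7))
#' allele_record("exp", count_range = c(2000, 2400))
allele_record <- function(id, decomposition = NULL, count_range = NULL,
                          thresholds = class_thresholds()) {
  if (is.null(decomposition) && is.null(count_range)) {
    stop("allele needs a decomposition or a count_range", call. = FALSE)
  }
  if (!is.null(decomposition)) stop_if_not_decomposition(decomposition)
  if (!is.null(count_range)) {
    if (length(count_range) == 1L) count_range <- rep(count_range, 2L)
    lo <- as_count(count_range[1], "count_range[lo]", 1)
    hi <- as_count(count_range[2], "count_range[hi]", 1)
    if (lo > hi) stop("count_range must satisfy lo <= hi", call. = FALSE)
    if (hi > .MAX_EXPANSION) {
      stop(sprintf("count_range upper bound exceeds the maximum observed expansion (%d)",
                   .MAX_EXPANSION), call. = FALSE)
    }
    count_range <- c(lo, hi)
  }
  cls <- if (!is.null(decomposition)) {
    structural_class(decomposition)
  } else if (count_range[2] >= thresholds$pathogenic_min) {
    "expanded"
  } else if (count_range[2] <= 12L) {
    "short_uninterrupted"
  } else if (count_range[2] >= 22L) {
    "long_uninterrupted"
  } else {
    "unclassified"
  }
  a <- structure(list(id = as.character(id), decomposition = decomposition,
                      count_range = count_range, structural_class = cls),
                 class = "allele_record")
  a$effective_count <- effective_cctg_count(a)
  a$diagnostic_category <- diagnostic_category(a, thresholds)
  a
}

#' @export
print.allele_record <- function(x, ...) {
  what <- if (!is.null(x$decomposition)) {
    repeat_notation(x$decomposition)
  } else if (x$count_range[1] == x$count_range[2]) {
    sprintf("(CCTG)%d", x$count_range[1])
  } else {
    sprintf("(CCTG)%d-%d", x$count_range[1], x$count_range[2])
  }
  cat(sprintf("<allele_record> %s: %s [%s, %s]\n", x$id, what,
              x$structural_class, x$diagnostic_category))
  invisible(x)
}

#' Effective uninterrupted CCTG count of an allele
#'
#' The count to which diagnostic thresholds apply: the longest
#' uninterrupted CCTG run for sequenced alleles, the upper bound of the
#' mosaic count range for count-only alleles (conservative with respect
#' to diagnostic escalation).
#'
#' @param a An [allele_record()].
#' @return Integer count.
#' @export
effective_cctg_count <- function(a) {
  if (!inherits(a, "allele_record")) stop("expected an 'allele_record'", call. = FALSE)
  if (!is.null(a$decomposition)) longest_cctg_run(a$decomposition) else a$count_range[2]
}

#' Diagnostic category of an allele
#'
#' Applies [class_thresholds()] to the [effective_cctg_count()]:
#' `normal` up to `normal_max`, `pathogenic` from `pathogenic_min`,
#' `gray_premutation` in between. Interrupted alleles (`y > 0`) are always
#' `normal` regardless of their CCTG total: interruptions stabilise the
#' array, and pathogenicity requires an uninterrupted tract.
#'
#' @param a An [allele_record()], or a [motif_decomposition()] (wrapped on
#'   the fly).
#' @param thresholds A [class_thresholds()].
#' @return One of `"normal"`, `"gray_premutation"`, `"pathogenic"`.
#' @export
#' @examples
#' diagnostic_category(allele_record("g", count_range = 48))  # gray_premutation
diagnostic_category <- function(a, thresholds = class_thresholds()) {
  if (is_decomposition(a)) a <- allele_record("", decomposition = a, thresholds = thresholds)
  if (!inherits(a, "allele_record")) stop("expected an 'allele_record'", call. = FALSE)
  if (!is.null(a$decomposition) && interruption_count(a$decomposition) > 0L) {
    return("normal")
  }
  n <- effective_cctg_count(a)
  if (n <= thresholds$normal_max) "normal"
  else if (n >= thresholds$pathogenic_min) "pathogenic"
  else "gray_premutation"
}

#' Tally structural classes and diagnostic categories over alleles
#'
#' @param alleles A non-empty list of [allele_record()] objects.
#' @return A list with two data frames, `structural` and `diagnostic`,
#'   each with columns `level`, `count`, `pct` (percentages of all alleles,
#'   rounded half-up to one decimal).
#' @export
classify_cohort <- function(alleles) {
  if (!length(alleles)) stop("no alleles to classify", call. = FALSE)
  if (!all(vapply(alleles, inherits, TRUE, "allele_record"))) {
    stop("'alleles' must be a list of allele_record objects", call. = FALSE)
  }
  n <- length(alleles)
  tally <- function(values, levels) {
    counts <- table(factor(values, levels = levels))
    data.frame(level = names(counts), count = as.integer(counts),
               pct = round_half_up(100 * as.integer(counts) / n, 1),
               row.names = NULL, stringsAsFactors = FALSE)
  }
  list(
    structural = tally(vapply(alleles, `[[`, "", "structural_class"),
                       .STRUCTURAL_CLASSES),
    diagnostic = tally(vapply(alleles, `[[`, "", "diagnostic_category"),
                       .DIAGNOSTIC_CATEGORIES),
    n = n
  )
}
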