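# The (TG)v(TCTG)w(CCTG)x(NCTG)y(CCTG)z motif grammar: construction,
# rendering, arithmetic.

#' Admissible repeat tetramers
#'
#' The tetramer alphabet of the combined repeat tract. `CCTG` is the
#' disease-associated unit; `TCTG`, `GCTG` and `ACTG` are the "NCTG"
#' interruption tetramers that break the CCTG array in healthy-range
#' alleles.
#'
#' @return Character vector of the four admissible tetramer labels.
#' @export
#' @examples
#' repeat_tetramers()
repeat_tetramers <- function() c("CCTG", "TCTG", "GCTG", "ACTG")

.NCTG <- c("TCTG", "GCTG", "ACTG")

#' Construct a motif decomposition of the combined repeat tract
#'
#' A decomposition describes one allele of the CNBP intron-1 locus as
#' `(TG)v (TCTG)w (CCTG)x <block> (CCTG)z`, where `block` is the ordered
#' interruption window of `y = length(block)` tetramers. The interruption
#' window is the minimal window spanning the first to the last non-CCTG
#' tetramer of the CCTG array: its first and last labels are never `CCTG`,
#' but internal `CCTG` units are part of the window and count towards `y`.
#' Uninterrupted alleles carry all their CCTG units in `x` (`y = 0` forces
#' `z = 0`).
#'
#' Validity rules (violations raise an error naming the rule):
#' * all block labels belong to [repeat_tetramers()];
#' * a nonempty block neither starts nor ends with `CCTG`;
#' * a nonempty block requires `x >= 1` (otherwise leading `TCTG` labels
#'   would be indistinguishable from the `w` segment);
#' * an empty block forces `z = 0`.
#'
#' `v = 0` or `w = 0` on a nonempty tract triggers a warning: observed
#' healthy-range alleles have `v` 14--26 and `w` 7--11.
#'
#' @param v Number of leading `TG` dinucleotide units (>= 0).
#' @param w Number of leading `TCTG` tetramer units (>= 0).
#' @param x Number of `CCTG` units before the interruption window (>= 0).
#' @param block Character vector of tetramer labels forming the
#'   interruption window; may be empty.
#' @param z Number of `CCTG` units after the interruption window (>= 0).
#' @return An object of class `motif_decomposition`.
#' @seealso [render_tract()], [decompose_tract()], [tract_length()]
#' @export
#' @examples
#' # the longest sequenced healthy allele (168 bp), uninterrupted
#' motif_decomposition(18, 10, 23)
#' # the shortest (108 bp), with a three-tetramer interruption window
#' motif_decomposition(16, 7, 5, c("TCTG", "CCTG", "TCTG"), 4)
motif_decomposition <- function(v, w, x, block = character(), z = 0L) {
  v <- as_count(v, "v"); w <- as_count(w, "w"); x <- as_count(x, "x")
  z <- as_count(z, "z")
  block <- toupper(as.character(block))
  if (length(block) && !all(block %in% repeat_tetramers())) {
    bad <- block[!block %in% repeat_tetramers()][1]
    stop(sprintf("invalid block label '%s': block labels must be one of %s",
                 bad, paste(repeat_tetramers(), collapse = "/")), call. = FALSE)
  }
  if (length(block)) {
    if (block[1] == "CCTG" || block[length(block)] == "CCTG") {
      stop("interruption block must not start or end with CCTG", call. = FALSE)
    }
    if (x < 1L) {
      stop("a nonempty interruption block requires x >= 1", call. = FALSE)
    }
  } else if (z > 0L) {
    stop("z must be 0 when the interruption block is empty (y = 0 implies z = 0)",
         call. = FALSE)
  }
  d <- structure(list(v = v, w = w, x = x, block = block, z = z),
                 class = "motif_decomposition")
  if ((v == 0L || w == 0L) && tract_length(d) > 0L) {
    warning("v = 0 or w = 0 is outside the observed polymorphic range (v 14-26, w 7-11)",
            call. = FALSE)
  }
  d
}

#' @export
print.motif_decomposition <- function(x, ...) {
  cat("<motif_decomposition> ", repeat_notation(x),
      "  [", tract_length(x), " bp]\n", sep = "")
  invisible(x)
}

#' @export
format.motif_decomposition <- function(x, ...) repeat_notation(x)

is_decomposition <- function(d) inherits(d, "motif_decomposition")

stop_if_not_decomposition <- function(d) {
  if (!is_decomposition(d)) stop("expected a 'motif_decomposition' object", call. = FALSE)
  invisible(d)
}

#' Number of tetramers in the interruption window
#'
#' The `y` term of the five-part motif: 0 for uninterrupted alleles, 3 or
#' 5 for the interruption windows observed in healthy-range alleles.
#'
#' @param d A [motif_decomposition()].
#' @return Integer count of tetramers in the window (including internal CCTGs).
#' @export
interruption_count <- function(d) {
  stop_if_not_decomposition(d)
  length(d$block)
}

#' Render a decomposition as a DNA string
#'
#' Concatenates `TG` x v, `TCTG` x w, `CCTG` x x, the interruption window
#' labels in order, and `CCTG` x z.
#'
#' @param d A [motif_decomposition()].
#' @return A single uppercase DNA string whose number of characters equals
#'   [tract_length()].
#' @export
#' @examples
#' render_tract(motif_decomposition(18, 10, 23))  # 168 characters
render_tract <- function(d) {
  stop_if_not_decomposition(d)
  paste0(strrep("TG", d$v), strrep("TCTG", d$w), strrep("CCTG", d$x),
         paste(d$block, collapse = ""), strrep("CCTG", d$z))
}

#' Combined repeat tract length in base pairs
#'
#' `2 v + 4 (w + x + y + z)`: the fragment-analysis length convention under
#' which the worked healthy-range structures sum exactly to their reported
#' allele sizes (108--168 bp).
#'
#' @param d A [motif_decomposition()].
#' @return Integer length in bp.
#' @export
#' @examples
#' tract_length(motif_decomposition(18, 10, 23))                              # 168
#' tract_length(motif_decomposition(16, 7, 5, c("TCTG", "CCTG", "TCTG"), 4))  # 108
tract_length <- function(d) {
  stop_if_not_decomposition(d)
  2L * d$v + 4L * (d$w + d$x + length(d$block) + d$z)
}

#' Longest uninterrupted CCTG run
#'
#' The maximum number of consecutive `CCTG` tetramers anywhere in the
#' tract (the `x` segment, runs internal to the interruption window, or
#' the `z` segment). Diagnostic thresholds apply to this uninterrupted
#' run, because instability and pathogenicity are properties of the pure
#' CCTG array.
#'
#' @param d A [motif_decomposition()].
#' @return Integer run length.
#' @export
longest_cctg_run <- function(d) {
  stop_if_not_decomposition(d)
  best <- max(d$x, d$z)
  if (length(d$block)) {
    r <- rle(d$block == "CCTG")
    inner <- r$lengths[r$values]
    if (length(inner)) best <- max(best, inner)
  }
  best
}

#' Total CCTG tetramer count
#'
#' All CCTG units in the tract: `x + z` plus any CCTG labels internal to
#' the interruption window. This is the count behind the structural class
#' bounds of healthy-range alleles.
#'
#' @param d A [motif_decomposition()].
#' @return Integer count.
#' @export
total_cctg <- function(d) {
  stop_if_not_decomposition(d)
  d$x + d$z + sum(d$block == "CCTG")
}

#' Canonical text notation for a decomposition
#'
#' Renders the decomposition in the field's standard notation, e.g.
#' `"(TG)16(TCTG)7(CCTG)5(NCTG)3(CCTG)4"`. Uninterrupted alleles render
#' without the NCTG and trailing CCTG terms.
#'
#' @param d A [motif_decomposition()].
#' @return A single character string.
#' @export
#' @examples
#' repeat_notation(motif_decomposition(18, 10, 23))
repeat_notation <- function(d) {
  stop_if_not_decomposition(d)
  out <- sprintf("(TG)%d(TCTG)%d(CCTG)%d", d$v, d$w, d$x)
  if (length(d$block)) {
    out <- sprintf("%s(NCTG)%d(CCTG)%d", out, length(d$block), d$z)
  }
  out
}

#' Core interruption-motif notation
#'
#' The `(CCTG)x(NCTG)y(CCTG)z` core of an interrupted allele, or
#' `(CCTG)x` for an uninterrupted one. Used to tabulate interruption-motif
#' frequencies across a sequenced catalogue.
#'
#' @param d A [motif_decomposition()].
#' @return A single character string.
#' @export
core_notation <- function(d) {
  stop_if_not_decomposition(d)
  if (length(d$block)) {
    sprintf("(CCTG)%d(NCTG)%d(CCTG)%d", d$x, length(d$block), d$z)
  } else {
    sprintf("(CCTG)%d", d$x)
  }
}

#' Test two decompositions for equality
#'
#' @param a,b [motif_decomposition()] objects.
#' @return Logical.
#' @export
same_decomposition <- function(a, b) {
  stop_if_not_decomposition(a); stop_if_not_decomposition(b)
  a$v == b$v && a$w == b$w && a$x == b$x && a$z == b$z &&
    length(a$block) == length(b$block) && all(a$block == b$block)
}
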