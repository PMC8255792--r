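# Locating and parsing the combined repeat tract from DNA sequence.

.TRACT_REGEX <- "(?:TG)*(?:[ACGT]CTG)+"

# Parse a candidate region that is already known to be (TG)* followed by
# in-frame tetramers. Returns a motif_decomposition or a condition-free
# NULL-with-reason list used by the locator.
parse_region <- function(region, offset = 0L) {
  m <- regmatches(region, regexpr("^(?:TG)*", region))[[1]]
  v <- nchar(m) %/% 2L
  rest <- substr(region, nchar(m) + 1L, nchar(region))
  n4 <- nchar(rest)
  if (n4 %% 4L != 0L) {
    return(list(error = sprintf(
      "tetramer frame broken at offset %d: %d trailing bases do not fill a tetramer",
      offset + nchar(m), n4 %% 4L)))
  }
  if (n4 == 0L) {
    return(list(error = sprintf("no tetramer section at offset %d", offset)))
  }
  tets <- substring(rest, seq(1L, n4, by = 4L), seq(4L, n4, by = 4L))
  bad <- which(!tets %in% repeat_tetramers())
  if (length(bad)) {
    i <- bad[1]
    return(list(error = sprintf(
      "non-grammar tetramer '%s' at offset %d", tets[i],
      offset + nchar(m) + 4L * (i - 1L))))
  }
  nt <- length(tets)
  w <- 0L
  while (w < nt && tets[w + 1L] == "TCTG") w <- w + 1L
  x <- 0L
  while (w + x < nt && tets[w + x + 1L] == "CCTG") x <- x + 1L
  if (x == 0L) {
    return(list(error = sprintf(
      "tract lacks a CCTG core (x >= 1 required) at offset %d", offset)))
  }
  rem <- if (w + x < nt) tets[(w + x + 1L):nt] else character()
  if (!length(rem)) {
    block <- character(); z <- 0L
  } else {
    last_non <- max(which(rem != "CCTG"))  # rem[1] != "CCTG" since x is maximal
    block <- rem[seq_len(last_non)]
    z <- length(rem) - last_non
  }
  d <- suppressWarnings(motif_decomposition(v, w, x, block, z))
  list(decomposition = d)
}

# All maximal grammar regions of `seq` that parse successfully, as a list
# of (decomposition, start, end) with 0-based half-open coordinates.
locate_candidates <- function(seq) {
  m <- gregexpr(.TRACT_REGEX, seq, perl = TRUE)[[1]]
  out <- list()
  errs <- character()
  if (m[1] != -1L) {
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    for (i in seq_along(starts)) {
      region <- substr(seq, starts[i], starts[i] + lens[i] - 1L)
      p <- parse_region(region, offset = starts[i] - 1L)
      if (is.null(p$error)) {
        out[[length(out) + 1L]] <- list(
          decomposition = p$decomposition,
          start = starts[i] - 1L,
          end = starts[i] - 1L + lens[i])
      } else {
        errs <- c(errs, p$error)
      }
    }
  }
  list(candidates = out, errors = errs)
}

#' Locate and decompose the combined repeat tract in a DNA sequence
#'
#' Finds the grammar-matching region `(TG)* ([ACGT]CTG)+` in `seq` and
#' parses it into a [motif_decomposition()]: `v` is the greedy maximal run
#' of `TG` dinucleotides (unique, because `TGTC`/`TGGC`/... are not
#' admissible tetramers), `w` the run of leading `TCTG` tetramers, `x` the
#' CCTG run up to the first interruption, the block the minimal window
#' from the first to the last non-CCTG tetramer, and `z` the trailing CCTG
#' run. For every valid decomposition `d`,
#' `decompose_tract(render_tract(d))` recovers `d` exactly.
#'
#' With `full = TRUE` (default) the matched tract must span the whole
#' input; any flanking or inserted base is a parse error, so a corrupted
#' tract can never be silently re-framed. With `full = FALSE` the tract is
#' located inside a longer sequence; exactly one parseable grammar region
#' must exist, and its 0-based half-open coordinates are reported.
#'
#' If the forward strand does not match, the reverse complement is tried
#' and the matching strand is reported (coordinates then refer to the
#' reverse-complemented sequence).
#'
#' @param seq A single DNA string (A/C/G/T, case-insensitive).
#' @param full Require the tract to cover the entire input? Default `TRUE`.
#' @return A list of class `tract_match` with elements `decomposition`
#'   ([motif_decomposition()]), `start`, `end` (0-based half-open) and
#'   `strand` (`"+"` or `"-"`).
#' @export
#' @examples
#' decompose_tract("TGTGTCTGCCTG")  # (TG)2(TCTG)1(CCTG)1
decompose_tract <- function(seq, full = TRUE) {
  if (length(seq) != 1L || !is.character(seq)) {
    stop("'seq' must be a single character string", call. = FALSE)
  }
  seq <- toupper(seq)
  if (!grepl("^[ACGT]+$", seq)) {
    stop("sequence must contain only A/C/G/T", call. = FALSE)
  }
  hit <- locate_strand(seq, full)
  if (!is.null(hit)) return(hit)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  hit <- locate_strand(rc, full, strand = "-")
  if (!is.null(hit)) return(hit)
  # reconstruct the forward-strand failure message for the error
  res <- locate_candidates(seq)
  detail <- if (length(res$candidates) && full) {
    cc <- res$candidates[[1]]
    sprintf("grammar region [%d, %d) does not span the full input (use full = FALSE to locate within context)",
            cc$start, cc$end)
  } else if (length(res$errors)) {
    res$errors[1]
  } else {
    "no grammar match in sequence"
  }
  stop(sprintf("cannot decompose sequence: %s", detail), call. = FALSE)
}

locate_strand <- function(seq, full, strand = "+") {
  res <- locate_candidates(seq)
  cand <- res$candidates
  if (full) {
    cand <- Filter(function(cc) cc$start == 0L && cc$end == nchar(seq), cand)
  }
  if (!length(cand)) return(NULL)
  if (length(cand) > 1L) {
    stop(sprintf(
      "ambiguous parse: %d disjoint grammar regions (offsets %s); expected exactly one",
      length(cand), paste(vapply(cand, `[[`, 0L, "start"), collapse = ", ")),
      call. = FALSE)
  }
  structure(c(cand[[1]], list(strand = strand)), class = "tract_match")
}

#' @export
print.tract_match <- function(x, ...) {
  cat("<tract_match> strand ", x$strand, ", [", x$start, ", ", x$end, "): ",
      repeat_notation(x$decomposition), "\n", sep = "")
  invisible(x)
}
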