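# Independent brute-force oracle: enumerate every (v, w, x, block, z)
# whose rendering equals `seq`, by trying all segmentations. Shares no
# code with the parser.

chunk4 <- function(s) {
  n <- nchar(s)
  if (n == 0L || n %% 4L != 0L) return(NULL)
  substring(s, seq(1L, n, 4L), seq(4L, n, 4L))
}

try_make <- function(v, w, x, block, z) {
  suppressWarnings(tryCatch(motif_decomposition(v, w, x, block, z),
                            error = function(e) NULL))
}

enumerate_decompositions <- function(seq) {
  tet_ok <- repeat_tetramers()
  out <- list()
  L <- nchar(seq)
  v <- 0L
  repeat {
    tets <- chunk4(substr(seq, 2L * v + 1L, L))
    if (!is.null(tets) && all(tets %in% tet_ok)) {
      n <- length(tets)
      for (w in 0:n) {
        if (w > 0L && tets[w] != "TCTG") break
        for (x in 0:(n - w)) {
          if (x > 0L && tets[w + x] != "CCTG") break
          rem <- if (w + x < n) tets[(w + x + 1L):n] else character()
          if (!length(rem)) {
            cand <- try_make(v, w, x, character(), 0L)
            if (!is.null(cand)) out[[length(out) + 1L]] <- cand
          } else {
            for (z in 0:(length(rem) - 1L)) {
              ztail <- if (z > 0L) rem[(length(rem) - z + 1L):length(rem)] else character()
              if (all(ztail == "CCTG")) {
                cand <- try_make(v, w, x, rem[seq_len(length(rem) - z)], z)
                if (!is.null(cand)) out[[length(out) + 1L]] <- cand
              }
            }
          }
        }
      }
    }
    if (substr(seq, 2L * v + 1L, 2L * v + 2L) != "TG") break
    v <- v + 1L
  }
  out
}

# Random valid decomposition generator (constructor-valid by design).
random_block <- function(y) {
  if (y == 0L) return(character())
  nctg <- c("TCTG", "GCTG", "ACTG")
  labs <- sample(repeat_tetramers(), y, replace = TRUE)
  labs[1L] <- sample(nctg, 1L)
  labs[y] <- sample(nctg, 1L)
  labs
}

random_decomposition <- function(vmax = 40L, wmax = 15L, tetmax = 80L) {
  v <- sample(0:vmax, 1L)
  w <- sample(0:wmax, 1L)
  y <- sample(c(0L, 0L, 1L, 2L, 3L, 4L, 5L, 6L), 1L)
  x <- sample(1:max(1L, tetmax - y - 1L), 1L)
  z <- if (y > 0L) sample(0:max(0L, tetmax - x - y), 1L) else 0L
  suppressWarnings(motif_decomposition(v, w, x, random_block(y), z))
}

# Random valid decomposition whose rendered tract is at most max_bp.
random_small_decomposition <- function(max_bp = 80L) {
  repeat {
    d <- random_decomposition(vmax = 10L, wmax = 4L, tetmax = 12L)
    if (tract_length(d) <= max_bp) return(d)
  }
}
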