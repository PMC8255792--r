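# internal helpers shared across modules

# Round half away from zero, the convention used for all reported
# percentages (base round() is banker's rounding).
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

as_count <- function(x, name, min = 0) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != as.integer(x) || x < min) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

as_prob <- function(x, name) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a probability in [0, 1]", name), call. = FALSE)
  }
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
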