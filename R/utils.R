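# Internal helpers shared across modules: IUPAC state encoding, seeded RNG
# scoping, and small input checks.

# Bitmask encoding of nucleotide states: A=1, C=2, G=4, T=8.  Ambiguity codes
# are unions; '-' and '?' carry no information and map to the full set.
.state_bits <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L,
  "-" = 15L, "?" = 15L
)

.single_bits <- c(1L, 2L, 4L, 8L)
.bit_base <- c(`1` = "A", `2` = "C", `4` = "G", `8` = "T")

#' @noRd
chars_of <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

# Sequences (named character vector) -> integer bitmask matrix, rows = ids.
# Illegal characters raise an error naming the id and position.
#' @noRd
encode_states <- function(seqs) {
  stopifnot(length(seqs) >= 1L)
  n <- length(seqs)
  L <- nchar(seqs[[1L]])
  out <- matrix(NA_integer_, n, L, dimnames = list(names(seqs), NULL))
  for (i in seq_len(n)) {
    ch <- chars_of(toupper(seqs[[i]]))
    bits <- unname(.state_bits[ch])
    if (anyNA(bits)) {
      pos <- which(is.na(bits))[1L]
      stop(sprintf("illegal character '%s' at position %d in sequence '%s'",
                   ch[pos], pos, names(seqs)[i]), call. = FALSE)
    }
    out[i, ] <- bits
  }
  out
}

# Bitmask matrix restricted to unambiguous single bases; everything else NA.
# Used by the distance and diagnostic-site code, where ambiguity codes are
# excluded from comparison entirely.
#' @noRd
encode_resolved <- function(seqs) {
  m <- encode_states(seqs)
  m[!(m %in% .single_bits)] <- NA_integer_
  m
}

# Evaluate expr under a fixed RNG state without disturbing the caller's.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Named substream of a top-level seed, so pipeline stages draw independently.
#' @noRd
substream <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.double(seed) * 7919 + h) %% 2147483587)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
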