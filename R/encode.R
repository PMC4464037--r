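# Numeric DNA alphabet: A=0, C=1, G=2, T=3. XOR of two symbols is again a
# symbol because the alphabet size is a power of two; all hashing below relies
# on this.

.SYM_CHARS <- c("A", "C", "G", "T")

#' Encode a DNA string over the 2-bit numeric alphabet
#'
#' Maps `A/C/G/T` (case-insensitive) to the integers `0/1/2/3`. The undefined
#' base `N` is assigned the numeric value 0 (i.e. treated as `A` by every
#' downstream comparison) and its positions are recorded in the
#' `"n_positions"` attribute (1-based), so callers can mask or filter
#' alignments overlapping runs of `N` if desired.
#'
#' @param x A single character string over `A,C,G,T,N` (either case).
#' @return An integer vector of symbols in `0:3`, with attribute
#'   `n_positions` holding the 1-based positions where an `N` was encoded.
#' @examples
#' encode_dna("ACGT")
#' attr(encode_dna("NGC"), "n_positions")
#' @export
encode_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) stop("cannot encode an empty sequence")
  code <- utf8ToInt(x)
  map <- integer(128L) - 1L
  map[utf8ToInt("A")] <- 0L; map[utf8ToInt("a")] <- 0L
  map[utf8ToInt("C")] <- 1L; map[utf8ToInt("c")] <- 1L
  map[utf8ToInt("G")] <- 2L; map[utf8ToInt("g")] <- 2L
  map[utf8ToInt("T")] <- 3L; map[utf8ToInt("t")] <- 3L
  map[utf8ToInt("N")] <- 0L; map[utf8ToInt("n")] <- 0L
  bad <- code > 127L
  sym <- integer(length(code))
  sym[!bad] <- map[code[!bad]]
  sym[bad] <- -1L
  if (any(sym < 0L)) {
    p <- which(sym < 0L)[1L]
    stop(sprintf("invalid character '%s' at position %d", substr(x, p, p), p))
  }
  is_n <- code == utf8ToInt("N") | code == utf8ToInt("n")
  attr(sym, "n_positions") <- which(is_n)
  sym
}

#' Decode numeric symbols back to a DNA string
#'
#' @param sym Integer vector of symbols in `0:3`.
#' @return A character string over `A,C,G,T`.
#' @export
decode_dna <- function(sym) {
  stopifnot(all(sym >= 0L & sym <= 3L))
  paste(.SYM_CHARS[sym + 1L], collapse = "")
}

#' Reverse complement of an encoded sequence
#'
#' Complementation is `XOR 3` in the numeric alphabet (A<->T, C<->G).
#'
#' @param sym Integer vector of symbols in `0:3`.
#' @return The reverse-complemented symbol vector.
#' @export
revcomp_dna <- function(sym) {
  rev(bitwXor(as.integer(sym), 3L))
}

#' Decode a Phred+33 quality string to integer scores
#'
#' @param q A single character string of Sanger (Phred+33) qualities.
#' @return Integer vector of Phred scores.
#' @examples
#' phred_decode("!!II")
#' @export
phred_decode <- function(q) {
  stopifnot(is.character(q), length(q) == 1L)
  v <- utf8ToInt(q) - 33L
  if (any(v < 0L)) stop("quality string contains characters below '!' (Phred+33)")
  v
}
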