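# The hash-function layer.
#
# h_xor maps a length-m pattern to a length-w fingerprint by XOR-folding the
# ceiling(m/w) - 1 aligned windows P[iw..iw+w) together with the final window
# P[m-w..m). The ceiling reading of the window count ensures every pattern
# position feeds at least one window (when w does not divide m the final
# window overlaps the last aligned one), which is what makes the hash
# Hamming-aware with the tight 2k bound: a substitution perturbs the
# fingerprint at one offset (position covered once) or at two related offsets
# (position in the overlap region).
#
# The fold is XOR-linear: h(P xor D) = h(P) xor h(D), so the image of a
# Hamming ball around P is h(P) xor {h(D) : weight(D) <= k}, a small set that
# can be enumerated by composing per-substitution "error events".

.check_width <- function(m, w) {
  if (w < 1L) stop("fingerprint width w must be >= 1")
  if (w > m) stop("fingerprint width w must not exceed the pattern length m")
  if (w > 32L) stop("fingerprint width w must be <= 32")
}

.bitw_fold <- function(p, w, op) {
  # shared window decomposition for hash_xor / quality_mask
  if (is.matrix(p)) {
    m <- ncol(p)
    .check_width(m, w)
    cw <- ceiling(m / w)
    f <- p[, (m - w + 1L):m, drop = FALSE]
    if (cw >= 2L) {
      for (i in 0:(cw - 2L)) {
        g <- op(f, p[, (i * w + 1L):(i * w + w), drop = FALSE])
        dim(g) <- dim(f)
        f <- g
      }
    }
    f
  } else {
    m <- length(p)
    .check_width(m, w)
    cw <- ceiling(m / w)
    f <- p[(m - w + 1L):m]
    if (cw >= 2L) {
      for (i in 0:(cw - 2L)) f <- op(f, p[(i * w + 1L):(i * w + w)])
    }
    as.integer(f)
  }
}

#' XOR fingerprint of a pattern
#'
#' Computes the length-`w` fingerprint of an encoded pattern: the symbol-wise
#' XOR of the aligned windows `P[iw..iw+w)`, `i = 0..ceiling(m/w)-2`, and the
#' final window `P[m-w..m)`. When `m == w` the fingerprint is the pattern
#' itself. The function is a de Bruijn hash (fingerprints of patterns shifted
#' by one position overlap in `w - 1` symbols) and Hamming-aware (`k`
#' substitutions in the pattern change at most `2k` fingerprint symbols).
#'
#' @param p Integer vector of symbols in `0:3` (a pattern), or an integer
#'   matrix with one pattern per row (all hashed at once).
#' @param w Fingerprint width, `1 <= w <= min(m, 32)`.
#' @return An integer vector of length `w`, or a matrix with `w` columns when
#'   `p` is a matrix.
#' @examples
#' hash_xor(c(0L, 1L, 2L, 3L, 0L, 1L), 4)
#' @export
hash_xor <- function(p, w) {
  .bitw_fold(p, as.integer(w), bitwXor)
}

#' Fingerprint string of a text
#'
#' Extends the pattern hash to a text `T` of length `n`: the output is the
#' unique string of length `n - m + w` whose window of width `w` at every
#' position `i` equals `hash_xor` of the text window of length `m` at `i`
#' (the de Bruijn property makes consecutive fingerprints consistent, so such
#' a string exists). The succinct index is built over this string.
#'
#' @param tsym Integer vector of text symbols in `0:3`.
#' @param m Pattern (block) length.
#' @param w Fingerprint width.
#' @return Integer vector of length `n - m + w`.
#' @export
hash_text <- function(tsym, m, w) {
  n <- length(tsym)
  m <- as.integer(m); w <- as.integer(w)
  if (n < m) stop("text shorter than the block length m")
  .check_width(m, w)
  cw <- ceiling(m / w)
  out <- integer(n - m + w)
  out[1:w] <- hash_xor(tsym[1:m], w)
  if (n > m) {
    i <- 1:(n - m)
    acc <- tsym[i + m] # last symbol of the final window of window i
    if (cw >= 2L) {
      for (j in 0:(cw - 2L)) acc <- bitwXor(acc, tsym[i + (j + 1L) * w])
    }
    out[w + i] <- acc
  }
  out
}

#' Low-quality mask of a block in fingerprint space
#'
#' Folds the indicator of low base quality through the same window
#' decomposition as [hash_xor()], using OR instead of XOR: entry `i` of the
#' mask is 3 exactly when at least one base feeding fingerprint offset `i`
#' has Phred quality `<= q`. The values 0 and 3 are used for their binary
#' representations (00 and 11), so the mask can absorb any symbol-level
#' difference under bitwise OR.
#'
#' @param qual Integer vector of Phred scores for the block (length `m`).
#' @param w Fingerprint width.
#' @param q Quality threshold; the default 15 is the operating point used
#'   throughout the package.
#' @return Integer vector over `{0, 3}` of length `w`, with attribute
#'   `threshold_q`.
#' @export
quality_mask <- function(qual, w, q = 15L) {
  qual <- as.integer(qual)
  if (any(qual < 0L)) stop("Phred scores must be >= 0")
  fq <- ifelse(qual > q, 0L, 3L)
  out <- .bitw_fold(fq, as.integer(w), bitwOr)
  attr(out, "threshold_q") <- as.integer(q)
  out
}

#' Quality filter predicate on a candidate fingerprint
#'
#' A candidate fingerprint `f` passes when it differs from the block
#' fingerprint `h_b` only at masked (low-quality) offsets, i.e. when
#' `(f XOR h_b) OR mask == mask`.
#'
#' @param f Candidate fingerprint (integer vector, length `w`).
#' @param h_b Fingerprint of the searched block.
#' @param mask Low-quality mask from [quality_mask()].
#' @return `TRUE` or `FALSE`.
#' @export
passes_quality_filter <- function(f, h_b, mask) {
  if (length(f) != length(h_b) || length(f) != length(mask))
    stop("fingerprint and mask widths differ")
  d <- bitwXor(as.integer(f), as.integer(h_b))
  all(bitwOr(d, as.integer(mask)) == as.integer(mask))
}

# Per-substitution error events in fingerprint space for an (m, w) block.
# A substitution with XOR value e at a position covered by one window yields
# a single event {offset o, value e}; a position in the overlap between the
# last aligned window and the final window yields a paired event with value e
# at offsets (b + (m mod w), b), b in [0, overlap). Returns a matrix of delta
# fingerprints, one event per row; at most (2*sigma - 2)*w = 6w rows.
.fingerprint_events <- function(m, w) {
  rows <- list()
  for (e in 1:3) {
    for (o in 0:(w - 1L)) {
      d <- integer(w); d[o + 1L] <- e
      rows[[length(rows) + 1L]] <- d
    }
  }
  if (m %% w != 0L) {
    r <- m %% w
    overlap <- ceiling(m / w) * w - m
    for (e in 1:3) {
      for (b in 0:(overlap - 1L)) {
        d <- integer(w); d[b + 1L] <- e; d[b + r + 1L] <- e
        rows[[length(rows) + 1L]] <- d
      }
    }
  }
  do.call(rbind, rows)
}

#' Enumerate the squeezed Hamming ball in fingerprint space
#'
#' Returns a set of fingerprints guaranteed to contain `hash_xor(P')` for
#' every pattern `P'` within Hamming distance `k` of `P` (candidate
#' completeness), while never exceeding `sum_{j<=k} (6w)^j` elements
#' (candidate budget). Extra members are false-positive candidates that the
#' plain-text verification step removes. With a quality `mask`, the set is
#' intersected with the fingerprints passing [passes_quality_filter()]; the
#' result still contains the fingerprint of any `P'` that differs from `P`
#' only at positions whose fingerprint offsets are masked.
#'
#' @param p Encoded pattern (integer vector over `0:3`).
#' @param w Fingerprint width.
#' @param k Maximum number of substitutions, `k >= 0`.
#' @param mask Optional quality mask from [quality_mask()].
#' @return Integer matrix with `w` columns, one candidate fingerprint per
#'   row. Always contains `hash_xor(p, w)` (first row).
#' @export
enumerate_fingerprint_candidates <- function(p, w, k, mask = NULL) {
  w <- as.integer(w); k <- as.integer(k)
  if (k < 0L) stop("k must be >= 0")
  m <- length(p)
  .check_width(m, w)
  f0 <- hash_xor(p, w)
  deltas <- matrix(0L, nrow = 1L, ncol = w)
  if (k > 0L) {
    ev <- .fingerprint_events(m, w)
    pow4 <- 4^(0:(w - 1L)) # w <= 32 > 26 never occurs with k > 0 in practice,
                           # but guard the exact-double key range anyway
    if (w > 26L) stop("candidate enumeration supports w <= 26")
    keyof <- function(mat) as.vector(mat %*% pow4)
    seen <- 0
    frontier <- deltas
    for (j in seq_len(k)) {
      nf <- nrow(frontier); ne <- nrow(ev)
      expanded <- bitwXor(frontier[rep(seq_len(nf), each = ne), , drop = FALSE],
                          ev[rep(seq_len(ne), times = nf), , drop = FALSE])
      dim(expanded) <- c(nf * ne, w)
      keys <- keyof(expanded)
      keep <- !duplicated(keys) & !(keys %in% seen)
      frontier <- expanded[keep, , drop = FALSE]
      seen <- c(seen, keys[keep])
      if (nrow(frontier) == 0L) break
      deltas <- rbind(deltas, frontier)
    }
  }
  cand <- bitwXor(deltas, matrix(f0, nrow = nrow(deltas), ncol = w, byrow = TRUE))
  dim(cand) <- dim(deltas)
  if (!is.null(mask)) {
    mask <- as.integer(mask)
    if (length(mask) != w) stop("mask width differs from fingerprint width")
    mm <- matrix(mask, nrow(deltas), w, byrow = TRUE)
    or <- bitwOr(deltas, mm)
    dim(or) <- dim(deltas)
    ok <- rowSums(or != mm) == 0L
    cand <- cand[ok, , drop = FALSE]
  }
  storage.mode(cand) <- "integer"
  cand
}
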