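# The dB-hash index: BWT of the fingerprint string h(T) (plus sentinel) with
# wavelet-tree rank, a sampled suffix array for locate, an auxiliary table of
# precomputed backward-search intervals for all length-w_aux fingerprint
# prefixes, and the plain text packed at 3 bits per base for verification.
#
# Contigs are concatenated at the coordinate level; no alignment may span a
# contig boundary (enforced at verification), so no separator symbol is
# reserved and the alphabet stays at sigma = 4.

.DBHASH_MAGIC <- "DBH1"
.DBHASH_VERSION <- 1L

#' Suffix array of a sentinel-terminated symbol string
#'
#' The last element must be a unique minimum (the sentinel); by convention
#' `-1L` is used. Construction uses prefix doubling; correctness is
#' independent of the algorithm, and a naive full sort serves as the test
#' oracle.
#'
#' @param s Integer vector whose last element is strictly smaller than every
#'   other element.
#' @return Integer vector: the permutation of `0:(length(s)-1)` sorting all
#'   suffixes lexicographically (0-based positions).
#' @examples
#' build_suffix_array(c(1L, 0L, -1L))
#' @export
build_suffix_array <- function(s) {
  s <- as.integer(s)
  n <- length(s)
  if (n < 1L) stop("empty string")
  sent <- s[n]
  if (any(s[-n] <= sent)) stop("last element must be a unique minimal sentinel")
  cpp_suffix_array(s)
}

#' Burrows-Wheeler transform from a suffix array
#'
#' @param s Sentinel-terminated integer string (as for
#'   [build_suffix_array()]).
#' @param sa Its suffix array (0-based).
#' @return Integer vector `BWT[i] = s[sa[i] - 1]`, wrapping so that the row
#'   starting at position 0 emits the sentinel.
#' @export
bwt_from_sa <- function(s, sa) {
  s <- as.integer(s)
  n <- length(s)
  if (length(sa) != n || !setequal(sa, 0:(n - 1L))) stop("sa is not a valid suffix array")
  s[((sa - 1L) %% n) + 1L]
}

.default_w <- function(m, n) {
  w <- ceiling(log(m * n, base = 4))
  max(4L, min(as.integer(w), m, 32L))
}

.default_w_aux <- function(w, n) {
  ln <- log(n, base = 4)
  wa <- floor(ln - log(ln, base = 4))
  max(0L, min(as.integer(wa), w - 1L))
}

#' Build a dB-hash index over a reference
#'
#' Computes the fingerprint string `h(T)` of the concatenated reference,
#' builds its BWT with wavelet-tree rank support, samples one suffix-array
#' pointer every `sa_step` text positions, precomputes backward-search
#' intervals for all `4^w_aux` fingerprint prefixes, and stores the plain
#' text packed at 3 bits per base for candidate verification.
#'
#' The block length `m` is fixed once the index is built: only reads of
#' length `>= m` can be aligned against it, in blocks of length `m`. The
#' fingerprint width defaults to `ceiling(log4(m * n))` clamped to
#' `[4, min(m, 32)]`; the auxiliary depth defaults to
#' `floor(log4(n) - log4(log4(n)))` clamped to `[0, w - 1]`, which keeps the
#' table within `n / log(n)` entries.
#'
#' @param reference Path to a FASTA file (possibly gzipped) or a named
#'   character vector of contig sequences.
#' @param m Block length (pattern length the index is tuned for).
#' @param w Fingerprint width override; `NULL` for the default sizing rule.
#' @param sa_step Suffix-array sampling step (default 16).
#' @param w_aux Auxiliary-table prefix depth override; `NULL` for the default.
#' @return An object of class `dbhash_index`.
#' @export
build_index <- function(reference, m, w = NULL, sa_step = 16L, w_aux = NULL) {
  m <- as.integer(m)
  if (m < 1L) stop("block length m must be >= 1")
  sa_step <- as.integer(sa_step)
  if (sa_step < 1L) stop("sa_step must be >= 1")
  contigs <- if (is.character(reference) && length(reference) == 1L &&
                 !grepl("[^ACGTNacgtn]", reference) && nchar(reference) >= m) {
    # a bare sequence string is accepted as a single contig
    setNames(unname(reference),
             if (is.null(names(reference))) "contig_1" else names(reference))
  } else if (is.character(reference) && file.exists(reference[1]) &&
             length(reference) == 1L) {
    read_fasta(reference)
  } else {
    reference
  }
  if (is.null(names(contigs)) || anyNA(names(contigs)) || any(names(contigs) == ""))
    names(contigs) <- paste0("contig_", seq_along(contigs))
  lens <- nchar(contigs)
  short <- lens < m
  if (any(short)) {
    warning(sprintf("skipping %d contig(s) shorter than m = %d", sum(short), m))
    contigs <- contigs[!short]
    lens <- lens[!short]
  }
  if (length(contigs) == 0L) stop("no contig of length >= m")

  enc <- lapply(unname(contigs), encode_dna)
  n_pos <- integer(0)
  off <- cumsum(c(0L, lens[-length(lens)]))
  for (i in seq_along(enc)) {
    np <- attr(enc[[i]], "n_positions")
    if (length(np)) n_pos <- c(n_pos, np - 1L + off[i])
  }
  tsym <- unlist(lapply(enc, as.integer), use.names = FALSE)
  n <- length(tsym)
  if (is.null(w)) w <- .default_w(m, n)
  w <- as.integer(w)
  .check_width(m, w)
  if (is.null(w_aux)) w_aux <- .default_w_aux(w, n)
  w_aux <- as.integer(w_aux)
  if (w_aux < 0L || w_aux >= max(w, 1L))
    stop("w_aux must lie in [0, w - 1]")
  bound <- .default_w_aux(w, n)
  if (w_aux > bound)
    stop(sprintf("w_aux = %d exceeds the n-bit budget bound %d", w_aux, bound))

  ht <- hash_text(tsym, m, w)
  fm <- cpp_build_fm(ht, sa_step)
  idx <- list(
    version = .DBHASH_VERSION,
    m = m, w = w, w_aux = w_aux, s = sa_step,
    n = n, nh = length(ht), nprime = fm$nprime,
    contigs = tibble::tibble(name = names(contigs),
                             length = as.integer(lens),
                             offset = as.integer(off)),
    C = fm$C, dollar_row = fm$dollar_row,
    wt_b1 = fm$wt_b1, wt_b2l = fm$wt_b2l, wt_b2r = fm$wt_b2r,
    mark = fm$mark, sa_samples = fm$sa_samples,
    text_words = cpp_pack_text(tsym),
    n_positions = as.integer(n_pos)
  )
  if (w_aux > 0L) {
    aux <- cpp_build_aux(idx, w_aux)
    idx$aux_l <- aux$aux_l
    idx$aux_r <- aux$aux_r
  } else {
    idx$aux_l <- integer(0)
    idx$aux_r <- integer(0)
  }
  class(idx) <- "dbhash_index"
  idx
}

#' @export
print.dbhash_index <- function(x, ...) {
  cat(sprintf("dB-hash index: n = %d bases in %d contig(s)\n",
              x$n, nrow(x$contigs)))
  cat(sprintf("  block length m = %d, fingerprint width w = %d, w_aux = %d, SA step = %d\n",
              x$m, x$w, x$w_aux, x$s))
  st <- index_stats(x)
  cat(sprintf("  core payload: %.0f bytes (%.2f bytes/base)\n",
              sum(st$bytes), sum(st$bytes) / x$n))
  invisible(x)
}

#' Backward search for a fingerprint
#'
#' Refines the suffix-array interval of rows of the BWT of `h(T)` prefixed by
#' `f`, one symbol at a time from the last symbol. When the auxiliary table
#' is enabled, its precomputed interval replaces the first `w_aux` refinement
#' steps; results are identical either way.
#'
#' @param index A `dbhash_index`.
#' @param f Fingerprint (integer vector over `0:3`); an empty vector returns
#'   the full row interval.
#' @param use_aux Use the auxiliary prefix table when applicable.
#' @return Integer vector of length 2: the half-open row interval \code{[l, r)},
#'   whose width is the number of occurrences of `f` in `h(T)`.
#' @export
backward_search <- function(index, f, use_aux = TRUE) {
  stopifnot(inherits(index, "dbhash_index"))
  f <- as.integer(f)
  if (any(f < 0L | f > 3L)) stop("fingerprint symbols must be in 0:3")
  cpp_backward_search(unclass(index), f, isTRUE(use_aux))
}

#' Locate the text positions of a row interval
#'
#' Walks each row of the interval backwards with LF steps to the nearest
#' sampled suffix-array pointer.
#'
#' @param index A `dbhash_index`.
#' @param interval Length-2 interval vector from [backward_search()].
#' @return Sorted integer vector of 0-based positions in `h(T)` (equivalently
#'   in the concatenated text).
#' @export
locate_occurrences <- function(index, interval) {
  stopifnot(inherits(index, "dbhash_index"), length(interval) == 2L)
  l <- as.integer(interval[1]); r <- as.integer(interval[2])
  if (l > r || l < 0L || r > index$nprime) stop("invalid row interval")
  if (l == r) return(integer(0))
  cpp_locate(unclass(index), l, r)
}

#' Hash lookup: all positions where a fingerprint occurs in h(T)
#'
#' Composition of [backward_search()] and [locate_occurrences()]. By the de
#' Bruijn extension property, the result is a superset of the exact
#' occurrence positions of any pattern hashing to `f`.
#'
#' @inheritParams backward_search
#' @return Sorted integer vector of 0-based positions.
#' @export
lookup_fingerprint <- function(index, f, use_aux = TRUE) {
  locate_occurrences(index, backward_search(index, f, use_aux))
}

#' Wavelet-tree access and rank over the BWT (testing surface)
#'
#' `wavelet_access` reconstructs the BWT symbol at row `i` (`-1` for the
#' sentinel row); `wavelet_rank` counts occurrences of symbol `c` among the
#' first `i` BWT rows (the sentinel is not counted as any symbol).
#'
#' @param index A `dbhash_index`.
#' @param i Row index, 0-based (`rank` counts rows `[0, i)`).
#' @param c Symbol in `0:3`.
#' @return An integer.
#' @export
wavelet_access <- function(index, i) {
  stopifnot(inherits(index, "dbhash_index"))
  cpp_wt_access(unclass(index), as.integer(i))
}

#' @rdname wavelet_access
#' @export
wavelet_rank <- function(index, c, i) {
  stopifnot(inherits(index, "dbhash_index"))
  cpp_wt_occ(unclass(index), as.integer(c), as.integer(i))
}

#' Pack / unpack a symbol vector at 3 bits per base
#'
#' The plain text is stored in blocks of 8 symbols per 32-bit word, which
#' lets the verifier compare one block per word operation.
#'
#' @param sym Integer vector of symbols in `0:3`.
#' @return `pack_dna_text`: integer vector of packed words.
#' @export
pack_dna_text <- function(sym) {
  cpp_pack_text(as.integer(sym))
}

#' @rdname pack_dna_text
#' @param words Packed words from `pack_dna_text`.
#' @param n Total number of symbols stored.
#' @param from 0-based start of the slice to unpack.
#' @param len Number of symbols to unpack (default: all).
#' @export
unpack_dna_text <- function(words, n, from = 0L, len = n - from) {
  cpp_unpack_text(words, as.integer(n), as.integer(from), as.integer(len))
}

#' Verify a candidate position by bounded Hamming distance
#'
#' Compares the pattern with the text window at `pos` block-by-block (8
#' symbols per word) with early exit once the running mismatch count exceeds
#' `k`.
#'
#' @param index A `dbhash_index`.
#' @param p Encoded pattern (integer vector over `0:3`).
#' @param pos 0-based position in the concatenated text.
#' @param k Mismatch bound.
#' @return The Hamming distance if `<= k`, otherwise `NA_integer_`.
#' @export
hamming_verify <- function(index, p, pos, k) {
  stopifnot(inherits(index, "dbhash_index"))
  d <- cpp_hamming_verify(index$text_words, index$n, cpp_pack_text(as.integer(p)),
                          length(p), as.integer(pos), as.integer(k))
  if (d < 0L) NA_integer_ else d
}

#' Space accounting of the index payload
#'
#' Reports the bytes actually held by each bit-packed component: wavelet-tree
#' payload bits, rank directories, the row-marking bit vector, sampled
#' suffix-array pointers, the auxiliary interval table and the 3-bit packed
#' text. Components are itemised rather than asserted against a closed-form
#' total.
#'
#' @param index A `dbhash_index`.
#' @return A tibble with columns `component` and `bytes`.
#' @export
index_stats <- function(index) {
  stopifnot(inherits(index, "dbhash_index"))
  bv_payload <- function(bv) 4 * length(bv$words)
  bv_dirs <- function(bv) 4 * length(bv$dirs)
  tibble::tibble(
    component = c("wavelet_bits", "rank_directories", "mark_bits",
                  "sa_samples", "aux_table", "packed_text"),
    bytes = c(
      bv_payload(index$wt_b1) + bv_payload(index$wt_b2l) + bv_payload(index$wt_b2r),
      bv_dirs(index$wt_b1) + bv_dirs(index$wt_b2l) + bv_dirs(index$wt_b2r) +
        bv_dirs(index$mark),
      bv_payload(index$mark),
      4 * length(index$sa_samples),
      4 * (length(index$aux_l) + length(index$aux_r)),
      4 * length(index$text_words)
    )
  )
}

# --- serialization ----------------------------------------------------------
# Versioned, magic-tagged binary with explicit little-endian 32-bit integers.

.wb_ivec <- function(con, v) {
  writeBin(length(v), con, size = 4L, endian = "little")
  writeBin(as.integer(v), con, size = 4L, endian = "little")
}
.rb_ivec <- function(con) {
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  readBin(con, "integer", n, size = 4L, endian = "little")
}
.wb_bv <- function(con, bv) {
  .wb_ivec(con, bv$words); .wb_ivec(con, bv$dirs)
  writeBin(as.integer(bv$len), con, size = 4L, endian = "little")
}
.rb_bv <- function(con) {
  words <- .rb_ivec(con); dirs <- .rb_ivec(con)
  len <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  list(words = words, dirs = dirs, len = len)
}
.wb_str <- function(con, s) {
  raw <- charToRaw(enc2utf8(s))
  writeBin(length(raw), con, size = 4L, endian = "little")
  writeBin(raw, con)
}
.rb_str <- function(con) {
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  rawToChar(readBin(con, "raw", n))
}

#' Serialize / deserialize a dB-hash index
#'
#' The on-disk format is a versioned, magic-tagged binary with explicit
#' little-endian 32-bit integers; the build parameters (`m`, `w`, `w_aux`,
#' `s`) travel in the header so an aligner can refuse incompatible queries.
#' A load followed by a save reproduces the file byte for byte.
#'
#' @param index A `dbhash_index`.
#' @param path Output / input file path.
#' @return `write_index` returns `path` invisibly; `read_index` returns the
#'   index.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "dbhash_index"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.DBHASH_MAGIC), con)
  for (fld in c("version", "m", "w", "w_aux", "s", "n", "nh", "nprime", "dollar_row"))
    writeBin(as.integer(index[[fld]]), con, size = 4L, endian = "little")
  writeBin(nrow(index$contigs), con, size = 4L, endian = "little")
  for (i in seq_len(nrow(index$contigs))) {
    .wb_str(con, index$contigs$name[i])
    writeBin(c(index$contigs$length[i], index$contigs$offset[i]), con,
             size = 4L, endian = "little")
  }
  .wb_ivec(con, index$C)
  for (fld in c("wt_b1", "wt_b2l", "wt_b2r", "mark")) .wb_bv(con, index[[fld]])
  for (fld in c("sa_samples", "aux_l", "aux_r", "text_words", "n_positions"))
    .wb_ivec(con, index[[fld]])
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, .DBHASH_MAGIC)) stop("not a dB-hash index file: bad magic")
  hdr <- readBin(con, "integer", 9L, size = 4L, endian = "little")
  names(hdr) <- c("version", "m", "w", "w_aux", "s", "n", "nh", "nprime", "dollar_row")
  if (hdr[["version"]] != .DBHASH_VERSION)
    stop(sprintf("unsupported index format version %d", hdr[["version"]]))
  nc <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  nm <- character(nc); ln <- integer(nc); off <- integer(nc)
  for (i in seq_len(nc)) {
    nm[i] <- .rb_str(con)
    v <- readBin(con, "integer", 2L, size = 4L, endian = "little")
    ln[i] <- v[1]; off[i] <- v[2]
  }
  idx <- as.list(hdr)
  idx$contigs <- tibble::tibble(name = nm, length = ln, offset = off)
  idx$C <- .rb_ivec(con)
  for (fld in c("wt_b1", "wt_b2l", "wt_b2r", "mark")) idx[[fld]] <- .rb_bv(con)
  for (fld in c("sa_samples", "aux_l", "aux_r", "text_words", "n_positions"))
    idx[[fld]] <- .rb_ivec(con)
  class(idx) <- "dbhash_index"
  idx
}
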