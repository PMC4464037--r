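# The randomized k-mismatch search: split the read into non-overlapping
# blocks of the index block length m, enumerate the squeezed Hamming ball of
# each block in fingerprint space (radius floor(k / t) by pigeonhole), look
# the candidate fingerprints up in the succinct index, and verify every
# candidate read start against the packed plain text at the full read length.

#' Split a read into index-compatible blocks
#'
#' Produces `t = floor(len / m)` non-overlapping blocks at offsets `0, m,
#' 2m, ...`; when `m` does not divide the read length, one extra block
#' anchored at `len - m` (overlapping the previous one) is appended so every
#' read position is covered. The pigeonhole argument uses only the `t`
#' non-overlapping blocks.
#'
#' @param len Read length (or an encoded read, whose length is used).
#' @param m Index block length.
#' @return A tibble with columns `offset` (0-based) and `block` (index),
#'   plus attribute `t` = number of non-overlapping blocks.
#' @examples
#' split_into_blocks(100, 30)
#' @export
split_into_blocks <- function(len, m) {
  if (length(len) > 1L) len <- length(len)
  len <- as.integer(len); m <- as.integer(m)
  if (len < m) stop("read shorter than the index block length m: unalignable")
  t <- len %/% m
  off <- (0:(t - 1L)) * m
  if (len %% m != 0L) off <- c(off, len - m)
  out <- tibble::tibble(offset = off, block = seq_along(off))
  attr(out, "t") <- t
  out
}

#' Per-block error budget
#'
#' By pigeonhole, any occurrence of the read with at most `k` mismatches has
#' at least one of the `t` non-overlapping blocks carrying at most
#' `floor(k / t)` of them.
#'
#' @param k Total mismatch bound for the read.
#' @param t Number of non-overlapping blocks.
#' @return `floor(k / t)`.
#' @export
errors_per_block <- function(k, t) {
  k <- as.integer(k); t <- as.integer(t)
  if (t < 1L) stop("t must be >= 1")
  k %/% t
}

#' Candidate read-start positions from one block
#'
#' Enumerates the fingerprint candidates of the block (radius `k_b`,
#' optionally quality-filtered), looks each up in the index, and converts
#' every hit position `p` into the implied read start `p - offset`. Negative
#' starts are discarded; contig-boundary checks happen at verification.
#'
#' @param index A `dbhash_index`.
#' @param block Encoded block (integer vector of length `index$m`).
#' @param offset 0-based offset of the block within the read.
#' @param k_b Per-block error budget.
#' @param mask Optional quality mask for the block (quality mode).
#' @return Sorted unique integer vector of candidate read starts (0-based,
#'   concatenated-text coordinates).
#' @export
search_block <- function(index, block, offset, k_b, mask = NULL) {
  stopifnot(inherits(index, "dbhash_index"))
  if (length(block) != index$m) stop("block length must equal the index block length m")
  cand <- enumerate_fingerprint_candidates(block, index$w, k_b, mask)
  starts <- integer(0)
  for (i in seq_len(nrow(cand))) {
    iv <- cpp_backward_search(unclass(index), cand[i, ], TRUE)
    if (iv[1] < iv[2]) {
      pos <- cpp_locate(unclass(index), iv[1], iv[2])
      starts <- c(starts, pos - as.integer(offset))
    }
  }
  sort(unique(starts[starts >= 0L]))
}

.empty_alignments <- function() {
  tibble::tibble(read_id = character(0), contig = character(0),
                 pos = integer(0), strand = character(0),
                 mismatches = integer(0), block = integer(0))
}

.align_one_strand <- function(index, sym, qual, k, mode, read_id, strand) {
  len <- length(sym)
  blocks <- split_into_blocks(len, index$m)
  t <- attr(blocks, "t")
  k_b <- errors_per_block(k, t)
  pat_words <- cpp_pack_text(sym)
  rows <- list()
  seen_starts <- integer(0)
  for (b in seq_len(nrow(blocks))) {
    off <- blocks$offset[b]
    bsym <- sym[(off + 1L):(off + index$m)]
    mask <- NULL
    if (mode == "quality" && !is.null(qual))
      mask <- quality_mask(qual[(off + 1L):(off + index$m)], index$w)
    starts <- search_block(index, bsym, off, k_b, mask)
    starts <- setdiff(starts, seen_starts)
    seen_starts <- c(seen_starts, starts)
    for (p in starts) {
      if (p + len > index$n) next
      ci <- findInterval(p, index$contigs$offset)
      if (p + len > index$contigs$offset[ci] + index$contigs$length[ci]) next
      d <- cpp_hamming_verify(index$text_words, index$n, pat_words, len, p, k)
      if (d >= 0L) {
        rows[[length(rows) + 1L]] <- list(
          read_id = read_id, contig = index$contigs$name[ci],
          pos = p - index$contigs$offset[ci], strand = strand,
          mismatches = d, block = blocks$block[b])
      }
    }
  }
  if (!length(rows)) return(.empty_alignments())
  dplyr::bind_rows(lapply(rows, tibble::as_tibble))
}

#' Align one read against a dB-hash index
#'
#' Searches both the read and its reverse complement. In sensitive mode every
#' text position matching the read with at most `k` mismatches is reported
#' (candidate completeness plus pigeonhole make this exhaustive). In quality
#' mode candidate fingerprints are restricted to those differing from each
#' block's fingerprint only at low-quality offsets, which prunes the search
#' drastically but may miss occurrences whose errors sit at high-quality
#' positions.
#'
#' @param index A `dbhash_index`.
#' @param sequence Read sequence (character string or encoded integer
#'   vector).
#' @param quality Optional Phred+33 quality string (or integer scores);
#'   required for quality mode.
#' @param k Maximum number of mismatches.
#' @param mode `"sensitive"` (qualities ignored) or `"quality"`.
#' @param read_id Identifier carried into the result.
#' @return A tibble with columns `read_id`, `contig`, `pos` (0-based,
#'   contig-local, forward-strand leftmost), `strand` (`"+"`/`"-"`),
#'   `mismatches` and `block` (seed block that produced the hit), ordered by
#'   mismatch count then (contig, position, strand); deduplicated by
#'   (contig, pos, strand).
#' @export
align_read <- function(index, sequence, quality = NULL, k = 4L,
                       mode = c("sensitive", "quality"), read_id = "read") {
  stopifnot(inherits(index, "dbhash_index"))
  mode <- match.arg(mode)
  sym <- if (is.character(sequence)) encode_dna(sequence) else as.integer(sequence)
  len <- length(sym)
  if (len < index$m) {
    out <- .empty_alignments()
    attr(out, "unalignable") <- TRUE
    return(out)
  }
  qv <- NULL
  if (!is.null(quality)) {
    qv <- if (is.character(quality)) phred_decode(quality) else as.integer(quality)
    if (length(qv) != len) stop("quality length differs from sequence length")
  }
  if (mode == "quality" && is.null(qv))
    stop("quality mode requires base qualities; use mode = 'sensitive' for FASTA reads")
  k <- as.integer(k)
  fwd <- .align_one_strand(index, sym, qv, k, mode, read_id, "+")
  rc <- .align_one_strand(index, revcomp_dna(sym), if (is.null(qv)) NULL else rev(qv),
                          k, mode, read_id, "-")
  out <- dplyr::bind_rows(fwd, rc)
  if (nrow(out)) {
    out <- out %>%
      dplyr::mutate(.ci = match(.data$contig, index$contigs$name)) %>%
      dplyr::arrange(.data$mismatches, .data$.ci, .data$pos, .data$strand) %>%
      dplyr::distinct(.data$contig, .data$pos, .data$strand, .keep_all = TRUE) %>%
      dplyr::select(-".ci")
  }
  attr(out, "contig_levels") <- index$contigs$name
  out
}

#' Align a table of reads
#'
#' @param index A `dbhash_index`.
#' @param reads A tibble with columns `id`, `sequence` and optionally
#'   `quality` (Phred+33 strings), e.g. from [read_fastq()] or
#'   [sample_reads()].
#' @inheritParams align_read
#' @return A tibble of all alignments (see [align_read()]) of class
#'   `dbhash_alignments`, with an attribute `stats` summarising reads
#'   processed, aligned, unique/multiple, unmapped and unalignable (shorter
#'   than `m`).
#' @export
align_reads <- function(index, reads, k = 4L, mode = c("sensitive", "quality")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)))
  has_q <- "quality" %in% names(reads)
  n_unalignable <- 0L
  res <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    q <- if (has_q) reads$quality[i] else NULL
    a <- align_read(index, reads$sequence[i], q, k, mode, read_id = reads$id[i])
    if (isTRUE(attr(a, "unalignable"))) n_unalignable <- n_unalignable + 1L
    res[[i]] <- a
  }
  out <- dplyr::bind_rows(res)
  if (!nrow(out)) out <- .empty_alignments()
  best <- if (nrow(out)) report_best(out) else
    tibble::tibble(read_id = character(0), multiplicity = integer(0))
  n_reads <- nrow(reads)
  n_aligned <- length(unique(out$read_id))
  stats <- tibble::tibble(
    reads = n_reads,
    aligned = n_aligned,
    unique = sum(best$multiplicity == 1L),
    multiple = sum(best$multiplicity > 1L),
    unmapped = n_reads - n_aligned,
    unalignable = n_unalignable,
    k = as.integer(k), mode = mode
  )
  attr(out, "stats") <- stats
  attr(out, "contig_levels") <- index$contigs$name
  class(out) <- c("dbhash_alignments", class(out))
  out
}

#' Primary alignment per read
#'
#' Picks, for every read, the alignment with the fewest mismatches, breaking
#' ties deterministically by (contig order, position, strand with `+`
#' first), and annotates how many co-optimal locations the read has.
#'
#' @param alignments Tibble from [align_read()] / [align_reads()].
#' @return A tibble with one row per aligned read: the chosen alignment plus
#'   a `multiplicity` column (number of co-optimal locations).
#' @export
report_best <- function(alignments) {
  if (!nrow(alignments)) {
    return(tibble::tibble(read_id = character(0), contig = character(0),
                          pos = integer(0), strand = character(0),
                          mismatches = integer(0), block = integer(0),
                          multiplicity = integer(0)))
  }
  lv <- attr(alignments, "contig_levels")
  ci <- if (is.null(lv)) match(alignments$contig, sort(unique(alignments$contig)))
        else match(alignments$contig, lv)
  alignments %>%
    dplyr::mutate(.ci = ci) %>%
    dplyr::group_by(.data$read_id) %>%
    dplyr::filter(.data$mismatches == min(.data$mismatches)) %>%
    dplyr::mutate(multiplicity = dplyr::n()) %>%
    dplyr::arrange(.data$.ci, .data$pos, .data$strand, .by_group = TRUE) %>%
    dplyr::slice(1L) %>%
    dplyr::ungroup() %>%
    dplyr::select(-".ci")
}
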