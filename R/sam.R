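# SAM output for a mismatch-only aligner: the CIGAR is always <len>M, the NM
# tag carries the Hamming distance, and MAPQ encodes uniqueness (37 for a
# unique best alignment, 0 when co-optimal locations exist). Internal
# coordinates are 0-based half-open; SAM POS is 1-based.

.sam_escape <- function(x) gsub("[\t\r\n]", " ", x)

#' Write alignments as SAM
#'
#' Emits one record per read: the primary alignment chosen by
#' [report_best()] for aligned reads, and an unmapped record (FLAG 4, RNAME
#' `*`, POS 0) for the rest. Reverse-strand records store the
#' reverse-complemented sequence and reversed quality, as the SAM convention
#' requires.
#'
#' @param best Tibble from [report_best()] (one row per aligned read).
#' @param reads Tibble with columns `id`, `sequence` and optionally
#'   `quality`; every read appears in the output.
#' @param index The `dbhash_index` used (provides the `@SQ` header lines).
#' @param path Output path.
#' @param cl Optional command-line string echoed into the `@PG` header for
#'   provenance.
#' @return `path`, invisibly.
#' @export
write_sam <- function(best, reads, index, path, cl = NULL) {
  stopifnot(inherits(index, "dbhash_index"))
  hdr <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", index$contigs$name, index$contigs$length),
    paste0("@PG\tID:dbhash\tPN:dbhash\tVN:",
           as.character(utils::packageVersion("dbhash")),
           if (!is.null(cl)) paste0("\tCL:", .sam_escape(cl)) else "")
  )
  has_q <- "quality" %in% names(reads)
  hit <- match(reads$id, best$read_id)
  lines <- character(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    seq_str <- reads$sequence[i]
    q_str <- if (has_q && !is.na(reads$quality[i])) reads$quality[i] else "*"
    j <- hit[i]
    if (is.na(j)) {
      lines[i] <- paste(.sam_escape(reads$id[i]), 4L, "*", 0L, 0L, "*",
                        "*", 0L, 0L, seq_str, q_str, sep = "\t")
    } else {
      flag <- if (best$strand[j] == "-") 16L else 0L
      if (best$strand[j] == "-") {
        seq_str <- decode_dna(revcomp_dna(encode_dna(seq_str)))
        if (q_str != "*") q_str <- paste(rev(strsplit(q_str, "")[[1]]), collapse = "")
      }
      mapq <- if (best$multiplicity[j] == 1L) 37L else 0L
      lines[i] <- paste(.sam_escape(reads$id[i]), flag, best$contig[j],
                        best$pos[j] + 1L, mapq,
                        paste0(nchar(reads$sequence[i]), "M"),
                        "*", 0L, 0L, seq_str, q_str,
                        paste0("NM:i:", best$mismatches[j]), sep = "\t")
    }
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Parse a SAM file into a tibble
#'
#' A minimal reader for the subset of SAM this package emits (used by the
#' evaluator); headers are skipped, and the NM tag is extracted when
#' present.
#'
#' @param path Path to a SAM file.
#' @return A tibble with columns `id`, `flag`, `contig`, `pos` (0-based;
#'   `NA` for unmapped), `mapq`, `strand`, `unmapped`, `nm`.
#' @export
parse_sam <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) {
    return(tibble::tibble(id = character(0), flag = integer(0),
                          contig = character(0), pos = integer(0),
                          mapq = integer(0), strand = character(0),
                          unmapped = logical(0), nm = integer(0)))
  }
  fld <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i) vapply(fld, `[[`, character(1), i)
  flag <- as.integer(get(2))
  unmapped <- bitwAnd(flag, 4L) != 0L
  nm <- vapply(fld, function(f) {
    tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1])) else NA_integer_
  }, integer(1))
  tibble::tibble(
    id = get(1), flag = flag, contig = get(3),
    pos = ifelse(unmapped, NA_integer_, as.integer(get(4)) - 1L),
    mapq = as.integer(get(5)),
    strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
    unmapped = unmapped, nm = nm
  )
}
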