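# Readers and writers for the standard formats. Parsing of FASTA/FASTQ is
# delegated to Biostrings (gzip handled transparently); the wrappers add the
# contracts the aligner needs: duplicate-contig rejection and diagnostics
# that name the offending line when a file is malformed.

.diagnose_fasta <- function(path) {
  con <- gzfile(path, "rt") # gzfile reads plain text too
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (!length(nonempty)) return("file is empty")
  if (!startsWith(lines[nonempty[1]], ">"))
    return(sprintf("line %d: expected a '>' header", nonempty[1]))
  NULL
}

.diagnose_fastq <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  ln <- 0L
  repeat {
    rec <- readLines(con, n = 4L, warn = FALSE)
    if (!length(rec)) return(NULL)
    if (length(rec) < 4L)
      return(sprintf("line %d: truncated record", ln + length(rec)))
    if (!startsWith(rec[1], "@"))
      return(sprintf("line %d: expected a '@' header", ln + 1L))
    if (!startsWith(rec[3], "+"))
      return(sprintf("line %d: expected a '+' separator", ln + 3L))
    if (nchar(rec[2]) != nchar(rec[4]))
      return(sprintf("line %d: quality length differs from sequence length", ln + 4L))
    ln <- ln + 4L
  }
}

#' Read a (possibly gzipped) FASTA reference
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of contig sequences; duplicate contig
#'   names are rejected.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) {
      diag <- .diagnose_fasta(path)
      stop(sprintf("malformed FASTA '%s'%s", path,
                   if (is.null(diag)) paste0(": ", conditionMessage(e))
                   else paste0(": ", diag)), call. = FALSE)
    })
  nm <- sub("\\s.*$", "", names(set)) # contig name = first token of the header
  if (anyDuplicated(nm))
    stop(sprintf("duplicate contig name(s) in '%s': %s", path,
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  setNames(as.character(set), nm)
}

#' Read a (possibly gzipped) FASTQ file
#'
#' Qualities are kept as Sanger/Phred+33 strings; decode with
#' [phred_decode()].
#'
#' @param path Path to a FASTQ file.
#' @return A tibble with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  diag <- .diagnose_fastq(path) # structural pre-check names the bad line
  if (!is.null(diag)) stop(sprintf("malformed FASTQ '%s': %s", path, diag))
  set <- withCallingHandlers(
    tryCatch(
      Biostrings::readQualityScaledDNAStringSet(path),
      error = function(e) {
        stop(sprintf("malformed FASTQ '%s': %s", path, conditionMessage(e)),
             call. = FALSE)
      }),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  tibble::tibble(
    id = sub("\\s.*$", "", names(set)),
    sequence = unname(as.character(set)),
    quality = unname(as.character(Biostrings::quality(set)))
  )
}

#' Write contigs to FASTA / reads to FASTQ
#'
#' @param contigs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path) {
  set <- Biostrings::DNAStringSet(contigs)
  names(set) <- names(contigs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_fasta
#' @param reads Tibble with columns `id`, `sequence`, `quality`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  lines <- character(4L * nrow(reads))
  lines[seq(1L, by = 4L, length.out = nrow(reads))] <- paste0("@", reads$id)
  lines[seq(2L, by = 4L, length.out = nrow(reads))] <- reads$sequence
  lines[seq(3L, by = 4L, length.out = nrow(reads))] <- "+"
  lines[seq(4L, by = 4L, length.out = nrow(reads))] <- reads$quality
  writeLines(lines, path)
  invisible(path)
}
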