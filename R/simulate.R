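# Synthetic data: random references, reads sampled with position/strand
# truth, substitution errors tied to low base quality (the two-level quality
# model: one value above the threshold, one below — the quality-aware search
# only discriminates at the threshold, so two levels exercise every code
# path), and high-quality substitutions standing in for SNPs.

#' Generate a random reference genome
#'
#' Symbols are i.i.d. with `P(G or C) = gc_fraction`, split evenly within
#' each pair.
#'
#' @param lengths Integer vector of contig lengths.
#' @param gc_fraction Target GC content in `[0, 1]`.
#' @param seed Optional integer seed; fixes the output exactly.
#' @param names Contig names (default `contig_1`, `contig_2`, ...).
#' @return Named character vector of contig sequences.
#' @export
random_genome <- function(lengths, gc_fraction = 0.5, seed = NULL, names = NULL) {
  lengths <- as.integer(lengths)
  if (any(lengths < 1L)) stop("contig lengths must be >= 1")
  if (!is.numeric(gc_fraction) || gc_fraction < 0 || gc_fraction > 1)
    stop("gc_fraction must lie in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  if (is.null(names)) names <- paste0("contig_", seq_along(lengths))
  out <- vapply(lengths, function(n) {
    decode_dna(sample(0:3, n, replace = TRUE, prob = p))
  }, character(1))
  setNames(out, names)
}

#' Sample reads with truth records
#'
#' Reads are drawn uniformly over positions and strands. Each base gets a
#' low quality (`q_low`) with probability `low_q_fraction`, otherwise a high
#' quality (`q_high`); sequencing errors are substitutions placed only at
#' low-quality bases, each miscalled with probability `error_rate`
#' (emulating the association between miscalls and low Phred scores). SNPs
#' are modelled as read-level substitutions applied to any base with
#' probability `snp_rate`; a base carrying a SNP is forced to high quality,
#' which is what makes SNPs indistinguishable from ordinary high-quality
#' mismatches to the aligner. All mutation counts are logged per read.
#'
#' @param genome Named character vector of contigs (from [random_genome()]
#'   or [read_fasta()]).
#' @param n_reads Number of reads.
#' @param read_len Read length (default 100).
#' @param error_rate Miscall probability per low-quality base (default 0.2).
#' @param low_q_fraction Fraction of bases assigned low quality (default
#'   0.1).
#' @param snp_rate Per-base SNP substitution probability (default 0.005).
#' @param q_low,q_high The two Phred levels (defaults 10 and 35, straddling
#'   the quality threshold 15).
#' @param seed Optional integer seed.
#' @return A list with `reads` (tibble `id`, `sequence`, `quality`) and
#'   `truth` (tibble `id`, `contig`, `start` 0-based forward-strand
#'   leftmost, `strand`, `n_errors`, `n_snps`).
#' @export
sample_reads <- function(genome, n_reads, read_len = 100L, error_rate = 0.2,
                         low_q_fraction = 0.1, snp_rate = 0.005,
                         q_low = 10L, q_high = 35L, seed = NULL) {
  n_reads <- as.integer(n_reads); read_len <- as.integer(read_len)
  lens <- nchar(genome)
  if (read_len > min(lens)) stop("read_len exceeds the shortest contig")
  if (!is.null(seed)) set.seed(as.integer(seed))
  enc <- lapply(unname(genome), encode_dna)
  nwin <- lens - read_len + 1L
  ci <- sample.int(length(genome), n_reads, replace = TRUE, prob = nwin)
  start <- vapply(ci, function(i) sample.int(nwin[i], 1L) - 1L, integer(1))
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)

  W <- matrix(0L, n_reads, read_len)
  for (i in seq_len(n_reads))
    W[i, ] <- enc[[ci[i]]][(start[i] + 1L):(start[i] + read_len)]
  flip <- strand == "-"
  if (any(flip))
    W[flip, ] <- t(apply(W[flip, , drop = FALSE], 1L, revcomp_dna))

  snp <- matrix(runif(n_reads * read_len) < snp_rate, n_reads, read_len)
  lowq <- matrix(runif(n_reads * read_len) < low_q_fraction, n_reads, read_len)
  err <- lowq & !snp & matrix(runif(n_reads * read_len) < error_rate,
                              n_reads, read_len)
  mut <- snp | err
  if (any(mut)) {
    shift <- sample.int(3L, sum(mut), replace = TRUE)
    W[mut] <- bitwXor(W[mut], shift) # XOR with 1..3 changes the symbol
  }
  qmat <- matrix(q_high, n_reads, read_len)
  qmat[lowq & !snp] <- q_low # SNP bases are forced to high quality

  ids <- sprintf("read_%d", seq_len(n_reads))
  reads <- tibble::tibble(
    id = ids,
    sequence = apply(W, 1L, decode_dna),
    quality = apply(qmat, 1L, function(q) intToUtf8(q + 33L))
  )
  truth <- tibble::tibble(
    id = ids,
    contig = names(genome)[ci],
    start = as.integer(start),
    strand = strand,
    n_errors = as.integer(rowSums(err)),
    n_snps = as.integer(rowSums(snp))
  )
  list(reads = reads, truth = truth)
}

#' Write / read a truth table
#'
#' Plain TSV round-trip for the truth records produced by [sample_reads()].
#'
#' @param truth Truth tibble.
#' @param path File path.
#' @return `path` invisibly / the truth tibble.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Evaluate alignments against simulation truth
#'
#' A mapped read is *correct* when contig and strand both coincide with the
#' truth record and the reported position is within `tolerance` bases of the
#' true position (the tolerance absorbs clipped or indel-shifted starts);
#' otherwise it is *incorrect*. Unmapped reads form their own category.
#' Reads aligned in multiple positions are judged on their unique reported
#' (primary) alignment. Results are stratified by whether the read carries
#' at least one SNP.
#'
#' @param truth Truth tibble from [sample_reads()] (or [read_truth()]).
#' @param sam Path to a SAM file, or a tibble from [parse_sam()].
#' @param tolerance Maximum distance (bases) between reported and true
#'   position still counted correct (default 50).
#' @return An object of class `dbhash_eval`: a list with `per_read` (per-read
#'   classification), `summary` (per-stratum counts, recall, precision) and
#'   `tolerance`.
#' @export
evaluate_alignments <- function(truth, sam, tolerance = 50L) {
  aln <- if (is.character(sam)) parse_sam(sam) else tibble::as_tibble(sam)
  missing_in_truth <- setdiff(aln$id, truth$id)
  if (length(missing_in_truth))
    stop(sprintf("SAM read id(s) absent from truth: %s",
                 paste(head(missing_in_truth, 5L), collapse = ", ")))
  j <- match(aln$id, truth$id)
  per_read <- tibble::tibble(
    id = aln$id,
    true_contig = truth$contig[j],
    true_start = truth$start[j],
    true_strand = truth$strand[j],
    contig = aln$contig, pos = aln$pos, strand = aln$strand,
    unmapped = aln$unmapped,
    n_errors = truth$n_errors[j],
    n_snps = truth$n_snps[j]
  )
  per_read$class <- ifelse(
    per_read$unmapped, "unmapped",
    ifelse(per_read$contig == per_read$true_contig &
             per_read$strand == per_read$true_strand &
             abs(per_read$pos - per_read$true_start) <= tolerance,
           "correct", "incorrect"))
  strat <- function(df, label) {
    n <- nrow(df)
    ncor <- sum(df$class == "correct")
    nmap <- sum(df$class != "unmapped")
    tibble::tibble(stratum = label, n = n, correct = ncor,
                   incorrect = sum(df$class == "incorrect"),
                   unmapped = n - nmap,
                   recall = if (n) ncor / n else NA_real_,
                   precision = if (nmap) ncor / nmap else NA_real_)
  }
  summary <- dplyr::bind_rows(
    strat(per_read, "all"),
    strat(per_read[per_read$n_snps > 0L, ], "with_snp"),
    strat(per_read[per_read$n_snps == 0L, ], "without_snp")
  )
  structure(list(per_read = per_read, summary = summary,
                 tolerance = as.integer(tolerance)),
            class = "dbhash_eval")
}

#' @export
print.dbhash_eval <- function(x, ...) {
  cat(sprintf("alignment evaluation (tolerance %d bases)\n", x$tolerance))
  print(x$summary)
  invisible(x)
}
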