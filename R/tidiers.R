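# broom-style accessors and quick plots for the package's result objects.

#' Tidy a dB-hash index
#'
#' @param x A `dbhash_index`.
#' @param ... Unused.
#' @return One row per contig: name, length, offset.
#' @export
tidy.dbhash_index <- function(x, ...) {
  x$contigs
}

#' One-row summary of a dB-hash index
#'
#' @param x A `dbhash_index`.
#' @param ... Unused.
#' @return A one-row tibble: text size, build parameters and payload bytes.
#' @export
glance.dbhash_index <- function(x, ...) {
  st <- index_stats(x)
  tibble::tibble(n = x$n, contigs = nrow(x$contigs), m = x$m, w = x$w,
                 w_aux = x$w_aux, sa_step = x$s,
                 payload_bytes = sum(st$bytes),
                 bytes_per_base = sum(st$bytes) / x$n)
}

#' Alignment run statistics
#'
#' @param x A `dbhash_alignments` tibble from [align_reads()].
#' @param ... Unused.
#' @return The one-row stats tibble recorded during alignment (reads
#'   processed, aligned, unique, multiple, unmapped, unalignable).
#' @export
glance.dbhash_alignments <- function(x, ...) {
  attr(x, "stats")
}

#' Tidy an alignment evaluation
#'
#' @param x A `dbhash_eval` from [evaluate_alignments()].
#' @param ... Unused.
#' @return The per-stratum summary tibble.
#' @export
tidy.dbhash_eval <- function(x, ...) {
  x$summary
}

#' @rdname tidy.dbhash_eval
#' @export
glance.dbhash_eval <- function(x, ...) {
  x$summary[x$summary$stratum == "all", ]
}

#' Plot an alignment evaluation
#'
#' Stacked per-stratum classification of reads (correct / incorrect /
#' unmapped).
#'
#' @param object A `dbhash_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dbhash_eval <- function(object, ...) {
  pr <- object$per_read
  pr$stratum <- ifelse(pr$n_snps > 0L, "with_snp", "without_snp")
  df <- dplyr::count(pr, .data$stratum, .data$class)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$n,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "reads", fill = NULL,
                  title = sprintf("alignment correctness (tolerance %d bases)",
                                  object$tolerance)) +
    ggplot2::theme_minimal()
}

#' Plot the space accounting of an index
#'
#' @param object A `dbhash_index`.
#' @param ... Unused.
#' @return A ggplot object: bytes per component of the succinct payload.
#' @export
autoplot.dbhash_index <- function(object, ...) {
  st <- index_stats(object)
  ggplot2::ggplot(st, ggplot2::aes(x = stats::reorder(.data$component,
                                                      .data$bytes),
                                   y = .data$bytes)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "bytes",
                  title = sprintf("index payload: %.2f bytes/base",
                                  sum(st$bytes) / object$n)) +
    ggplot2::theme_minimal()
}

#' Brute-force k-mismatch reference scanner
#'
#' Scans every position of a symbol text for occurrences of a pattern with
#' at most `k` mismatches by direct comparison with early exit. This is the
#' independent reference against which the index-based search is validated;
#' it shares no code with the index path.
#'
#' @param text Encoded text (integer vector over `0:3`) or character string.
#' @param pattern Encoded pattern or character string.
#' @param k Mismatch bound.
#' @return A tibble with columns `pos` (0-based) and `mismatches`.
#' @export
scan_kmismatch <- function(text, pattern, k) {
  tsym <- if (is.character(text)) encode_dna(text) else as.integer(text)
  psym <- if (is.character(pattern)) encode_dna(pattern) else as.integer(pattern)
  r <- cpp_kmismatch_scan(tsym, psym, as.integer(k))
  tibble::tibble(pos = r$pos, mismatches = r$dist)
}
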