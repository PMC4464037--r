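search_fixture <- function(n = 10000, m = 20, seed = 101) {
  g <- random_genome(n, seed = seed)
  list(genome = g,
       tsym = as.integer(encode_dna(unname(g[[1]]))),
       index = build_index(g, m = m))
}

test_that("block splitting covers the read and reports t", {
  b <- split_into_blocks(60, 30)
  expect_equal(b$offset, c(0L, 30L))
  expect_equal(attr(b, "t"), 2L)
  b <- split_into_blocks(100, 30)
  expect_equal(b$offset, c(0L, 30L, 60L, 70L))
  expect_equal(attr(b, "t"), 3L)
  b <- split_into_blocks(30, 30)
  expect_equal(b$offset, 0L)
  expect_error(split_into_blocks(25, 30), "unalignable")
})

test_that("per-block budget satisfies the pigeonhole principle", {
  expect_equal(errors_per_block(4, 2), 2L)
  expect_equal(errors_per_block(5, 2), 2L)
  # brute force over all placements of k errors into t blocks
  for (t in 1:4) {
    for (k in 0:6) {
      kb <- errors_per_block(k, t)
      placements <- expand.grid(rep(list(0:k), t))
      placements <- placements[rowSums(placements) == k, , drop = FALSE]
      if (nrow(placements)) {
        expect_true(all(apply(placements, 1, min) <= kb),
                    info = sprintf("k=%d t=%d", k, t))
      }
    }
  }
})

test_that("planted blocks are recovered by the block search", {
  fx <- search_fixture()
  idx <- fx$index
  set.seed(1)
  for (rep in 1:25) {
    pos <- sample(0:(10000 - idx$m), 1)
    block <- fx$tsym[(pos + 1):(pos + idx$m)]
    # exact block
    expect_true(pos %in% search_block(idx, block, 0L, 0L))
    # block with one substitution, searched at radius 1
    b2 <- block
    j <- sample(idx$m, 1)
    b2[j] <- bitwXor(b2[j], sample(1:3, 1))
    expect_true(pos %in% search_block(idx, b2, 0L, 1L))
  }
  # offset handling: candidate start is hit position minus block offset
  pos <- 4321L
  block <- fx$tsym[(pos + 1):(pos + idx$m)]
  expect_true((pos - 20L) %in% search_block(idx, block, 20L, 0L))
})

test_that("align_read finds exact and mismatched copies on both strands", {
  fx <- search_fixture()
  idx <- fx$index
  g1 <- unname(fx$genome[[1]])
  read <- substr(g1, 501, 600)
  a <- align_read(idx, read, k = 4, read_id = "fwd")
  expect_gte(nrow(a), 1L)
  expect_true(any(a$pos == 500L & a$strand == "+" & a$mismatches == 0L))
  # reverse strand
  rc <- decode_dna(revcomp_dna(encode_dna(read)))
  a2 <- align_read(idx, rc, k = 4, read_id = "rev")
  expect_true(any(a2$pos == 500L & a2$strand == "-" & a2$mismatches == 0L))
  # substitutions are counted
  sym <- encode_dna(read)
  sym[c(10, 50, 90)] <- bitwXor(sym[c(10, 50, 90)], c(1L, 3L, 2L))
  a3 <- align_read(idx, decode_dna(sym), k = 4, read_id = "mut")
  expect_true(any(a3$pos == 500L & a3$strand == "+" & a3$mismatches == 3L))
  # too-short reads are unalignable
  a4 <- align_read(idx, substr(g1, 1, 10), k = 1)
  expect_equal(nrow(a4), 0L)
  expect_true(attr(a4, "unalignable"))
})

test_that("sensitive mode equals the brute-force scan on both strands", {
  fx <- search_fixture(n = 8000, m = 16, seed = 55)
  idx <- fx$index
  sim <- sample_reads(fx$genome, 60, read_len = 50, seed = 56)
  k <- 3
  for (i in seq_len(nrow(sim$reads))) {
    a <- align_read(idx, sim$reads$sequence[i], k = k,
                    read_id = sim$reads$id[i])
    sym <- encode_dna(sim$reads$sequence[i])
    fwd <- scan_kmismatch(fx$tsym, sym, k)
    rev <- scan_kmismatch(fx$tsym, revcomp_dna(sym), k)
    want <- rbind(
      if (nrow(fwd)) cbind(fwd, strand = "+"),
      if (nrow(rev)) cbind(rev, strand = "-"))
    got_keys <- sprintf("%d%s:%d", a$pos, a$strand, a$mismatches)
    want_keys <- if (is.null(want)) character(0) else
      sprintf("%d%s:%d", want$pos, want$strand, want$mismatches)
    expect_setequal(got_keys, want_keys)
  }
})

test_that("raising k never removes a reported position", {
  fx <- search_fixture(n = 5000, m = 16, seed = 77)
  idx <- fx$index
  sim <- sample_reads(fx$genome, 20, read_len = 60, seed = 78)
  for (i in seq_len(nrow(sim$reads))) {
    keys <- lapply(0:4, function(k) {
      a <- align_read(idx, sim$reads$sequence[i], k = k)
      sprintf("%d%s", a$pos, a$strand)
    })
    for (k in 1:4) expect_true(all(keys[[k]] %in% keys[[k + 1]]))
  }
})

test_that("alignment is deterministic", {
  fx <- search_fixture(n = 4000, m = 16, seed = 91)
  sim <- sample_reads(fx$genome, 10, read_len = 50, seed = 92)
  a1 <- align_reads(fx$index, sim$reads, k = 3)
  a2 <- align_reads(fx$index, sim$reads, k = 3)
  expect_identical(as.data.frame(a1), as.data.frame(a2))
})

test_that("quality mode recovers reads whose errors are all low-quality", {
  fx <- search_fixture(n = 20000, m = 50, seed = 33)
  idx <- fx$index
  sim <- sample_reads(fx$genome, 120, read_len = 100, snp_rate = 0,
                      error_rate = 0.3, low_q_fraction = 0.08, seed = 34)
  keep <- sim$truth$n_errors <= 4
  reads <- sim$reads[keep, ]
  truth <- sim$truth[keep, ]
  for (i in seq_len(nrow(reads))) {
    a <- align_read(idx, reads$sequence[i], reads$quality[i], k = 4,
                    mode = "quality", read_id = reads$id[i])
    hit <- any(a$pos == truth$start[i] & a$strand == truth$strand[i])
    expect_true(hit, info = reads$id[i])
    if (i <= 15) {
      # quality-mode output is a subset of sensitive-mode output
      s <- align_read(idx, reads$sequence[i], reads$quality[i], k = 4,
                      mode = "sensitive", read_id = reads$id[i])
      expect_true(all(sprintf("%d%s", a$pos, a$strand) %in%
                        sprintf("%d%s", s$pos, s$strand)))
    }
  }
  expect_error(align_read(idx, reads$sequence[1], NULL, k = 2, mode = "quality"),
               "requires")
})

test_that("alignments never span a contig boundary", {
  g <- random_genome(c(600, 600), seed = 111)
  idx <- build_index(g, m = 16)
  # a read straddling the concatenation joint must not be reported
  joint <- paste0(substr(g[[1]], 571, 600), substr(g[[2]], 1, 30))
  a <- align_read(idx, joint, k = 0)
  expect_false(any(a$contig == "contig_1" & a$pos > 600 - 60))
  # while a read inside one contig is
  a2 <- align_read(idx, substr(g[[2]], 101, 160), k = 0)
  expect_true(any(a2$contig == "contig_2" & a2$pos == 100L))
})

test_that("report_best picks minimal distance with deterministic ties", {
  aln <- tibble::tibble(
    read_id = c("r1", "r1", "r2", "r2", "r3"),
    contig = c("c1", "c1", "c2", "c1", "c1"),
    pos = c(10L, 99L, 5L, 5L, 7L),
    strand = c("+", "+", "+", "+", "-"),
    mismatches = c(3L, 1L, 2L, 2L, 0L),
    block = 1L)
  attr(aln, "contig_levels") <- c("c1", "c2")
  best <- report_best(aln)
  b1 <- best[best$read_id == "r1", ]
  expect_equal(b1$pos, 99L); expect_equal(b1$multiplicity, 1L)
  b2 <- best[best$read_id == "r2", ]
  expect_equal(b2$contig, "c1") # contig order breaks the tie
  expect_equal(b2$multiplicity, 2L)
  expect_equal(best[best$read_id == "r3", ]$mismatches, 0L)
  expect_equal(nrow(report_best(aln[0, ])), 0L)
})

test_that("align_reads aggregates run statistics", {
  fx <- search_fixture(n = 3000, m = 20, seed = 121)
  sim <- sample_reads(fx$genome, 15, read_len = 50, seed = 122)
  reads <- dplyr::bind_rows(
    sim$reads,
    tibble::tibble(id = "tiny", sequence = "ACGTACGT",
                   quality = strrep("I", 8)))
  a <- align_reads(fx$index, reads, k = 3)
  st <- glance(a)
  expect_equal(st$reads, 16L)
  expect_equal(st$unalignable, 1L)
  expect_equal(st$aligned + st$unmapped, 16L)
  expect_equal(st$unique + st$multiple, st$aligned)
})
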