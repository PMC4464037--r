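make_index <- function(n = 3000, m = 16, seed = 42, ...) {
  g <- random_genome(n, seed = seed)
  build_index(g, m = m, ...)
}

test_that("suffix array construction matches hand and naive-sort oracles", {
  expect_equal(build_suffix_array(c(1L, 0L, -1L)), c(2L, 1L, 0L))
  expect_equal(build_suffix_array(c(0L, 0L, 0L, -1L)), c(3L, 2L, 1L, 0L))
  set.seed(17)
  for (rep in 1:3) {
    s <- c(random_syms(2000), -1L)
    expect_equal(build_suffix_array(s), naive_suffix_array(s))
  }
  expect_error(build_suffix_array(c(1L, 0L, 2L)), "sentinel")
})

test_that("BWT from SA is a permutation, matches hand value, and inverts", {
  s <- c(1L, 0L, -1L)
  sa <- build_suffix_array(s)
  bwt <- bwt_from_sa(s, sa)
  expect_equal(bwt, c(0L, 1L, -1L))
  set.seed(23)
  s <- c(random_syms(500), -1L)
  sa <- build_suffix_array(s)
  bwt <- bwt_from_sa(s, sa)
  expect_equal(sort(bwt), sort(s)) # permutation property
  # invert via LF mapping
  n <- length(s)
  ord <- order(bwt)             # stable: first column of the sorted rotations
  lf <- integer(n); lf[ord] <- seq_len(n)
  rec <- integer(n)
  row <- which(sa == 0L)
  for (i in n:1) { rec[i] <- bwt[row]; row <- lf[row] }
  expect_equal(rec, s)
})

test_that("wavelet tree access and rank agree with naive counting", {
  idx <- make_index(n = 2500, m = 12)
  # reconstruct the BWT independently from the fingerprint string
  g <- random_genome(2500, seed = 42)
  tsym <- as.integer(encode_dna(unname(g[[1]])))
  ht <- hash_text(tsym, idx$m, idx$w)
  s <- c(ht, -1L)
  bwt <- bwt_from_sa(s, naive_suffix_array(s))
  np <- idx$nprime
  acc <- vapply(0:(np - 1), function(i) wavelet_access(idx, i), integer(1))
  expect_equal(acc, bwt)
  set.seed(1)
  for (i in sample(0:np, 60)) {
    for (c in 0:3) {
      expect_equal(wavelet_rank(idx, c, i), naive_rank(bwt, c, i))
    }
  }
})

test_that("backward search equals naive substring counting and locating", {
  n <- 2000
  g <- random_genome(n, seed = 7)
  idx <- build_index(g, m = 20)
  tsym <- as.integer(encode_dna(unname(g[[1]])))
  ht <- hash_text(tsym, idx$m, idx$w)
  set.seed(8)
  for (rep in 1:40) {
    f <- if (rep %% 2 == 0) {
      i <- sample(length(ht) - idx$w, 1)
      ht[(i + 1):(i + idx$w)] # a fingerprint present in h(T)
    } else {
      random_syms(idx$w)      # random, usually absent
    }
    iv <- backward_search(idx, f)
    hits <- naive_substring_positions(ht, f)
    expect_equal(iv[2] - iv[1], length(hits))
    expect_equal(locate_occurrences(idx, iv), sort(hits))
    expect_equal(lookup_fingerprint(idx, f), sort(hits))
  }
  # empty query: all rows
  expect_equal(backward_search(idx, integer(0)), c(0L, idx$nprime))
})

test_that("locate is sound and complete for every sampling step", {
  n <- 1500
  g <- random_genome(n, seed = 19)
  tsym <- as.integer(encode_dna(unname(g[[1]])))
  for (s in c(1, 4, 16, 64)) {
    idx <- build_index(g, m = 16, sa_step = s)
    ht <- hash_text(tsym, idx$m, idx$w)
    set.seed(s)
    for (rep in 1:10) {
      i <- sample(length(ht) - idx$w, 1)
      f <- ht[(i + 1):(i + idx$w)]
      expect_equal(lookup_fingerprint(idx, f),
                   sort(naive_substring_positions(ht, f)),
                   info = sprintf("sa_step=%d", s))
    }
  }
})

test_that("auxiliary hash is transparent and matches direct backward search", {
  idx <- make_index(n = 4000, m = 20)
  expect_gt(idx$w_aux, 0)
  set.seed(3)
  for (rep in 1:30) {
    f <- random_syms(idx$w)
    expect_equal(backward_search(idx, f, use_aux = TRUE),
                 backward_search(idx, f, use_aux = FALSE))
  }
  # table entries equal w_aux-step backward search on their own digit string
  wa <- idx$w_aux
  for (u in sample(0:(4^wa - 1), 16)) {
    digs <- (u %/% 4^((wa - 1):0)) %% 4
    expect_equal(c(idx$aux_l[u + 1], idx$aux_r[u + 1]),
                 backward_search(idx, digs, use_aux = FALSE))
  }
  # prefix intervals partition the rows whose suffix holds a full w_aux prefix
  widths <- idx$aux_r - idx$aux_l
  expect_equal(sum(widths), idx$nprime - idx$w_aux)
})

test_that("packed text round-trips and the verifier counts mismatches", {
  set.seed(29)
  tsym <- random_syms(123)
  words <- pack_dna_text(tsym)
  expect_equal(unpack_dna_text(words, 123), tsym)
  expect_equal(unpack_dna_text(words, 123, from = 17, len = 30),
               tsym[18:47])
  idx <- make_index(n = 2000, m = 16, seed = 5)
  g <- random_genome(2000, seed = 5)
  tsym <- as.integer(encode_dna(unname(g[[1]])))
  # exact window
  expect_equal(hamming_verify(idx, tsym[101:150], 100, 0), 0L)
  # two planted mismatches
  p <- tsym[101:150]
  p[c(3, 40)] <- bitwXor(p[c(3, 40)], c(1L, 2L))
  expect_equal(hamming_verify(idx, p, 100, 2), 2L)
  expect_true(is.na(hamming_verify(idx, p, 100, 1)))
  # random windows vs a symbol-by-symbol counter
  for (rep in 1:50) {
    pos <- sample(0:(2000 - 37), 1)
    q <- random_syms(37)
    d <- sum(tsym[(pos + 1):(pos + 37)] != q)
    expect_equal(hamming_verify(idx, q, pos, 37), d)
  }
  expect_error(hamming_verify(idx, random_syms(10), 1995, 4), "range")
})

test_that("index build applies the sizing rules and skips short contigs", {
  g <- random_genome(c(2000, 30), seed = 2)
  expect_warning(idx <- build_index(g, m = 50), "skipping 1 contig")
  expect_equal(nrow(idx$contigs), 1L)
  # w = ceiling(log4(m n)) clamped to [4, min(m, 32)]
  expect_equal(idx$w, max(4L, min(ceiling(log(50 * 2000, 4)), 50L, 32L)))
  expect_error(suppressWarnings(build_index(random_genome(40, seed = 1), m = 50)),
               "no contig")
  # aux bound enforcement
  expect_error(build_index(random_genome(2000, seed = 1), m = 20, w_aux = 20),
               "w_aux")
})

test_that("serialization round-trips byte-identically and preserves queries", {
  idx <- make_index(n = 3000, m = 16, seed = 11)
  f1 <- tempfile(); f2 <- tempfile()
  write_index(idx, f1)
  idx2 <- read_index(f1)
  write_index(idx2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  set.seed(4)
  for (rep in 1:10) {
    f <- random_syms(idx$w)
    expect_identical(lookup_fingerprint(idx2, f), lookup_fingerprint(idx, f))
  }
  expect_equal(idx2$contigs, idx$contigs)
  bad <- tempfile(); writeLines("not an index", bad)
  expect_error(read_index(bad), "magic")
  unlink(c(f1, f2, bad))
})

test_that("space accounting itemises a small payload", {
  idx <- make_index(n = 5000, m = 20, seed = 13)
  st <- index_stats(idx)
  expect_setequal(st$component,
                  c("wavelet_bits", "rank_directories", "mark_bits",
                    "sa_samples", "aux_table", "packed_text"))
  expect_true(all(st$bytes >= 0))
  expect_lt(sum(st$bytes) / idx$n, 2) # small even at desk scale
})

test_that("bit-vector rank is exact at superblock boundaries and vector end", {
  set.seed(6)
  for (len in c(255, 256, 1024, 1989, 2048)) {
    bits <- as.integer(runif(len) < 0.5)
    bv <- dbhash:::cpp_build_bitvector(bits)
    for (i in c(0, 255, 256, 257, len - 1, len)) {
      if (i < 0 || i > len) next
      expect_equal(dbhash:::cpp_bv_rank1(bv, i),
                   if (i == 0) 0L else sum(bits[seq_len(i)]),
                   info = sprintf("len=%d i=%d", len, i))
    }
  }
})
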