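# Independent oracles and fixture generators. These deliberately re-derive
# every quantity from first principles (naive loops, full sorts, direct
# formula evaluation) and share no code with the implementation paths they
# check.

# all length-m strings over 0:3 as a (4^m x m) matrix, most significant first
all_strings <- function(m) {
  n <- 4L^m
  v <- 0:(n - 1L)
  sapply(seq_len(m), function(j) (v %/% 4L^(m - j)) %% 4L)
}

random_syms <- function(n) sample(0:3, n, replace = TRUE)

# literal evaluation of the fingerprint formula: XOR of the ceiling(m/w)-1
# aligned windows and the final window, one symbol at a time
naive_hash_xor <- function(p, w) {
  m <- length(p)
  cw <- as.integer(ceiling(m / w))
  f <- integer(w)
  if (cw >= 2) {
    for (i in 0:(cw - 2)) {
      for (j in 1:w) f[j] <- bitwXor(f[j], p[i * w + j])
    }
  }
  for (j in 1:w) f[j] <- bitwXor(f[j], p[m - w + j])
  f
}

# suffix array by sorting suffix strings; symbols mapped to letters so that
# lexicographic string order equals symbol order, sentinel (-1) below all
naive_suffix_array <- function(s) {
  chars <- c("!", "a", "b", "c", "d", "e")[s + 2L]
  str <- paste(chars, collapse = "")
  suff <- substring(str, seq_len(nchar(str)))
  order(suff) - 1L
}

# count of symbol c among x[1..i] (i counted 0-based exclusive)
naive_rank <- function(x, c, i) if (i == 0L) 0L else sum(x[seq_len(i)] == c)

# all occurrences of pattern f in text ht with 0 mismatches (naive scan)
naive_substring_positions <- function(ht, f) {
  w <- length(f)
  n <- length(ht)
  if (w > n) return(integer(0))
  hits <- integer(0)
  for (i in 0:(n - w)) {
    if (all(ht[(i + 1):(i + w)] == f)) hits <- c(hits, i)
  }
  hits
}

# naive k-mismatch scan in pure R (small inputs only)
naive_kmismatch <- function(text, pat, k) {
  n <- length(text); m <- length(pat)
  out <- list()
  for (i in 0:(n - m)) {
    d <- sum(text[(i + 1):(i + m)] != pat)
    if (d <= k) out[[length(out) + 1L]] <- c(i, d)
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, out)
}

# every pattern within Hamming distance k of p (rows), including p itself
hamming_ball <- function(p, k) {
  m <- length(p)
  rows <- list(p)
  if (k >= 1) {
    for (j in 1:m) for (e in 1:3) {
      q <- p; q[j] <- bitwXor(q[j], e)
      rows[[length(rows) + 1L]] <- q
    }
  }
  if (k >= 2 && m >= 2) {
    cmb <- utils::combn(m, 2)
    for (ci in seq_len(ncol(cmb))) {
      for (e1 in 1:3) for (e2 in 1:3) {
        q <- p
        q[cmb[1, ci]] <- bitwXor(q[cmb[1, ci]], e1)
        q[cmb[2, ci]] <- bitwXor(q[cmb[2, ci]], e2)
        rows[[length(rows) + 1L]] <- q
      }
    }
  }
  do.call(rbind, rows)
}

fp_key <- function(mat) apply(mat, 1L, paste, collapse = ",")

# hash every row of a pattern matrix with the naive evaluator
naive_hash_rows <- function(mat, w) {
  t(apply(mat, 1L, naive_hash_xor, w = w))
}
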