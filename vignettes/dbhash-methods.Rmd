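---
title: "Succinct hash indexing and randomized k-mismatch search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Succinct hash indexing and randomized k-mismatch search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbhash)
```

## The problem

Aligning short reads against a reference with up to $k$ mismatches pulls in
two directions. Hash indexes over length-$m$ substrings are sensitive and
fast but store a position table of $n \log n$ bits — tens of gigabytes for a
mammalian genome. Burrows–Wheeler (FM) indexes are succinct but natively
support exact matching only, so mismatches must be injected by backtracking
or block splitting at a cost that grows quickly with $k$.

`dbhash` combines the two: it hashes the text into a *fingerprint string*
and builds a succinct FM-type index over that string, so hash lookups are
simulated by backward search in linear space, while the hash function's
structure keeps approximate search cheap.

## The fingerprint map

Work over the numeric DNA alphabet $\Sigma = \{0,1,2,3\}$ (A, C, G, T; `N`
is assigned the value 0 and its positions recorded separately). For a
pattern $P$ of length $m$ and a word size $w \le m$, the fingerprint is the
symbol-wise XOR of the $\lceil m/w\rceil - 1$ aligned windows
$P[iw..iw{+}w)$ together with the final window $P[m{-}w..m)$:

$$ h_\oplus(P) \;=\; \bigoplus_{i=0}^{\lceil m/w\rceil-2} P[iw..iw{+}w)
   \;\oplus\; P[m{-}w..m). $$

We read the window count as a ceiling so that *every* pattern position feeds
at least one window; when $w \nmid m$ the final window overlaps the last
aligned one by $m' = \lceil m/w\rceil w - m$ symbols. Under a floor reading
the uncovered positions would make some substitutions invisible to the hash,
breaking both properties below.

Two properties make this map useful:

* **de Bruijn (shift compatibility).** If $P[1..m) = Q[0..m{-}1)$ then
  $h_\oplus(P)[1..w) = h_\oplus(Q)[0..w{-}1)$. Consequently the map extends
  to a text $T$ of length $n$: there is a unique string $h(T)$ of length
  $n-m+w$ whose width-$w$ window at every position $i$ equals
  $h_\oplus(T[i..i{+}m))$ (`hash_text()`). An exact occurrence of $P$ at $i$
  therefore implies an occurrence of $h_\oplus(P)$ in $h(T)$ at $i$; the
  converse can fail, and such *false positives* are removed by plain-text
  verification.
* **Hamming awareness.** $d_H(P,P') \le k$ implies
  $d_H(h_\oplus(P), h_\oplus(P')) \le 2k$: the whole Hamming ball of radius
  $k$ around $P$ maps into a small ball in fingerprint space.

Because the fold is XOR-linear, $h_\oplus(P \oplus D) = h_\oplus(P) \oplus
h_\oplus(D)$: the image of the ball is $h_\oplus(P)$ XOR the set of
fingerprint deltas of low-weight substitution patterns. A substitution at a
position covered once perturbs one fingerprint offset (any of $w$ offsets,
3 possible XOR values); a position in the overlap region perturbs two
related offsets, $(b + (m \bmod w),\, b)$ for $b < m'$. That is at most
$(2\sigma-2)w = 6w$ *error events* per substitution, so
`enumerate_fingerprint_candidates()` composes at most
$\sum_{j\le k}(6w)^j$ candidate fingerprints — exponentially fewer than the
$(\sigma-1)^k \binom{m}{k}$ raw neighbours — while provably containing the
fingerprint of every neighbour (completeness is tested exhaustively over
Hamming balls; the budget is asserted on every enumeration).

## The succinct index

`build_index()` stores, for a reference of total length $n$:

* the BWT of $h(T)\cdot\$$ as a two-level wavelet tree
  ($2n'$ payload bits, $n' = n-m+w+1$) with word-level rank directories;
* a sampled suffix array: one pointer for every `sa_step`-th text position
  (default 16), with a marking bit vector, so `locate` walks at most
  `sa_step`$-1$ LF steps;
* an auxiliary table of the backward-search intervals of all $4^{w_{aux}}$
  length-$w_{aux}$ fingerprint prefixes, replacing the first $w_{aux}$
  refinement steps of each lookup by one table access. The depth is capped
  at $\log_\sigma n - \log_\sigma \log_\sigma n$, which keeps the table
  within $n/\log n$ entries;
* the plain text packed at 3 bits per base in blocks of 8 symbols per word,
  so candidate verification compares one block per word operation with
  early exit past $k$ mismatches.

Defaults follow the sizing rules $w = \lceil \log_\sigma(mn) \rceil$
clamped to $[4, \min(m, 32)]$ and
$w_{aux} = \min(w-1, \lfloor \log_\sigma n - \log_\sigma\log_\sigma n
\rfloor)$. `index_stats()` itemises the payload (wavelet bits, rank
directories, mark bits, SA samples, auxiliary table, packed text) rather
than asserting a closed-form total; on random references the sum is well
under 2 bytes per base.

Contigs are concatenated at the coordinate level: no separator symbol is
reserved (keeping $\sigma = 4$), and alignments spanning a contig boundary
are rejected at verification, which is observationally equivalent.

A sentinel ranked below every symbol terminates $h(T)$ for suffix-array
construction (prefix doubling; any correct construction would do — the test
suite pins it against a naive full sort). The index serialises to a
versioned, magic-tagged little-endian binary whose header carries
$(m, w, w_{aux}, s)$; save → load → save is byte-identical.

## The search

`align_read()` implements seed-and-verify with a pigeonhole split:

1. the read is cut into $t = \lfloor \mathrm{len}/m \rfloor$ non-overlapping
   blocks (plus one extra block anchored at the read end when $m \nmid
   \mathrm{len}$, for coverage); any occurrence with $\le k$ mismatches
   leaves some non-overlapping block with at most $k_b = \lfloor k/t
   \rfloor$ of them;
2. each block's squeezed ball of $\le \sum_{j \le k_b}(6w)^j$ candidate
   fingerprints is looked up in the index (backward search + locate), and
   every hit position, shifted by the block offset, becomes a candidate
   read start;
3. candidates are verified against the packed text at full read length with
   bound $k$.

Both the read and its reverse complement are searched; the index stores the
forward text only. In **sensitive** mode the guarantees compose: every text
position matching within $k$ mismatches is reported, and the suite checks
exact agreement with a brute-force scanner over a 100 kb genome. In
**quality** mode, a candidate fingerprint is searched only if it differs
from the block fingerprint solely at offsets fed by at least one base of
Phred quality $\le q$ (default $q = 15$): the mask
$h_\vee(Q)$ folds the low-quality indicator $f_q$ (0 above the threshold, 3
at or below it — values chosen for their binary representations 00/11)
through the same window decomposition with OR, and the filter keeps $f$
when $(f \oplus h_\oplus(B)) \vee h_\vee(Q) = h_\vee(Q)$. Reads whose every
mismatch sits on a low-quality base are still found with certainty
(verified on 1000 plantings); occurrences whose errors hide under
high-quality bases may be missed — that is the deliberate trade of the
heuristic, and quality-mode output is always a subset of sensitive-mode
output.

`report_best()` picks the minimal-mismatch alignment per read with a
deterministic tie-break (contig order, then position, then strand) and
annotates the number of co-optimal locations; `write_sam()` emits one
record per read with `<len>M` CIGAR (the aligner is mismatch-only), the
Hamming distance in `NM`, and MAPQ 37 for unique best alignments versus 0
for multi-mappers — the format never defines MAPQ for this situation, so a
simple documented convention is used.

## Synthetic data and the correctness criterion

`random_genome()` draws i.i.d. bases at a chosen GC fraction.
`sample_reads()` emulates the validation conditions: uniform positions and
strands; a two-level quality string (Phred 35 / 10 around the threshold 15
— the quality-aware search only discriminates *at* the threshold, so two
levels exercise every code path); sequencing errors only at low-quality
bases (default: 10% of bases low-quality, each miscalled with probability
0.2, i.e. ≈2% per-base error, an Illumina-like rate); and SNPs as
high-quality read-level substitutions at rate 0.005 per base — from the
aligner's point of view a SNP is just a high-quality mismatch, so reference
editing is unnecessary and truth tracking stays trivial. Every mutation is
logged, so each read's truth record (contig, 0-based start, strand, error
and SNP counts) reconstructs it exactly.

What the generator does *not* emulate: position-dependent error profiles,
indels, duplicated or repetitive genome structure, coverage biases. Passing
the oracle-equivalence tests on this data demonstrates algorithmic
correctness of the index and search — not field accuracy on real libraries,
which depends on genome repetitiveness and error structure.

`evaluate_alignments()` applies the standard simulation criterion: an
alignment is correct when contig and strand match the truth and the
position is within 50 bases (absorbing clip- or indel-induced shifts);
multi-mappers are judged on their unique primary alignment; unmapped reads
form their own category. Results are stratified by SNP content so the
quality heuristic's effect on variant-carrying reads can be read off
directly.

## Numerical and design choices

* **Problem sizes in the validation suite** (chosen to exercise every
  boundary while keeping the default test run short): shift compatibility
  exhaustively over all $4^6$ patterns at $w=4$; window consistency on a
  $10^4$-base text for $m \in \{8,20\}$, $w \in \{4,8\}$; Hamming awareness
  exhaustively for $m \le 8$, $k \le 2$ plus $10^4$ random pairs at
  $m{=}100$, $w{=}10$, $k \le 4$; candidate sets exhaustively over Hamming
  balls with exact set equality at $m = w$; the FM layer against naive
  scans on 500 text/pattern pairs across sampling steps $\{1,4,16,64\}$
  with and without the auxiliary table; end-to-end oracle equivalence for
  2000 hundred-base reads on a 100 kb genome at $k = 4$.
* **Ties and degenerate inputs.** Empty patterns are rejected; `N` encodes
  as 0 and counts as an ordinary symbol in Hamming distance (reads
  overlapping reference `N` runs can still align; recorded positions let a
  caller hard-mask if desired). Candidate starts that would run off the
  text or cross a contig boundary are discarded silently — they cannot be
  valid leftmost starts.
* **Determinism.** Alignment involves no randomness; simulators are exact
  functions of their seed.
* **Known limitations.** No indel handling (CIGAR is always all-match), no
  paired-end logic, no trimming, single-threaded, and the whole index lives
  in memory — at roughly 1.5–2 bytes per base plus R object overhead, which
  is comfortable to a few hundred megabases but not for gigabase genomes.

## Session info

```{r}
sessionInfo()
```
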