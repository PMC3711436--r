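# Independent oracles and fixture builders. These deliberately re-derive the
# quantities by brute force (substring scans, full dynamic programming) so the
# fast package implementations are checked against something they do not
# share code with.

random_dna <- function(n, at = 0.5) {
  paste(sample(c("A", "T", "C", "G"), n, replace = TRUE,
               prob = c(at / 2, at / 2, (1 - at) / 2, (1 - at) / 2)),
        collapse = "")
}

r_revcomp <- function(x) {
  chartr("ACGTN", "TGCAN",
         vapply(strsplit(x, "", fixed = TRUE),
                function(v) paste(rev(v), collapse = ""), ""))
}

# all canonical k-mers of a sequence, N-windows excluded, by plain substrings
r_canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  starts <- seq_len(n - k + 1L)
  words <- substring(seq, starts, starts + k - 1L)
  words <- words[!grepl("N", words, fixed = TRUE)]
  if (!length(words)) return(character())
  sort(unique(pmin(words, r_revcomp(words))))
}

# would this read be baited? brute force: >= n distinct read k-mers (either
# strand) that occur verbatim in the reference (either strand)
r_bait_oracle <- function(read, ref, k, n = 1L) {
  rk <- unique(r_canonical_kmers(read, k))
  refk <- r_canonical_kmers(ref, k)
  sum(rk %in% refk) >= n
}

# full overlap-alignment DP (score only): free end gaps on the reference and
# at read ends that run off the reference ends; single strand
r_overlap_score_1 <- function(read, ref, ma = 1, mi = -1, go = -2) {
  m <- nchar(read); n <- nchar(ref)
  rc <- strsplit(read, "", fixed = TRUE)[[1]]
  cc <- strsplit(ref, "", fixed = TRUE)[[1]]
  H <- matrix(0, m + 1L, n + 1L)
  H[, 1L] <- 0                       # read prefix may hang off the left end
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- if (rc[i] == cc[j] && rc[i] != "N") ma else mi
      H[i + 1L, j + 1L] <- max(H[i, j] + s, H[i, j + 1L] + go,
                               H[i + 1L, j] + go)
    }
  }
  max(H[m + 1L, ], H[, n + 1L])
}

r_overlap_score <- function(read, ref, ...) {
  max(r_overlap_score_1(read, ref, ...),
      r_overlap_score_1(r_revcomp(read), ref, ...))
}

# error-free tiling reads covering a linear genome, alternating strands
tile_reads <- function(genome, read_length, step, prefix = "t") {
  L <- nchar(genome)
  starts <- unique(c(seq(1L, L - read_length + 1L, by = step),
                     L - read_length + 1L))
  seqs <- substring(genome, starts, starts + read_length - 1L)
  flip <- seq_along(seqs) %% 2L == 0L
  seqs[flip] <- r_revcomp(seqs[flip])
  data.frame(id = paste0(prefix, seq_along(starts)), seq = seqs,
             qual = NA_character_, stringsAsFactors = FALSE)
}

# place a substitution at given 1-based positions, cycling the replacement
mutate_at <- function(seq, pos) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  rot <- c(A = "C", C = "G", G = "T", T = "A", N = "A")
  ch[pos] <- rot[ch[pos]]
  paste(ch, collapse = "")
}
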