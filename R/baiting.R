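# In silico baiting: recruit reads sharing exact k-mers with the reference.
#
# This is the specificity filter of the whole pipeline: the subsequent mapping
# step is deliberately tolerant (up to 15% mismatches), so recruitment demands
# at least n exact, strand-symmetric (canonical) k-mers shared with the
# current reference. Defaults n = 1, k = 31.

#' Baiting parameters
#'
#' @param k k-mer length (default 31). Long k-mers make the filter specific;
#'   `k` must not exceed the shortest read for recruitment to be possible.
#' @param n Minimum number of distinct read k-mers that must be present in the
#'   reference index (default 1).
#' @param pair_rescue If `TRUE`, the mate of every recruited read is recruited
#'   as well (used by the de novo mode; requires a paired pool).
#' @return An object of class `bait_params`.
#' @export
bait_params <- function(k = 31L, n = 1L, pair_rescue = FALSE) {
  k <- as.integer(k); n <- as.integer(n)
  stopifnot(k >= 8L, k <= 31L, n >= 1L, is.logical(pair_rescue))
  structure(list(k = k, n = n, pair_rescue = pair_rescue),
            class = "bait_params")
}

#' Build a canonical k-mer index over reference sequences
#'
#' The index is the set of canonical (lexicographic minimum of forward and
#' reverse-complement) k-mers of every N-free length-`k` window of every
#' reference; windows containing `N` are skipped. Multi-contig references
#' contribute jointly to one index.
#'
#' @param refs Reference sequence(s): character vector, records `data.frame`,
#'   contig or assembly.
#' @param k k-mer length (default 31).
#' @return An object of class `kmer_index` with elements `k` and `kmers`.
#' @export
build_kmer_index <- function(refs, k = 31L) {
  k <- as.integer(k)
  stopifnot(k >= 8L, k <= 31L)
  records <- as_records(refs)
  if (nrow(records) == 0L) stop("refs must be non-empty")
  assert_dna(records$seq, "reference")
  kmers <- cpp_canonical_kmers(records$seq, k)
  if (length(kmers) == 0L) {
    stop("no baitable k-mers: all references are shorter than k = ", k,
         " (or consist of N)")
  }
  structure(list(k = k, kmers = kmers), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k = %d, %d canonical k-mers\n", x$k, length(x$kmers)))
  invisible(x)
}

#' Bait reads from a pool
#'
#' Recruits exactly those reads having at least `n` distinct N-free canonical
#' k-mers present in the reference index; with `pair_rescue`, the mates of all
#' recruited reads are recruited too. Pairing and provenance are preserved in
#' the returned (sub-)pool. An empty result is valid.
#'
#' @param pool A [read_pool()].
#' @param index A [build_kmer_index()] result.
#' @param params [bait_params()]; `index` must have been built with
#'   `params$k`.
#' @return A [read_pool()] containing the recruited subset.
#' @export
bait_reads <- function(pool, index, params = bait_params()) {
  stopifnot(inherits(pool, "read_pool"), inherits(index, "kmer_index"))
  if (index$k != params$k) {
    stop("index was built with k = ", index$k, " but params$k = ", params$k)
  }
  hits <- cpp_kmer_hit_counts(pool$records$seq, index$kmers, index$k)
  ids <- pool$records$id[hits >= params$n]
  if (isTRUE(params$pair_rescue) && length(ids)) {
    if (is.null(pool$pairing)) {
      stop("pair_rescue requires a paired pool (run pair_reads() first)")
    }
    p <- pool$pairing
    hit_pair <- p$fwd %in% ids | p$rev %in% ids
    ids <- union(ids, c(p$fwd[hit_pair], p$rev[hit_pair]))
  }
  subset_pool(pool, ids)
}
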