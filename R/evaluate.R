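# Scoring reconstructions against truth, recruitment metrics, k-mer spectrum
# estimates and K2P distances.

#' Compare an assembled contig with the true genome
#'
#' For circular comparisons the truth is first rotated (and reverse-
#' complemented if needed) to the offset that a shared-k-mer vote identifies,
#' then the two sequences are aligned with free terminal gaps. Substitutions
#' and indel events (one contiguous gap = one event, regardless of length)
#' are counted over the aligned region; `identity_pct` is matching columns /
#' alignment columns x 100 and `length_pct` is the aligned truth span /
#' truth length x 100.
#'
#' @param asm Assembled sequence ([contig()], records or character).
#' @param truth True genome (character, possibly named).
#' @param circular Rotate/strand-match the truth before aligning.
#' @return An object of class `diff_report` with `substitutions`, `indels`,
#'   `identity_pct`, `length_pct`, `circular_confirmed` and
#'   `no_credible_match`.
#' @export
compare_assemblies <- function(asm, truth, circular = FALSE) {
  circ_flag <- inherits(asm, "mito_contig") && asm$circular
  a <- as_records(asm)$seq[1]
  t <- unname(truth[1])
  Lt <- nchar(t)
  if (circular) {
    ori <- orient_to(a, t)
    t <- ori$truth
  }
  band <- max(200L, abs(nchar(a) - nchar(t)) + 50L)
  al <- cpp_global_align(a, t, band)
  ca <- strsplit(al$aln_a, "", fixed = TRUE)[[1]]
  ct <- strsplit(al$aln_b, "", fixed = TRUE)[[1]]
  ncols <- length(ca)
  if (ncols == 0L) {
    return(structure(list(substitutions = NA_integer_, indels = NA_integer_,
                          identity_pct = 0, length_pct = 0,
                          circular_confirmed = circ_flag,
                          no_credible_match = TRUE),
                     class = "diff_report"))
  }
  gap_a <- ca == "-"
  gap_t <- ct == "-"
  match <- !gap_a & !gap_t & ca == ct
  subs <- sum(!gap_a & !gap_t & ca != ct)
  gap_any <- gap_a | gap_t
  indels <- sum(gap_any & !c(FALSE, gap_any[-ncols]))   # gap-run starts
  identity <- 100 * sum(match) / ncols
  aligned_truth <- sum(!gap_t)
  # credible = at least half of the shorter sequence is matched; free-end
  # alignment of unrelated sequences keeps a short high-identity patch, so
  # identity over aligned columns alone cannot flag junk
  credible <- sum(match) >= 0.5 * min(nchar(a), Lt)
  structure(list(substitutions = subs, indels = indels,
                 identity_pct = identity,
                 length_pct = 100 * aligned_truth / Lt,
                 circular_confirmed = circ_flag,
                 no_credible_match = !credible),
            class = "diff_report")
}

#' @export
print.diff_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.diff_report <- function(x, ...) {
  s <- sprintf("%d/%d (%.2f%%)", x$substitutions, x$indels, x$identity_pct)
  if (x$no_credible_match) s <- paste(s, "[no credible match]")
  s
}

# Rotate (and possibly reverse-complement) the truth so that it starts where
# the assembly starts: each shared k-mer between the assembly and the doubled
# truth implies an offset; the modal offset wins.
orient_to <- function(asm_seq, truth, k = 21L) {
  vote <- function(truth_seq) {
    L <- nchar(truth_seq)
    doubled <- paste0(truth_seq, substr(truth_seq, 1L, L - 1L))
    m <- nchar(asm_seq)
    step <- max(1L, (m - k) %/% 400L)
    starts <- seq(1L, max(1L, m - k + 1L), by = step)
    words <- substr(rep(asm_seq, length(starts)), starts, starts + k - 1L)
    hits <- lapply(seq_along(starts), function(i) {
      p <- gregexpr(words[i], doubled, fixed = TRUE)[[1]]
      if (p[1] == -1L) return(integer())
      (p - starts[i]) %% L
    })
    offs <- unlist(hits, use.names = FALSE)
    if (!length(offs)) return(list(n = 0L, offset = 0L))
    tab <- sort(table(offs), decreasing = TRUE)
    list(n = as.integer(tab[1]), offset = as.integer(names(tab)[1]))
  }
  fwd <- vote(truth)
  rcs <- reverse_complement(truth)
  rev <- vote(rcs)
  use_rc <- rev$n > fwd$n
  tseq <- if (use_rc) rcs else truth
  off <- if (use_rc) rev$offset else fwd$offset
  L <- nchar(tseq)
  rotated <- if (off > 0L) {
    paste0(substr(tseq, off + 1L, L), substr(tseq, 1L, off))
  } else {
    tseq
  }
  list(truth = rotated, offset = off, revcomp = use_rc)
}

#' Read-recruitment metrics for a reconstruction
#'
#' `reads_pct` is the fraction of the target genome's reads that were
#' recruited; `fp_pct` is the fraction of recruited reads of foreign
#' (heterospecific) origin.
#'
#' @param recruited Recruited read ids (character vector) or a [read_pool()].
#' @param provenance Named character vector mapping read id to source label.
#' @param target_label The target genome's label.
#' @return An object of class `recruitment_report` with `reads_pct`,
#'   `fp_pct` and `n_recruited`.
#' @export
recruitment_metrics <- function(recruited, provenance, target_label) {
  ids <- if (inherits(recruited, "read_pool")) recruited$records$id else recruited
  if (length(ids) == 0L) {
    warning("empty recruited pool", call. = FALSE)
    return(structure(list(reads_pct = 0, fp_pct = 0, n_recruited = 0L),
                     class = "recruitment_report"))
  }
  missing <- setdiff(ids, names(provenance))
  if (length(missing)) {
    stop("recruited reads without provenance: ", missing[1])
  }
  target_ids <- names(provenance)[provenance == target_label]
  n_target_rec <- sum(ids %in% target_ids)
  structure(list(reads_pct = 100 * n_target_rec / length(target_ids),
                 fp_pct = 100 * (length(ids) - n_target_rec) / length(ids),
                 n_recruited = length(ids)),
            class = "recruitment_report")
}

#' @export
print.recruitment_report <- function(x, ...) {
  cat(sprintf("<recruitment> %.2f%% of target reads recovered, %.2f%% false positives (n = %d)\n",
              x$reads_pct, x$fp_pct, x$n_recruited))
  invisible(x)
}

#' K-mer spectrum statistics of a read pool
#'
#' Histogram of canonical k-mer multiplicities; the spectrum peak above the
#' low-coverage noise region estimates the k-mer coverage, and the genome
#' size is estimated as (total k-mer instances above the noise cutoff) /
#' peak coverage. The ratio of two pools' peaks estimates relative copy
#' number (e.g. mitochondrial vs nuclear).
#'
#' @param pool A [read_pool()] (or records/character vector of reads).
#' @param k k-mer length (default 20).
#' @param noise_cutoff Multiplicities at or below this value are treated as
#'   sequencing-error noise (default 3).
#' @return An object of class `spectrum_report` with `histogram` (data.frame
#'   `coverage`, `n_kmers`), `peak_cov` and `genome_size_est`.
#' @export
kmer_spectrum_stats <- function(pool, k = 20L, noise_cutoff = 3L) {
  records <- as_records(pool)
  if (nrow(records) == 0L) stop("empty read pool")
  mult <- cpp_kmer_multiplicities(records$seq, as.integer(k))
  if (length(mult) == 0L) stop("no k-mers: reads shorter than k?")
  tab <- table(mult)
  histogram <- data.frame(coverage = as.integer(names(tab)),
                          n_kmers = as.integer(tab))
  above <- histogram[histogram$coverage > noise_cutoff, , drop = FALSE]
  if (nrow(above) == 0L) {
    stop("spectrum peak indistinguishable from noise (no k-mer multiplicity above ",
         noise_cutoff, ")")
  }
  peak_cov <- above$coverage[which.max(above$n_kmers)]
  total_above <- sum(as.numeric(mult[mult > noise_cutoff]))
  structure(list(k = as.integer(k), histogram = histogram,
                 peak_cov = peak_cov,
                 genome_size_est = total_above / peak_cov,
                 noise_cutoff = as.integer(noise_cutoff)),
            class = "spectrum_report")
}

#' @export
print.spectrum_report <- function(x, ...) {
  cat(sprintf("<kmer spectrum> k = %d, peak coverage %d, genome size estimate %.0f bp\n",
              x$k, x$peak_cov, x$genome_size_est))
  invisible(x)
}

#' Copy-number ratio from two spectrum peaks
#'
#' The fold-excess of one pool's k-mer coverage peak over another's, e.g.
#' the mitochondrial readpool peak over the whole-dataset (nuclear) peak.
#'
#' @param a,b [kmer_spectrum_stats()] reports or bare peak coverages.
#' @return Numeric fold ratio.
#' @export
copy_ratio <- function(a, b) {
  pa <- if (inherits(a, "spectrum_report")) a$peak_cov else a
  pb <- if (inherits(b, "spectrum_report")) b$peak_cov else b
  pa / pb
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' `d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q))` with `P` and `Q` the transition
#' and transversion fractions over compared columns. Gapped or N columns are
#' excluded pairwise.
#'
#' @param a,b Aligned sequences of equal length (character).
#' @return The K2P distance (numeric).
#' @export
kimura2p <- function(a, b) {
  a <- toupper(unname(a[1])); b <- toupper(unname(b[1]))
  if (nchar(a) != nchar(b)) stop("sequences must be aligned (equal length)")
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  ca <- ca[ok]; cb <- cb[ok]
  n <- length(ca)
  if (n == 0L) stop("no comparable columns")
  diff <- ca != cb
  transition <- diff & ((ca %in% c("A", "G") & cb %in% c("A", "G")) |
                          (ca %in% c("C", "T") & cb %in% c("C", "T")))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) stop("distance undefined (saturation)")
  -0.5 * log(arg1 * sqrt(arg2))
}
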