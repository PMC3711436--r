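# Read placement on the current reference.
#
# Acceptance contract (the two rules the pipeline lives by):
#   (a) mismatches <= floor(max_mismatch_frac * overlap_len), where mismatches
#       counts substitutions plus inserted/deleted bases within the aligned
#       overlap (default fraction 0.15), and
#   (b) a read overhanging a contig end must overlap the contig by at least
#       min_edge_overlap aligned columns (default 30) to count as an
#       extension.
# Scores (+1 match, -1 mismatch, -2 gap) only rank candidate placements; the
# two rules above are the contract.

#' Mapping parameters
#'
#' @param max_mismatch_frac Maximum fraction of the alignment overlap that may
#'   be mismatched (substitutions + indel bases); default 0.15.
#' @param min_edge_overlap Minimum aligned overlap (bases) at a contig edge
#'   for a read to be accepted as an extension; default 30.
#' @param band_width Window pad (bases) around exact k-mer anchor diagonals
#'   for the seed-and-extend alignment; default 20.
#' @param strict_frac Mismatch fraction used when the initial mapping is
#'   repeated with high stringency; default 0.05.
#' @return An object of class `mapping_params`.
#' @export
mapping_params <- function(max_mismatch_frac = 0.15, min_edge_overlap = 30L,
                           band_width = 20L, strict_frac = 0.05) {
  stopifnot(strict_frac >= 0, strict_frac <= max_mismatch_frac,
            max_mismatch_frac <= 1, min_edge_overlap >= 1)
  structure(list(max_mismatch_frac = max_mismatch_frac,
                 min_edge_overlap = as.integer(min_edge_overlap),
                 band_width = as.integer(band_width),
                 strict_frac = strict_frac),
            class = "mapping_params")
}

#' Overlap-align one read against one contig
#'
#' Best free-end-gap (overlap) alignment under +1/-1/-2 scoring, computed on
#' both strands; the higher-scoring strand is returned with deterministic
#' tie-breaking (lower `ref_start`, then `+` strand). Read bases can hang off
#' the contig ends without penalty (reported as overhangs); a best score of
#' zero or less is reported as no credible alignment (`found = FALSE`).
#'
#' @param read Read sequence (character) or one-row records `data.frame`.
#' @param contig Contig sequence (character).
#' @param band_width Unused by the exhaustive aligner; kept so that callers
#'   can pass [mapping_params()] values through.
#' @return A list with `found`, `score`, `strand`, 0-based half-open
#'   `ref_start`/`ref_end`, `mismatches` (substitutions + indel bases),
#'   `overlap_len`, the aligned strings and the overhangs.
#' @export
align_overlap <- function(read, contig, band_width = NULL) {
  rec <- as_records(read)
  stopifnot(nrow(rec) == 1L, is_string(contig))
  seqs <- c(rec$seq, reverse_complement(rec$seq))
  cands <- lapply(seqs, cpp_overlap_align, ref = contig)
  pick <- pick_better(cands[[1]], TRUE, cands[[2]], FALSE)
  res <- if (pick) cands[[1]] else cands[[2]]
  strand <- if (pick) "+" else "-"
  finish_alignment(res, strand, if (pick) seqs[[1]] else seqs[[2]], rec$id)
}

# comparator mirroring the C++ tie-break: score desc, ref_start asc, + strand
pick_better <- function(a, a_plus, b, b_plus) {
  if (!isTRUE(b$found)) return(TRUE)
  if (!isTRUE(a$found)) return(FALSE)
  if (a$score != b$score) return(a$score > b$score)
  if (a$ref_start != b$ref_start) return(a$ref_start < b$ref_start)
  a_plus
}

finish_alignment <- function(res, strand, oriented, read_id) {
  m <- nchar(oriented)
  mism <- res$nsub + res$nins + res$ndel
  list(found = isTRUE(res$found) && res$score > 0,
       read_id = read_id, score = res$score, strand = strand,
       ref_start = res$ref_start, ref_end = res$ref_end,
       mismatches = mism, overlap_len = res$overlap_len,
       aln_read = res$aln_read, aln_ref = res$aln_ref,
       left_overhang = substr(oriented, 1L, res$read_start),
       right_overhang = substr(oriented, res$read_end + 1L, m))
}

#' Place reads on an assembly
#'
#' Seed-and-extend placement of a batch of reads on every contig of an
#' assembly, followed by the acceptance rules above. Each read is assigned to
#' its best-scoring contig (ties go to the lowest contig index). Rejection is
#' a normal outcome and is recorded with a reason.
#'
#' @param reads Records `data.frame`, [read_pool()], or character vector.
#' @param assembly An [assembly()] (or anything coercible to one).
#' @param params [mapping_params()].
#' @param anchor_k Exact k-mer length used to anchor candidate placements
#'   (default 12; baited reads are guaranteed a 31-mer anchor, smaller anchors
#'   also catch placements against a divergent reference).
#' @return A `data.frame` of placements: one row per read with coordinates
#'   (0-based half-open), strand, `mismatches`, `overlap_len`, overhangs,
#'   `accepted` and `reason`.
#' @export
map_pool <- function(reads, assembly, params = mapping_params(), anchor_k = 12L) {
  records <- as_records(reads)
  assembly <- as_assembly(assembly)
  ncontig <- length(assembly$contigs)
  stopifnot(ncontig >= 1L)
  per_contig <- lapply(seq_len(ncontig), function(ci) {
    ctg <- assembly$contigs[[ci]]
    df <- cpp_map_reads(records$seq, ctg$seq, as.integer(anchor_k),
                        params$band_width)
    df$contig_index <- ci
    df$contig_id <- ctg$id
    df
  })
  # best contig per read: score desc, contig index asc
  best <- per_contig[[1]]
  if (ncontig > 1L) {
    for (ci in 2:ncontig) {
      cand <- per_contig[[ci]]
      sc_best <- ifelse(best$found, best$score, -Inf)
      sc_cand <- ifelse(cand$found, cand$score, -Inf)
      take <- sc_cand > sc_best
      best[take, ] <- cand[take, ]
    }
  }
  n <- nrow(records)
  oriented <- records$seq
  neg <- which(!is.na(best$strand) & best$strand == "-")
  if (length(neg)) oriented[neg] <- reverse_complement(oriented[neg])
  mism <- best$nsub + best$nins + best$ndel
  left <- ifelse(best$found, substr(oriented, 1L, best$read_start), "")
  right <- ifelse(best$found,
                  substr(oriented, best$read_end + 1L, nchar(oriented)), "")
  overhanging <- nchar(left) > 0L | nchar(right) > 0L
  reason <- rep("ok", n)
  accepted <- rep(TRUE, n)
  no_aln <- !best$found | (!is.na(best$score) & best$score <= 0L)
  accepted[no_aln] <- FALSE
  reason[no_aln] <- "no_alignment"
  bad_mm <- !no_aln & mism > floor(params$max_mismatch_frac * best$overlap_len)
  accepted[which(bad_mm)] <- FALSE
  reason[which(bad_mm)] <- "mismatch_frac"
  bad_edge <- !no_aln & !bad_mm & overhanging &
    best$overlap_len < params$min_edge_overlap
  accepted[which(bad_edge)] <- FALSE
  reason[which(bad_edge)] <- "edge_overlap"
  data.frame(read_id = records$id,
             contig_id = ifelse(best$found, best$contig_id, NA_character_),
             contig_index = ifelse(best$found, best$contig_index, NA_integer_),
             strand = best$strand,
             ref_start = best$ref_start, ref_end = best$ref_end,
             score = best$score, mismatches = mism,
             overlap_len = best$overlap_len,
             read_start = best$read_start, read_end = best$read_end,
             aln_read = best$aln_read, aln_ref = best$aln_ref,
             left_overhang = left, right_overhang = right,
             accepted = accepted, reason = reason,
             stringsAsFactors = FALSE)
}

#' Place a single read
#'
#' Convenience wrapper around [map_pool()] for one read; returns the one-row
#' placement as a list.
#'
#' @inheritParams map_pool
#' @param read One read (character or one-row records `data.frame`).
#' @return A list (one placement) with `accepted` and `reason`.
#' @export
place_read <- function(read, assembly, params = mapping_params(), anchor_k = 12L) {
  df <- map_pool(read, assembly, params, anchor_k)
  as.list(df[1L, ])
}

#' Export placements as TSV
#'
#' Human-facing report: coordinates are converted to 1-based inclusive.
#'
#' @param placements Result of [map_pool()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_placements_tsv <- function(placements, path) {
  out <- placements[, c("read_id", "contig_id", "ref_start", "ref_end",
                        "strand", "mismatches", "overlap_len", "accepted",
                        "reason")]
  out$ref_start <- out$ref_start + 1L   # 1-based inclusive for reports
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
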