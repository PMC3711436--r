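# Consensus building, a small greedy de novo assembler, and circularity
# detection/trimming.

#' Construct a contig
#'
#' @param id Contig id.
#' @param seq Consensus sequence.
#' @param coverage Per-base integer coverage (defaults to zeros).
#' @param circular Whether the contig is circular (terminal duplication
#'   already trimmed).
#' @return An object of class `mito_contig`.
#' @export
contig <- function(id, seq, coverage = NULL, circular = FALSE) {
  seq <- toupper(seq)
  assert_dna(seq, "contig")
  if (is.null(coverage)) coverage <- integer(nchar(seq))
  stopifnot(length(coverage) == nchar(seq))
  structure(list(id = id, seq = seq, coverage = as.integer(coverage),
                 circular = isTRUE(circular)),
            class = "mito_contig")
}

#' @export
print.mito_contig <- function(x, ...) {
  cat(sprintf("<contig> %s: %d bp, mean coverage %.1f, %s\n", x$id,
              nchar(x$seq), mean(x$coverage),
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Construct an assembly
#'
#' An assembly is an ordered list of contigs (the current reference, which may
#' be gapped/multi-contig) plus the set of recruited read ids.
#'
#' @param contigs List of [contig()] objects.
#' @param recruited_ids Character vector of recruited read ids.
#' @return An object of class `mito_assembly`.
#' @export
assembly <- function(contigs, recruited_ids = character()) {
  stopifnot(all(vapply(contigs, inherits, TRUE, "mito_contig")))
  ids <- vapply(contigs, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("contig ids must be unique")
  structure(list(contigs = contigs, recruited_ids = recruited_ids),
            class = "mito_assembly")
}

#' Coerce to an assembly
#'
#' Accepts an assembly, contig, records `data.frame` or (named) character
#' vector of sequences.
#'
#' @param x Object to coerce.
#' @return A `mito_assembly`.
#' @export
as_assembly <- function(x) {
  if (inherits(x, "mito_assembly")) return(x)
  if (inherits(x, "mito_contig")) return(assembly(list(x)))
  records <- as_records(x)
  assembly(lapply(seq_len(nrow(records)), function(i) {
    contig(records$id[i], records$seq[i])
  }))
}

#' @export
print.mito_assembly <- function(x, ...) {
  cat(sprintf("<assembly> %d contig(s), total %d bp, %d recruited reads\n",
              length(x$contigs),
              sum(vapply(x$contigs, function(c) nchar(c$seq), 0L)),
              length(x$recruited_ids)))
  for (ctg in x$contigs) print(ctg)
  invisible(x)
}

#' Total assembly length
#' @param asm A `mito_assembly`.
#' @export
assembly_length <- function(asm) {
  sum(vapply(asm$contigs, function(c) nchar(c$seq), 0L))
}

# Expand one placement's aligned strings into per-reference-column votes.
# Returns list(pos, base) for ref-consuming columns (base "-" = deletion) and
# a data.frame of insertions (site = 1-based ref position the insertion
# follows, str = inserted bases).
expand_placement <- function(aln_read, aln_ref, ref_start) {
  fr <- strsplit(aln_ref, "", fixed = TRUE)[[1]]
  rd <- strsplit(aln_read, "", fixed = TRUE)[[1]]
  is_ref <- fr != "-"
  refpos <- ref_start + cumsum(is_ref)       # 1-based position of ref columns
  ins <- NULL
  if (any(!is_ref)) {
    idx <- which(!is_ref)
    runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
    site <- vapply(runs, function(r) refpos[r[1]], 0)
    str <- vapply(runs, function(r) paste(rd[r], collapse = ""), "")
    keep <- site > ref_start                 # drop insertions before column 1
    ins <- data.frame(site = site[keep], str = str[keep],
                      stringsAsFactors = FALSE)
  }
  list(pos = refpos[is_ref], base = rd[is_ref], ins = ins)
}

#' Rebuild the reference from accepted placements
#'
#' Per-column majority vote over placed read bases; the old reference base is
#' excluded from the vote, so the output consensus is purely read-derived.
#' Columns with read coverage below `min_cov` are excised and split the
#' contig; accepted edge overhangs are appended as extensions with their own
#' coverage; insertions/deletions supported by the column majority are
#' incorporated. Ties are broken alphabetically (a base beats a deletion).
#'
#' @param placements [map_pool()] output (only `accepted` rows are used).
#' @param asm The current [assembly()].
#' @param min_cov Minimum read coverage for a column to be retained
#'   (default 1).
#' @return A new `mito_assembly` (contig order preserved; split parts are
#'   numbered `id.1`, `id.2`, ...).
#' @export
build_consensus <- function(placements, asm, min_cov = 1L) {
  asm <- as_assembly(asm)
  pl <- placements[placements$accepted, , drop = FALSE]
  if (nrow(pl) == 0L) {
    warning("no accepted placements; assembly returned unchanged", call. = FALSE)
    return(asm)
  }
  out <- list()
  for (ci in seq_along(asm$contigs)) {
    ctg <- asm$contigs[[ci]]
    rows <- which(pl$contig_index == ci)
    if (length(rows) == 0L) next       # zero coverage everywhere: excised
    L <- nchar(ctg$seq)
    exp <- lapply(rows, function(r) {
      expand_placement(pl$aln_read[r], pl$aln_ref[r], pl$ref_start[r])
    })
    pos <- unlist(lapply(exp, `[[`, "pos"), use.names = FALSE)
    base <- unlist(lapply(exp, `[[`, "base"), use.names = FALSE)
    cov <- tabulate(pos, nbins = L)
    bidx <- match(base, c("A", "C", "G", "T", "-"))   # N casts no vote
    ok <- !is.na(bidx)
    counts <- matrix(tabulate((pos[ok] - 1L) * 5L + bidx[ok], nbins = 5L * L),
                     nrow = 5L)
    vote <- integer(L)
    voted <- which(cov > 0L)
    vote[voted] <- max.col(t(counts[, voted, drop = FALSE]), ties.method = "first")
    cons <- rep(NA_character_, L)
    cons[voted] <- c("A", "C", "G", "T", "-")[vote[voted]]
    keep <- cov >= max(1L, as.integer(min_cov))
    # insertions: committed where the majority of reads covering the junction
    # carry the same inserted string
    ins_all <- do.call(rbind, lapply(exp, `[[`, "ins"))
    committed_ins <- list()
    if (!is.null(ins_all) && nrow(ins_all)) {
      starts <- pl$ref_start[rows]
      ends <- pl$ref_end[rows]
      for (site in unique(ins_all$site)) {
        strs <- ins_all$str[ins_all$site == site]
        jcov <- sum(starts < site & ends >= site + 1L)
        tab <- sort(table(strs), decreasing = TRUE)
        if (tab[1] * 2L > jcov) {
          committed_ins[[as.character(site)]] <-
            list(str = names(tab)[1], support = as.integer(tab[1]))
        }
      }
    }
    # edge extensions: majority per column among overhanging accepted reads
    ext <- function(strings, left) {
      if (!length(strings)) return(list(seq = "", cov = integer()))
      lens <- nchar(strings)
      dmax <- max(lens)
      ch <- lapply(strings, function(s) strsplit(s, "", fixed = TRUE)[[1]])
      d <- unlist(lapply(ch, function(v) {
        l <- length(v)
        if (left) l - seq_len(l) + 1L else seq_len(l)
      }), use.names = FALSE)
      b <- unlist(ch, use.names = FALSE)
      bi <- match(b, c("A", "C", "G", "T"))
      ok2 <- !is.na(bi)
      cnts <- matrix(tabulate((d[ok2] - 1L) * 4L + bi[ok2], nbins = 4L * dmax),
                     nrow = 4L)
      cv <- colSums(cnts)
      reach <- which(cv == 0L)
      dlim <- if (length(reach)) min(reach) - 1L else dmax
      if (dlim == 0L) return(list(seq = "", cov = integer()))
      vt <- max.col(t(cnts[, seq_len(dlim), drop = FALSE]), ties.method = "first")
      bases <- c("A", "C", "G", "T")[vt]
      if (left) list(seq = paste(rev(bases), collapse = ""), cov = rev(cv[seq_len(dlim)]))
      else list(seq = paste(bases, collapse = ""), cov = cv[seq_len(dlim)])
    }
    lext <- ext(pl$left_overhang[rows][nchar(pl$left_overhang[rows]) > 0L], TRUE)
    rext <- ext(pl$right_overhang[rows][nchar(pl$right_overhang[rows]) > 0L], FALSE)
    # stitch: split retained interior columns into runs of consecutive columns
    kept <- which(keep)
    if (length(kept) == 0L) next
    run_id <- cumsum(c(1L, diff(kept) != 1L))
    runs <- split(kept, run_id)
    nparts <- length(runs)
    for (pi in seq_len(nparts)) {
      cols <- runs[[pi]]
      seq_parts <- character(0)
      cov_parts <- integer(0)
      for (p in cols) {
        if (cons[p] != "-") {
          seq_parts <- c(seq_parts, cons[p])
          cov_parts <- c(cov_parts, cov[p])
        }
        insp <- committed_ins[[as.character(p)]]
        if (!is.null(insp)) {
          seq_parts <- c(seq_parts, insp$str)
          cov_parts <- c(cov_parts, rep(insp$support, nchar(insp$str)))
        }
      }
      sq <- paste(seq_parts, collapse = "")
      cv <- cov_parts
      first_part <- pi == 1L && cols[1] == 1L
      last_part <- pi == nparts && cols[length(cols)] == L
      if (first_part && nchar(lext$seq)) {
        sq <- paste0(lext$seq, sq); cv <- c(lext$cov, cv)
      }
      if (last_part && nchar(rext$seq)) {
        sq <- paste0(sq, rext$seq); cv <- c(cv, rext$cov)
      }
      if (!nchar(sq)) next
      id <- if (nparts == 1L) ctg$id else paste0(ctg$id, ".", pi)
      out[[length(out) + 1L]] <- contig(id, sq, cv, circular = FALSE)
    }
  }
  if (!length(out)) {
    warning("consensus empty after coverage filtering; assembly unchanged",
            call. = FALSE)
    return(asm)
  }
  assembly(out, recruited_ids = asm$recruited_ids)
}

#' Greedy overlap assembler (verification mode)
#'
#' Repeatedly merges the pair of sequences with the highest-scoring ungapped
#' suffix-prefix overlap of at least `min_overlap` bases and within
#' `max_mismatch_frac`, taking both orientations into account; exact
#' containments are absorbed. Deterministic tie-break: longer merged length,
#' then lexicographically smaller contig id. Intended for mitogenome-scale
#' recruited pools, not whole-genome data.
#'
#' @param pool A [read_pool()] (or records/character vector).
#' @param min_overlap Minimum overlap length (default 30).
#' @param max_mismatch_frac Maximum mismatch fraction within the overlap
#'   (default 0.15).
#' @return List of [contig()] objects, longest first.
#' @export
greedy_assemble <- function(pool, min_overlap = 30L, max_mismatch_frac = 0.15) {
  records <- as_records(pool)
  seqs <- records$seq
  ids <- records$id
  n0 <- length(seqs)
  if (n0 <= 1L) {
    return(lapply(seq_len(n0), function(i) {
      contig(ids[i], seqs[i], rep(1L, nchar(seqs[i])))
    }))
  }
  k <- min(16L, as.integer(min_overlap))
  active <- rep(TRUE, n0)
  # k-mer -> contig indices (never pruned; filtered by `active` on use)
  kmap <- new.env(hash = TRUE, parent = emptyenv())
  register <- function(i) {
    for (w in cpp_canonical_kmers(seqs[i], k)) {
      kmap[[w]] <- c(kmap[[w]], i)
    }
  }
  partners <- function(i) {
    hits <- unlist(lapply(cpp_canonical_kmers(seqs[i], k), function(w) {
      kmap[[w]]
    }), use.names = FALSE)
    hits <- unique(hits)
    hits[hits != i & active[hits]]
  }
  for (i in seq_len(n0)) register(i)
  score_pair <- function(i, j) {
    m <- cpp_best_merge(seqs[i], seqs[j], as.integer(min_overlap),
                        max_mismatch_frac)
    if (m$type == "none") return(NULL)
    list(i = i, j = j, merged = m$merged,
         score = if (m$type == "contain") Inf else m$score,
         mlen = nchar(m$merged), key_id = min(ids[i], ids[j]))
  }
  edges <- list()
  for (i in seq_len(n0)) {
    for (j in partners(i)) {
      if (j > i) {
        e <- score_pair(i, j)
        if (!is.null(e)) edges[[length(edges) + 1L]] <- e
      }
    }
  }
  repeat {
    edges <- Filter(function(e) active[e$i] && active[e$j], edges)
    if (!length(edges)) break
    best <- edges[[1L]]
    for (e in edges[-1L]) {
      if (e$score > best$score ||
          (e$score == best$score && e$mlen > best$mlen) ||
          (e$score == best$score && e$mlen == best$mlen &&
           e$key_id < best$key_id)) {
        best <- e
      }
    }
    active[c(best$i, best$j)] <- FALSE
    seqs <- c(seqs, best$merged)
    ids <- c(ids, best$key_id)
    active <- c(active, TRUE)
    m <- length(seqs)
    register(m)
    for (j in partners(m)) {
      e <- score_pair(m, j)
      if (!is.null(e)) edges[[length(edges) + 1L]] <- e
    }
  }
  keep <- which(active)
  ord <- keep[order(-nchar(seqs[keep]), ids[keep])]
  lapply(ord, function(i) {
    contig(ids[i], seqs[i], rep(1L, nchar(seqs[i])), circular = FALSE)
  })
}

#' Detect and trim circularity
#'
#' If a suffix of the contig of at least `min_overlap` bases matches its
#' prefix with at least `min_identity` (ungapped), the duplicated suffix is
#' trimmed and the contig flagged circular; otherwise the contig is returned
#' unchanged. Detection is anchored on an exact occurrence of the leading 20
#' bases in the downstream half of the contig.
#'
#' @param ctg A [contig()].
#' @param min_overlap Minimum terminal duplication length (default 100).
#' @param min_identity Minimum ungapped identity of the duplication
#'   (default 0.95).
#' @return The (possibly trimmed, circular) contig.
#' @export
detect_circularity <- function(ctg, min_overlap = 100L, min_identity = 0.95) {
  stopifnot(inherits(ctg, "mito_contig"))
  if (ctg$circular) return(ctg)
  res <- cpp_self_overlap(ctg$seq, as.integer(min_overlap), min_identity)
  if (res$overlap > 0L) {
    newlen <- nchar(ctg$seq) - res$overlap
    ctg$seq <- substr(ctg$seq, 1L, newlen)
    ctg$coverage <- ctg$coverage[seq_len(newlen)]
    ctg$circular <- TRUE
  }
  ctg
}

#' Write an assembly as FASTA
#'
#' Description lines carry `circular=true|false` and the per-contig mean
#' coverage.
#'
#' @param asm A `mito_assembly`.
#' @param path Output FASTA path.
#' @param coverage_tsv Optional path for a per-base coverage TSV
#'   (contig, pos, coverage; positions 1-based).
#' @return `path`, invisibly.
#' @export
write_assembly_fasta <- function(asm, path, coverage_tsv = NULL) {
  asm <- as_assembly(asm)
  lines <- unlist(lapply(asm$contigs, function(ctg) {
    c(sprintf(">%s circular=%s mean_coverage=%.1f", ctg$id,
              if (ctg$circular) "true" else "false", mean(ctg$coverage)),
      ctg$seq)
  }))
  writeLines(lines, path)
  if (!is.null(coverage_tsv)) {
    cov <- do.call(rbind, lapply(asm$contigs, function(ctg) {
      data.frame(contig = ctg$id, pos = seq_along(ctg$coverage),
                 coverage = ctg$coverage)
    }))
    write.table(cov, coverage_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
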