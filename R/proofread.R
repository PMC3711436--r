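# Paired-end proofreading mode for pooled / metagenomic read sets.
#
# A read pair is incorporated into the growing readpool only if at least one
# mate aligns with 100% identity (zero mismatches, zero gaps) over its full
# length within the trusted reference; the other mate may extend beyond the
# reference end and contributes extension candidates. Extension columns are
# committed only where all perfectly anchored candidates agree (unanimity), so
# the contig always consists of the seed plus unanimously committed columns:
# the trusted mask is all-TRUE by construction. Pairs whose anchored mate is
# perfect but whose other mate conflicts with the committed consensus are
# rejected and counted as avoided false positives. A persistent two-sided
# conflict (>= 2 reads supporting each of two bases at the next extension
# column) halts further extension at that end, mirroring the behaviour on
# conserved blocks shared between congeners.

#' One proofreading iteration
#'
#' Performs a single bait / strict-anchor / unanimous-extend cycle on the
#' current state. Normally called via [run_iterations()] with
#' `config$proofread = TRUE`.
#'
#' @param state An `iteration_state` whose assembly has a single contig (the
#'   growing reference seeded from one barcode).
#' @param pool A fully paired [read_pool()].
#' @param config [run_config()].
#' @return The updated `iteration_state`.
#' @export
proofread_extend <- function(state, pool, config = run_config(proofread = TRUE)) {
  stopifnot(inherits(state, "iteration_state"))
  if (is.null(pool$pairing)) {
    stop("proofreading requires a fully paired pool (run pair_reads() first)")
  }
  if (length(state$assembly$contigs) != 1L) {
    stop("proofreading operates on a single-contig reference seeded from one barcode")
  }
  ctg <- state$assembly$contigs[[1]]
  L <- nchar(ctg$seq)
  read_len_max <- max(nchar(pool$records$seq))
  map_ref <- if (ctg$circular) {
    paste0(ctg$seq, substr(ctg$seq, 1L, min(read_len_max - 1L, L - 1L)))
  } else {
    ctg$seq
  }
  ref_len <- nchar(map_ref)
  idx <- build_kmer_index(map_ref, config$bait$k)
  hits <- cpp_kmer_hit_counts(pool$records$seq, idx$kmers, config$bait$k)
  baited <- pool$records$id[hits >= config$bait$n]
  p <- pool$pairing
  # a pair stays a candidate until it is "done": either both mates have been
  # placed perfectly and fully inside the reference (no extension potential
  # left) or the pair was rejected for conflicting with committed consensus
  # (the conflict is permanent, the reference only grows)
  cand <- (p$fwd %in% baited | p$rev %in% baited) &
    !(p$pair_id %in% state$done_pairs)
  state$iteration <- state$iteration + 1L
  if (!any(cand)) {
    state$count_history <- c(state$count_history, length(state$recruited_ids))
    state$length_history <- c(state$length_history, L)
    return(state)
  }
  pc <- p[cand, , drop = FALSE]
  ids <- unique(c(pc$fwd, pc$rev))
  rows <- match(ids, pool$records$id)
  seqs <- pool$records$seq[rows]
  lens <- nchar(seqs)
  mp <- cpp_map_reads(seqs, map_ref, config$anchor_k, config$map$band_width)
  mism <- mp$nsub + mp$nins + mp$ndel
  found <- mp$found
  perfect <- found & mism == 0L & mp$read_start == 0L & mp$read_end == lens
  # a mate contradicts the committed consensus only through a credible
  # (positive-score) alignment; spurious anchor hits are not conflict evidence
  conflict <- found & mism > 0L & mp$score > 0L
  ext_left <- !ctg$circular & found & mism == 0L & mp$read_start > 0L &
    mp$ref_start == 0L & mp$overlap_len >= config$ext_min_overlap
  ext_right <- !ctg$circular & found & mism == 0L & mp$read_end < lens &
    mp$ref_end == ref_len & mp$overlap_len >= config$ext_min_overlap
  fi <- match(pc$fwd, ids)
  ri <- match(pc$rev, ids)
  anchored <- perfect[fi] | perfect[ri]
  pair_conflict <- (conflict[fi] & !perfect[fi]) | (conflict[ri] & !perfect[ri])
  incorporate <- anchored & !pair_conflict
  rejected <- anchored & pair_conflict
  state$fp_avoided <- state$fp_avoided + sum(rejected)
  settled <- perfect    # fully aligned, zero mismatch: nothing left to add
  state$done_pairs <- union(state$done_pairs,
                            c(pc$pair_id[rejected],
                              pc$pair_id[settled[fi] & settled[ri]]))
  # extension candidates come from incorporated pairs only
  cand_rows <- unique(c(fi[incorporate], ri[incorporate]))
  ext_commit <- function(which_flag, left) {
    sel <- intersect(cand_rows, which(which_flag))
    if (!length(sel)) {
      return(list(seq = "", cov = integer(), halted = FALSE))
    }
    oriented <- seqs[sel]
    neg <- mp$strand[sel] == "-"
    if (any(neg)) oriented[neg] <- reverse_complement(oriented[neg])
    strings <- if (left) {
      substr(oriented, 1L, mp$read_start[sel])
    } else {
      substr(oriented, mp$read_end[sel] + 1L, lens[sel])
    }
    ch <- strsplit(strings, "", fixed = TRUE)
    d <- unlist(lapply(ch, function(v) {
      l <- length(v)
      if (left) rev(seq_len(l)) else seq_len(l)
    }), use.names = FALSE)
    b <- unlist(ch, use.names = FALSE)
    bi <- match(b, c("A", "C", "G", "T"))
    ok <- !is.na(bi)
    dmax <- max(d[ok], 0L)
    if (dmax == 0L) return(list(seq = "", cov = integer(), halted = FALSE))
    cnts <- matrix(tabulate((d[ok] - 1L) * 4L + bi[ok], nbins = 4L * dmax),
                   nrow = 4L)
    support <- colSums(cnts > 0L)     # distinct bases per column
    cv <- colSums(cnts)
    commit_to <- 0L
    halted <- FALSE
    for (dd in seq_len(dmax)) {
      if (support[dd] == 1L) {
        commit_to <- dd
      } else {
        if (support[dd] >= 2L && sort(cnts[, dd], decreasing = TRUE)[2] >= 2L) {
          halted <- TRUE
        }
        break
      }
    }
    if (commit_to == 0L) return(list(seq = "", cov = integer(), halted = halted))
    bases <- c("A", "C", "G", "T")[max.col(t(cnts[, seq_len(commit_to),
                                                  drop = FALSE]),
                                           ties.method = "first")]
    if (left) {
      list(seq = paste(rev(bases), collapse = ""),
           cov = rev(cv[seq_len(commit_to)]), halted = halted)
    } else {
      list(seq = paste(bases, collapse = ""),
           cov = cv[seq_len(commit_to)], halted = halted)
    }
  }
  lc <- ext_commit(ext_left, left = TRUE)
  rc <- ext_commit(ext_right, left = FALSE)
  new_seq <- paste0(lc$seq, ctg$seq, rc$seq)
  new_cov <- c(lc$cov, ctg$coverage, rc$cov)
  ctg2 <- contig(ctg$id, new_seq, new_cov, circular = ctg$circular)
  if (!ctg2$circular) {
    ctg2 <- detect_circularity(ctg2, config$circ_min_overlap,
                               config$circ_min_identity)
  }
  state$halted <- state$halted || lc$halted || rc$halted
  state$recruited_ids <- union(state$recruited_ids,
                               c(pc$fwd[incorporate], pc$rev[incorporate]))
  state$assembly <- assembly(list(ctg2), recruited_ids = state$recruited_ids)
  state$trusted_mask <- rep(TRUE, nchar(ctg2$seq))
  state$count_history <- c(state$count_history, length(state$recruited_ids))
  state$length_history <- c(state$length_history, nchar(ctg2$seq))
  state
}

# Full proofreading run: iterate proofread_extend() to stationarity.
proofread_run <- function(pool, seed, config, verbose = FALSE) {
  seed_records <- as_records(seed)
  if (nrow(seed_records) != 1L) {
    stop("proofreading is only applicable with a single barcode seed sequence")
  }
  if (is.null(pool$pairing)) {
    stop("proofreading requires a fully paired pool (run pair_reads() first)")
  }
  ctg0 <- contig(seed_records$id[1], seed_records$seq[1],
                 integer(nchar(seed_records$seq[1])))
  state <- new_iteration_state(assembly(list(ctg0)))
  state$trusted_mask <- rep(TRUE, nchar(ctg0$seq))
  converged <- FALSE
  notes <- character()
  while (state$iteration < config$max_iterations) {
    state <- proofread_extend(state, pool, config)
    if (verbose) {
      ctg <- state$assembly$contigs[[1]]
      message(sprintf("iteration %d: %d recruited, %d bp%s%s",
                      state$iteration, length(state$recruited_ids),
                      nchar(ctg$seq), if (ctg$circular) ", circular" else "",
                      if (state$halted) ", halted" else ""))
    }
    if (is_stationary(state$count_history, config$convergence_window) &&
        is_stationary(state$length_history, config$convergence_window)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    notes <- c(notes, sprintf(
      "max_iterations (%d) reached without a stationary read count",
      config$max_iterations))
  }
  if (state$halted) {
    notes <- c(notes, "extension halted at a two-sided read conflict")
  }
  # final per-base coverage of the committed contig from the recruited reads
  if (length(state$recruited_ids)) {
    ctg <- state$assembly$contigs[[1]]
    sub <- subset_pool(pool, state$recruited_ids)
    read_len_max <- max(nchar(pool$records$seq))
    map_ref <- if (ctg$circular) {
      paste0(ctg$seq, substr(ctg$seq, 1L, read_len_max - 1L))
    } else {
      ctg$seq
    }
    mpf <- cpp_map_reads(sub$records$seq, map_ref, config$anchor_k,
                         config$map$band_width)
    okp <- which(mpf$found & (mpf$nsub + mpf$nins + mpf$ndel) == 0L)
    L <- nchar(ctg$seq)
    cov <- integer(L)
    if (length(okp)) {
      pos <- unlist(lapply(okp, function(i) {
        seq.int(mpf$ref_start[i] + 1L, mpf$ref_end[i])
      }), use.names = FALSE)
      pos <- ((pos - 1L) %% L) + 1L
      cov <- tabulate(pos, nbins = L)
    }
    ctg$coverage <- cov
    state$assembly$contigs[[1]] <- ctg
  }
  run_report(state, converged, config, notes)
}
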