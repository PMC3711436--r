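# Orchestration of the iterative bait -> map -> consensus loop.
#
# Each iteration baits the FULL original pool against the current assembly and
# accumulates recruited read ids by union, which makes the recruited count
# non-decreasing and guarantees termination: the loop stops when the count is
# unchanged across convergence_window successive comparisons ("the number of
# mapped reads becomes stationary") or when max_iterations is reached.

#' Run configuration
#'
#' @param mode `"mapping"` (place recruited reads on the reference and rebuild
#'   the consensus) or `"denovo"` (re-assemble the recruited pool from scratch
#'   each iteration; activates pair rescue).
#' @param quick Reduce the pool by baiting against the distant reference
#'   before the initial mapping (the quick initial-fishing option).
#' @param proofread Strict paired-end mode for pooled/metagenomic samples;
#'   requires a fully paired pool and a single barcode seed.
#' @param bait [bait_params()].
#' @param map [mapping_params()].
#' @param max_iterations Iteration cap (default 200, above the worst case
#'   observed for a barcode-seeded mapping run).
#' @param convergence_window Number of successive unchanged counts that define
#'   stationarity (default 1, i.e. two equal consecutive counts).
#' @param min_cov Column coverage floor for the consensus (default 1).
#' @param anchor_k Anchor k-mer length for placement (default 12).
#' @param ext_min_overlap Proofreading: minimum exact contig overlap (bases)
#'   for an extending mate (default 20).
#' @param circ_min_overlap,circ_min_identity Circularity detection thresholds
#'   (defaults 100 bp, 0.95).
#' @param seed_rng Optional RNG seed recorded in the report (the pipeline is
#'   deterministic given its inputs).
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("mapping", "denovo"), quick = FALSE,
                       proofread = FALSE, bait = bait_params(),
                       map = mapping_params(), max_iterations = 200L,
                       convergence_window = 1L, min_cov = 1L,
                       anchor_k = 12L, ext_min_overlap = 20L,
                       circ_min_overlap = 100L, circ_min_identity = 0.95,
                       seed_rng = NULL) {
  mode <- match.arg(mode)
  stopifnot(max_iterations >= 1L, convergence_window >= 1L)
  structure(list(mode = mode, quick = isTRUE(quick),
                 proofread = isTRUE(proofread), bait = bait, map = map,
                 max_iterations = as.integer(max_iterations),
                 convergence_window = as.integer(convergence_window),
                 min_cov = as.integer(min_cov),
                 anchor_k = as.integer(anchor_k),
                 ext_min_overlap = as.integer(ext_min_overlap),
                 circ_min_overlap = as.integer(circ_min_overlap),
                 circ_min_identity = circ_min_identity,
                 seed_rng = seed_rng),
            class = "run_config")
}

new_iteration_state <- function(assembly, recruited_ids = character(),
                                count_history = integer(), iteration = 0L) {
  structure(list(iteration = iteration, assembly = assembly,
                 recruited_ids = recruited_ids,
                 count_history = count_history, length_history = integer(),
                 trusted_mask = NULL, halted = FALSE, fp_avoided = 0L,
                 done_pairs = character()),
            class = "iteration_state")
}

# Stationarity: the last (window + 1) values are identical. Convergence
# demands a stationary recruited count AND a stationary assembly length
# ("until all gaps are closed and the number of reads remains stationary").
is_stationary <- function(h, window) {
  length(h) >= window + 1L &&
    length(unique(h[(length(h) - window):length(h)])) == 1L
}

#' Build the iteration-0 reference from a distant relative's mitogenome
#'
#' Maps the pool against the distant reference (the whole pool, or the baited
#' subset when `quick = TRUE`), builds a read-only consensus and excises
#' uncovered columns, so that no base of the distant reference survives into
#' the starting assembly. The result is typically gapped/multi-contig where
#' only conserved regions attracted reads.
#'
#' @param pool A [read_pool()].
#' @param distant_ref The related species' mitogenome (character or records).
#' @param config [run_config()].
#' @param strict Use `strict_frac` instead of `max_mismatch_frac` for the
#'   initial mapping (the high-stringency re-run).
#' @return An `iteration_state` holding the iteration-0 assembly.
#' @export
initial_reference <- function(pool, distant_ref, config = run_config(),
                              strict = FALSE) {
  ref_records <- as_records(distant_ref)
  stopifnot(nrow(ref_records) >= 1L)
  sub <- pool
  if (config$quick) {
    idx <- build_kmer_index(ref_records, config$bait$k)
    sub <- bait_reads(pool, idx, config$bait)
  }
  params <- config$map
  if (isTRUE(strict)) params$max_mismatch_frac <- params$strict_frac
  asm0 <- as_assembly(ref_records)
  if (n_reads(sub) == 0L) {
    stop("seed too distant: no reads recruited; try quick = FALSE or a ",
         "barcode seed from the target species")
  }
  pl <- map_pool(sub$records, asm0, params, anchor_k = min(config$anchor_k, 10L))
  if (!any(pl$accepted)) {
    stop("seed too distant: zero reads place on the reference; try ",
         "quick = FALSE or a barcode seed from the target species")
  }
  asm1 <- build_consensus(pl, asm0, config$min_cov)
  asm1$recruited_ids <- pl$read_id[pl$accepted]
  new_iteration_state(asm1, recruited_ids = pl$read_id[pl$accepted])
}

# Reference used for baiting/mapping: circular contigs are padded with their
# own leading bases so reads spanning the origin are recruitable/placeable.
wrap_records <- function(asm, pad) {
  data.frame(
    id = vapply(asm$contigs, `[[`, "", "id"),
    seq = vapply(asm$contigs, function(ctg) {
      if (ctg$circular && pad > 0L) {
        paste0(ctg$seq, substr(ctg$seq, 1L, min(pad, nchar(ctg$seq) - 1L)))
      } else ctg$seq
    }, ""),
    qual = NA_character_, stringsAsFactors = FALSE)
}

#' Run the iterative baiting-and-mapping loop
#'
#' Starting from a seed sequence (a barcode or a full related genome used
#' directly as the iteration-0 reference) or from an [initial_reference()]
#' state, iterates: (1) bait the full pool against the current assembly,
#' accumulating recruited ids; (2) rebuild the reference, either by mapping
#' the recruited reads and calling a consensus (`mode = "mapping"`) or by
#' greedy de novo assembly of the recruited pool (`mode = "denovo"`, with
#' pair rescue); (3) detect circularity; until the recruited count is
#' stationary. In proofreading mode the strict paired-end procedure is used
#' instead (see [proofread_extend()]).
#'
#' @param pool A [read_pool()].
#' @param seed Seed sequence (character / records) or an `iteration_state`.
#' @param config [run_config()].
#' @param verbose Print one line per iteration.
#' @return An object of class `run_report` with elements `iterations_used`,
#'   `converged`, `assembly`, `recruited_ids`, `count_history`, `state`,
#'   `config` and `notes`.
#' @export
run_iterations <- function(pool, seed, config = run_config(), verbose = FALSE) {
  stopifnot(inherits(pool, "read_pool"))
  if (config$proofread) {
    return(proofread_run(pool, seed, config, verbose))
  }
  state <- if (inherits(seed, "iteration_state")) {
    seed
  } else {
    new_iteration_state(as_assembly(seed))
  }
  read_len_max <- max(nchar(pool$records$seq))
  pair_rescue <- config$bait$pair_rescue || config$mode == "denovo"
  bparams <- config$bait
  bparams$pair_rescue <- pair_rescue
  notes <- character()
  converged <- FALSE
  it <- 0L
  while (it < config$max_iterations) {
    it <- it + 1L
    ref <- wrap_records(state$assembly, read_len_max - 1L)
    idx <- build_kmer_index(ref, config$bait$k)
    baited <- bait_reads(pool, idx, bparams)
    state$recruited_ids <- union(state$recruited_ids, baited$records$id)
    count <- length(state$recruited_ids)
    sub <- subset_pool(pool, state$recruited_ids)
    all_circular <- all(vapply(state$assembly$contigs, `[[`, TRUE, "circular"))
    if (!all_circular) {
      if (config$mode == "mapping") {
        pl <- map_pool(sub$records, state$assembly, config$map, config$anchor_k)
        if (any(pl$accepted)) {
          state$assembly <- build_consensus(pl, state$assembly, config$min_cov)
        }
      } else {
        ctgs <- greedy_assemble(sub, min_overlap = config$map$min_edge_overlap,
                                max_mismatch_frac = config$map$max_mismatch_frac)
        state$assembly <- assembly(ctgs, recruited_ids = state$recruited_ids)
      }
      state$assembly$contigs <- lapply(state$assembly$contigs,
                                       detect_circularity,
                                       min_overlap = config$circ_min_overlap,
                                       min_identity = config$circ_min_identity)
    }
    state$assembly$recruited_ids <- state$recruited_ids
    state$count_history <- c(state$count_history, count)
    state$length_history <- c(state$length_history,
                              assembly_length(state$assembly))
    state$iteration <- it
    if (verbose) {
      message(sprintf("iteration %d: %d recruited, %d contig(s), %d bp",
                      it, count, length(state$assembly$contigs),
                      assembly_length(state$assembly)))
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
  run_report(state, converged, config, notes)
}

run_report <- function(state, converged, config, notes = character()) {
  structure(list(iterations_used = state$iteration, converged = converged,
                 assembly = state$assembly,
                 recruited_ids = state$recruited_ids,
                 count_history = state$count_history,
                 fp_avoided = state$fp_avoided, halted = state$halted,
                 state = state, config = config, notes = notes),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d iteration(s), %s\n", x$iterations_used,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  recruited reads: %d\n", length(x$recruited_ids)))
  print(x$assembly)
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Write run outputs to a directory
#'
#' Writes the final assembly FASTA, the recruited reads as FASTQ, a
#' per-iteration TSV and a key=value report.
#'
#' @param report A `run_report`.
#' @param pool The pool the run used (for the recruited-read FASTQ).
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_run_outputs <- function(report, pool, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_assembly_fasta(report$assembly, file.path(outdir, "assembly.fasta"),
                       coverage_tsv = file.path(outdir, "coverage.tsv"))
  rec <- subset_pool(pool, report$recruited_ids)
  write_sequences(rec$records, file.path(outdir, "recruited.fastq"), "fastq")
  iters <- data.frame(iteration = seq_along(report$count_history),
                      recruited = report$count_history)
  write.table(iters, file.path(outdir, "iterations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  keys <- c(iterations_used = report$iterations_used,
            converged = report$converged,
            recruited = length(report$recruited_ids),
            contigs = length(report$assembly$contigs),
            total_length = assembly_length(report$assembly),
            halted = report$halted, fp_avoided = report$fp_avoided,
            seed_rng = if (is.null(report$config$seed_rng)) "NA"
                       else report$config$seed_rng)
  writeLines(paste0(names(keys), "=", unlist(keys)),
             file.path(outdir, "report.txt"))
  invisible(outdir)
}
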