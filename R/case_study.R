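# The pooled-sample benchmark: several related mitogenomes, one pooled read
# set, one strict proofreading reconstruction per genome.

#' Pooled multi-genome proofreading experiment
#'
#' Simulates (or accepts) a set of related circular mitogenomes, generates an
#' error-free paired read pool from all of them, and reconstructs each genome
#' individually in proofreading mode from a barcode-length seed cut from that
#' genome. Per genome it reports iterations, convergence, per-base accuracy
#' and recovered length against the truth, the fraction of the genome's own
#' reads recruited, and the false-positive (foreign-read) fraction.
#'
#' @param n_genomes Number of related genomes (default 5).
#' @param genome_length Genome length in bp (default 16600).
#' @param at_content AT fraction of the simulated genomes (default 0.55).
#' @param divergence Per-branch K2P divergence from the common ancestor
#'   (default 0.065, i.e. ~0.13 pairwise).
#' @param reads_per_genome Total reads simulated per genome (default 6000).
#' @param read_length,insert_mean,insert_sd Read geometry (defaults 150,
#'   300, 50).
#' @param seed_length Length of the barcode seed cut from each target genome
#'   (default 1200).
#' @param linear Simulate reads from the linear sequence instead of the
#'   circle (reproduces the linear-simulation end artefact).
#' @param genomes Optional named character vector of genome sequences to use
#'   instead of simulating them (e.g. downloaded reference mitogenomes).
#' @param config Optional [run_config()] override (proofread is forced on).
#' @param rng_seed Seed for all randomness.
#' @param verbose Print per-genome progress.
#' @return A list with `per_genome` (a `data.frame` of metrics), `reports`
#'   (the run reports), `genomes` and `pool`.
#' @export
pooled_reconstruction_experiment <- function(
    n_genomes = 5L, genome_length = 16600L, at_content = 0.55,
    divergence = 0.065, reads_per_genome = 6000L, read_length = 150L,
    insert_mean = 300L, insert_sd = 50L, seed_length = 1200L,
    linear = FALSE, genomes = NULL, config = NULL, rng_seed = 1L,
    verbose = FALSE) {
  with_seed(rng_seed, {
    if (is.null(genomes)) {
      anc <- simulate_ancestor(genome_spec(genome_length, at_content,
                                           rng_seed = draw_seeds(1L)))
      genomes <- do.call(c, lapply(seq_len(n_genomes), function(i) {
        evolve_genome(anc, divergence, rng_seed = draw_seeds(1L),
                      name = sprintf("g%d", i))
      }))
    }
    labels <- names(genomes)
    pools <- lapply(labels, function(lab) {
      simulate_reads(genomes[lab],
                     sim_config(read_length = read_length,
                                insert_mean = insert_mean,
                                insert_sd = insert_sd,
                                n_reads = reads_per_genome,
                                linear = linear,
                                rng_seed = draw_seeds(1L)))
    })
    pool <- pool_readsets(pools)
    seed_offsets <- floor(runif(length(labels)) *
                            (nchar(genomes) - seed_length))
    if (is.null(config)) config <- run_config()
    config$proofread <- TRUE
    reports <- list()
    rows <- list()
    for (i in seq_along(labels)) {
      lab <- labels[i]
      seed <- setNames(substr(genomes[lab], seed_offsets[i] + 1L,
                              seed_offsets[i] + seed_length),
                       paste0(lab, "_seed"))
      rep <- run_iterations(pool, seed, config)
      ctg <- rep$assembly$contigs[[1]]
      cmp <- compare_assemblies(ctg, genomes[lab], circular = TRUE)
      recr <- recruitment_metrics(rep$recruited_ids, pool$provenance, lab)
      reports[[lab]] <- rep
      rows[[lab]] <- data.frame(
        genome = lab, iterations = rep$iterations_used,
        converged = rep$converged, circular = ctg$circular,
        halted = rep$halted,
        accuracy_pct = cmp$identity_pct, length_pct = cmp$length_pct,
        substitutions = cmp$substitutions, indels = cmp$indels,
        reads_pct = recr$reads_pct, fp_pct = recr$fp_pct,
        n_recruited = recr$n_recruited, stringsAsFactors = FALSE)
      if (verbose) {
        message(sprintf(
          "%s: %d iterations, %.2f%% accuracy, %.2f%% length, %.2f%% reads, %.2f%% fp",
          lab, rep$iterations_used, cmp$identity_pct, cmp$length_pct,
          recr$reads_pct, recr$fp_pct))
      }
    }
    list(per_genome = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         reports = reports, genomes = genomes, pool = pool)
  })
}
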