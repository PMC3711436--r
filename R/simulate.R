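# Synthetic circular mitogenome-like sequences and paired-end reads.
#
# The generator's defaults restate the pooled-sample benchmark world: five
# ~16.6 kb circular genomes, error-free 150 bp paired reads with insert
# 300 +/- 50 bp, 6000 reads (3000 pairs, ~54x) per genome; AT content 0.55
# (teleost-like; 0.62 for the flatworm-like setting) and, optionally, a
# 750-800 bp non-coding tandem repeat.

#' Genome specification
#'
#' @param length Genome length in bp (default 16600).
#' @param at_content Fraction of A+T (default 0.55).
#' @param repeat_unit Optional length (bp) of a non-coding tandem-repeat unit,
#'   typically in 750-800; `NULL` for no repeat.
#' @param repeat_copies Number of tandem copies (>= 2) when `repeat_unit` is
#'   given.
#' @param rng_seed Optional seed for reproducible generation.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(length = 16600L, at_content = 0.55,
                        repeat_unit = NULL, repeat_copies = 2L,
                        rng_seed = NULL) {
  stopifnot(length >= 1000L, at_content > 0, at_content < 1)
  if (!is.null(repeat_unit)) {
    stopifnot(repeat_unit >= 1L, repeat_copies >= 2L)
    if (repeat_unit * repeat_copies >= length) {
      stop("repeat total length must be smaller than the genome length")
    }
  }
  structure(list(length = as.integer(length), at_content = at_content,
                 repeat_unit = if (is.null(repeat_unit)) NULL else
                   as.integer(repeat_unit),
                 repeat_copies = as.integer(repeat_copies),
                 rng_seed = rng_seed),
            class = "genome_spec")
}

#' Simulate an ancestral circular genome
#'
#' Bases are i.i.d. with `P(A) = P(T) = at_content/2`; if a repeat is
#' specified, tandem copies of one random unit are inserted at a random
#' position. Reproducible given `rng_seed`.
#'
#' @param spec A [genome_spec()].
#' @return Named character vector of length 1 (the circular genome sequence).
#' @export
simulate_ancestor <- function(spec = genome_spec()) {
  with_seed(spec$rng_seed, {
    probs <- c(A = spec$at_content / 2, T = spec$at_content / 2,
               C = (1 - spec$at_content) / 2, G = (1 - spec$at_content) / 2)
    draw <- function(n) sample(names(probs), n, replace = TRUE, prob = probs)
    if (is.null(spec$repeat_unit)) {
      seq <- paste(draw(spec$length), collapse = "")
    } else {
      rep_total <- spec$repeat_unit * spec$repeat_copies
      backbone_len <- spec$length - rep_total
      backbone <- draw(backbone_len)
      unit <- paste(draw(spec$repeat_unit), collapse = "")
      at <- sample.int(backbone_len - 1L, 1L)
      seq <- paste0(paste(backbone[seq_len(at)], collapse = ""),
                    strrep(unit, spec$repeat_copies),
                    paste(backbone[(at + 1L):backbone_len], collapse = ""))
    }
    setNames(seq, "ancestor")
  })
}

#' Evolve a genome by random substitution to a target K2P distance
#'
#' Each site is substituted independently with the probability that gives an
#' expected Kimura two-parameter distance of `divergence` under equal
#' transition/transversion weighting (the three alternative bases are equally
#' likely, so the closed form `p = 3/4 (1 - exp(-4 d / 3))` applies). Length
#' is preserved; reproducible given `rng_seed`.
#'
#' @param ancestor Genome sequence (character, possibly named).
#' @param divergence Target expected K2P distance (substitutions/site) in
#'   `[0, 0.75]`.
#' @param rng_seed Optional seed.
#' @param name Name for the descendant (default `"descendant"`).
#' @return Named character vector of length 1.
#' @export
evolve_genome <- function(ancestor, divergence, rng_seed = NULL,
                          name = "descendant") {
  stopifnot(divergence >= 0, divergence <= 0.75)
  seq <- unname(ancestor[1])
  if (divergence == 0) return(setNames(seq, name))
  with_seed(rng_seed, {
    p <- 3 / 4 * (1 - exp(-4 * divergence / 3))
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(chars)) < p & chars %in% c("A", "C", "G", "T"))
    if (length(hit)) {
      alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                  G = c("A", "C", "T"), T = c("A", "C", "G"))
      pick <- sample.int(3L, length(hit), replace = TRUE)
      chars[hit] <- mapply(function(b, k) alt[[b]][k], chars[hit], pick,
                           USE.NAMES = FALSE)
    }
    setNames(paste(chars, collapse = ""), name)
  })
}

#' Read-simulation configuration
#'
#' @param read_length Read length in bp (default 150).
#' @param insert_mean,insert_sd Insert size mean and SD in bp (defaults
#'   300 and 50; inserts are truncated to at least `read_length`).
#' @param n_reads Total number of reads (must be even; default 6000, i.e.
#'   3000 pairs, ~54x on a 16.6 kb genome).
#' @param error_rate Per-base substitution error rate (default 0).
#' @param linear Sample fragments from the linear sequence instead of the
#'   circle, reproducing the coverage deficit toward the reference ends that
#'   linear-reference simulation causes.
#' @param rng_seed Optional seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(read_length = 150L, insert_mean = 300L, insert_sd = 50L,
                       n_reads = 6000L, error_rate = 0, linear = FALSE,
                       rng_seed = NULL) {
  stopifnot(insert_mean >= read_length, n_reads %% 2L == 0L,
            error_rate >= 0, error_rate < 1)
  structure(list(read_length = as.integer(read_length),
                 insert_mean = as.integer(insert_mean),
                 insert_sd = as.integer(insert_sd),
                 n_reads = as.integer(n_reads), error_rate = error_rate,
                 linear = isTRUE(linear), rng_seed = rng_seed),
            class = "sim_config")
}

#' Simulate paired-end reads from a circular genome
#'
#' Fragment starts are uniform on the circle (reads may span the origin, or
#' uniform on the linear sequence with `linear = TRUE`); insert lengths are
#' normal(`insert_mean`, `insert_sd`) truncated to at least `read_length`;
#' the forward mate is the 5' end of the + strand, the reverse mate the
#' reverse complement of the 3' end. Substitution errors are applied at
#' `error_rate` per base. Reads get ids `<genome>_r<i>/1` and `/2`, pairing
#' is populated, and provenance is the genome name.
#'
#' @param genome Named character vector of length 1 (the genome).
#' @param config A [sim_config()].
#' @return A paired, provenance-labelled [read_pool()].
#' @export
simulate_reads <- function(genome, config = sim_config()) {
  seq <- unname(genome[1])
  label <- names(genome)[1]
  if (is.null(label) || is.na(label)) label <- "genome"
  L <- nchar(seq)
  rl <- config$read_length
  stopifnot(L > config$insert_mean + 4L * config$insert_sd)
  npair <- config$n_reads %/% 2L
  with_seed(config$rng_seed, {
    ins <- pmin(L, pmax(rl, round(rnorm(npair, config$insert_mean,
                                        config$insert_sd))))
    if (config$linear) {
      start <- floor(runif(npair) * (L - ins + 1L))      # 0-based
    } else {
      start <- floor(runif(npair) * L)
    }
    doubled <- paste0(seq, seq)
    frag <- substr(rep(doubled, npair), start + 1L, start + ins)
    fwd <- substr(frag, 1L, rl)
    rev <- reverse_complement(substr(frag, ins - rl + 1L, ins))
    if (config$error_rate > 0) {
      corrupt <- function(x) {
        ch <- strsplit(x, "", fixed = TRUE)
        vapply(ch, function(v) {
          hit <- which(runif(length(v)) < config$error_rate)
          if (length(hit)) {
            alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                        G = c("A", "C", "T"), T = c("A", "C", "G"))
            v[hit] <- vapply(v[hit], function(b) {
              sample(alt[[b]], 1L)
            }, "")
          }
          paste(v, collapse = "")
        }, "")
      }
      fwd <- corrupt(fwd)
      rev <- corrupt(rev)
    }
    pair_id <- sprintf("%s_r%d", label, seq_len(npair))
    fid <- paste0(pair_id, "/1")
    rid <- paste0(pair_id, "/2")
    records <- data.frame(
      id = as.vector(rbind(fid, rid)),
      seq = as.vector(rbind(fwd, rev)),
      qual = strrep("I", rl), stringsAsFactors = FALSE)
    pairing <- data.frame(pair_id = pair_id, fwd = fid, rev = rid,
                          stringsAsFactors = FALSE)
    provenance <- setNames(rep(label, nrow(records)), records$id)
    read_pool(records, pairing, provenance)
  })
}

#' Pool several read sets
#'
#' Concatenates pools, preserving pairing and provenance; read counts are
#' additive. Read ids must be unique across pools (the simulator prefixes
#' them with the genome label).
#'
#' @param pools List of [read_pool()] objects.
#' @return One pooled [read_pool()].
#' @export
pool_readsets <- function(pools) {
  stopifnot(length(pools) >= 1L, all(vapply(pools, inherits, TRUE, "read_pool")))
  records <- do.call(rbind, lapply(pools, `[[`, "records"))
  if (anyDuplicated(records$id)) {
    stop("read id collision while pooling: ",
         records$id[duplicated(records$id)][1])
  }
  pairings <- lapply(pools, `[[`, "pairing")
  pairing <- if (all(vapply(pairings, is.null, TRUE))) NULL else
    do.call(rbind, pairings[!vapply(pairings, is.null, TRUE)])
  provs <- lapply(pools, `[[`, "provenance")
  provenance <- if (all(vapply(provs, is.null, TRUE))) NULL else
    do.call(c, provs[!vapply(provs, is.null, TRUE)])
  read_pool(records, pairing, provenance)
}
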