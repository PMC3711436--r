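sim_pool <- function(genome, n_reads, read_length = 150, insert_mean = 300,
                     insert_sd = 40, seed = 1) {
  simulate_reads(genome, sim_config(read_length = read_length,
                                    insert_mean = insert_mean,
                                    insert_sd = insert_sd, n_reads = n_reads,
                                    rng_seed = seed))
}

test_that("initial mapping against the target's own genome is exact", {
  g <- evolve_genome(simulate_ancestor(genome_spec(3000, rng_seed = 81)), 0,
                     name = "g")
  pool <- sim_pool(g, 800, seed = 82)
  st <- initial_reference(pool, setNames(unname(g), "ref"), run_config())
  expect_s3_class(st, "iteration_state")
  # consensus over covered columns equals the truth (reference casts no vote);
  # origin-spanning reads may extend both ends, hence the tripled genome
  ctg <- st$assembly$contigs[[1]]
  expect_true(grepl(ctg$seq, strrep(unname(g), 3), fixed = TRUE))
  expect_gt(nchar(ctg$seq), 2900)
})

test_that("a reference sharing only conserved blocks yields a gapped start", {
  set.seed(83)
  g <- setNames(random_dna(3000), "g")
  pool <- read_pool(tile_reads(unname(g), 150, 30))
  # distant reference: random backbone carrying two conserved blocks of g
  distant <- setNames(paste0(random_dna(300),
                             substr(unname(g), 501, 900),
                             random_dna(400),
                             substr(unname(g), 1901, 2300),
                             random_dna(300)), "distant")
  st <- initial_reference(pool, distant, run_config())
  expect_gte(length(st$assembly$contigs), 2L)
  seqs <- vapply(st$assembly$contigs, `[[`, "", "seq")
  # both conserved cores are recovered verbatim
  expect_true(any(grepl(substr(unname(g), 501, 900), seqs, fixed = TRUE)))
  expect_true(any(grepl(substr(unname(g), 1901, 2300), seqs, fixed = TRUE)))
  # and no distant-reference backbone sequence survives into the consensus
  backbone_kmers <- r_canonical_kmers(substr(unname(distant), 1, 300), 31)
  contig_kmers <- unlist(lapply(seqs, r_canonical_kmers, k = 31))
  expect_equal(length(intersect(backbone_kmers, contig_kmers)), 0L)

  # unrelated reference: nothing places
  expect_error(initial_reference(pool, setNames(random_dna(2000), "x"),
                                 run_config()),
               "seed too distant")
})

test_that("quick mode equals bait-then-map on the reduced pool", {
  set.seed(84)
  g <- setNames(random_dna(2500), "g")
  pool <- read_pool(tile_reads(unname(g), 150, 40))
  distant <- setNames(paste0(random_dna(200), substr(unname(g), 801, 1600),
                             random_dna(200)), "d")
  cfgq <- run_config(quick = TRUE)
  st_quick <- initial_reference(pool, distant, cfgq)
  reduced <- bait_reads(pool, build_kmer_index(distant, 31), cfgq$bait)
  st_manual <- initial_reference(reduced, distant, run_config())
  expect_equal(vapply(st_quick$assembly$contigs, `[[`, "", "seq"),
               vapply(st_manual$assembly$contigs, `[[`, "", "seq"))
})

test_that("seeding with the full true genome converges immediately and exactly", {
  g <- evolve_genome(simulate_ancestor(genome_spec(3000, rng_seed = 85)), 0,
                     name = "g")
  pool <- sim_pool(g, 1000, seed = 86)      # 50x
  rep <- run_iterations(pool, setNames(unname(g), "seed"),
                        run_config(max_iterations = 10))
  expect_true(rep$converged)
  expect_lte(rep$iterations_used, 3L)
  cmp <- compare_assemblies(rep$assembly$contigs[[1]], g, circular = TRUE)
  expect_equal(cmp$identity_pct, 100)
  # recruited counts are non-decreasing and bounded by the pool size
  expect_true(all(diff(rep$count_history) >= 0))
  expect_lte(max(rep$count_history), n_reads(pool))
})

test_that("a barcode seed recovers the full circular genome in mapping mode", {
  g <- evolve_genome(simulate_ancestor(genome_spec(3000, rng_seed = 87)), 0,
                     name = "g")
  pool <- sim_pool(g, 1200, seed = 88)
  seed <- setNames(substr(unname(g), 1201, 1850), "coi")   # ~650 bp barcode
  rep <- run_iterations(pool, seed, run_config(max_iterations = 60))
  expect_true(rep$converged)
  ctg <- rep$assembly$contigs[[1]]
  expect_true(ctg$circular)
  cmp <- compare_assemblies(ctg, g, circular = TRUE)
  expect_equal(cmp$identity_pct, 100)
  expect_equal(cmp$length_pct, 100)
})

test_that("self-recovery holds for random seeds of repeat-free genomes", {
  # parameter-recovery property: any >= 200 bp exact seed substring recovers
  # the full circle at 100% identity from error-free paired reads
  for (trial in 1:2) {
    g <- evolve_genome(simulate_ancestor(genome_spec(2600,
                                                     rng_seed = 89 + trial)),
                       0, name = "g")
    pool <- sim_pool(g, 1000, seed = 91 + trial)
    off <- sample(1:(2600 - 260), 1)
    seed <- setNames(substr(unname(g), off, off + 199 + sample(0:60, 1)), "s")
    rep <- run_iterations(pool, seed, run_config(max_iterations = 60))
    cmp <- compare_assemblies(rep$assembly$contigs[[1]], g, circular = TRUE)
    expect_equal(cmp$identity_pct, 100)
    expect_true(rep$converged)
  }
})

test_that("de novo mode with pair rescue needs fewer iterations than mapping", {
  g <- evolve_genome(simulate_ancestor(genome_spec(4000, rng_seed = 95)), 0,
                     name = "g")
  # long inserts: de novo extension per iteration can reach insert range,
  # mapping-mode extension is limited to read length minus the edge overlap
  pool <- sim_pool(g, 700, read_length = 150, insert_mean = 600,
                   insert_sd = 40, seed = 96)
  seed <- setNames(substr(unname(g), 1001, 1500), "seed")
  rep_map <- run_iterations(pool, seed,
                            run_config(mode = "mapping", max_iterations = 40))
  rep_dn <- run_iterations(pool, seed,
                           run_config(mode = "denovo", max_iterations = 40))
  expect_true(rep_dn$converged)
  expect_lt(rep_dn$iterations_used, rep_map$iterations_used)
  # both modes reconstruct the genome
  cmp <- compare_assemblies(rep_dn$assembly$contigs[[1]], g, circular = TRUE)
  expect_gte(cmp$identity_pct, 99.9)
})

test_that("proofreading incorporates perfect pairs and extends unanimously", {
  set.seed(97)
  g <- random_dna(800)
  seed <- setNames(substr(g, 1, 400), "seed")
  # p1: one mate perfect inside the trusted region, the other extends right
  recs <- data.frame(
    id = c("p1/1", "p1/2", "p2/1", "p2/2"),
    seq = c(substr(g, 301, 400),
            r_revcomp(substr(g, 381, 480)),
            mutate_at(substr(g, 201, 300), 50),   # 1 mismatch to trusted
            r_revcomp(substr(g, 451, 550))),      # mate: no anchor at all
    qual = NA_character_, stringsAsFactors = FALSE)
  pool <- pair_reads(read_pool(recs), "suffix")
  cfg <- run_config(proofread = TRUE, max_iterations = 3)
  rep <- run_iterations(pool, seed, cfg)
  # p1 incorporated, contig extended by the mate's overhang
  expect_setequal(rep$recruited_ids, c("p1/1", "p1/2"))
  ctg <- rep$assembly$contigs[[1]]
  expect_equal(ctg$seq, substr(g, 1, 480))
  # p2 not incorporated: its anchored mate is not 100% identical
  expect_false(any(c("p2/1", "p2/2") %in% rep$recruited_ids))
})

test_that("proofreading rejects pairs whose mate conflicts with consensus", {
  set.seed(98)
  g <- random_dna(800)                       # target genome
  seed <- setNames(substr(g, 1, 400), "seed")
  # the foreign pair anchors perfectly on a conserved block inside the seed,
  # but its mate disagrees with the committed consensus where it overlaps the
  # contig end (a heterospecific read from a diverged congener)
  overlap_f <- mutate_at(substr(g, 381, 400), c(1, 20))
  recs <- data.frame(
    id = c("t1/1", "t1/2", "f1/1", "f1/2"),
    seq = c(substr(g, 281, 380), r_revcomp(substr(g, 381, 480)),
            substr(g, 251, 350),                  # perfect in trusted block
            r_revcomp(paste0(overlap_f, random_dna(70)))),
    qual = NA_character_, stringsAsFactors = FALSE)
  pool <- pair_reads(read_pool(recs), "suffix")
  cfg <- run_config(proofread = TRUE, max_iterations = 4)
  rep <- run_iterations(pool, seed, cfg)
  expect_setequal(rep$recruited_ids, c("t1/1", "t1/2"))
  expect_gte(rep$fp_avoided, 1L)
  expect_equal(rep$assembly$contigs[[1]]$seq, substr(g, 1, 480))
})

test_that("a two-sided unanimous-extension conflict halts extension", {
  set.seed(100)
  g <- random_dna(700)
  seed <- setNames(substr(g, 1, 400), "seed")
  ext_a <- substr(g, 401, 480)                      # one extension haplotype
  ext_b <- mutate_at(ext_a, seq(1, 80, by = 8))     # a conflicting one
  mk <- function(tag, ext) {
    data.frame(id = paste0(tag, c("/1", "/2")),
               seq = c(substr(g, 261, 360),
                       r_revcomp(paste0(substr(g, 381, 400), ext))),
               qual = NA_character_, stringsAsFactors = FALSE)
  }
  recs <- rbind(mk("a1", ext_a), mk("a2", ext_a), mk("b1", ext_b),
                mk("b2", ext_b))
  pool <- pair_reads(read_pool(recs), "suffix")
  cfg <- run_config(proofread = TRUE, max_iterations = 3)
  rep <- run_iterations(pool, seed, cfg)
  expect_true(rep$halted)
  # nothing was committed at the conflicting columns
  expect_equal(rep$assembly$contigs[[1]]$seq, substr(g, 1, 400))
})

test_that("proofreading demands a paired pool and a single seed", {
  set.seed(99)
  pool <- read_pool(data.frame(id = "r1", seq = random_dna(100),
                               qual = NA_character_, stringsAsFactors = FALSE))
  cfg <- run_config(proofread = TRUE, max_iterations = 2)
  expect_error(run_iterations(pool, setNames(random_dna(300), "s"), cfg),
               "paired")
  pool2 <- pair_reads(read_pool(data.frame(
    id = c("a/1", "a/2"), seq = c(random_dna(100), random_dna(100)),
    qual = NA_character_, stringsAsFactors = FALSE)), "suffix")
  expect_error(run_iterations(pool2, c(s1 = random_dna(300),
                                       s2 = random_dna(300)), cfg),
               "single")
})
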