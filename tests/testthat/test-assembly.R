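make_placements <- function(records, asm, params = mapping_params()) {
  map_pool(records, asm, params)
}

test_that("consensus from error-free tiling reads reproduces the genome", {
  set.seed(41)
  g <- random_dna(1200)
  asm <- as_assembly(setNames(g, "c1"))
  reads <- tile_reads(g, 100, 20)
  pl <- make_placements(reads, asm)
  out <- build_consensus(pl, asm)
  expect_equal(length(out$contigs), 1L)
  expect_equal(out$contigs[[1]]$seq, g)
  expect_true(all(out$contigs[[1]]$coverage >= 1L))
})

test_that("an uncovered interior column splits the contig", {
  set.seed(42)
  g <- random_dna(900)
  asm <- as_assembly(setNames(g, "c1"))
  # tile two blocks, leaving 401..500 uncovered
  reads <- rbind(tile_reads(substr(g, 1, 400), 80, 40, "l"),
                 tile_reads(substr(g, 501, 900), 80, 40, "r"))
  pl <- make_placements(reads, asm)
  out <- build_consensus(pl, asm)
  expect_equal(length(out$contigs), 2L)
  expect_equal(out$contigs[[1]]$seq, substr(g, 1, 400))
  expect_equal(out$contigs[[2]]$seq, substr(g, 501, 900))
  expect_equal(out$contigs[[1]]$id, "c1.1")
})

test_that("majority vote resolves conflicting columns; reference is excluded", {
  set.seed(43)
  g <- random_dna(200)
  asm <- as_assembly(setNames(g, "c1"))
  base <- substr(g, 51, 150)
  reads <- data.frame(id = paste0("r", 1:4),
                      seq = c(base, base, base, mutate_at(base, 60)),
                      qual = NA_character_, stringsAsFactors = FALSE)
  pl <- make_placements(reads, asm)
  out <- build_consensus(pl, asm)
  # column {A,A,A,C}-style: majority wins, the dissenter is outvoted
  expect_equal(out$contigs[[1]]$seq, base)

  # when ALL reads carry a variant, it replaces the reference base
  # (the reference casts no vote)
  var <- mutate_at(base, 50)
  reads2 <- data.frame(id = paste0("v", 1:3), seq = c(var, var, var),
                       qual = NA_character_, stringsAsFactors = FALSE)
  out2 <- build_consensus(make_placements(reads2, asm), asm)
  expect_equal(out2$contigs[[1]]$seq, var)
})

test_that("edge overhangs extend the contig and are read-supported", {
  set.seed(44)
  g <- random_dna(800)
  ctg <- substr(g, 101, 700)
  asm <- as_assembly(setNames(ctg, "c1"))
  reads <- rbind(tile_reads(ctg, 100, 50, "in"),
                 data.frame(id = c("le", "re"),
                            seq = c(substr(g, 51, 150), substr(g, 651, 750)),
                            qual = NA_character_, stringsAsFactors = FALSE))
  pl <- make_placements(reads, asm)
  out <- build_consensus(pl, asm)
  expect_equal(out$contigs[[1]]$seq, substr(g, 51, 750))
  # every appended extension base is supported by >= 1 anchored read
  expect_true(all(out$contigs[[1]]$coverage >= 1L))
})

test_that("greedy assembly merges overlaps and reconstructs toy genomes", {
  set.seed(45)
  a <- random_dna(120)
  b <- paste0(substr(a, 81, 120), random_dna(80))   # 40 bp exact overlap
  ctgs <- greedy_assemble(c(r1 = a, r2 = b), min_overlap = 30)
  expect_equal(length(ctgs), 1L)
  expect_equal(nchar(ctgs[[1]]$seq), 200L)
  expect_equal(ctgs[[1]]$seq, paste0(a, substr(b, 41, 120)))

  # no qualifying overlap: two contigs
  ctgs <- greedy_assemble(c(r1 = random_dna(100), r2 = random_dna(100)),
                          min_overlap = 30)
  expect_equal(length(ctgs), 2L)

  # error-free 2x tiling of random genomes reconstructs them exactly
  for (trial in 1:3) {
    g <- random_dna(sample(1000:2500, 1))
    reads <- tile_reads(g, 100, 50)
    ctgs <- greedy_assemble(read_pool(reads), min_overlap = 30)
    expect_equal(length(ctgs), 1L)
    expect_true(ctgs[[1]]$seq == g || ctgs[[1]]$seq == r_revcomp(g))
  }
})

test_that("circularity detection trims terminal duplications", {
  set.seed(46)
  g <- random_dna(2000)
  dup <- contig("c", paste0(g, substr(g, 1, 200)))
  out <- detect_circularity(dup, min_overlap = 100)
  expect_true(out$circular)
  expect_equal(nchar(out$seq), 2000L)
  expect_equal(out$seq, g)

  plain <- detect_circularity(contig("c", g), min_overlap = 100)
  expect_false(plain$circular)
  expect_equal(plain$seq, g)

  short_dup <- contig("c", paste0(g, substr(g, 1, 50)))
  out <- detect_circularity(short_dup, min_overlap = 100)
  expect_false(out$circular)                 # 50 bp < min_overlap

  # a 5% diverged duplication is still recognised at min_identity 0.95
  noisy <- paste0(g, mutate_at(substr(g, 1, 200), seq(25, 200, by = 25)))
  out <- detect_circularity(contig("c", noisy), min_overlap = 100,
                            min_identity = 0.95)
  expect_true(out$circular)
  expect_equal(nchar(out$seq), 2000L)
})

test_that("assembly FASTA output carries circular flags and coverage", {
  set.seed(47)
  asm <- assembly(list(contig("c1", random_dna(100), rep(5L, 100), TRUE)))
  fa <- tempfile(fileext = ".fa")
  cov <- tempfile(fileext = ".tsv")
  write_assembly_fasta(asm, fa, cov)
  lines <- readLines(fa)
  expect_match(lines[1], "circular=true")
  expect_match(lines[1], "mean_coverage=5.0")
  expect_equal(nrow(read.delim(cov)), 100L)
})
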