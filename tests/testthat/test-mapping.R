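test_that("overlap alignment matches the full-DP oracle", {
  set.seed(31)
  ctg <- random_dna(300)
  # exact interior substring: full-length, zero-mismatch alignment
  read <- substr(ctg, 101, 160)
  al <- align_overlap(read, ctg)
  expect_true(al$found)
  expect_equal(al$score, 60L)
  expect_equal(al$mismatches, 0L)
  expect_equal(c(al$ref_start, al$ref_end), c(100L, 160L))

  # hopeless read: best overlap score <= 0, no credible alignment
  al <- align_overlap("GGGG", strrep("A", 50))
  expect_false(al$found)

  # random reads (some mutated, some reverse-complemented, some junk) agree
  # in score with an independent full dynamic-programming oracle
  for (i in 1:12) {
    read <- switch(sample(3, 1),
                   substr(ctg, s <- sample(1:240, 1), s + 59),
                   mutate_at(substr(ctg, s <- sample(1:240, 1), s + 59),
                             sample(1:60, 5)),
                   random_dna(60))
    if (runif(1) < 0.5) read <- r_revcomp(read)
    al <- align_overlap(read, ctg)
    expect_equal(al$score, r_overlap_score(read, ctg))
  }
})

test_that("placement acceptance obeys the mismatch-fraction rule exactly", {
  set.seed(32)
  ctg <- random_dna(400)
  asm <- as_assembly(setNames(ctg, "c1"))
  interior <- substr(ctg, 151, 250)        # 100 bp, fully interior
  # substitutions clustered in the first 62 bp so an exact anchor survives
  pos <- seq(2, 62, by = 4)
  r15 <- mutate_at(interior, pos[1:15])
  r16 <- mutate_at(interior, pos[1:16])
  p15 <- place_read(r15, asm)
  p16 <- place_read(r16, asm)
  expect_true(p15$accepted)
  expect_equal(p15$mismatches, 15L)
  expect_false(p16$accepted)
  expect_equal(p16$reason, "mismatch_frac")

  # acceptance is invariant under reverse-complementing the read
  p15rc <- place_read(r_revcomp(r15), asm)
  expect_true(p15rc$accepted)
  expect_equal(p15rc$strand, "-")
  expect_equal(p15rc$mismatches, 15L)
  expect_equal(c(p15rc$ref_start, p15rc$ref_end),
               c(p15$ref_start, p15$ref_end))
})

test_that("edge extensions require a 30-base overlap at the contig end", {
  set.seed(33)
  g <- random_dna(600)
  ctg <- substr(g, 1, 400)
  asm <- as_assembly(setNames(ctg, "c1"))
  # read overlapping the 3' end by exactly 30 / 29 bases, then overhanging
  r30 <- substr(g, 371, 470)
  r29 <- substr(g, 372, 471)
  p30 <- place_read(r30, asm)
  p29 <- place_read(r29, asm)
  expect_true(p30$accepted)
  expect_equal(p30$overlap_len, 30L)
  expect_equal(nchar(p30$right_overhang), 70L)
  expect_false(p29$accepted)
  expect_equal(p29$reason, "edge_overlap")
  # an interior read with the same overlap length is not edge-constrained
  expect_true(place_read(substr(g, 100, 129), asm)$accepted)
})

test_that("accepted placements always satisfy both acceptance inequalities", {
  set.seed(34)
  g <- random_dna(2000)
  params <- mapping_params()
  asm <- as_assembly(setNames(substr(g, 1, 1500), "c1"))
  reads <- vapply(1:60, function(i) {
    s <- sample(1:(2000 - 120), 1)
    r <- substr(g, s, s + 119)
    nmut <- sample(0:24, 1)
    if (nmut > 0) r <- mutate_at(r, sample(1:120, nmut))
    if (runif(1) < 0.5) r <- r_revcomp(r)
    r
  }, "")
  pl <- map_pool(data.frame(id = paste0("r", 1:60), seq = reads,
                            qual = NA_character_, stringsAsFactors = FALSE),
                 asm, params)
  acc <- pl[pl$accepted, ]
  expect_true(all(acc$mismatches <=
                    floor(params$max_mismatch_frac * acc$overlap_len)))
  over <- nchar(acc$left_overhang) > 0 | nchar(acc$right_overhang) > 0
  expect_true(all(acc$overlap_len[over] >= params$min_edge_overlap))
  # anchored (banded-window) and exhaustive alignment agree within the band
  for (i in sample(which(pl$accepted), 10)) {
    expect_equal(pl$score[i], r_overlap_score(reads[i], substr(g, 1, 1500)))
  }
})

test_that("multi-contig assignment picks the best-scoring contig", {
  set.seed(35)
  c1 <- random_dna(300)
  c2 <- random_dna(300)
  asm <- as_assembly(c(a = c1, b = c2))
  p <- place_read(substr(c2, 51, 150), asm)
  expect_equal(p$contig_id, "b")
  expect_true(p$accepted)
  tsv <- tempfile(fileext = ".tsv")
  write_placements_tsv(map_pool(data.frame(id = "x", seq = substr(c1, 1, 80),
                                           qual = NA_character_,
                                           stringsAsFactors = FALSE), asm),
                       tsv)
  got <- read.delim(tsv)
  expect_equal(got$ref_start, 1L)   # reports are 1-based inclusive
})
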