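test_that("ancestor simulation honours composition, repeats and the seed", {
  spec <- genome_spec(10000, at_content = 0.55, rng_seed = 51)
  g <- simulate_ancestor(spec)
  expect_equal(nchar(unname(g)), 10000L)
  at <- mean(strsplit(unname(g), "")[[1]] %in% c("A", "T"))
  expect_lt(abs(at - 0.55), 0.02)
  expect_identical(g, simulate_ancestor(spec))   # determinism

  rspec <- genome_spec(10000, repeat_unit = 780, repeat_copies = 2,
                       rng_seed = 52)
  gr <- simulate_ancestor(rspec)
  expect_equal(nchar(unname(gr)), 10000L)
  # an exact 780 bp tandem duplication exists: some 780 bp window equals the
  # next 780 bp window
  s <- unname(gr)
  starts <- 1:(10000 - 1560 + 1)
  hit <- any(vapply(starts, function(i) {
    substr(s, i, i + 779) == substr(s, i + 780, i + 1559)
  }, TRUE))
  expect_true(hit)
  expect_error(genome_spec(2000, repeat_unit = 780, repeat_copies = 3),
               "repeat")
})

test_that("evolved genomes hit the target K2P divergence", {
  anc <- simulate_ancestor(genome_spec(16600, rng_seed = 53))
  expect_identical(unname(evolve_genome(anc, 0)), unname(anc))
  d1 <- evolve_genome(anc, 0.13, rng_seed = 54, name = "d1")
  expect_equal(nchar(unname(d1)), nchar(unname(anc)))
  expect_lt(abs(kimura2p(anc, d1) - 0.13), 0.02)
  # independent cross-check with ape's K80 distance
  m <- t(sapply(list(unname(anc), unname(d1)),
                function(s) strsplit(tolower(s), "")[[1]]))
  dd <- ape::dist.dna(ape::as.DNAbin(m), model = "K80")
  expect_lt(abs(as.numeric(dd) - kimura2p(anc, d1)), 1e-6)
  # distances are additive: two descendants at 0.13 sit ~0.26 apart
  d2 <- evolve_genome(anc, 0.13, rng_seed = 55, name = "d2")
  expect_true(kimura2p(d1, d2) > 0.24 && kimura2p(d1, d2) < 0.28)
})

test_that("simulated read pools have the stated geometry", {
  g <- evolve_genome(simulate_ancestor(genome_spec(16600, rng_seed = 56)), 0,
                     name = "gX")
  pool <- simulate_reads(g, sim_config(rng_seed = 57))   # paper defaults
  expect_equal(n_reads(pool), 6000L)
  expect_equal(nrow(pool$pairing), 3000L)
  expect_true(all(nchar(pool$records$seq) == 150L))
  expect_true(all(pool$provenance == "gX"))
  # ~54x coverage
  cov <- 6000 * 150 / 16600
  expect_lt(abs(cov - 54.2), 5.5)
  # error-free reads are exact substrings of the doubled circle or its rc
  doubled <- paste0(unname(g), unname(g))
  doubled_rc <- r_revcomp(doubled)
  some <- sample(6000, 120)
  expect_true(all(vapply(pool$records$seq[some], function(s) {
    grepl(s, doubled, fixed = TRUE) || grepl(s, doubled_rc, fixed = TRUE)
  }, TRUE)))
  # realised insert sizes: recover each pair's span on the circle
  ins <- vapply(sample(3000, 400), function(i) {
    f <- pool$records$seq[2 * i - 1]
    r <- r_revcomp(pool$records$seq[2 * i])
    fs <- regexpr(f, doubled, fixed = TRUE)
    rs <- regexpr(r, doubled, fixed = TRUE)
    if (fs < 0 || rs < 0) return(NA_real_)
    d <- (rs - fs) %% 16600
    d + 150
  }, 0)
  ins <- ins[!is.na(ins) & ins < 600]
  expect_lt(abs(mean(ins) - 300), 5)
  expect_lt(abs(sd(ins) - 50), 10)
  # coverage is approximately uniform on the circle (no position bias)
  pos <- vapply(sample(6000, 500), function(i) {
    p <- regexpr(pool$records$seq[i], doubled, fixed = TRUE)
    if (p < 0) p <- regexpr(r_revcomp(pool$records$seq[i]), doubled,
                            fixed = TRUE)
    ((p - 1) %% 16600) + 1
  }, 0)
  cs <- suppressWarnings(stats::chisq.test(table(cut(pos, 8))))
  expect_gt(cs$p.value, 1e-4)
})

test_that("linear sampling avoids the origin; pooling is additive", {
  g <- evolve_genome(simulate_ancestor(genome_spec(5000, rng_seed = 58)), 0,
                     name = "gl")
  pool <- simulate_reads(g, sim_config(n_reads = 400, linear = TRUE,
                                       rng_seed = 59))
  # under linear sampling every read is a substring of the LINEAR sequence
  lin <- unname(g)
  lin_rc <- r_revcomp(lin)
  expect_true(all(vapply(pool$records$seq, function(s) {
    grepl(s, lin, fixed = TRUE) || grepl(s, lin_rc, fixed = TRUE)
  }, TRUE)))

  g2 <- evolve_genome(g, 0.05, rng_seed = 60, name = "g2")
  p2 <- simulate_reads(g2, sim_config(n_reads = 400, rng_seed = 61))
  merged <- pool_readsets(list(pool, p2))
  expect_equal(n_reads(merged), 800L)
  expect_equal(nrow(merged$pairing), 400L)
  expect_setequal(unique(merged$provenance), c("gl", "g2"))
  expect_identical(pool_readsets(list(p2))$records, p2$records)
  expect_error(pool_readsets(list(pool, pool)), "collision")
})
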