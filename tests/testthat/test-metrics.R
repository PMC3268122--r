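test_that("complexity matches constructions and the brute-force oracle", {
  set.seed(201)
  # random sequence: no >= 20 bp self-repeat, w.h.p.
  g <- rand_dna(5000)
  expect_equal(complexity(g), 0)
  # S + S: every position lies inside a repeat copy
  s <- rand_dna(700)
  expect_equal(complexity(paste0(s, s)), 1)
  # two planted copies of one unit: complexity = 2 * unit / total
  gen <- generate_genome(20000, repeats = list(c(1000L, 2L)), seed = 202)
  expect_equal(complexity(gen$seq), 0.1, tolerance = 0.005)
  # oracle agreement on a small instance (the oracle is quadratic)
  small <- generate_genome(3000, repeats = list(c(150L, 2L)), seed = 205)
  expect_equal(complexity(small$seq), oracle_complexity(small$seq, 20))
  expect_equal(complexity(small$seq), 0.1, tolerance = 0.01)
  expect_error(complexity(""))
})

test_that("similarity is symmetric, 1 on identity, and oracle-exact", {
  set.seed(203)
  a <- rand_dna(800)
  expect_equal(similarity(a, a), 1)
  expect_lt(similarity(a, rand_dna(800)), 0.02)
  for (trial in 1:8) {
    pair <- make_related_pair(t_len = sample(100:250, 1))
    mm <- sample(c(10L, 15L), 1)
    expect_equal(similarity(pair$q, pair$t, mm),
                 oracle_similarity(pair$q, pair$t, mm))
    expect_equal(similarity(pair$q, pair$t, mm),
                 similarity(pair$t, pair$q, mm))
  }
  # similarity decreases with the substitution rate
  g <- rand_dna(4000)
  sims <- vapply(c(0.01, 0.05, 0.1), function(r)
    similarity(g, mutate_reference(g, sub_rate = r, seed = 204)$seq),
    numeric(1))
  expect_true(all(diff(sims) < 0))
})

test_that("n50 follows the genome-relative definition", {
  expect_equal(n50(7000, 7000), 7000L)
  expect_equal(n50(c(50, 40, 30), 120), 40L)  # running sums 50, 90 >= 60
  expect_equal(n50(10, 100), 0L)              # threshold unreachable
  set.seed(207)
  for (trial in 1:30) {
    lens <- sample(1:500, sample(1:12, 1), replace = TRUE)
    G <- sample(100:3000, 1)
    expect_equal(n50(lens, G), oracle_n50(lens, G))
    expect_lte(n50(lens, G), max(lens))
  }
})

test_that("bona fide classification separates substrings, mutants and chimeras", {
  set.seed(211)
  g <- rand_dna(50000)
  expect_true(classify_bona_fide(contig("c", substr(g, 5001, 7000)), g))
  # 1 substitution per 1000 bp: chains split but matched stays >= 95%
  mut <- strsplit(substr(g, 10001, 14000), "")[[1]]
  at <- seq(500, 3500, by = 1000)
  mut[at] <- vapply(mut[at], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  expect_true(classify_bona_fide(contig("m", paste(mut, collapse = "")), g))
  # chimera of two loci far apart: no chain covers 95%
  chim <- paste0(substr(g, 1001, 2500), substr(g, 40001, 41500))
  expect_false(classify_bona_fide(contig("x", chim), g))
})

test_that("accuracy is the proportion of bona fide contigs", {
  set.seed(213)
  g <- rand_dna(60000)
  good <- vapply(seq(1, 45001, by = 5000), function(s)
    substr(g, s, s + 1499), character(1))[1:9]
  chim <- paste0(substr(g, 2001, 2800), substr(g, 50001, 50800))
  a <- assembly("mix", sprintf("c%02d", 1:10), c(good, chim))
  expect_equal(accuracy(a, g), 0.9)
  expect_equal(accuracy(assembly("good", "c", good[1]), g), 1)
  expect_equal(accuracy(assembly("bad", "c", chim), g), 0)
  expect_error(accuracy(assembly("none"), g), "empty")
})

test_that("rank scores implement the 4-method weighting with shared ties", {
  base <- data.frame(dataset = "d1",
                     method = c("m1", "m2", "m3", "m4"),
                     avg_len = c(4, 3, 2, 1), n50 = c(4, 3, 2, 1),
                     longest = c(4, 3, 2, 1),
                     genome_fraction = c(4, 3, 2, 1))
  sc <- rank_scores(base)
  expect_equal(sc[["m1"]], 16)  # best in all 4 categories: 4 x weight 4
  expect_equal(sc[["m4"]], 4)   # worst in all 4: 4 x weight 1
  tied <- base
  tied$n50 <- 1
  sc2 <- rank_scores(tied)
  expect_equal(sc2[["m4"]], 3 * 1 + 2.5)  # full tie shares (4+3+2+1)/4
  expect_error(rank_scores(base[base$method != "m4", ]), "4 methods")
  # scores accumulate over datasets
  two <- rbind(base, within(base, dataset <- "d2"))
  expect_equal(rank_scores(two)[["m1"]], 32)
})

test_that("proportion_extended counts protrusion and shared best hits", {
  set.seed(217)
  g <- rand_dna(10000)
  # comparative contig strictly contains the de novo contig with 50 bp flanks
  den <- assembly("d", "d1", substr(g, 1051, 2050))
  comp <- assembly("c", "c1", substr(g, 1001, 2100))
  expect_equal(proportion_extended(den, comp), 1)
  # identical sets: nothing can be extended
  expect_equal(proportion_extended(den, den), 0)
  # two de novo contigs mapping to opposite ends of one long comparative
  # contig share a best hit: both count
  den2 <- assembly("d", c("d1", "d2"),
                   c(substr(g, 3001, 4000), substr(g, 5001, 6000)))
  comp2 <- assembly("c", "c1", substr(g, 3001, 6000))
  expect_equal(proportion_extended(den2, comp2), 1)
})

test_that("assembly_stats ties the pieces together", {
  set.seed(219)
  g <- rand_dna(20000)
  tiles <- tile_genome(g, mean_len = 2000L, overlap = 0L, seed = 220)
  st <- assembly_stats(tiles, g)
  expect_equal(st$total_len, sum(contig_lengths(tiles)))
  expect_equal(st$avg_len, st$total_len / st$n_contigs)
  expect_gte(st$longest, st$avg_len)
  expect_equal(st$accuracy, 1)
  expect_equal(st$genome_fraction, 1)
  expect_equal(st$n50, n50(contig_lengths(tiles), 20000))
})
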