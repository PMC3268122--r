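test_that("generate_genome plants exact non-overlapping repeats, reproducibly", {
  g1 <- generate_genome(30000, repeats = list(c(1500L, 2L)), seed = 5)
  g2 <- generate_genome(30000, repeats = list(c(1500L, 2L)), seed = 5)
  expect_identical(g1$seq, g2$seq)
  expect_equal(nchar(g1$seq), 30000L)
  expect_equal(nrow(g1$repeats), 2L)
  copies <- substring(g1$seq, g1$repeats$start, g1$repeats$end)
  expect_equal(copies[1], copies[2])
  expect_equal(complexity(g1$seq), 0.1, tolerance = 0.005)
  expect_equal(complexity(generate_genome(20000, seed = 6)$seq), 0)
  expect_error(generate_genome(1000, repeats = list(c(600L, 2L))),
               "exceed")
})

test_that("mutate_reference is the identity at zero rates and logs rearrangements", {
  g <- generate_genome(30000, seed = 7)$seq
  m0 <- mutate_reference(g, seed = 8)
  expect_identical(m0$seq, g)
  expect_equal(nrow(m0$log), 0L)
  m <- mutate_reference(g, n_rearrangements = 2L, seed = 9)
  expect_equal(nrow(m$log), 2L)
  expect_true(all(m$log$type %in% c("inversion", "translocation")))
  # rearrangements change the sequence but preserve exact-match content
  # (inverted/moved segments still match, on the other strand or diagonal),
  # so similarity stays 1; only point divergence lowers it
  expect_false(identical(m$seq, g))
  expect_equal(similarity(g, m$seq), 1, tolerance = 0.01)
  expect_lt(similarity(g, mutate_reference(g, sub_rate = 0.05,
                                           n_rearrangements = 2L,
                                           seed = 9)$seq), 1)
  expect_identical(mutate_reference(g, n_rearrangements = 2L, seed = 9)$seq,
                   m$seq)
})

test_that("calibrate_reference lands in the similarity band", {
  g <- generate_genome(40000, seed = 11)$seq
  ref <- calibrate_reference(g, band = c(0.80, 0.92), n_rearrangements = 2L,
                             seed = 12)
  expect_gte(ref$similarity, 0.80)
  expect_lte(ref$similarity, 0.92)
  expect_equal(similarity(g, ref$seq), ref$similarity)
})

test_that("simulate_reads follows the fragment-count formula and pair geometry", {
  set.seed(21)
  g <- rand_dna(15000)
  reads <- simulate_reads(g, sim_params(C = 60, L = 300, R = 75, seed = 22))
  # floor(G * C / (2R)) fragments; each yields two R bp reads, so total
  # bases = G * C and the fold coverage comes out exactly
  expect_equal(nrow(reads), 6000L)
  expect_equal(2 * nrow(reads) * 75 / 15000, 60)
  expect_true(all(nchar(reads$fwd) == 75L))
  expect_true(all(nchar(reads$rev) == 75L))
  expect_true(all(reads$frag_start >= 0 & reads$frag_start <= 15000 - 300))
  # without errors, fwd and rc(rev) reconstruct the fragment ends exactly
  idx <- sample.int(6000L, 50L)
  frags <- substring(g, reads$frag_start[idx] + 1, reads$frag_start[idx] + 300)
  expect_equal(reads$fwd[idx], substr(frags, 1, 75))
  expect_equal(reverse_complement(reads$rev[idx]), substr(frags, 226, 300))
  # coverage too small for a single pair
  tiny <- simulate_reads(g, sim_params(C = 0.005, L = 300, R = 75, seed = 23))
  expect_equal(nrow(tiny), 0L)
  expect_error(simulate_reads(rand_dna(200), sim_params()), "shorter")
  # bit-reproducible
  again <- simulate_reads(g, sim_params(C = 60, L = 300, R = 75, seed = 22))
  expect_identical(reads, again)
})

test_that("empirical depth matches the target coverage and starts look uniform", {
  set.seed(25)
  g <- rand_dna(20000)
  pr <- sim_params(C = 30, L = 300, R = 75, seed = 26)
  reads <- simulate_reads(g, pr)
  # mean per-base read depth over the genome: 2 * n * R / G
  expect_equal(2 * nrow(reads) * pr$R / nchar(g), pr$C, tolerance = 0.05)
  ks <- suppressWarnings(
    stats::ks.test(reads$frag_start, "punif", 0, nchar(g) - pr$L))
  expect_gt(ks$p.value, 1e-3)
})

test_that("write_fastq emits a well-formed forward-reverse pair", {
  set.seed(27)
  g <- rand_dna(3000)
  reads <- simulate_reads(g, sim_params(C = 2, seed = 28))
  pre <- file.path(withr::local_tempdir(), "sim")
  write_fastq(reads, pre)
  l1 <- readLines(paste0(pre, "_1.fastq"))
  l2 <- readLines(paste0(pre, "_2.fastq"))
  expect_equal(length(l1), 4L * nrow(reads))
  expect_equal(length(l2), 4L * nrow(reads))
  expect_true(all(startsWith(l1[seq(1, length(l1), 4)], "@")))
  expect_equal(l1[seq(2, length(l1), 4)], reads$fwd)
  expect_equal(nchar(l1[seq(4, length(l1), 4)]), nchar(reads$fwd))
})

test_that("fixture assemblies vote-ready geometry and independent chimeras", {
  g <- generate_genome(40000, seed = 31)
  asms <- make_fixture_assemblies(g$seq, 3, 1500L, chimera_rate = 0,
                                  avoid = g$repeats, seed = 32)
  expect_length(asms, 3L)
  for (a in asms) expect_true(all(a$contigs$truth == "bona_fide"))
  asms2 <- make_fixture_assemblies(g$seq, 3, 1500L, chimera_rate = 0.2,
                                   avoid = g$repeats, seed = 33)
  chims <- lapply(asms2, function(a)
    a$contigs$seq[a$contigs$truth == "chimeric"])
  expect_gt(length(unlist(chims)), 0L)
  # chimeras are never shared between assemblies
  expect_equal(anyDuplicated(unlist(chims)), 0L)
  # and every chimera really is non-colinear with the genome
  for (s in unlist(chims)) {
    expect_false(classify_bona_fide(contig("x", s), g$seq))
  }
  expect_error(make_fixture_assemblies(g$seq, 1), ">= 2")
})

test_that("fixture A-contigs plant reference-biased chimeras at divergent regions", {
  g <- generate_genome(50000, seed = 35)
  ref <- calibrate_reference(g$seq, n_rearrangements = 3L, seed = 36)
  ref$id <- "ref1"
  none <- make_fixture_acontigs(g$seq, list(ref), miss_rate = 0,
                                avoid = g$repeats, seed = 37)[[1]]
  expect_true(all(none$contigs$truth == "bona_fide"))
  all_of_them <- make_fixture_acontigs(g$seq, list(ref), miss_rate = 1,
                                       avoid = g$repeats, seed = 37)[[1]]
  n_chim <- sum(all_of_them$contigs$truth == "chimeric")
  expect_gte(n_chim, 1L)
  expect_lte(n_chim, 3L)
  vars <- attr(all_of_them, "variants")
  expect_equal(sum(!is.na(vars$causal)), n_chim)
  # chimeric contigs are non-colinear with the genome; genuine ones are exact
  for (i in seq_len(n_contigs(all_of_them))) {
    ct <- all_of_them$contigs[i, ]
    if (ct$truth == "chimeric") {
      expect_false(classify_bona_fide(contig(ct$id, ct$seq), g$seq))
    } else {
      expect_true(grepl(ct$seq, g$seq, fixed = TRUE))
    }
  }
})

test_that("the full fixture is deterministic per seed", {
  fx1 <- genome_fixture(seed = 41, genome_len = 3e4, n_refs = 2,
                        n_rearrangements = 2)
  fx2 <- genome_fixture(seed = 41, genome_len = 3e4, n_refs = 2,
                        n_rearrangements = 2)
  expect_identical(fx1$genome, fx2$genome)
  expect_identical(fx1$dbg$contigs, fx2$dbg$contigs)
  expect_identical(lapply(fx1$acontig_sets, function(a) a$contigs),
                   lapply(fx2$acontig_sets, function(a) a$contigs))
  for (r in fx1$references) {
    expect_gte(r$similarity, 0.80)
    expect_lte(r$similarity, 0.92)
  }
})
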