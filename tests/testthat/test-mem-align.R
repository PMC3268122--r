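test_that("find_mems handles the canonical small cases", {
  # identical hexamers: a single full-length forward match; the reverse
  # complement shares no 4-mer
  b <- find_mems("AAACCC", "AAACCC", 4)
  expect_equal(nrow(b), 1L)
  expect_equal(b$strand, "+")
  expect_equal(c(b$q_start, b$q_end, b$t_start, b$t_end), c(0L, 6L, 0L, 6L))

  # poly-T vs poly-A: only reverse-strand matches; the longest is the full
  # length-5 anti-diagonal (shifted anti-diagonals are boundary-maximal too)
  b <- find_mems("TTTTT", "AAAAA", 4)
  expect_true(all(b$strand == "-"))
  expect_equal(max(b$len), 5L)
  expect_equal(sum(b$len == 5L), 1L)
  expect_equal(nrow(b[b$strand == "+", ]), 0L)

  # two independent random sequences: no 20 bp match, w.h.p.
  set.seed(101)
  q <- rand_dna(200); t <- rand_dna(200)
  b <- find_mems(q, t, 20)
  expect_equal(nrow(b), nrow(oracle_mems(q, t, 20)))
  expect_equal(nrow(b), 0L)

  expect_error(find_mems("", "ACGT", 4))
})

test_that("find_mems agrees exactly with the brute-force oracle", {
  set.seed(23)
  for (trial in 1:40) {
    pair <- make_related_pair(t_len = sample(60:300, 1),
                              n_seg = sample(1:4, 1),
                              seg_len = sample(12:40, 1))
    mm <- sample(c(8L, 10L, 15L), 1)
    impl <- find_mems(pair$q, pair$t, mm)
    orc <- oracle_mems(pair$q, pair$t, mm)
    expect_equal(as_block_key(impl), as_block_key(orc))
  }
  # with N bases, which match nothing
  set.seed(29)
  for (trial in 1:10) {
    t <- rand_dna(150)
    q <- paste0(substr(t, 20, 80), "N", substr(t, 82, 140))
    impl <- find_mems(q, t, 10)
    orc <- oracle_mems(q, t, 10)
    expect_equal(as_block_key(impl), as_block_key(orc))
    expect_false(any(grepl("N", substring(q, impl$q_start + 1, impl$q_end))))
  }
})

test_that("find_mems blocks are the coordinate-transpose of the reversed comparison", {
  set.seed(31)
  for (trial in 1:10) {
    pair <- make_related_pair(t_len = 150)
    ab <- find_mems(pair$q, pair$t, 12)
    ba <- find_mems(pair$t, pair$q, 12)
    key_ab <- sort(paste(ab$q_start, ab$q_end, ab$t_start, ab$t_end, ab$strand))
    # "x matches rc(y)" is the same relation as "y matches rc(x)", so the
    # transpose is a plain coordinate swap on both strands
    key_ba <- sort(paste(ba$t_start, ba$t_end, ba$q_start, ba$q_end, ba$strand))
    expect_equal(key_ab, key_ba)
  }
})

test_that("chain_mems applies gap, cluster and trimming rules", {
  p <- align_params()
  one <- data.frame(q_idx = 1L, t_idx = 1L, q_start = 0L, q_end = 150L,
                    t_start = 10L, t_end = 160L, strand = "+", len = 150L,
                    q_len = 150L, t_len = 200L, q_id = "q", t_id = "t")
  ch <- chain_mems(one, p)
  expect_length(ch, 1L)
  expect_equal(ch[[1]]$matched, 150L)
  expect_equal(ch[[1]]$max_indel, 0L)

  # two blocks, query gap 10 and target gap 10: one chain, indel 0
  two <- rbind(one, within(one, {
    q_start <- 160L; q_end <- 310L; t_start <- 170L; t_end <- 320L
  }))
  two$q_len <- 310L; two$t_len <- 330L
  ch <- chain_mems(two, p)
  expect_length(ch, 1L)
  expect_equal(ch[[1]]$matched, 300L)
  expect_equal(ch[[1]]$max_indel, 0L)

  # target gap 600 > maxgap: two chains
  far <- rbind(one, within(one, {
    q_start <- 150L; q_end <- 300L; t_start <- 760L; t_end <- 910L
  }))
  far$q_len <- 300L; far$t_len <- 950L
  ch <- chain_mems(far, p)
  expect_length(ch, 2L)
  # and the asymmetric gap shows up as an indel when within maxgap
  near <- rbind(one, within(one, {
    q_start <- 150L; q_end <- 300L; t_start <- 360L; t_end <- 510L
  }))
  near$q_len <- 300L; near$t_len <- 550L
  ch <- chain_mems(near, p)
  expect_length(ch, 1L)
  expect_equal(ch[[1]]$max_indel, 200L)  # |query gap 0 - target gap 200|

  expect_length(chain_mems(one[0, ], p), 0L)
})

test_that("chain matched never exceeds input total and is 0-indel on identity", {
  set.seed(37)
  for (trial in 1:10) {
    s <- rand_dna(sample(150:400, 1))
    blocks <- find_mems(s, s, 15)
    for (ch in chain_mems(blocks, align_params(min_match = 15))) {
      expect_lte(ch$matched, sum(blocks$len))
    }
    bc <- best_chain(contig("a", s), contig("b", s),
                     align_params(min_match = 15))
    expect_equal(bc$matched, nchar(s))
    expect_equal(bc$max_indel, 0L)
  }
})

test_that("best_chain prefers the dominant alignment and returns NULL when nothing survives", {
  set.seed(41)
  t <- rand_dna(2000)
  # query = a 600 bp substring of the target, plus a spurious shared 20-mer
  q <- paste0(substr(t, 201, 800), substr(t, 1500, 1519))
  bc <- best_chain(contig("q", q), contig("t", t), align_params())
  expect_gte(bc$matched, 600L)
  expect_equal(bc$t_span[1], 200L)

  none <- best_chain(contig("q", rand_dna(300)), contig("t", t),
                     align_params())
  expect_null(none)
})

test_that("coverage unions intervals and stays within [0, 1]", {
  mk_chain <- function(ts, te) {
    structure(list(q_id = "q", t_id = "t", strand = "+", q_len = 100L,
                   t_len = 100L,
                   blocks = data.frame(q_start = ts, q_end = te,
                                       t_start = ts, t_end = te,
                                       len = te - ts),
                   matched = sum(te - ts), max_indel = 0L,
                   q_span = range(c(ts, te)), t_span = range(c(ts, te))),
              class = "mem_chain")
  }
  cp <- coverage(list(mk_chain(0L, 50L), mk_chain(25L, 75L)), 100L)
  expect_equal(cp$fraction, 0.75)
  expect_equal(nrow(cp$intervals), 1L)
  expect_equal(coverage(list(), 100L)$fraction, 0)
  expect_equal(coverage(list(mk_chain(0L, 100L)), 100L)$fraction, 1)
  # monotone under adding chains
  c1 <- coverage(list(mk_chain(0L, 30L)), 100L)$fraction
  c2 <- coverage(list(mk_chain(0L, 30L), mk_chain(60L, 80L)), 100L)$fraction
  expect_gte(c2, c1)
  expect_error(coverage(list(), 0L), "positive")
})

test_that("is_contained matches a direct substring-search oracle", {
  set.seed(43)
  b <- rand_dna(300)
  expect_true(is_contained(b, b))
  expect_true(is_contained(substr(b, 11, 60), b))
  expect_true(is_contained(reverse_complement(substr(b, 6, 50)), b))
  expect_false(is_contained(rand_dna(40), b))
  for (trial in 1:20) {
    hay <- rand_dna(150)
    needle <- if (trial %% 2 == 0) {
      s <- sample.int(100, 1)
      piece <- substr(hay, s, s + sample(10:40, 1))
      if (trial %% 4 == 0) reverse_complement(piece) else piece
    } else rand_dna(sample(10:40, 1))
    expect_equal(is_contained(needle, hay), oracle_contained(needle, hay))
  }
})

test_that("alignment reports use 1-based inclusive coordinates", {
  set.seed(47)
  t <- rand_dna(400)
  ch <- best_chain(contig("q", substr(t, 51, 250)), contig("t", t),
                   align_params())
  f <- withr::local_tempfile(fileext = ".tsv")
  write_alignment_report(list(ch), f)
  rep <- utils::read.delim(f)
  expect_equal(rep$t_start, 51L)
  expect_equal(rep$t_end, 250L)
  expect_equal(rep$q_start, 1L)
  expect_equal(rep$matched, 200L)
})
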