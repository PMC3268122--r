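#' Bona fide classification parameters
#'
#' A contig is bona fide when its best alignment chain against the truth
#' genome covers at least `min_cov` of the contig length in matched bases
#' with no within-chain indel larger than `max_indel`.
#'
#' @param min_cov Minimum matched fraction of the contig length.
#' @param max_indel Maximum within-chain indel, bp.
#' @param align [align_params()] used for the chains.
#' @return A list of class `bona_fide_params`.
#' @export
bona_fide_params <- function(min_cov = 0.95, max_indel = 50L,
                             align = align_params()) {
  if (min_cov <= 0 || min_cov > 1) stop("min_cov must be in (0, 1]")
  structure(list(min_cov = min_cov, max_indel = as.integer(max_indel),
                 align = align), class = "bona_fide_params")
}

.union_len <- function(starts, ends) {
  if (!length(starts)) return(0L)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start = starts + 1L,
                                                      end = ends))))
}

#' Repeat complexity of a genome
#'
#' Fraction of genome positions lying inside at least one non-identity
#' maximal exact self-match of length at least `min_repeat_len`, on either
#' strand; positions are counted once.
#'
#' @param genome DNA string.
#' @param min_repeat_len Minimum repeat (self-match) length, bp.
#' @return Real in `[0, 1]`.
#' @export
complexity <- function(genome, min_repeat_len = 20L) {
  genome <- toupper(genome)
  .check_seq(genome, "genome")
  if (nchar(genome) < min_repeat_len) stop("genome shorter than min_repeat_len")
  b <- .mems_raw(genome, genome, min_repeat_len, self_mode = TRUE)
  # both sides of each self-match lie on the same sequence
  .union_len(c(b$q_start, b$t_start), c(b$q_end, b$t_end)) / nchar(genome)
}

#' Similarity between two genomes
#'
#' Positions of each genome inside maximal exact matches (>= `min_match_len`,
#' both strands) against the other are unioned; the similarity is
#' `(covered_a + covered_b) / (len_a + len_b)`, so identical genomes score 1
#' and the measure is symmetric.
#'
#' @param a,b DNA strings.
#' @param min_match_len Minimum match length, bp.
#' @return Real in `[0, 1]`.
#' @export
similarity <- function(a, b, min_match_len = 20L) {
  a <- toupper(a); b <- toupper(b)
  .check_seq(a, "a"); .check_seq(b, "b")
  blocks <- .mems_raw(a, b, min_match_len)
  ca <- .union_len(blocks$q_start, blocks$q_end)
  cb <- .union_len(blocks$t_start, blocks$t_end)
  (ca + cb) / (nchar(a) + nchar(b))
}

#' Genome-relative N50
#'
#' After sorting contig lengths in descending order, the length of the first
#' contig at which the running sum reaches half the genome length; 0 when the
#' total never gets there.
#'
#' @param contig_lengths Integer vector of contig lengths.
#' @param genome_len Genome length used for simulation, bp (> 0).
#' @return Integer N50 (0 if unreachable).
#' @export
n50 <- function(contig_lengths, genome_len) {
  if (genome_len <= 0) stop("genome_len must be positive")
  if (!length(contig_lengths)) return(0L)
  s <- sort(as.integer(contig_lengths), decreasing = TRUE)
  hit <- which(cumsum(as.numeric(s)) >= genome_len / 2)
  if (!length(hit)) return(0L)
  s[hit[1]]
}

# Best chain of each assembly contig against the truth genome, computed in
# one batch scan.
.best_chains_vs_genome <- function(seqs, ids, truth_genome, align) {
  blocks <- .mems_raw(seqs, truth_genome, align$min_match)
  out <- vector("list", length(seqs))
  if (!nrow(blocks)) return(out)
  for (qi in unique(blocks$q_idx)) {
    qb <- blocks[blocks$q_idx == qi, , drop = FALSE]
    qb$q_id <- ids[qi]; qb$t_id <- "genome"
    out[qi] <- list(.pick_best_chain(chain_mems(qb, align)))
  }
  out
}

#' Classify a contig as bona fide against a truth genome
#'
#' @param c A `contig` (or DNA string).
#' @param truth_genome Truth genome DNA string.
#' @param params A [bona_fide_params()] object.
#' @return Logical flag.
#' @export
classify_bona_fide <- function(c, truth_genome, params = bona_fide_params()) {
  c <- .as_contig(c)
  ch <- best_chain(c, contig("genome", truth_genome), params$align)
  !is.null(ch) && ch$matched >= params$min_cov * nchar(c$seq) &&
    ch$max_indel <= params$max_indel
}

#' Accuracy of an assembly against a truth genome
#'
#' The proportion of bona fide contigs.
#'
#' @param assembly A non-empty `assembly`.
#' @param truth_genome Truth genome DNA string.
#' @param params A [bona_fide_params()] object.
#' @return Real in `[0, 1]`.
#' @export
accuracy <- function(assembly, truth_genome, params = bona_fide_params()) {
  if (n_contigs(assembly) == 0L) stop("accuracy of an empty assembly is undefined")
  mean(.bona_fide_flags(assembly, truth_genome, params))
}

.bona_fide_flags <- function(assembly, truth_genome, params = bona_fide_params()) {
  seqs <- assembly$contigs$seq
  chains <- .best_chains_vs_genome(seqs, assembly$contigs$id, truth_genome,
                                   params$align)
  vapply(seq_along(seqs), function(i) {
    ch <- chains[[i]]
    !is.null(ch) && ch$matched >= params$min_cov * nchar(seqs[i]) &&
      ch$max_indel <= params$max_indel
  }, logical(1))
}

#' Assembly summary statistics
#'
#' Total/average/longest contig length, contig count, genome-relative N50,
#' and — when a truth genome is supplied — accuracy and the fraction of
#' genome positions covered by bona fide contigs.
#'
#' @param assembly A non-empty `assembly`.
#' @param truth_genome Optional truth genome DNA string.
#' @param params A [bona_fide_params()] object.
#' @return One-row data frame.
#' @export
assembly_stats <- function(assembly, truth_genome = NULL,
                           params = bona_fide_params()) {
  if (n_contigs(assembly) == 0L) stop("empty assembly")
  lens <- contig_lengths(assembly)
  out <- data.frame(label = assembly$label,
                    n_contigs = length(lens),
                    total_len = sum(lens),
                    avg_len = sum(lens) / length(lens),
                    longest = max(lens),
                    n50 = NA_integer_,
                    accuracy = NA_real_,
                    genome_fraction = NA_real_)
  if (!is.null(truth_genome)) {
    out$n50 <- n50(lens, nchar(truth_genome))
    chains <- .best_chains_vs_genome(assembly$contigs$seq,
                                     assembly$contigs$id, truth_genome,
                                     params$align)
    flags <- vapply(seq_along(chains), function(i) {
      ch <- chains[[i]]
      !is.null(ch) && ch$matched >= params$min_cov * lens[i] &&
        ch$max_indel <= params$max_indel
    }, logical(1))
    out$accuracy <- mean(flags)
    bf <- chains[flags]
    starts <- unlist(lapply(bf, function(ch) ch$blocks$t_start))
    ends <- unlist(lapply(bf, function(ch) ch$blocks$t_end))
    out$genome_fraction <- .union_len(starts, ends) / nchar(truth_genome)
  }
  out
}

#' Weighted rank scores across four contiguity categories
#'
#' For each dataset and each of the four categories (average length, N50,
#' longest length, genome fraction), the four methods are ranked in
#' descending order of the category value; the best gets weight 4 and the
#' worst weight 1, with ties sharing the mean of their tied weights. A
#' method's score is the sum of its weights over all datasets and categories.
#'
#' @param metric_table Data frame with columns `dataset`, `method`,
#'   `avg_len`, `n50`, `longest`, `genome_fraction`; exactly 4 methods per
#'   dataset.
#' @return Named numeric vector of scores, one per method.
#' @export
rank_scores <- function(metric_table) {
  cats <- c("avg_len", "n50", "longest", "genome_fraction")
  stopifnot(all(c("dataset", "method", cats) %in% names(metric_table)))
  methods <- sort(unique(metric_table$method))
  if (length(methods) != 4L)
    stop("rank scoring is defined for exactly 4 methods")
  scores <- stats::setNames(numeric(length(methods)), methods)
  for (ds in unique(metric_table$dataset)) {
    sub <- metric_table[metric_table$dataset == ds, , drop = FALSE]
    if (nrow(sub) != 4L || anyDuplicated(sub$method))
      stop("each dataset needs one row per method")
    for (cat in cats) {
      w <- 5 - rank(-sub[[cat]], ties.method = "average")
      scores[sub$method] <- scores[sub$method] + w
    }
  }
  scores
}

#' Proportion of de novo contigs extendable by comparative contigs
#'
#' A de novo contig counts as extended when its best chain onto some
#' comparative contig leaves at least `min_ext` bp of the comparative contig
#' protruding beyond at least one of its ends, or when it shares its best-hit
#' comparative contig with another de novo contig (a merge opportunity).
#'
#' @param denovo,comparative Non-empty `assembly` objects.
#' @param align An [align_params()] object.
#' @param min_ext Minimum protrusion, bp.
#' @return Real in `[0, 1]`: the fraction of de novo contigs extended.
#' @export
proportion_extended <- function(denovo, comparative, align = align_params(),
                                min_ext = 10L) {
  if (n_contigs(denovo) == 0L || n_contigs(comparative) == 0L)
    stop("both assemblies must be non-empty")
  blocks <- .mems_raw(denovo$contigs$seq, comparative$contigs$seq,
                      align$min_match)
  nq <- n_contigs(denovo)
  best_t <- rep(NA_integer_, nq)
  prot <- logical(nq)
  if (nrow(blocks)) {
    for (qi in unique(blocks$q_idx)) {
      qb <- blocks[blocks$q_idx == qi, , drop = FALSE]
      chains <- list()
      for (ti in unique(qb$t_idx)) {
        tb <- qb[qb$t_idx == ti, , drop = FALSE]
        tb$q_id <- denovo$contigs$id[qi]
        tb$t_id <- comparative$contigs$id[ti]
        chains <- c(chains, chain_mems(tb, align))
      }
      ch <- .pick_best_chain(chains)
      if (is.null(ch)) next
      best_t[qi] <- match(ch$t_id, comparative$contigs$id)
      ql <- ch$q_len; tl <- ch$t_len
      if (ch$strand == "+") {
        left <- (ch$t_span[1]) - (ch$q_span[1])
        right <- (tl - ch$t_span[2]) - (ql - ch$q_span[2])
      } else {
        left <- (tl - ch$t_span[2]) - (ch$q_span[1])
        right <- (ch$t_span[1]) - (ql - ch$q_span[2])
      }
      prot[qi] <- left >= min_ext || right >= min_ext
    }
  }
  shared <- !is.na(best_t) & best_t %in% best_t[duplicated(best_t) & !is.na(best_t)]
  mean(prot | shared)
}
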