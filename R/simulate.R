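#' Read-simulation parameters
#'
#' Fold coverage `C`, fragment (insert) length `L` and read length `R` of a
#' forward-reverse paired-end library. Defaults are the standard short-read
#' simulation setting used throughout the package: C = 60, L = 300, R = 75.
#'
#' @param C Fold coverage (> 0).
#' @param L Fragment length, bp.
#' @param R Read length, bp (R <= L).
#' @param sub_error Per-base substitution error rate of reads, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(C = 60, L = 300L, R = 75L, sub_error = 0, seed = 1L) {
  L <- as.integer(L); R <- as.integer(R)
  if (C <= 0) stop("C must be positive")
  if (R > L) stop("R must be <= L")
  if (sub_error < 0 || sub_error >= 1) stop("sub_error must be in [0, 1)")
  structure(list(C = C, L = L, R = R, sub_error = sub_error,
                 seed = as.integer(seed)), class = "sim_params")
}

.rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# uniform integer in [lo, hi], safe for degenerate ranges
.runif_int <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

.mutate_subs <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(v)) < rate & v != "N")
  if (length(hit)) {
    repl <- vapply(v[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    v[hit] <- repl
  }
  paste(v, collapse = "")
}

#' Generate a random genome with planted repeats
#'
#' An i.i.d. uniform background with exact copies of random repeat units
#' planted at non-overlapping positions. The repeat annotation makes the
#' expected repeat complexity controllable: two planted copies of one 5 kb
#' unit in a 100 kb genome give complexity 0.1.
#'
#' @param length Genome length, bp.
#' @param repeats List of `c(unit_len, copies)` pairs.
#' @param seed Integer seed; output is deterministic per seed.
#' @return List with `seq` (DNA string) and `repeats` (data frame of planted
#'   copies, 1-based inclusive coordinates).
#' @export
generate_genome <- function(length, repeats = list(), seed = 1L) {
  length <- as.integer(length)
  total <- sum(vapply(repeats, function(r) as.numeric(r[1]) * r[2], numeric(1)))
  if (total > length) stop("planted repeats exceed genome length")
  withr::with_seed(as.integer(seed), {
    g <- .rand_dna(length)
    ann <- data.frame(unit = integer(), copy = integer(),
                      start = integer(), end = integer())
    taken <- IRanges::IRanges()
    for (u in seq_along(repeats)) {
      ulen <- as.integer(repeats[[u]][1]); copies <- as.integer(repeats[[u]][2])
      unit <- .rand_dna(ulen)
      for (cp in seq_len(copies)) {
        ok <- FALSE
        for (try in 1:1000) {
          s <- sample.int(length - ulen + 1L, 1L)
          cand <- IRanges::IRanges(start = s, end = s + ulen - 1L)
          if (!length(IRanges::findOverlaps(cand, taken))) {
            taken <- c(taken, cand)
            substr(g, s, s + ulen - 1L) <- unit
            ann <- rbind(ann, data.frame(unit = u, copy = cp, start = s,
                                         end = s + ulen - 1L))
            ok <- TRUE
            break
          }
        }
        if (!ok) stop("could not place repeat copies without overlap")
      }
    }
    list(seq = g, repeats = ann)
  })
}

#' Mutate a genome into a diverged reference
#'
#' Applies, in order: block rearrangements (inversions in place, or
#' translocations that move a segment to a distant position), then short
#' indels, then point substitutions. The variant log records each
#' rearrangement's anchor on the *target* genome coordinates (1-based
#' inclusive), which is what downstream fixture generation needs to plant
#' reference-biased misassemblies.
#'
#' @param genome Target genome DNA string.
#' @param sub_rate Per-base substitution rate in `[0, 1)`.
#' @param indel_rate Per-base indel initiation rate in `[0, 1)`.
#' @param indel_len Length range `c(min, max)` of each indel, bp.
#' @param n_rearrangements Number of block rearrangements.
#' @param rearr_len Length range of rearranged segments, bp.
#' @param anchor_range Optional `c(lo, hi)` restricting rearrangement anchors
#'   to a genome region (1-based); used to keep different references diverged
#'   in disjoint regions.
#' @param seed Integer seed.
#' @return List with `seq` (the reference), `log` (data frame: `type`,
#'   `t_start`, `t_end`, `src_start`, `src_end`) and the rates used.
#' @export
mutate_reference <- function(genome, sub_rate = 0, indel_rate = 0,
                             indel_len = c(1L, 10L), n_rearrangements = 0L,
                             rearr_len = c(1500L, 2500L),
                             anchor_range = NULL, seed = 1L) {
  if (sub_rate < 0 || sub_rate >= 1 || indel_rate < 0 || indel_rate >= 1)
    stop("rates must be in [0, 1)")
  G <- nchar(genome)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  withr::with_seed(as.integer(seed), {
    log <- data.frame(type = character(), t_start = integer(),
                      t_end = integer(), src_start = integer(),
                      src_end = integer())
    v <- strsplit(genome, "", fixed = TRUE)[[1]]
    if (n_rearrangements > 0L) {
      lo <- if (is.null(anchor_range)) 5000L else as.integer(anchor_range[1])
      hi <- if (is.null(anchor_range)) G - 5000L else as.integer(anchor_range[2])
      margin <- max(rearr_len) + 500L
      lo <- max(lo, margin); hi <- min(hi, G - margin)
      if (hi <= lo) stop("anchor range too small for rearrangements")
      anchors <- integer(0)
      for (i in seq_len(n_rearrangements)) {
        a <- NA_integer_
        for (try in 1:1000) {
          cand <- .runif_int(lo, hi)
          if (!length(anchors) || min(abs(anchors - cand)) > 2L * margin) {
            a <- cand
            break
          }
        }
        if (is.na(a))
          stop("could not place rearrangement anchors: the anchor range is ",
               "too small for ", n_rearrangements, " rearrangements kept ",
               2L * margin, " bp apart; enlarge the genome/range or reduce ",
               "n_rearrangements")
        anchors <- c(anchors, a)
        seg <- .runif_int(rearr_len[1], rearr_len[2])
        type <- sample(c("inversion", "translocation"), 1L)
        if (type == "inversion") {
          log <- rbind(log, data.frame(type = type, t_start = a,
                                       t_end = a + seg - 1L,
                                       src_start = NA_integer_,
                                       src_end = NA_integer_))
        } else {
          u <- NA_integer_
          for (try in 1:1000) {
            cand <- .runif_int(1L, G - seg)
            if (abs(cand - a) > 4L * margin &&
                (length(anchors) < 2L ||
                   min(abs(anchors[-length(anchors)] - cand)) > 2L * margin)) {
              u <- cand
              break
            }
          }
          if (is.na(u)) stop("could not place translocation source")
          log <- rbind(log, data.frame(type = type, t_start = a, t_end = a,
                                       src_start = u, src_end = u + seg - 1L))
        }
      }
      # inversions first (no coordinate shifts), then translocation edits
      # from highest coordinate down so lower coordinates stay valid;
      # rearranged loci are pairwise separated, so edits never interact
      inv <- log[log$type == "inversion", , drop = FALSE]
      for (i in seq_len(nrow(inv)))
        v[inv$t_start[i]:inv$t_end[i]] <-
          unname(comp[rev(v[inv$t_start[i]:inv$t_end[i]])])
      tr <- log[log$type == "translocation", , drop = FALSE]
      if (nrow(tr)) {
        edits <- rbind(
          data.frame(pos = tr$t_start, op = "ins",
                     src_s = tr$src_start, src_e = tr$src_end),
          data.frame(pos = tr$src_start, op = "del",
                     src_s = tr$src_start, src_e = tr$src_end))
        edits <- edits[order(-edits$pos), , drop = FALSE]
        gv <- strsplit(genome, "", fixed = TRUE)[[1]]
        for (i in seq_len(nrow(edits))) {
          if (edits$op[i] == "del") {
            v <- v[-(edits$pos[i]:(edits$pos[i] +
                                     (edits$src_e[i] - edits$src_s[i])))]
          } else {
            v <- append(v, gv[edits$src_s[i]:edits$src_e[i]],
                        after = edits$pos[i] - 1L)
          }
        }
      }
    }
    if (indel_rate > 0) {
      pos <- which(stats::runif(length(v)) < indel_rate)
      for (p in rev(pos)) {
        l <- .runif_int(indel_len[1], indel_len[2])
        if (stats::runif(1) < 0.5) {
          v <- v[-(p:min(p + l - 1L, length(v)))]
        } else {
          v <- append(v, sample(c("A", "C", "G", "T"), l, replace = TRUE),
                      after = p)
        }
      }
    }
    if (sub_rate > 0) {
      hit <- which(stats::runif(length(v)) < sub_rate & v != "N")
      if (length(hit))
        v[hit] <- vapply(v[hit], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    }
    list(seq = paste(v, collapse = ""), log = log, sub_rate = sub_rate,
         indel_rate = indel_rate)
  })
}

#' Calibrate a reference into a similarity band
#'
#' Bisects the substitution rate until [similarity()] between the target
#' genome and the mutated reference lands inside `band` (rearrangements are
#' included at every step, so the achieved similarity is measured on the
#' final reference).
#'
#' @param genome Target genome DNA string.
#' @param band Similarity band `c(lo, hi)`.
#' @param n_rearrangements Rearrangements passed to [mutate_reference()].
#' @param anchor_range Anchor restriction passed to [mutate_reference()].
#' @param seed Integer seed.
#' @param max_iter Maximum bisection steps.
#' @return As [mutate_reference()], plus `similarity` and `sub_rate`.
#' @export
calibrate_reference <- function(genome, band = c(0.80, 0.92),
                                n_rearrangements = 3L, anchor_range = NULL,
                                seed = 1L, max_iter = 12L) {
  lo <- 0.005; hi <- 0.12
  target <- mean(band)
  best <- NULL
  for (i in seq_len(max_iter)) {
    rate <- (lo + hi) / 2
    ref <- mutate_reference(genome, sub_rate = rate,
                            n_rearrangements = n_rearrangements,
                            anchor_range = anchor_range, seed = seed)
    sim <- similarity(genome, ref$seq)
    best <- c(ref, list(similarity = sim))
    if (sim >= band[1] && sim <= band[2]) break
    if (sim > target) lo <- rate else hi <- rate
  }
  if (best$similarity < band[1] || best$similarity > band[2])
    warning("calibration did not land in the similarity band (got ",
            round(best$similarity, 3), ")")
  best
}

#' Simulate forward-reverse paired-end reads
#'
#' Exactly `floor(G * C / (2 * R))` fragments of length `L` with start
#' positions i.i.d. uniform on the genome; each yields a forward read from
#' the fragment's 5' end and the reverse complement of its 3' end.
#'
#' @param genome DNA string with `nchar(genome) >= L`.
#' @param params A [sim_params()] object.
#' @return Data frame with `id`, `fwd`, `rev`, `frag_start` (0-based).
#' @export
simulate_reads <- function(genome, params = sim_params()) {
  G <- nchar(genome)
  if (G < params$L) stop("genome shorter than the fragment length")
  n <- floor(G * params$C / (2 * params$R))
  withr::with_seed(params$seed, {
    if (n < 1) {
      return(data.frame(id = character(), fwd = character(),
                        rev = character(), frag_start = integer()))
    }
    starts <- sample.int(G - params$L + 1L, n, replace = TRUE) - 1L
    frags <- substring(genome, starts + 1L, starts + params$L)
    fwd <- substr(frags, 1L, params$R)
    rev <- reverse_complement(substr(frags, params$L - params$R + 1L,
                                     params$L))
    if (params$sub_error > 0) {
      fwd <- vapply(fwd, .mutate_subs, character(1), rate = params$sub_error,
                    USE.NAMES = FALSE)
      rev <- vapply(rev, .mutate_subs, character(1), rate = params$sub_error,
                    USE.NAMES = FALSE)
    }
    data.frame(id = sprintf("read_%06d", seq_len(n)), fwd = fwd, rev = rev,
               frag_start = starts)
  })
}

#' Write simulated read pairs as a FASTQ pair
#'
#' Reads carry a constant quality character; no quality model is simulated.
#'
#' @param reads Data frame from [simulate_reads()].
#' @param prefix Output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @return The two paths, invisibly.
#' @export
write_fastq <- function(reads, prefix) {
  p1 <- paste0(prefix, "_1.fastq"); p2 <- paste0(prefix, "_2.fastq")
  q <- function(s) strrep("I", nchar(s))
  writeLines(rbind(paste0("@", reads$id, "/1"), reads$fwd, "+",
                   q(reads$fwd)), p1)
  writeLines(rbind(paste0("@", reads$id, "/2"), reads$rev, "+",
                   q(reads$rev)), p2)
  invisible(c(p1, p2))
}

# Breakpoints for a tiling of [1, G], spaced around mean_len, snapped outside
# `avoid` intervals (1-based inclusive data frame with start/end) so contig
# ends never carry repeat sequence.
.tiling_cuts <- function(G, mean_len, avoid = NULL) {
  cuts <- integer(0)
  p <- 0L
  while (TRUE) {
    step <- round(stats::runif(1, 0.75, 1.25) * mean_len)
    p <- p + as.integer(step)
    if (p >= G) break
    if (!is.null(avoid) && nrow(avoid)) {
      repeat {
        inside <- which(avoid$start - 50L <= p & p <= avoid$end + 50L)
        if (!length(inside)) break
        p <- avoid$end[inside[1]] + 51L
      }
      if (p >= G) break
    }
    cuts <- c(cuts, p)
  }
  cuts
}

#' Tile a genome into bona fide contigs
#'
#' Cuts the genome into consecutive substring contigs of approximately
#' `mean_len`, each extended `overlap` bp into its right neighbour so that
#' adjacent contigs share an exact overlap. Breakpoints are kept away from
#' the intervals in `avoid` (e.g. planted repeats). All contigs are labeled
#' bona fide.
#'
#' @param genome DNA string.
#' @param mean_len Mean contig length, bp.
#' @param overlap Overlap into the right neighbour, bp.
#' @param avoid Optional data frame of 1-based intervals to keep free of
#'   breakpoints.
#' @param label Assembly label.
#' @param seed Integer seed.
#' @return An `assembly` of bona fide tiling contigs, in genome order.
#' @export
tile_genome <- function(genome, mean_len = 800L, overlap = 100L,
                        avoid = NULL, label = "tiling", seed = 1L) {
  G <- nchar(genome)
  withr::with_seed(as.integer(seed), {
    cuts <- .tiling_cuts(G, mean_len, avoid)
    starts <- c(1L, cuts + 1L)
    ends <- pmin(c(cuts, G) + overlap, G)
    ids <- sprintf("%s_c%04d", label, seq_along(starts))
    assembly(label, ids, substring(genome, starts, ends),
             truth = rep("bona_fide", length(starts)))
  })
}

#' Emulate several de novo assemblies with planted chimeras
#'
#' A shared fine breakpoint grid is drawn once; each assembly independently
#' coarsens it (keeping each interior cut with probability 1/2), so its
#' contigs are concatenations of consecutive grid segments and contigs of one
#' assembly are frequently exact substrings of another's — the situation
#' consensus voting exploits. With probability `chimera_rate` a contig is
#' replaced by a chimeric join of its own left half with a locus at least
#' `10 * mean_contig_len` away; chimeras are drawn independently per
#' assembly, so no chimera is ever shared between two assemblies.
#'
#' @param genome DNA string.
#' @param n_assemblies Number of emulated assemblies (>= 2).
#' @param mean_contig_len Mean contig length, bp.
#' @param chimera_rate Per-contig chimera probability.
#' @param avoid Optional repeat intervals kept free of breakpoints.
#' @param seed Integer seed.
#' @return List of `assembly` objects with truth labels.
#' @export
make_fixture_assemblies <- function(genome, n_assemblies = 3L,
                                    mean_contig_len = 1500L,
                                    chimera_rate = 0, avoid = NULL,
                                    seed = 1L) {
  G <- nchar(genome)
  if (n_assemblies < 2L) stop("consensus selection needs >= 2 assemblies")
  if (mean_contig_len >= G) stop("mean_contig_len must be below genome length")
  withr::with_seed(as.integer(seed), {
    grid <- .tiling_cuts(G, max(250L, round(mean_contig_len / 2)), avoid)
    lapply(seq_len(n_assemblies), function(ai) {
      keep <- stats::runif(length(grid)) < 0.5
      cuts <- grid[keep]
      starts <- c(1L, cuts + 1L)
      ends <- c(cuts, G)
      seqs <- substring(genome, starts, ends)
      truth <- rep("bona_fide", length(seqs))
      for (i in seq_along(seqs)) {
        if (stats::runif(1) >= chimera_rate) next
        len <- nchar(seqs[i])
        half <- max(1L, len %/% 2L)
        min_d <- 10L * mean_contig_len
        lo_ok <- starts[i] - min_d - half > 1L
        hi_ok <- ends[i] + min_d + half < G
        if (!lo_ok && !hi_ok) next
        side <- if (lo_ok && hi_ok) sample(c(-1L, 1L), 1L)
                else if (lo_ok) -1L else 1L
        far <- if (side < 0)
          .runif_int(1L, starts[i] - min_d - half)
        else
          .runif_int(ends[i] + min_d, G - half)
        seqs[i] <- paste0(substr(seqs[i], 1L, half),
                          substr(genome, far, far + half - 1L))
        truth[i] <- "chimeric"
      }
      lab <- paste0("asm", ai)
      assembly(lab, sprintf("%s_c%04d", lab, seq_along(seqs)), seqs,
               truth = truth)
    })
  })
}

#' Emulate comparative assemblies with reference-biased misassemblies
#'
#' Per reference, the target genome is tiled into bona fide substring
#' contigs. For each logged rearrangement of that reference, with
#' probability `miss_rate` the contig overlapping the anchor is replaced by
#' a chimera that carries the reference's structure there: for an inversion,
#' the reverse complement of the segment; for a translocation, the distant
#' source segment inserted at the anchor. The structural middle additionally
#' carries point substitutions at the reference's divergence rate, and each
#' flank is capped at 1.4 times the middle length so the divergent part is a
#' substantial fraction of the chimera.
#'
#' @param genome Target genome DNA string.
#' @param references List of reference objects from [mutate_reference()] /
#'   [calibrate_reference()], each with an `id` element added.
#' @param miss_rate Probability that a divergent region produces a
#'   misassembled contig.
#' @param mean_contig_len Mean A-contig length, bp.
#' @param avoid Optional repeat intervals kept free of breakpoints.
#' @param seed Integer seed.
#' @return List of `assembly` objects (one per reference) with truth labels;
#'   each carries a `variants` attribute linking chimeric contigs to their
#'   causal rearrangement.
#' @export
make_fixture_acontigs <- function(genome, references, miss_rate = 1,
                                  mean_contig_len = 8000L, avoid = NULL,
                                  seed = 1L) {
  if (!length(references)) stop("need at least one reference")
  G <- nchar(genome)
  withr::with_seed(as.integer(seed), {
    lapply(seq_along(references), function(ri) {
      ref <- references[[ri]]
      rid <- ref$id %||% paste0("ref", ri)
      cuts <- .tiling_cuts(G, mean_contig_len, avoid)
      starts <- c(1L, cuts + 1L)
      ends <- c(cuts, G)
      seqs <- substring(genome, starts, ends)
      truth <- rep("bona_fide", length(seqs))
      causal <- rep(NA_character_, length(seqs))
      log <- ref$log
      if (!is.null(log) && nrow(log)) for (v in seq_len(nrow(log))) {
        if (stats::runif(1) >= miss_rate) next
        a_s <- log$t_start[v]; a_e <- log$t_end[v]
        ci <- which(starts <= a_s & ends >= a_e)
        if (!length(ci)) next
        ci <- ci[1]
        middle <- if (log$type[v] == "inversion")
          reverse_complement(substr(genome, a_s, a_e))
        else
          substr(genome, log$src_start[v], log$src_end[v])
        middle <- .mutate_subs(middle, ref$sub_rate %||% 0)
        mlen <- nchar(middle)
        flank <- round(1.4 * mlen)
        fl_s <- max(starts[ci], a_s - flank)
        fr_e <- min(ends[ci], a_e + flank)
        left <- if (a_s > fl_s) substr(genome, fl_s, a_s - 1L) else ""
        right <- if (log$type[v] == "inversion") {
          if (fr_e > a_e) substr(genome, a_e + 1L, fr_e) else ""
        } else {
          if (fr_e >= a_s) substr(genome, a_s, fr_e) else ""
        }
        seqs[ci] <- paste0(left, middle, right)
        truth[ci] <- "chimeric"
        causal[ci] <- paste0(log$type[v], "@", a_s)
      }
      a <- assembly(rid, sprintf("%s_c%04d", rid, seq_along(seqs)), seqs,
                    truth = truth)
      attr(a, "variants") <- data.frame(id = a$contigs$id, causal = causal)
      a
    })
  })
}

#' Build one complete synthetic validation fixture
#'
#' The package's standard study condition: a 100 kb genome with planted
#' repeats (complexity above 6e-3), three references calibrated into the
#' 0.80-0.92 similarity band and diverged in disjoint regions, a bona fide
#' DBG tiling, and per-reference A-contig sets with reference-biased
#' misassemblies planted at every divergent region.
#'
#' @param seed Integer seed; every randomized part derives from it.
#' @param genome_len Genome length, bp.
#' @param n_refs Number of reference genomes.
#' @param n_rearrangements Divergent regions per reference.
#' @param similarity_band Target similarity band for references.
#' @param dbg_mean_len,dbg_overlap DBG tiling geometry, bp.
#' @param acontig_mean_len Mean A-contig length, bp.
#' @param miss_rate Chimera probability per divergent region.
#' @return List with `genome`, `repeats`, `references`, `dbg`,
#'   `acontig_sets`.
#' @export
genome_fixture <- function(seed = 1L, genome_len = 1e5, n_refs = 3L,
                           n_rearrangements = 3L,
                           similarity_band = c(0.80, 0.92),
                           dbg_mean_len = 800L, dbg_overlap = 100L,
                           acontig_mean_len = 8000L, miss_rate = 1) {
  seed <- as.integer(seed)
  gen <- generate_genome(genome_len, repeats = list(c(400L, 2L)), seed = seed)
  zones <- round(seq(0.05, 0.95, length.out = n_refs + 1L) * genome_len)
  references <- lapply(seq_len(n_refs), function(k) {
    ref <- calibrate_reference(gen$seq, band = similarity_band,
                               n_rearrangements = n_rearrangements,
                               anchor_range = c(zones[k], zones[k + 1L]),
                               seed = seed + 7919L * k)
    ref$id <- paste0("ref", k)
    ref
  })
  dbg <- tile_genome(gen$seq, mean_len = dbg_mean_len, overlap = dbg_overlap,
                     avoid = gen$repeats, label = "dbg", seed = seed + 101L)
  acontig_sets <- make_fixture_acontigs(gen$seq, references,
                                        miss_rate = miss_rate,
                                        mean_contig_len = acontig_mean_len,
                                        avoid = gen$repeats,
                                        seed = seed + 211L)
  list(genome = gen$seq, repeats = gen$repeats, references = references,
       dbg = dbg, acontig_sets = acontig_sets)
}
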