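#' Alignment parameters
#'
#' Settings for maximal-exact-match (MEM) seeding and colinear chaining.
#' `maxgap` bounds the gap allowed between adjacent chained matches on either
#' sequence; `mincluster` is the minimum total matched length a chain must
#' reach to be kept; `min_match` is the minimum MEM seed length. Defaults
#' mirror the stringent settings typical of whole-genome exact-match aligners
#' (maxgap 500, mincluster 100) with a 20 bp seed.
#'
#' @param min_match Minimum MEM length, bp.
#' @param maxgap Maximum gap between adjacent chained matches, bp.
#' @param mincluster Minimum matched bp per chain.
#' @return A list of class `align_params`.
#' @export
align_params <- function(min_match = 20L, maxgap = 500L, mincluster = 100L) {
  min_match <- as.integer(min_match)
  maxgap <- as.integer(maxgap)
  mincluster <- as.integer(mincluster)
  if (min_match < 1L || maxgap < 1L || mincluster < 1L)
    stop("alignment parameters must be positive")
  if (mincluster < min_match) stop("mincluster must be >= min_match")
  structure(list(min_match = min_match, maxgap = maxgap,
                 mincluster = mincluster), class = "align_params")
}

# Raw MEM scan over character vectors of sequences; adds sequence lengths.
.mems_raw <- function(qseqs, tseqs, min_match, self_mode = FALSE) {
  b <- .mem_scan_cpp(as.character(qseqs), as.character(tseqs),
                     as.integer(min_match), isTRUE(self_mode))
  b$q_len <- nchar(qseqs)[b$q_idx]
  b$t_len <- nchar(tseqs)[b$t_idx]
  b
}

#' Find maximal exact matches between two sequences
#'
#' Every maximal exact match of length at least `min_match`, on both strands.
#' The target is always reported forward; `strand` describes the query.
#' Coordinates are 0-based half-open. When query and target are the same
#' sequence, the trivial identity diagonal is excluded. `N` matches nothing,
#' including another `N`, so no match covers an `N`.
#'
#' @param query,target DNA strings.
#' @param min_match Minimum match length, bp.
#' @param q_id,t_id Ids recorded in the result.
#' @param self Set `TRUE` when the query *is* the target sequence (a
#'   self-comparison, as in repeat scanning): the trivial identity diagonal
#'   is then excluded. Two distinct but equal contigs are not a
#'   self-comparison; their full-length match is reported.
#' @return A data frame of match blocks sorted by `(t_start, q_start, strand)`
#'   with columns `q_id`, `t_id`, `q_start`, `q_end`, `t_start`, `t_end`,
#'   `strand`, `len`, `q_len`, `t_len`.
#' @export
find_mems <- function(query, target, min_match = 20L,
                      q_id = "query", t_id = "target", self = FALSE) {
  query <- toupper(query); target <- toupper(target)
  .check_seq(query, "query"); .check_seq(target, "target")
  if (self && !identical(query, target))
    stop("self = TRUE requires query and target to be the same sequence")
  b <- .mems_raw(query, target, min_match, self_mode = self)
  b$q_id <- rep(q_id, nrow(b))
  b$t_id <- rep(t_id, nrow(b))
  b <- b[order(b$t_start, b$q_start, b$strand), , drop = FALSE]
  rownames(b) <- NULL
  b[, c("q_id", "t_id", "q_start", "q_end", "t_start", "t_end",
        "strand", "len", "q_len", "t_len")]
}

# Chain one strand group by sparse dynamic programming; score = matched bp.
# Blocks overlapping on either coordinate may still be chained: the later
# block is trimmed by the overlap, which preserves exactness because an exact
# match shortened from its start on both coordinates stays exact. Chains are
# extracted greedily best-first, each block used at most once.
.chain_strand <- function(b, params) {
  minus <- b$strand[1] == "-"
  qlen <- b$q_len[1]
  if (minus) {
    qs <- qlen - b$q_end; qe <- qlen - b$q_start
  } else {
    qs <- b$q_start; qe <- b$q_end
  }
  o <- order(b$t_start, qs)
  b <- b[o, , drop = FALSE]; qs <- qs[o]; qe <- qe[o]
  if (nrow(b) > 2000L) {  # guard against pathological repeat blowups
    keep <- order(-b$len)[seq_len(2000L)]
    keep <- sort(keep)
    b <- b[keep, , drop = FALSE]; qs <- qs[keep]; qe <- qe[keep]
  }
  n <- nrow(b)
  ts <- b$t_start; te <- b$t_end; len <- b$len
  score <- as.numeric(len)
  prev <- integer(n)
  mg <- params$maxgap
  for (i in seq_len(n)) {
    if (i == 1L) next
    j <- seq_len(i - 1L)
    tg <- ts[i] - te[j]
    qg <- qs[i] - qe[j]
    ov <- pmax(0L, -tg, -qg)
    ok <- tg <= mg & qg <= mg & te[i] > te[j] & qe[i] > qe[j] &
      ov < len[i] & tg + ov <= mg & qg + ov <= mg
    if (!any(ok)) next
    cand <- ifelse(ok, score[j] + len[i] - ov, -Inf)
    bj <- which.max(cand)
    if (cand[bj] > score[i]) { score[i] <- cand[bj]; prev[i] <- bj }
  }
  # extract chains best-first from the single DP pass; a chain whose path
  # touches an already-used block is skipped (its blocks stay available to
  # later, lower-scoring chains only via their own paths)
  chains <- list()
  used <- logical(n)
  for (endp in order(-score)) {
    if (score[endp] < params$mincluster) break
    path <- integer(0); cur <- endp; clean <- TRUE
    while (cur != 0L) {
      if (used[cur]) { clean <- FALSE; break }
      path <- c(cur, path)
      cur <- prev[cur]
    }
    if (!clean) next
    used[path] <- TRUE
    chains[[length(chains) + 1L]] <-
      .build_chain(b[path, , drop = FALSE], qs[path], qe[path], minus, qlen)
  }
  chains
}

.build_chain <- function(b, qs, qe, minus, qlen) {
  n <- nrow(b)
  ts <- b$t_start; te <- b$t_end; len <- b$len
  max_indel <- 0L
  if (n > 1L) {
    for (i in 2:n) {
      tg <- ts[i] - te[i - 1L]
      qg <- qs[i] - qe[i - 1L]
      max_indel <- max(max_indel, abs(qg - tg))
      ov <- max(0L, -tg, -qg)
      if (ov > 0L) {  # trim the later block's start on both coordinates
        ts[i] <- ts[i] + ov
        qs[i] <- qs[i] + ov
        len[i] <- len[i] - ov
      }
    }
  }
  if (minus) {
    oq_start <- qlen - qe; oq_end <- qlen - qs
  } else {
    oq_start <- qs; oq_end <- qe
  }
  structure(list(
    q_id = b$q_id[1] %||% NA_character_,
    t_id = b$t_id[1] %||% NA_character_,
    strand = if (minus) "-" else "+",
    q_len = qlen, t_len = b$t_len[1],
    blocks = data.frame(q_start = oq_start, q_end = oq_end,
                        t_start = ts, t_end = te, len = len),
    matched = sum(len),
    max_indel = as.integer(max_indel),
    q_span = c(min(oq_start), max(oq_end)),
    t_span = c(min(ts), max(te))
  ), class = "mem_chain")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mem_chain <- function(x, ...) {
  cat("<mem_chain ", x$q_id, " vs ", x$t_id, " (", x$strand, "): matched ",
      x$matched, " bp in ", nrow(x$blocks), " blocks, max_indel ",
      x$max_indel, ">\n", sep = "")
  invisible(x)
}

#' Chain match blocks into colinear alignments
#'
#' Partitions compatible same-strand blocks into maximal-score colinear
#' chains (score = matched bp) by sparse dynamic programming. Adjacent gaps
#' larger than `maxgap` on either sequence break chains; chains whose total
#' matched length is below `mincluster` are dropped. Overlapping blocks are
#' resolved by trimming the later block.
#'
#' @param blocks A block data frame from [find_mems()] (one query/target
#'   pair).
#' @param params An [align_params()] object.
#' @return A list of `mem_chain` objects sorted by decreasing matched bp.
#' @export
chain_mems <- function(blocks, params = align_params()) {
  if (is.null(blocks) || nrow(blocks) == 0L) return(list())
  if (length(unique(blocks$q_id)) > 1L || length(unique(blocks$t_id)) > 1L)
    stop("chain_mems expects blocks of a single query/target pair")
  chains <- list()
  for (s in unique(blocks$strand)) {
    chains <- c(chains, .chain_strand(blocks[blocks$strand == s, , drop = FALSE],
                                      params))
  }
  chains[order(-vapply(chains, function(ch) ch$matched, numeric(1)),
               vapply(chains, function(ch) ch$max_indel, numeric(1)))]
}

# Order chains by: matched desc, max_indel asc, t_len desc, t_id asc.
.pick_best_chain <- function(chains) {
  if (!length(chains)) return(NULL)
  o <- order(-vapply(chains, function(ch) ch$matched, numeric(1)),
             vapply(chains, function(ch) ch$max_indel, numeric(1)),
             -vapply(chains, function(ch) ch$t_len, numeric(1)),
             vapply(chains, function(ch) as.character(ch$t_id), character(1)))
  chains[[o[1]]]
}

.as_contig <- function(x, id = "seq") {
  if (inherits(x, "contig")) return(x)
  if (is.character(x) && length(x) == 1L) return(contig(id, x))
  stop("expected a contig or a single DNA string")
}

#' Best alignment chain between two contigs
#'
#' The chain with maximal matched bp over both strands; ties broken by
#' smaller `max_indel`. Returns `NULL` if no chain reaches `mincluster`.
#'
#' @param query,target `contig` objects (or bare DNA strings).
#' @param params An [align_params()] object.
#' @return A `mem_chain` or `NULL`.
#' @export
best_chain <- function(query, target, params = align_params()) {
  q <- .as_contig(query, "query"); t <- .as_contig(target, "target")
  blocks <- find_mems(q$seq, t$seq, params$min_match, q$id, t$id)
  .pick_best_chain(chain_mems(blocks, params))
}

#' Coverage profile of a target by alignment chains
#'
#' Union of all chain block target-intervals, merged into disjoint sorted
#' intervals, with the covered fraction of the target.
#'
#' @param chains List of `mem_chain` objects sharing a target.
#' @param t_len Target length, bp (> 0).
#' @param t_id Target id recorded in the profile.
#' @return A list of class `coverage_profile` with `t_id`, `t_len`,
#'   `intervals` (0-based half-open data frame) and `fraction`.
#' @export
coverage <- function(chains, t_len, t_id = NULL) {
  t_len <- as.integer(t_len)
  if (is.na(t_len) || t_len <= 0L) stop("t_len must be positive")
  if (length(chains)) {
    tids <- unique(vapply(chains, function(ch) as.character(ch$t_id),
                          character(1)))
    if (length(tids) > 1L) stop("chains cover different targets")
    if (is.null(t_id)) t_id <- tids
  }
  starts <- unlist(lapply(chains, function(ch) ch$blocks$t_start))
  ends <- unlist(lapply(chains, function(ch) ch$blocks$t_end))
  if (length(starts)) {
    ir <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
    intervals <- data.frame(start = IRanges::start(ir) - 1L,
                            end = IRanges::end(ir))
    covered <- sum(IRanges::width(ir))
  } else {
    intervals <- data.frame(start = integer(), end = integer())
    covered <- 0L
  }
  structure(list(t_id = t_id %||% NA_character_, t_len = t_len,
                 intervals = intervals,
                 fraction = covered / t_len),
            class = "coverage_profile")
}

#' Exact containment test between two contigs
#'
#' `TRUE` iff the sequence of `a` occurs as an exact substring of the
#' sequence of `b` or of its reverse complement. Exactness keeps consensus
#' voting byte-deterministic; an optional mismatch-tolerant mode accepts
#' containment when the best alignment chain of `a` against `b` covers `a`
#' end to end with identity at least `1 - tol`.
#'
#' @param a,b `contig` objects (or bare DNA strings).
#' @param tol Mismatch tolerance in `[0, 1)`; `0` (default) is the exact test.
#' @param params [align_params()] used only in the tolerant mode.
#' @return Logical flag.
#' @export
is_contained <- function(a, b, tol = 0, params = align_params()) {
  a <- .as_contig(a, "a"); b <- .as_contig(b, "b")
  if (tol <= 0) {
    if (grepl("N", a$seq, fixed = TRUE)) return(FALSE)  # N matches nothing
    return(grepl(a$seq, b$seq, fixed = TRUE) ||
             grepl(a$seq, reverse_complement(b$seq), fixed = TRUE))
  }
  ch <- best_chain(a, b, params)
  if (is.null(ch)) return(FALSE)
  la <- nchar(a$seq)
  ch$matched >= (1 - tol) * la &&
    ch$q_span[1] <= tol * la && ch$q_span[2] >= (1 - tol) * la
}

#' Write a TSV alignment report
#'
#' One row per chain with 1-based inclusive coordinates, for compatibility
#' with common alignment-report conventions.
#'
#' @param chains List of `mem_chain` objects.
#' @param path Output path.
#' @param t_cov Optional named numeric of coverage fractions per target id.
#' @return `path`, invisibly.
#' @export
write_alignment_report <- function(chains, path, t_cov = NULL) {
  rows <- lapply(chains, function(ch) {
    data.frame(t_id = ch$t_id, q_id = ch$q_id,
               t_start = ch$t_span[1] + 1L, t_end = ch$t_span[2],
               q_start = ch$q_span[1] + 1L, q_end = ch$q_span[2],
               strand = ch$strand, matched = ch$matched,
               max_indel = ch$max_indel,
               t_cov_fraction = if (!is.null(t_cov)) t_cov[[as.character(ch$t_id)]] else NA_real_)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(t_id = character(), q_id = character(), t_start = integer(),
               t_end = integer(), q_start = integer(), q_end = integer(),
               strand = character(), matched = integer(),
               max_indel = integer(), t_cov_fraction = numeric())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
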