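#' Merge parameters
#'
#' Settings for the greedy exact-overlap merger that assembles the mixture
#' of DBG contigs and reliable A-contigs into the hybrid assembly. A dovetail
#' overlap joins a suffix of one contig to a prefix of (possibly the reverse
#' complement of) another, allowing at most `max_end_trim` bp of unaligned
#' overhang at the joined ends.
#'
#' @param min_overlap Minimum overlap length, bp.
#' @param min_overlap_ident Minimum overlap identity (matched / overlap
#'   span); 1 gives exact-overlap mode.
#' @param max_end_trim Maximum unaligned overhang at a joined end, bp.
#' @param align [align_params()] used for overlap detection.
#' @return A list of class `merge_params`.
#' @export
merge_params <- function(min_overlap = 30L, min_overlap_ident = 0.94,
                         max_end_trim = 20L, align = align_params()) {
  min_overlap <- as.integer(min_overlap)
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  if (min_overlap_ident <= 0 || min_overlap_ident > 1)
    stop("min_overlap_ident must be in (0, 1]")
  align$mincluster <- min(align$mincluster, min_overlap)
  structure(list(min_overlap = min_overlap,
                 min_overlap_ident = min_overlap_ident,
                 max_end_trim = as.integer(max_end_trim), align = align),
            class = "merge_params")
}

# Dovetail edges from the chains of one ordered contig pair (q = a, t = b).
# Ends are "L"/"R" in each contig's forward frame; intervals are the overlap
# region in each contig's forward frame, 0-based half-open.
.edges_from_chain <- function(ch, params) {
  trim <- params$max_end_trim
  qs <- ch$q_span[1]; qe <- ch$q_span[2]
  ts <- ch$t_span[1]; te <- ch$t_span[2]
  La <- ch$q_len; Lb <- ch$t_len
  span <- max(qe - qs, te - ts)
  ident <- ch$matched / span
  if (span < params$min_overlap || ident < params$min_overlap_ident)
    return(NULL)
  if (ch$max_indel > trim) return(NULL)
  mk <- function(ea, eb) {
    data.frame(a_id = ch$q_id, b_id = ch$t_id, a_end = ea, b_end = eb,
               strand = ch$strand, length = span, identity = ident,
               a_start = qs, a_stop = qe, b_start = ts, b_stop = te)
  }
  out <- NULL
  if (ch$strand == "+") {
    if (La - qe <= trim && ts <= trim) out <- rbind(out, mk("R", "L"))
    if (Lb - te <= trim && qs <= trim) out <- rbind(out, mk("L", "R"))
  } else {
    if (La - qe <= trim && Lb - te <= trim) out <- rbind(out, mk("R", "R"))
    if (qs <= trim && ts <= trim) out <- rbind(out, mk("L", "L"))
  }
  out
}

#' Find pairwise overlaps among contigs
#'
#' All dovetail and containment overlaps meeting the thresholds, both
#' strands, detected from exact-match chains anchored at sequence ends.
#' The result is symmetric: `overlap(a, b)` implies the mirrored record.
#'
#' @param contigs An `assembly` (or a data frame with `id`/`seq`).
#' @param params A [merge_params()] object.
#' @return Data frame with `a_id`, `b_id`, `type` (dovetail/containment),
#'   `strand`, `length`, `identity` plus internal splice coordinates for
#'   dovetails.
#' @export
find_overlaps <- function(contigs, params = merge_params()) {
  df <- if (inherits(contigs, "assembly")) contigs$contigs else contigs
  if (nrow(df) < 1L) stop("need at least one contig")
  empty <- data.frame(a_id = character(), b_id = character(),
                      type = character(), a_end = character(),
                      b_end = character(), strand = character(),
                      length = integer(), identity = numeric(),
                      a_start = integer(), a_stop = integer(),
                      b_start = integer(), b_stop = integer())
  if (nrow(df) == 1L) return(empty)
  edges <- list()
  # containments (exact, either strand)
  rc <- reverse_complement(df$seq)
  for (i in seq_len(nrow(df))) for (j in seq_len(nrow(df))) {
    if (i == j) next
    if (nchar(df$seq[i]) > nchar(df$seq[j])) next
    hasN <- grepl("N", df$seq[i], fixed = TRUE)
    if (hasN) next
    fwd <- grepl(df$seq[i], df$seq[j], fixed = TRUE)
    rev <- !fwd && grepl(df$seq[i], rc[j], fixed = TRUE)
    if (fwd || rev) {
      edges[[length(edges) + 1L]] <- data.frame(
        a_id = df$id[i], b_id = df$id[j], type = "containment",
        a_end = NA_character_, b_end = NA_character_,
        strand = if (fwd) "+" else "-",
        length = nchar(df$seq[i]), identity = 1,
        a_start = NA_integer_, a_stop = NA_integer_,
        b_start = NA_integer_, b_stop = NA_integer_)
    }
  }
  blocks <- .mems_raw(df$seq, df$seq, params$align$min_match, self_mode = TRUE)
  blocks <- blocks[blocks$q_idx < blocks$t_idx, , drop = FALSE]
  if (nrow(blocks)) {
    key <- paste(blocks$q_idx, blocks$t_idx)
    for (k in unique(key)) {
      kb <- blocks[key == k, , drop = FALSE]
      kb$q_id <- df$id[kb$q_idx[1]]
      kb$t_id <- df$id[kb$t_idx[1]]
      for (ch in chain_mems(kb, params$align)) {
        e <- .edges_from_chain(ch, params)
        if (!is.null(e)) edges[[length(edges) + 1L]] <- cbind(
          data.frame(type = "dovetail"), e)
      }
    }
  }
  if (!length(edges)) return(empty)
  out <- do.call(rbind, lapply(edges, function(e)
    e[, c("a_id", "b_id", "type", "a_end", "b_end", "strand", "length",
          "identity", "a_start", "a_stop", "b_start", "b_stop")]))
  # keep the best record per (pair, end combination)
  out <- out[order(-out$length, -out$identity), , drop = FALSE]
  out <- out[!duplicated(paste(out$a_id, out$b_id, out$type, out$a_end,
                               out$b_end)), , drop = FALSE]
  # mirrored records for symmetry
  mir <- out
  mir$a_id <- out$b_id; mir$b_id <- out$a_id
  mir$a_end <- out$b_end; mir$b_end <- out$a_end
  mir$a_start <- out$b_start; mir$a_stop <- out$b_stop
  mir$b_start <- out$a_start; mir$b_stop <- out$a_stop
  mir$type <- ifelse(out$type == "containment", "contains", out$type)
  res <- rbind(out, mir)
  res <- res[res$type != "contains", , drop = FALSE]
  res <- res[order(res$a_id, res$b_id, res$type), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.oriented_interval <- function(s, e, len, ori) {
  if (ori == "+") c(s, e) else c(len - e, len - s)
}

#' Merge DBG contigs and reliable A-contigs into a hybrid assembly
#'
#' Greedy overlap layout: exact containments are absorbed first; dovetail
#' overlaps are then merged longest-first (ties by higher identity, then id
#' pair), with each contig end used at most once and no cycles. Where the
#' two sides of an overlap disagree, the DBG contig's bases are kept (the
#' consensus set is the high-accuracy one). Every input contig ends up
#' contained in exactly one output contig.
#'
#' @param dbg DBG `assembly` (its contigs get base-call priority).
#' @param reliable_a Reliable A-contig `assembly` (may be empty).
#' @param params A [merge_params()] object.
#' @return An `assembly` labeled `"hybrid"`, sorted by descending length,
#'   with a `joins` attribute describing every dovetail join made (left id,
#'   right id, strand, overlap length, identity, and whether the join is
#'   supported by a DBG contig on either side).
#' @export
merge_assembly <- function(dbg, reliable_a = NULL, params = merge_params()) {
  pieces <- dbg$contigs
  pieces$is_dbg <- rep(TRUE, nrow(pieces))
  if (!is.null(reliable_a) && n_contigs(reliable_a) > 0L) {
    rel <- reliable_a$contigs
    rel$is_dbg <- FALSE
    if (any(rel$id %in% pieces$id)) rel$id <- paste0("A:", rel$id)
    pieces <- rbind(pieces, rel)
  }
  if (nrow(pieces) == 0L) stop("no input contigs to merge")
  pieces <- pieces[order(-nchar(pieces$seq), !pieces$is_dbg, pieces$id), ,
                   drop = FALSE]
  # absorb exact containments (either strand)
  kept <- remove_redundant(pieces)
  joins <- data.frame(left_id = character(), right_id = character(),
                      strand = character(), length = integer(),
                      identity = numeric(), dbg_supported = logical())
  if (nrow(kept) > 1L) {
    ov <- find_overlaps(kept, params)
    ov <- ov[ov$type == "dovetail", , drop = FALSE]
    if (nrow(ov)) {
      # each unordered (contig-end, contig-end) pair once
      side_a <- paste(ov$a_id, ov$a_end)
      side_b <- paste(ov$b_id, ov$b_end)
      key <- ifelse(side_a < side_b,
                    paste(side_a, side_b, ov$strand),
                    paste(side_b, side_a, ov$strand))
      ov <- ov[!duplicated(key), , drop = FALSE]
      ov <- ov[order(-ov$length, -ov$identity, ov$a_id, ov$b_id), ,
               drop = FALSE]
    }
  } else {
    ov <- NULL
  }
  n <- nrow(kept)
  idx <- stats::setNames(seq_len(n), kept$id)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  end_edge <- matrix(NA_integer_, nrow = n, ncol = 2,
                     dimnames = list(NULL, c("L", "R")))
  accepted <- list()
  if (!is.null(ov) && nrow(ov)) {
    for (r in seq_len(nrow(ov))) {
      a <- idx[[ov$a_id[r]]]; b <- idx[[ov$b_id[r]]]
      ea <- ov$a_end[r]; eb <- ov$b_end[r]
      if (!is.na(end_edge[a, ea]) || !is.na(end_edge[b, eb])) next
      ra <- find(a); rb <- find(b)
      if (ra == rb) next
      parent[ra] <- rb
      eid <- length(accepted) + 1L
      accepted[[eid]] <- ov[r, , drop = FALSE]
      end_edge[a, ea] <- eid
      end_edge[b, eb] <- eid
    }
  }
  # walk each component as a path, splicing sequences
  visited <- logical(n)
  out_ids <- character(); out_seqs <- character(); members <- list()
  hseq <- kept$seq
  hlen <- nchar(hseq)
  hid <- kept$id
  hdbg <- kept$is_dbg
  get_edge <- function(node, end) {
    e <- end_edge[node, end]
    if (is.na(e)) NULL else accepted[[e]]
  }
  for (start in seq_len(n)) {
    if (visited[start]) next
    degL <- !is.na(end_edge[start, "L"]); degR <- !is.na(end_edge[start, "R"])
    if (degL && degR) next  # interior node; reach it from a path end
    visited[start] <- TRUE
    if (!degL && !degR) {
      out_ids <- c(out_ids, hid[start]); out_seqs <- c(out_seqs, hseq[start])
      members[[length(members) + 1L]] <- hid[start]
      next
    }
    ori <- if (degR) "+" else "-"
    cur <- start
    out <- if (ori == "+") hseq[cur] else reverse_complement(hseq[cur])
    mem <- hid[cur]
    prev_edge_id <- NA_integer_
    repeat {
      exit_end <- if (ori == "+") "R" else "L"
      eid <- end_edge[cur, exit_end]
      if (is.na(eid) || (!is.na(prev_edge_id) && eid == prev_edge_id)) break
      e <- accepted[[eid]]
      if (e$a_id == hid[cur]) {
        nid <- e$b_id; n_end <- e$b_end
        p_int <- c(e$a_start, e$a_stop); n_int <- c(e$b_start, e$b_stop)
      } else {
        nid <- e$a_id; n_end <- e$a_end
        p_int <- c(e$b_start, e$b_stop); n_int <- c(e$a_start, e$a_stop)
      }
      nxt <- idx[[nid]]
      n_ori <- if (n_end == "L") "+" else "-"
      pI <- .oriented_interval(p_int[1], p_int[2], hlen[cur], ori)
      nI <- .oriented_interval(n_int[1], n_int[2], hlen[nxt], n_ori)
      sN <- if (n_ori == "+") hseq[nxt] else reverse_complement(hseq[nxt])
      # overlap bases come from the DBG side where only one side is DBG
      if (hdbg[nxt] && !hdbg[cur]) {
        cut_at <- pI[1]; from <- nI[1]
      } else {
        cut_at <- pI[2]; from <- nI[2]
      }
      keep_len <- nchar(out) - (hlen[cur] - cut_at)
      if (keep_len < 0L) break  # defensive: degenerate overlap geometry
      out <- paste0(substr(out, 1L, keep_len),
                    substr(sN, from + 1L, hlen[nxt]))
      joins <- rbind(joins, data.frame(
        left_id = hid[cur], right_id = hid[nxt],
        strand = e$strand, length = e$length, identity = e$identity,
        dbg_supported = hdbg[cur] || hdbg[nxt]))
      visited[nxt] <- TRUE
      mem <- c(mem, hid[nxt])
      prev_edge_id <- eid
      cur <- nxt
      ori <- n_ori
    }
    out_ids <- c(out_ids, paste0("hybrid_", length(out_ids) + 1L))
    out_seqs <- c(out_seqs, out)
    members[[length(members) + 1L]] <- mem
  }
  merged <- data.frame(id = out_ids, seq = out_seqs)
  # a merge can newly contain a previously unmergeable contig; absorb again
  merged <- remove_redundant(merged)
  res <- sort_assembly(assembly("hybrid", merged$id, merged$seq))
  attr(res, "joins") <- joins
  attr(res, "members") <- members
  res
}
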