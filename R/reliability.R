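#' Reliability-filter parameters
#'
#' An A-contig (comparative-assembly contig) is reliable when (1) no
#' alignment of an assigned DBG contig onto it shows an indel larger than
#' `max_indel`, and (2) the fraction of its length covered by its assigned
#' DBG contigs reaches the threshold `tau` (default 0.8). A-contigs shorter
#' than `min_len` are dropped before evaluation.
#'
#' @param tau Coverage threshold in `(0, 1]`.
#' @param max_indel Maximum tolerated within-chain indel, bp. The size that
#'   separates real structural disagreement from chaining noise; 50 bp at the
#'   default `maxgap`.
#' @param min_len Minimum A-contig length, bp.
#' @param align [align_params()] for DBG-to-A-contig alignment.
#' @return A list of class `reliability_params`.
#' @export
reliability_params <- function(tau = 0.8, max_indel = 50L, min_len = 500L,
                               align = align_params()) {
  if (tau <= 0 || tau > 1) stop("tau must be in (0, 1]")
  max_indel <- as.integer(max_indel)
  if (max_indel < 0L) stop("max_indel must be >= 0")
  structure(list(tau = tau, max_indel = max_indel,
                 min_len = as.integer(min_len), align = align),
            class = "reliability_params")
}

#' Assign each DBG contig to its best-matching A-contig
#'
#' Every DBG contig with at least one surviving chain is assigned to exactly
#' one A-contig: the best chain over all A-contigs and both strands (ties by
#' smaller max indel, larger target length, lexicographic target id). DBG
#' contigs without a chain reaching `mincluster` are omitted. Best-hit
#' assignment is what lets a bona fide A-contig outcompete a mis-assembled
#' copy of the same region built against another reference.
#'
#' @param dbg,acontigs Non-empty `assembly` objects.
#' @param align An [align_params()] object.
#' @return Named list (by DBG contig id) of lists with `a_id` and `chain`.
#' @export
assign_dbg_to_acontigs <- function(dbg, acontigs, align = align_params()) {
  if (n_contigs(dbg) == 0L || n_contigs(acontigs) == 0L)
    stop("both assemblies must be non-empty")
  blocks <- .mems_raw(dbg$contigs$seq, acontigs$contigs$seq, align$min_match)
  out <- list()
  if (!nrow(blocks)) return(out)
  for (qi in unique(blocks$q_idx)) {
    qb <- blocks[blocks$q_idx == qi, , drop = FALSE]
    chains <- list()
    for (ti in unique(qb$t_idx)) {
      tb <- qb[qb$t_idx == ti, , drop = FALSE]
      tb$q_id <- dbg$contigs$id[qi]
      tb$t_id <- acontigs$contigs$id[ti]
      chains <- c(chains, chain_mems(tb, align))
    }
    ch <- .pick_best_chain(chains)
    if (is.null(ch)) next
    out[[dbg$contigs$id[qi]]] <- list(a_id = ch$t_id, chain = ch)
  }
  out
}

#' Evaluate one A-contig against its assigned DBG chains
#'
#' Coverage is computed from the assigned chains only. The verdict reason
#' records the first failing criterion in the order: too short, indel, low
#' coverage.
#'
#' @param a A `contig`.
#' @param assigned_chains List of `mem_chain` objects targeting `a`.
#' @param params A [reliability_params()] object.
#' @return One-row data frame: `a_id`, `length`, `coverage`,
#'   `n_assigned_dbg`, `worst_indel`, `reliable`, `reason`.
#' @export
evaluate_acontig <- function(a, assigned_chains, params = reliability_params()) {
  a <- .as_contig(a)
  len <- nchar(a$seq)
  cov <- coverage(assigned_chains, len, t_id = a$id)$fraction
  worst <- if (length(assigned_chains))
    max(vapply(assigned_chains, function(ch) ch$max_indel, numeric(1))) else 0L
  reason <- "ok"
  if (len < params$min_len) reason <- "too_short"
  else if (worst > params$max_indel) reason <- "indel"
  else if (cov < params$tau) reason <- "low_coverage"
  data.frame(a_id = a$id, length = len, coverage = cov,
             n_assigned_dbg = length(assigned_chains),
             worst_indel = as.integer(worst),
             reliable = reason == "ok", reason = reason)
}

#' Select reliable A-contigs using DBG contigs
#'
#' A-contig sets (one per reference genome) are pooled, so each DBG contig
#' supports only its single best A-contig across all references; A-contigs
#' meeting both reliability criteria are returned.
#'
#' @param acontig_sets List of `assembly` objects, one per reference.
#' @param dbg The DBG `assembly` (may be empty: then every A-contig fails
#'   with coverage 0).
#' @param params A [reliability_params()] object.
#' @param per_reference If `TRUE`, run assignment within each reference's set
#'   separately instead of on the pool (for comparison only).
#' @return List with `reliable` (an `assembly` labeled `"reliable_A"`) and
#'   `verdicts` (a data frame over all input A-contigs, with `source`).
#' @export
select_reliable_acontigs <- function(acontig_sets, dbg,
                                     params = reliability_params(),
                                     per_reference = FALSE) {
  if (!length(acontig_sets)) stop("need at least one A-contig set")
  pool <- do.call(rbind, lapply(acontig_sets, function(a) a$contigs))
  if (anyDuplicated(pool$id))
    pool$id <- paste(pool$source, pool$id, sep = ":")
  long <- nchar(pool$seq) >= params$min_len
  assigned <- list()
  if (n_contigs(dbg) > 0L && any(long)) {
    eval_sets <- if (per_reference)
      split(pool[long, , drop = FALSE], pool$source[long])
    else list(pool[long, , drop = FALSE])
    for (sub in eval_sets) {
      am <- assign_dbg_to_acontigs(
        dbg, structure(list(label = "A", contigs = sub), class = "assembly"),
        params$align)
      assigned <- c(assigned, am)
    }
  }
  by_a <- split(lapply(assigned, `[[`, "chain"),
                vapply(assigned, `[[`, character(1), "a_id"))
  verdicts <- do.call(rbind, lapply(seq_len(nrow(pool)), function(i) {
    v <- evaluate_acontig(
      contig(pool$id[i], pool$seq[i], pool$source[i], pool$truth[i]),
      by_a[[pool$id[i]]] %||% list(), params)
    v$source <- pool$source[i]
    v
  }))
  rownames(verdicts) <- NULL
  ok <- pool[verdicts$reliable, , drop = FALSE]
  rel <- assembly("reliable_A", ok$id, ok$seq, source = ok$source,
                  truth = ok$truth)
  list(reliable = sort_assembly(rel), verdicts = verdicts)
}
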