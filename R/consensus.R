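#' Consensus-selection parameters
#'
#' A de novo contig is kept only when at least `min_support` of the input
#' assemblies contain it (exactly, or as an exact substring on either
#' strand); the contig's own assembly counts. Contigs shorter than `min_len`
#' are never candidates.
#'
#' @param min_support Minimum number of supporting assemblies (>= 2).
#' @param min_len Minimum candidate length, bp.
#' @return A list of class `consensus_params`.
#' @export
consensus_params <- function(min_support = 2L, min_len = 500L) {
  min_support <- as.integer(min_support); min_len <- as.integer(min_len)
  if (min_support < 2L) stop("min_support must be >= 2")
  if (min_len < 1L) stop("min_len must be >= 1")
  structure(list(min_support = min_support, min_len = min_len),
            class = "consensus_params")
}

# One searchable haystack per assembly: contigs and their reverse complements
# joined with '#' (never part of the alphabet, so matches cannot span it).
.containment_haystack <- function(a) {
  paste(c(a$contigs$seq, reverse_complement(a$contigs$seq)), collapse = "#")
}

.contained_in_haystack <- function(seq, haystack) {
  !grepl("N", seq, fixed = TRUE) && grepl(seq, haystack, fixed = TRUE)
}

#' Count assemblies supporting a contig
#'
#' The number of distinct assemblies containing at least one contig in which
#' `c` is exactly contained (either strand). The contig's own assembly counts
#' because a contig is contained in itself.
#'
#' @param c A `contig`.
#' @param assemblies List of `assembly` objects.
#' @return Integer support count.
#' @export
support_count <- function(c, assemblies) {
  c <- .as_contig(c)
  hay <- vapply(assemblies, .containment_haystack, character(1))
  sum(vapply(hay, function(h) .contained_in_haystack(c$seq, h), logical(1)))
}

#' Remove containment-redundant contigs
#'
#' Processes contigs in descending length (ties by id) and drops every contig
#' exactly contained, on either strand, in an already-kept contig. Among
#' mutually identical contigs the lexicographically smallest id survives.
#'
#' @param contigs A data frame with `id` and `seq` columns (plus any others),
#'   or an `assembly`.
#' @return The input rows that were kept, in processing order.
#' @export
remove_redundant <- function(contigs) {
  df <- if (inherits(contigs, "assembly")) contigs$contigs else contigs
  if (nrow(df) == 0L) return(df)
  df <- df[order(-nchar(df$seq), df$id), , drop = FALSE]
  keep <- logical(nrow(df))
  kept_seq <- character(0)
  kept_rc <- character(0)
  for (i in seq_len(nrow(df))) {
    s <- df$seq[i]
    hay <- paste(c(kept_seq, kept_rc), collapse = "#")
    if (length(kept_seq) && .contained_in_haystack(s, hay)) next
    keep[i] <- TRUE
    kept_seq <- c(kept_seq, s)
    kept_rc <- c(kept_rc, reverse_complement(s))
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select consensus (DBG) contigs from multiple de novo assemblies
#'
#' The first pipeline stage: a contig is chosen only when it is identical to
#' or an exact substring of contigs from at least `min_support` of the de
#' novo assemblies (its own included). Candidates shorter than `min_len` are
#' discarded before voting, and the selected set is made
#' containment-non-redundant.
#'
#' @param assemblies List of at least two `assembly` objects over the same
#'   read set.
#' @param params A [consensus_params()] object.
#' @return An `assembly` labeled `"DBG"`, sorted by descending length, with a
#'   `support` attribute: a data frame reporting id, length, source, support
#'   count and kept flag for every candidate.
#' @export
select_dbg_contigs <- function(assemblies, params = consensus_params()) {
  if (length(assemblies) < 2L) stop("need at least 2 de novo assemblies")
  hay <- vapply(assemblies, .containment_haystack, character(1))
  cand <- do.call(rbind, lapply(assemblies, function(a) a$contigs))
  cand <- cand[nchar(cand$seq) >= params$min_len, , drop = FALSE]
  support <- vapply(cand$seq, function(s) {
    sum(vapply(hay, function(h) .contained_in_haystack(s, h), logical(1)))
  }, integer(1), USE.NAMES = FALSE)
  kept <- support >= params$min_support
  sel <- cand[kept, , drop = FALSE]
  # ids may clash across assemblies; qualify with the source label
  if (anyDuplicated(sel$id)) sel$id <- paste(sel$source, sel$id, sep = ":")
  sel <- remove_redundant(sel)
  report <- data.frame(id = cand$id, length = nchar(cand$seq),
                       source = cand$source, support = support,
                       kept = kept & (cand$seq %in% sel$seq |
                                        reverse_complement(cand$seq) %in% sel$seq))
  out <- assembly("DBG", sel$id, sel$seq, source = sel$source,
                  truth = sel$truth)
  out <- sort_assembly(out)
  attr(out, "support") <- report
  out
}
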