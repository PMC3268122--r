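#' @useDynLib hybridasm, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
TRUTH_LEVELS <- c("bona_fide", "chimeric", "unknown")

.check_seq <- function(seq, what = "sequence") {
  if (!is.character(seq) || anyNA(seq)) stop(what, " must be a character vector without NA")
  if (any(nchar(seq) < 1L)) stop(what, " must have length >= 1")
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    ch <- regmatches(seq[bad][1], regexpr("[^ACGTN]", seq[bad][1]))
    stop("illegal character '", ch, "' in ", what, " (alphabet is A/C/G/T/N)")
  }
  invisible(seq)
}

#' Construct a contig
#'
#' A contig is one assembled sequence: an identifier, a DNA sequence over
#' `{A,C,G,T,N}`, a source label (which assembly or reference it came from)
#' and an optional truth label used by simulated fixtures.
#'
#' @param id Non-empty identifier.
#' @param seq DNA string over `{A,C,G,T,N}`.
#' @param source Text label of the assembly of origin.
#' @param truth One of `"bona_fide"`, `"chimeric"`, `"unknown"`. Real inputs
#'   default to `"unknown"`; simulated fixtures always set it.
#' @return An object of class `contig` (a named list).
#' @export
contig <- function(id, seq, source = NA_character_, truth = "unknown") {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    stop("contig id must be a non-empty string")
  seq <- toupper(seq)
  .check_seq(seq)
  truth <- match.arg(truth, TRUTH_LEVELS)
  structure(list(id = id, seq = seq, source = source, truth = truth),
            class = "contig")
}

#' Construct an assembly
#'
#' An ordered collection of contigs with unique ids and a label. Input order
#' is preserved; use [sort_assembly()] before writing outputs to get the
#' deterministic descending-length order used throughout the pipeline.
#'
#' @param label Assembly label (e.g. assembler name, `"DBG"`, `"hybrid"`).
#' @param ids,seqs Parallel character vectors of contig ids and sequences.
#' @param source Per-contig source labels; defaults to `label`.
#' @param truth Per-contig truth labels.
#' @return An object of class `assembly`: a list with `label` and a `contigs`
#'   data frame (columns `id`, `seq`, `source`, `truth`).
#' @export
assembly <- function(label, ids = character(), seqs = character(),
                     source = NULL, truth = NULL) {
  stopifnot(length(ids) == length(seqs))
  if (anyDuplicated(ids)) stop("duplicate contig ids in assembly '", label, "'")
  if (length(ids) && (any(is.na(ids)) || any(!nzchar(ids))))
    stop("contig ids must be non-empty")
  seqs <- toupper(seqs)
  if (length(seqs)) .check_seq(seqs)
  if (is.null(source)) source <- rep(label, length(ids))
  if (is.null(truth)) truth <- rep("unknown", length(ids))
  if (!all(truth %in% TRUTH_LEVELS)) stop("invalid truth label")
  structure(list(
    label = label,
    contigs = data.frame(id = as.character(ids), seq = as.character(seqs),
                         source = as.character(source),
                         truth = as.character(truth),
                         stringsAsFactors = FALSE)
  ), class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  n <- nrow(x$contigs)
  cat("<assembly '", x$label, "': ", n, " contigs, ",
      sum(nchar(x$contigs$seq)), " bp>\n", sep = "")
  invisible(x)
}

#' Number of contigs in an assembly
#' @param x An `assembly`.
#' @return Integer count.
#' @export
n_contigs <- function(x) nrow(x$contigs)

#' Contig lengths of an assembly
#' @param x An `assembly`.
#' @return Integer vector of sequence lengths, in contig order.
#' @export
contig_lengths <- function(x) nchar(x$contigs$seq)

#' Sort an assembly into canonical output order
#'
#' Descending sequence length, ties broken by id, so every pipeline stage is
#' byte-deterministic.
#'
#' @param x An `assembly`.
#' @return The assembly with contigs reordered.
#' @export
sort_assembly <- function(x) {
  o <- order(-nchar(x$contigs$seq), x$contigs$id)
  x$contigs <- x$contigs[o, , drop = FALSE]
  rownames(x$contigs) <- NULL
  x
}

#' Read a FASTA file into an assembly
#'
#' Accepts multi-line and single-line FASTA; blank lines are ignored. The
#' header token before the first whitespace becomes the contig id, sequences
#' are uppercased and `U` is mapped to `T`; any remaining character outside
#' `{A,C,G,T,N}` is an error, as are duplicate ids and empty files.
#'
#' @param path FASTA file path.
#' @param label Assembly label; defaults to the file name without extension.
#' @return An `assembly` with contigs in file order.
#' @export
read_fasta <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- chartr("u", "t", as.character(set))
  seqs <- chartr("U", "T", toupper(seqs))
  if (anyDuplicated(ids)) stop("duplicate ids in ", path)
  assembly(label, ids, seqs)
}

#' Write an assembly to a FASTA file
#'
#' @param x A non-empty `assembly`.
#' @param path Output path.
#' @param width Line width for wrapped sequence lines.
#' @return `path`, invisibly. Round-trips with [read_fasta()] on ids and
#'   sequences.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (n_contigs(x) == 0L) stop("refusing to write an empty assembly")
  set <- Biostrings::DNAStringSet(x$contigs$seq)
  names(set) <- x$contigs$id
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Reverse complement
#'
#' Length-preserving involution over `{A,C,G,T,N}`; `N` maps to `N`.
#'
#' @param seq Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  .check_seq(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}
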