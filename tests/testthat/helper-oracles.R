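# Brute-force oracles, independent of the package's k-mer/chaining code.
# MEMs are enumerated as maximal runs of base equality along every diagonal
# of the (query x target) comparison, on both strands.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# interval union length without IRanges (keeps the oracle independent)
union_len_oracle <- function(s, e) {
  if (!length(s)) return(0L)
  o <- order(s)
  s <- s[o]; e <- e[o]
  tot <- 0L; cs <- s[1]; ce <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > ce) {
      tot <- tot + ce - cs
      cs <- s[i]; ce <- e[i]
    } else ce <- max(ce, e[i])
  }
  tot + ce - cs
}

oracle_mems <- function(q, t, min_len, self = FALSE) {
  ta <- strsplit(t, "", fixed = TRUE)[[1]]
  nt <- length(ta)
  rows <- list()
  for (strand in c("+", "-")) {
    qa <- strsplit(if (strand == "+") q else reverse_complement(q),
                   "", fixed = TRUE)[[1]]
    nq <- length(qa)
    for (d in (-(nq - 1L)):(nt - 1L)) {
      i <- max(0L, -d):min(nq - 1L, nt - 1L - d)
      eq <- qa[i + 1L] == ta[i + d + 1L] & qa[i + 1L] != "N" &
        ta[i + d + 1L] != "N"
      r <- rle(eq)
      off <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
      for (k in seq_along(r$lengths)) {
        if (!r$values[k] || r$lengths[k] < min_len) next
        if (self && strand == "+" && d == 0L) next
        s <- i[1L] + off[k]; e <- s + r$lengths[k]
        if (strand == "+") {
          rows[[length(rows) + 1L]] <- c(s, e, s + d, e + d, 1L)
        } else {
          rows[[length(rows) + 1L]] <- c(nq - e, nq - s, s + d, e + d, 2L)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(q_start = integer(), q_end = integer(),
                      t_start = integer(), t_end = integer(),
                      strand = character(), len = integer()))
  }
  m <- do.call(rbind, rows)
  out <- data.frame(q_start = m[, 1], q_end = m[, 2], t_start = m[, 3],
                    t_end = m[, 4], strand = c("+", "-")[m[, 5]],
                    len = m[, 2] - m[, 1])
  out[order(out$t_start, out$q_start, out$strand), , drop = FALSE]
}

as_block_key <- function(b) {
  sort(paste(b$q_start, b$q_end, b$t_start, b$t_end, b$strand))
}

oracle_complexity <- function(g, min_len) {
  m <- oracle_mems(g, g, min_len, self = TRUE)
  union_len_oracle(c(m$q_start, m$t_start), c(m$q_end, m$t_end)) / nchar(g)
}

oracle_similarity <- function(a, b, min_len) {
  m <- oracle_mems(a, b, min_len)
  (union_len_oracle(m$q_start, m$q_end) +
     union_len_oracle(m$t_start, m$t_end)) / (nchar(a) + nchar(b))
}

oracle_n50 <- function(lens, genome_len) {
  lens <- sort(as.integer(lens), decreasing = TRUE)
  acc <- 0
  for (l in lens) {
    acc <- acc + l
    if (2 * acc >= genome_len) return(l)
  }
  0L
}

oracle_contained <- function(a, b) {
  if (grepl("N", a, fixed = TRUE)) return(FALSE)
  la <- nchar(a)
  hits <- function(hay) {
    nh <- nchar(hay)
    if (la > nh) return(FALSE)
    for (i in seq_len(nh - la + 1L)) {
      if (substr(hay, i, i + la - 1L) == a) return(TRUE)
    }
    FALSE
  }
  hits(b) || hits(reverse_complement(b))
}

# a pair of sequences sharing planted segments, so MEM sets are non-trivial
make_related_pair <- function(t_len = 200L, n_seg = 3L, seg_len = 25L) {
  seg_len <- min(seg_len, t_len)
  t <- rand_dna(t_len)
  parts <- character(0)
  for (i in seq_len(n_seg)) {
    parts <- c(parts, rand_dna(sample(5:20, 1)))
    s <- sample.int(t_len - seg_len + 1L, 1L)
    piece <- substr(t, s, s + seg_len - 1L)
    if (stats::runif(1) < 0.5) piece <- reverse_complement(piece)
    parts <- c(parts, piece)
  }
  parts <- c(parts, rand_dna(sample(5:20, 1)))
  list(q = paste(parts, collapse = ""), t = t)
}
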