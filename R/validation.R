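#' Run the standard reliability/merging validation suite
#'
#' For each seed, builds the standard synthetic study condition
#' ([genome_fixture()]: a 100 kb genome, three references in the 0.80-0.92
#' similarity band, a bona fide DBG tiling, and per-reference A-contig sets
#' with a misassembled contig planted at every divergent region), runs the
#' reliability filter and the merger, and measures: how many planted
#' misassemblies were excluded, and the accuracy (proportion of bona fide
#' contigs, judged against the truth genome) of the reliable A-contig set
#' and of the hybrid assembly.
#'
#' @param seeds Integer vector of fixture seeds.
#' @param genome_len Genome length, bp.
#' @param params A [reliability_params()] object.
#' @param merge A [merge_params()] object.
#' @param ... Further arguments to [genome_fixture()].
#' @return Data frame with one row per seed: `seed`, `n_planted`,
#'   `n_excluded`, `n_reliable`, `acc_reliable`, `acc_hybrid`,
#'   `n_dbg`, `n_hybrid`, `avg_dbg`, `avg_hybrid`, `n_joins`.
#' @export
validation_suite <- function(seeds = 1:20, genome_len = 1e5,
                             params = reliability_params(),
                             merge = merge_params(), ...) {
  rows <- lapply(seeds, function(s) {
    fx <- genome_fixture(seed = s, genome_len = genome_len, ...)
    pool <- do.call(rbind, lapply(fx$acontig_sets, function(a) a$contigs))
    planted <- sum(pool$truth == "chimeric")
    sel <- select_reliable_acontigs(fx$acontig_sets, fx$dbg, params)
    kept_chim <- sum(sel$reliable$contigs$truth == "chimeric")
    acc_rel <- if (n_contigs(sel$reliable) > 0L)
      accuracy(sel$reliable, fx$genome) else NA_real_
    hyb <- merge_assembly(fx$dbg, sel$reliable, merge)
    data.frame(seed = s, n_planted = planted,
               n_excluded = planted - kept_chim,
               n_reliable = n_contigs(sel$reliable),
               acc_reliable = acc_rel,
               acc_hybrid = accuracy(hyb, fx$genome),
               n_dbg = n_contigs(fx$dbg), n_hybrid = n_contigs(hyb),
               avg_dbg = mean(contig_lengths(fx$dbg)),
               avg_hybrid = mean(contig_lengths(hyb)),
               n_joins = nrow(attr(hyb, "joins")))
  })
  do.call(rbind, rows)
}

#' Run the standard consensus-selection validation suite
#'
#' For each seed, generates a genome with planted repeats, emulates three de
#' novo assemblies with independently planted chimeric contigs
#' ([make_fixture_assemblies()]), runs consensus selection, and measures the
#' accuracy of the selected DBG set against the truth genome, the number of
#' chimeric contigs that slipped through (by truth label), and the input
#' assemblies' own accuracies.
#'
#' @param seeds Integer vector of fixture seeds.
#' @param genome_len Genome length, bp.
#' @param chimera_rate Per-contig chimera probability in each input assembly.
#' @param params A [consensus_params()] object.
#' @return Data frame with one row per seed: `seed`, `n_selected`,
#'   `n_chimeric_selected`, `acc_dbg`, `min_input_acc`.
#' @export
consensus_suite <- function(seeds = 1:20, genome_len = 1e5,
                            chimera_rate = 0.1,
                            params = consensus_params()) {
  rows <- lapply(seeds, function(s) {
    g <- generate_genome(genome_len, repeats = list(c(400L, 2L)), seed = s)
    asms <- make_fixture_assemblies(g$seq, n_assemblies = 3L,
                                    mean_contig_len = 1500L,
                                    chimera_rate = chimera_rate,
                                    avoid = g$repeats, seed = s + 7L)
    dbg <- select_dbg_contigs(asms, params)
    data.frame(seed = s, n_selected = n_contigs(dbg),
               n_chimeric_selected = sum(dbg$contigs$truth == "chimeric"),
               acc_dbg = accuracy(dbg, g$seq),
               min_input_acc = min(vapply(asms, accuracy, numeric(1),
                                          truth_genome = g$seq)))
  })
  do.call(rbind, rows)
}
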