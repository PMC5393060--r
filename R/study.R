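#' Simulate a complete MNase-titration study
#'
#' One call builds the standard in-silico study design: a synthetic genome
#' with planted truth, filtered MNase titration libraries (4 levels per
#' replicate and time point), H3K27ac ChIP/input pairs, and the expression
#' table. The default world expresses the headline phenomenon under
#' acute activation: up-regulated regions gain accessibility while their
#' nucleosome occupancy stays put (no occupancy-loss class).
#'
#' All seeds are derived from `seed`; two calls with the same arguments
#' give identical studies.
#'
#' @param seed master seed.
#' @param chrom_lengths genome size (default one 2-Mb chromosome).
#' @param depth_per_level fragments per titration level (default 5e5).
#' @param chip_depth fragments per ChIP and input library (default 5e5).
#' @param n_replicates replicates per time point (default 2).
#' @param time_points time points to simulate (default 0h and 4h; ChIP
#'   pairs always include all three so enhancer time courses are complete).
#' @param gc_bias_strength GC bias injected into the MNase libraries
#'   (default 0).
#' @param n_genes,n_enhancers annotation sizes (default 120 / 40).
#' @param gene_class_props time-course class mix; default plants 20%
#'   accessibility-only up-regulation, 15% down, 65% unchanged.
#' @return list with `genome`, `titration[[time]][[rep]]` (list of 4
#'   filtered `fragment_set`s), `chip[[time]][[rep]]` (chip/input pairs)
#'   and `expression`.
#' @export
simulate_study <- function(seed = 1L,
                           chrom_lengths = c(chrL = 2e6L),
                           depth_per_level = 5e5,
                           chip_depth = 5e5,
                           n_replicates = 2L,
                           time_points = c("0h", "4h"),
                           gc_bias_strength = 0,
                           n_genes = 120L, n_enhancers = 40L,
                           gene_class_props = c(up_access_only = 0.20,
                                                up_access_and_occ_loss = 0,
                                                down = 0.15,
                                                unchanged = 0.65)) {
  seed <- as.integer(seed)
  spec <- synthetic_genome_spec(chrom_lengths = chrom_lengths,
                                n_genes = n_genes,
                                n_enhancers = n_enhancers,
                                gene_class_props = gene_class_props,
                                seed = seed)
  genome <- build_genome(spec)
  k <- 0L
  titration <- list()
  for (tp in time_points) for (r in seq_len(n_replicates)) {
    k <- k + 1L
    titration[[tp]][[r]] <- lapply(1:4, function(lv)
      filter_fragments(simulate_titration_fragments(
        genome, tp, lv, depth_per_level,
        gc_bias_strength = gc_bias_strength,
        seed = seed + 7919L * k + lv, replicate = r)))
  }
  chip <- list()
  for (tp in c("0h", "1h", "4h")) for (r in seq_len(n_replicates)) {
    k <- k + 1L
    chip[[tp]][[r]] <- simulate_chip_pair(genome, "H3K27ac", tp, chip_depth,
                                          seed = seed + 7919L * k,
                                          replicate = r)
  }
  list(genome = genome, titration = titration, chip = chip,
       expression = simulate_expression_table(genome, seed = seed + 31L))
}
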