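# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small genome for unit tests: 300 kb, a handful of genes/enhancers
test_genome <- function() {
  cached("test_genome", build_genome(synthetic_genome_spec(
    chrom_lengths = c(chrT = 3e5L), n_genes = 15L, n_enhancers = 6L,
    seed = 101L)))
}

# 0h titration series (filtered) on the test genome, depth 1e5/level
test_titration <- function() {
  cached("test_titration", {
    g <- test_genome()
    lapply(1:4, function(lv)
      filter_fragments(simulate_titration_fragments(g, "0h", lv, 1e5,
                                                    seed = 500L + lv)))
  })
}

# fragment_set from a plain table on a toy chromosome
toy_fragments <- function(starts, ends, chrom = "c1", L = 10000L,
                          metadata = list()) {
  fragment_set(data.table::data.table(chrom = chrom, start = starts,
                                      end = ends),
               metadata, setNames(as.integer(L), chrom))
}

# binned track from a plain numeric vector on one chromosome
toy_track <- function(values, bin_size = 200L, chrom = "c1") {
  L <- length(values) * bin_size
  binned_track(setNames(list(values), chrom), bin_size,
               setNames(as.integer(L), chrom))
}
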