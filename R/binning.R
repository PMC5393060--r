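#' Bin fragment frequencies
#'
#' Each fragment is assigned to exactly one bin by its midpoint
#' (`floor((start + end)/2)`), half-open tie to the right, so per-level
#' totals stay comparable regardless of fragment length. Values are in
#' counts per million retained fragments (CPM), using the fragment set's
#' `library_size`.
#'
#' @param fs a `fragment_set` with `chrom_lengths` available (either stored
#'   or supplied).
#' @param bin_size bin width in bp (default 200).
#' @param chrom_lengths named vector; defaults to the set's own.
#' @param normalize return CPM (default) or raw counts.
#' @return A `binned_track`.
#' @export
bin_frequencies <- function(fs, bin_size = 200, chrom_lengths = NULL,
                            normalize = TRUE) {
  if (bin_size <= 0) stop("bin_size must be positive")
  cl <- chrom_lengths %||% fs$chrom_lengths
  if (is.null(cl)) stop("chrom_lengths required (not stored on fragment_set)")
  frg <- fs$fragments
  values <- lapply(names(cl), function(ch) {
    nb <- ceiling(cl[[ch]] / bin_size)
    f <- frg[chrom == ch]
    if (!nrow(f)) return(numeric(nb))
    mid <- (f$start + f$end) %/% 2L
    b <- pmin(mid %/% bin_size + 1L, nb)
    tabulate(b, nbins = nb)
  })
  names(values) <- names(cl)
  if (normalize) {
    if (fs$library_size <= 0) stop("library_size must be positive for CPM")
    values <- lapply(values, normalize_to_library,
                     library_size = fs$library_size)
  }
  binned_track(values, bin_size, cl)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize ATAC-seq signal in the analysis bins
#'
#' Identical binning rules to [bin_frequencies()] so that ATAC signal is
#' directly comparable with the MNase tracks on the same grid.
#'
#' @inheritParams bin_frequencies
#' @export
summarize_atac <- function(fs, bin_size = 200, chrom_lengths = NULL,
                           normalize = TRUE) {
  bin_frequencies(fs, bin_size = bin_size, chrom_lengths = chrom_lengths,
                  normalize = normalize)
}

#' Per-base-pair coverage track
#'
#' Library-size-normalized number of fragments spanning each genomic
#' location (CPM per bp).
#'
#' @param fs a `fragment_set`.
#' @param chrom_lengths named vector; defaults to the set's own.
#' @param normalize divide by library size and scale to CPM (default TRUE).
#' @return A `bp_track`.
#' @export
coverage_track <- function(fs, chrom_lengths = NULL, normalize = TRUE) {
  cl <- chrom_lengths %||% fs$chrom_lengths
  if (is.null(cl)) stop("chrom_lengths required")
  frg <- fs$fragments
  scale <- if (normalize) {
    if (fs$library_size <= 0) stop("library_size must be positive")
    1e6 / fs$library_size
  } else 1
  values <- lapply(names(cl), function(ch) {
    L <- cl[[ch]]
    f <- frg[chrom == ch]
    if (!nrow(f)) return(numeric(L))
    cov <- IRanges::coverage(IRanges::IRanges(start = f$start + 1L, end = f$end),
                             width = L)
    as.numeric(cov) * scale
  })
  names(values) <- names(cl)
  bp_track(values, cl)
}

#' Occupancy from a pooled-digest library
#'
#' Traditional nucleosome occupancy: per-bp, library-normalized coverage of
#' a library where the digestion levels were pooled before sequencing.
#'
#' @param pooled_fs a `fragment_set` of the pooled digest.
#' @param chrom_lengths named vector; defaults to the set's own.
#' @return A `bp_track` with attribute `mode = "pooled"`.
#' @export
pooled_occupancy <- function(pooled_fs, chrom_lengths = NULL) {
  tr <- coverage_track(pooled_fs, chrom_lengths)
  attr(tr, "mode") <- "pooled"
  tr
}

#' Average a per-bp track into bins
#'
#' @param bptr a `bp_track`.
#' @param bin_size bin width (bp).
#' @return A `binned_track` of per-bin mean values.
#' @export
bin_bp_track <- function(bptr, bin_size = 200) {
  cl <- bptr$chrom_lengths
  values <- lapply(names(cl), function(ch) {
    v <- bptr$values[[ch]]
    L <- length(v)
    nb <- ceiling(L / bin_size)
    idx <- rep(seq_len(nb), each = bin_size, length.out = L)
    as.numeric(tapply(v, idx, mean))
  })
  names(values) <- names(cl)
  binned_track(values, bin_size, cl)
}
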