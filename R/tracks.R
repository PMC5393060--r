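#' Binned genomic track
#'
#' A per-chromosome vector of values on a fixed, non-overlapping grid that
#' starts at coordinate 0. The grid always covers the whole chromosome: when
#' the chromosome length is not a multiple of `bin_size` the last, partial
#' bin is retained and flagged so genome-wide summaries can exclude it.
#'
#' @param values named list, one numeric vector per chromosome.
#' @param bin_size bin width in bp.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return An object of class `binned_track`.
#' @export
binned_track <- function(values, bin_size, chrom_lengths) {
  stopifnot(bin_size > 0, is.list(values), !is.null(names(values)))
  chrom_lengths <- chrom_lengths[names(values)]
  n_expected <- ceiling(chrom_lengths / bin_size)
  ok <- vapply(names(values), function(ch) length(values[[ch]]) == n_expected[[ch]],
               logical(1))
  if (!all(ok))
    stop("binned_track: value vectors do not match ceiling(length/bin_size) grid")
  partial <- chrom_lengths %% bin_size != 0
  structure(
    list(values = values, bin_size = as.integer(bin_size),
         chrom_lengths = chrom_lengths, partial_last = partial),
    class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("binned_track: %d chromosome(s), bin_size=%d, %d bins\n",
              length(x$values), x$bin_size, sum(lengths(x$values))))
  invisible(x)
}

n_bins <- function(track) sum(lengths(track$values))

#' Flatten a binned track to a data.table
#'
#' @param track a `binned_track`.
#' @param drop_partial drop flagged partial terminal bins.
#' @return data.table with columns chrom, start, end, value.
#' @export
track_to_dt <- function(track, drop_partial = FALSE) {
  bs <- track$bin_size
  out <- rbindlist(lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    n <- length(v)
    dt <- data.table(chrom = ch,
                     start = as.integer((seq_len(n) - 1L) * bs),
                     end = as.integer(pmin(seq_len(n) * bs, track$chrom_lengths[[ch]])),
                     value = v)
    if (drop_partial && track$partial_last[[ch]]) dt <- dt[-n]
    dt
  }))
  out[]
}

#' Concatenate a track's values into one vector
#'
#' Partial terminal bins are excluded by default so genome-wide statistics
#' are not biased by truncated bins.
#'
#' @param track a `binned_track`.
#' @param drop_partial exclude flagged partial bins.
#' @export
track_values <- function(track, drop_partial = TRUE) {
  unlist(lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    if (drop_partial && track$partial_last[[ch]]) v <- v[-length(v)]
    v
  }), use.names = FALSE)
}

stopifnot_same_grid <- function(a, b) {
  if (a$bin_size != b$bin_size ||
      !identical(names(a$values), names(b$values)) ||
      !identical(lengths(a$values), lengths(b$values)))
    stop("tracks are not on the same bin grid")
}

#' Arithmetic combination of tracks on a shared grid
#' @param tracks list of `binned_track`s on one grid.
#' @param fn function applied row-wise to the matrix of per-bin values
#'   (e.g. `rowMeans`).
#' @keywords internal
combine_tracks <- function(tracks, fn) {
  for (t in tracks[-1]) stopifnot_same_grid(tracks[[1]], t)
  values <- lapply(names(tracks[[1]]$values), function(ch) {
    m <- do.call(cbind, lapply(tracks, function(t) t$values[[ch]]))
    fn(m)
  })
  names(values) <- names(tracks[[1]]$values)
  binned_track(values, tracks[[1]]$bin_size, tracks[[1]]$chrom_lengths)
}

#' Per-base-pair track
#'
#' Dense per-bp values, used for coverage-style occupancy without binning.
#'
#' @param values named list, one numeric vector (length = chromosome length)
#'   per chromosome.
#' @param chrom_lengths named integer vector.
#' @export
bp_track <- function(values, chrom_lengths) {
  chrom_lengths <- chrom_lengths[names(values)]
  ok <- vapply(names(values), function(ch) length(values[[ch]]) == chrom_lengths[[ch]],
               logical(1))
  if (!all(ok)) stop("bp_track: vector lengths must equal chromosome lengths")
  structure(list(values = values, chrom_lengths = chrom_lengths),
            class = "bp_track")
}

#' @export
print.bp_track <- function(x, ...) {
  cat(sprintf("bp_track: %d chromosome(s), %d bp\n",
              length(x$values), sum(lengths(x$values))))
  invisible(x)
}

#' Write a binned track as bedGraph
#'
#' @param track a `binned_track`.
#' @param path output file.
#' @param name track line name (omitted when `NULL`).
#' @export
write_bedgraph <- function(track, path, name = NULL) {
  dt <- track_to_dt(track)
  dt <- dt[is.finite(value)]
  if (!is.null(name)) {
    writeLines(sprintf("track type=bedGraph name=\"%s\"", name), path)
    fwrite(dt, path, sep = "\t", col.names = FALSE, append = TRUE)
  } else {
    fwrite(dt, path, sep = "\t", col.names = FALSE)
  }
  invisible(path)
}
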