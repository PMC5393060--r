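#' Construct a fragment set
#'
#' A fragment set holds paired-end sequencing templates as genomic intervals
#' (0-based, half-open) plus the sample metadata that downstream
#' normalization needs. `library_size` is the number of currently retained
#' fragments and is updated by every filter.
#'
#' @param fragments data.frame/data.table with columns `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param metadata named list; typically assay, time_point, level, replicate.
#' @param chrom_lengths optional named vector; when given, coordinates are
#'   validated against it.
#' @return Object of class `fragment_set`.
#' @export
fragment_set <- function(fragments, metadata = list(), chrom_lengths = NULL) {
  fragments <- as.data.table(fragments)
  needed <- c("chrom", "start", "end")
  if (!all(needed %in% names(fragments)))
    stop("fragments need columns chrom, start, end")
  fragments[, `:=`(start = as.integer(start), end = as.integer(end),
                   chrom = as.character(chrom))]
  if (nrow(fragments) && any(fragments$start < 0 | fragments$start >= fragments$end))
    stop("invalid fragment coordinates: need 0 <= start < end")
  if (!is.null(chrom_lengths)) {
    bad <- setdiff(unique(fragments$chrom), names(chrom_lengths))
    if (length(bad))
      stop("fragments on chromosomes absent from genome: ",
           paste(bad, collapse = ", "))
    over <- fragments[end > chrom_lengths[chrom]]
    if (nrow(over)) stop("fragment end beyond chromosome length")
  }
  structure(list(fragments = fragments[], metadata = metadata,
                 chrom_lengths = chrom_lengths,
                 library_size = nrow(fragments)),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  md <- if (length(x$metadata))
    paste(names(x$metadata), unlist(lapply(x$metadata, format)),
          sep = "=", collapse = ", ") else "no metadata"
  cat(sprintf("fragment_set: %d fragments (%s)\n", x$library_size, md))
  invisible(x)
}

fragment_lengths <- function(fs) fs$fragments$end - fs$fragments$start

#' Read paired-end fragments from BED or BAM
#'
#' BED input uses the first three columns (chrom, start, end), 0-based
#' half-open, one line per sequenced template. BAM input (requires the
#' Rsamtools package) keeps one interval per properly paired template, built
#' from the leftmost mate's position and the template length.
#'
#' @param path input file.
#' @param format `"BED"` or `"BAM"`; default guessed from the extension.
#' @param metadata metadata list stored on the result.
#' @param chrom_lengths optional named vector for coordinate validation.
#' @return A `fragment_set`.
#' @export
read_fragments <- function(path, format = NULL, metadata = list(),
                           chrom_lengths = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "BAM" else "BED"
  format <- match.arg(toupper(format), c("BED", "BAM"))
  if (format == "BED") {
    empty <- data.table(chrom = character(), start = integer(),
                        end = integer())
    dt <- if (file.size(path) == 0) empty else tryCatch(
      fread(path, header = FALSE, select = 1:3,
            col.names = c("chrom", "start", "end"),
            colClasses = list(character = 1, integer = 2:3)),
      error = function(e) stop("failed to parse BED ", path, ": ",
                               conditionMessage(e)))
    if (!nrow(dt)) dt <- empty
    if (nrow(dt)) {
      bad <- which(!is.finite(dt$start) | !is.finite(dt$end) | dt$start >= dt$end)
      if (length(bad))
        stop(sprintf("malformed BED record at line %d of %s", bad[1], path))
    }
  } else {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("BAM input requires the Rsamtools package")
    prm <- Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isProperPair = TRUE, isFirstMateRead = TRUE),
      what = c("rname", "pos", "isize"))
    b <- Rsamtools::scanBam(path, param = prm)[[1]]
    keep <- !is.na(b$pos) & !is.na(b$isize) & b$isize != 0
    # leftmost mate carries positive TLEN; 1-based pos -> 0-based start
    left <- b$isize[keep] > 0
    dt <- data.table(chrom = as.character(b$rname[keep][left]),
                     start = b$pos[keep][left] - 1L,
                     end = b$pos[keep][left] - 1L + abs(b$isize[keep][left]))
  }
  fragment_set(dt, metadata = metadata, chrom_lengths = chrom_lengths)
}

#' Write a fragment set as 6-column BED
#'
#' Columns: chrom, start, end, name, score (titration level when present,
#' else 0), strand ('.'). Coordinates 0-based half-open.
#'
#' @param fs a `fragment_set`.
#' @param path output file.
#' @export
write_fragments_bed <- function(fs, path) {
  dt <- copy(fs$fragments)
  lvl <- fs$metadata$level
  dt[, `:=`(name = sprintf("frag%d", .I),
            score = if (is.null(lvl)) 0L else as.integer(lvl),
            strand = ".")]
  fwrite(dt[, .(chrom, start, end, name, score, strand)], path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Filter fragments by insert size
#'
#' Retains fragments whose insert length is within `[min_len, max_len]`,
#' bounds inclusive: the removal rule discards strictly shorter than 50 bp
#' or strictly longer than 500 bp.
#'
#' @param fs a `fragment_set`.
#' @param min_len,max_len inclusive retention bounds in bp.
#' @return Filtered `fragment_set` with updated `library_size`.
#' @export
filter_by_insert <- function(fs, min_len = 50, max_len = 500) {
  if (min_len > max_len) stop("min_len must be <= max_len")
  len <- fragment_lengths(fs)
  keep <- len >= min_len & len <= max_len
  out <- fs
  out$fragments <- fs$fragments[keep]
  out$library_size <- nrow(out$fragments)
  out$metadata$n_removed_insert <- sum(!keep)
  out
}

#' Remove fragments at anomalous pileup positions
#'
#' Tag counts are accumulated at fragment 5' start positions genome-wide.
#' Over the positions that carry at least one tag, a Z-score
#' `(count - mean)/sd` is computed; fragments starting at positions with
#' `Z > z_thresh` are discarded. Positions with zero tags are excluded from
#' the statistic so that it reflects pileup pathology rather than genome
#' size. When all occupied positions carry identical counts (sd = 0) no
#' fragment is removed and a note is emitted.
#'
#' @param fs a `fragment_set`.
#' @param z_thresh removal threshold (default 7).
#' @return Filtered `fragment_set`.
#' @export
mask_anomalous_positions <- function(fs, z_thresh = 7) {
  out <- fs
  if (nrow(fs$fragments) == 0) return(out)
  frg <- fs$fragments
  cnt <- frg[, .N, by = .(chrom, start)]
  s <- sd(cnt$N)
  if (is.na(s) || s == 0) {
    message("mask_anomalous_positions: all occupied positions have equal counts; nothing removed")
    out$metadata$n_removed_anomalous <- 0L
    return(out)
  }
  m <- mean(cnt$N)
  bad <- cnt[(N - m) / s > z_thresh, .(chrom, start)]
  if (nrow(bad)) {
    frg <- frg[!bad, on = c("chrom", "start")]
  }
  out$fragments <- frg
  out$library_size <- nrow(frg)
  out$metadata$n_removed_anomalous <- fs$library_size - out$library_size
  out
}

#' Library-size normalization to counts per million
#'
#' @param counts numeric vector of per-bin counts.
#' @param library_size number of retained fragments in the library.
#' @return Frequencies in counts per million retained fragments.
#' @export
normalize_to_library <- function(counts, library_size) {
  if (is.null(library_size) || length(library_size) != 1 || library_size <= 0)
    stop("library_size must be a single positive number")
  counts * 1e6 / library_size
}

#' Apply the standard read-level filters and report
#'
#' Convenience wrapper: insert-size filter then anomalous-position mask,
#' returning the filtered set; removal counts per rule live in the result's
#' metadata.
#'
#' @param fs a `fragment_set`.
#' @param min_len,max_len insert-size bounds (inclusive).
#' @param z_thresh anomalous-position Z threshold.
#' @export
filter_fragments <- function(fs, min_len = 50, max_len = 500, z_thresh = 7) {
  mask_anomalous_positions(filter_by_insert(fs, min_len, max_len), z_thresh)
}
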