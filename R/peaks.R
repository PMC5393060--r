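#' Call stable nucleosome positions from a coverage track
#'
#' The per-bp occupancy coverage is smoothed with a Gaussian kernel
#' (sd `sigma`), local maxima are detected, those below the
#' `min_height_quantile` quantile of positive smoothed values are dropped,
#' and of any two surviving maxima closer than `min_spacing` only the
#' higher is kept (120 bp is below the nucleosome footprint, so one
#' nucleosome cannot be called twice).
#'
#' @param coverage a `bp_track` (non-negative values).
#' @param sigma Gaussian smoothing sd in bp (default 20).
#' @param min_spacing minimum distance between called peaks (default 120).
#' @param min_height_quantile prominence threshold as a quantile of the
#'   positive smoothed signal (default 0.25).
#' @return Object of class `peak_set`: data.table(chrom, pos, height) plus
#'   the smoothing parameters as attributes. Empty for all-zero coverage.
#' @export
call_stable_positions <- function(coverage, sigma = 20, min_spacing = 120,
                                  min_height_quantile = 0.25) {
  stopifnot(inherits(coverage, "bp_track"))
  half <- as.integer(ceiling(3 * sigma))
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  out <- list()
  for (ch in names(coverage$values)) {
    v <- coverage$values[[ch]]
    if (any(v < 0)) stop("coverage must be non-negative")
    if (all(v == 0)) next
    sm <- as.numeric(stats::filter(v, kern, sides = 2))
    sm[is.na(sm)] <- 0
    n <- length(sm)
    if (n < 3) next
    is_max <- sm[2:(n - 1)] > sm[1:(n - 2)] & sm[2:(n - 1)] >= sm[3:n]
    cand <- which(is_max) + 1L
    if (!length(cand)) next
    # plateaus: the rule above marks the left edge; recenter on the midpoint
    cand <- vapply(cand, function(i) {
      j <- i
      while (j < n && sm[j + 1L] == sm[i]) j <- j + 1L
      as.integer((i + j) %/% 2L)
    }, integer(1))
    thr <- quantile(sm[sm > 0], min_height_quantile)
    cand <- cand[sm[cand] >= thr]
    if (!length(cand)) next
    # spacing suppression: greedy from the highest peak down
    ord <- cand[order(sm[cand], decreasing = TRUE)]
    kept <- integer(0)
    for (p in ord) {
      if (!length(kept) || all(abs(kept - p) >= min_spacing))
        kept <- c(kept, p)
    }
    kept <- sort(kept)
    out[[ch]] <- data.table(chrom = ch, pos = kept - 1L,  # back to 0-based
                            height = sm[kept])
  }
  res <- if (length(out)) rbindlist(out) else
    data.table(chrom = character(), pos = integer(), height = numeric())
  structure(res, class = c("peak_set", class(res)),
            sigma = sigma, min_spacing = min_spacing,
            min_height_quantile = min_height_quantile)
}

#' Nearest-peak distances between two peak sets
#'
#' For each peak in `peaks_a`, the distance (bp) to the nearest peak in
#' `peaks_b` on the same chromosome; with `symmetric = TRUE` the pooled
#' distances of both directions.
#'
#' @param peaks_a,peaks_b `peak_set`s or tables with chrom, pos (both
#'   non-empty).
#' @param symmetric pool both directions (default FALSE).
#' @return Integer vector of distances.
#' @export
nearest_peak_distances <- function(peaks_a, peaks_b, symmetric = FALSE) {
  a <- as.data.table(peaks_a); b <- as.data.table(peaks_b)
  if (!nrow(a) || !nrow(b)) stop("both peak sets must be non-empty")
  one_way <- function(a, b) {
    unlist(lapply(intersect(unique(a$chrom), unique(b$chrom)), function(ch) {
      pa <- sort(a[chrom == ch, pos])
      pb <- sort(b[chrom == ch, pos])
      idx <- findInterval(pa, pb)
      lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(pb))
      pmin(abs(pa - pb[lo]), abs(pa - pb[hi]))
    }), use.names = FALSE)
  }
  d <- one_way(a, b)
  if (symmetric) d <- c(d, one_way(b, a))
  d
}

#' Positional-stability test: did nucleosomes move more than replicates do?
#'
#' Compares the nearest-peak distance distribution between time points with
#' the replicate-vs-replicate distance distribution by a two-sample
#' Kolmogorov-Smirnov test. When the time-course distances are not
#' significantly larger-spread than replicate noise (p > alpha), the
#' verdict is "stable".
#'
#' @param dist_rep_vs_rep distances between replicate peak sets (>= 50).
#' @param dist_t0_vs_t4 distances between time-point peak sets (>= 50).
#' @param alpha verdict level (default 0.05).
#' @return list(statistic = D, p.value, stable, verdict).
#' @export
compare_stability <- function(dist_rep_vs_rep, dist_t0_vs_t4, alpha = 0.05) {
  if (length(dist_rep_vs_rep) < 50 || length(dist_t0_vs_t4) < 50)
    stop("need >= 50 distances per sample")
  kt <- suppressWarnings(ks.test(dist_rep_vs_rep, dist_t0_vs_t4))
  stable <- kt$p.value > alpha
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       stable = stable, verdict = if (stable) "stable" else "repositioned")
}

#' Write peaks as BED6 (dyad +/- 73 bp, score = height)
#'
#' @param peaks a `peak_set`.
#' @param path output BED file.
#' @param chrom_lengths optional named vector for clipping.
#' @export
write_peaks_bed <- function(peaks, path, chrom_lengths = NULL) {
  dt <- as.data.table(peaks)
  out <- dt[, .(chrom, start = pmax(pos - 73L, 0L), end = pos + 74L,
                name = sprintf("nuc%d", seq_len(.N)),
                score = round(height, 4), strand = ".")]
  if (!is.null(chrom_lengths))
    out[, end := pmin(end, as.integer(chrom_lengths[chrom]))]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
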