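#' Titration series of binned frequency tracks
#'
#' Bundles the four library-normalized frequency tracks of one MNase
#' titration (increasing digestion depth) on a shared bin grid, together
#' with the regression abscissa. The regression uses the level INDEX
#' (1..4) by default, which keeps the accessibility estimator unit-free;
#' alternative abscissae (e.g. log enzyme units) can be supplied.
#'
#' @param tracks list of four `binned_track`s at increasing MNase levels.
#' @param levels numeric abscissa, one value per track (default `1:4`).
#' @return Object of class `titration_series`.
#' @export
titration_series <- function(tracks, levels = seq_along(tracks)) {
  if (length(tracks) != 4)
    stop("a titration series needs exactly 4 tracks (got ", length(tracks), ")")
  if (length(levels) != length(tracks)) stop("one level per track required")
  for (t in tracks[-1]) stopifnot_same_grid(tracks[[1]], t)
  structure(list(tracks = tracks, levels = as.numeric(levels)),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("titration_series: 4 levels (x = %s), %d bins, bin_size=%d\n",
              paste(x$levels, collapse = ","), n_bins(x$tracks[[1]]),
              x$tracks[[1]]$bin_size))
  invisible(x)
}

#' Build a titration series from four fragment sets
#'
#' Convenience wrapper: bins and CPM-normalizes each level's fragments on a
#' common grid.
#'
#' @param fragment_sets list of four `fragment_set`s, levels 1..4.
#' @param bin_size bin width (bp).
#' @param chrom_lengths named vector (defaults to the first set's own).
#' @param levels regression abscissa (default `1:4`).
#' @export
titration_series_from_fragments <- function(fragment_sets, bin_size = 200,
                                            chrom_lengths = NULL,
                                            levels = 1:4) {
  tracks <- lapply(fragment_sets, bin_frequencies, bin_size = bin_size,
                   chrom_lengths = chrom_lengths)
  titration_series(tracks, levels)
}

#' Per-bin slope of frequency across the titration
#'
#' Ordinary least-squares slope of the four normalized frequencies on the
#' level abscissa. For the default equally spaced index (1,2,3,4) this is
#' `(-3 f1 - f2 + f3 + 3 f4) / 10`. Bins with any missing frequency are
#' flagged missing (NA), not zero.
#'
#' @param series a `titration_series`.
#' @return A `binned_track` of raw (uncorrected, unflipped) slopes.
#' @export
fit_titration_slope <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  x <- series$levels
  xc <- x - mean(x)
  denom <- sum(xc^2)
  values <- lapply(names(series$tracks[[1]]$values), function(ch) {
    m <- do.call(cbind, lapply(series$tracks, function(t) t$values[[ch]]))
    as.numeric(m %*% xc) / denom
  })
  names(values) <- names(series$tracks[[1]]$values)
  binned_track(values, series$tracks[[1]]$bin_size,
               series$tracks[[1]]$chrom_lengths)
}

#' GC-correct titration slopes and orient as MACC scores
#'
#' Fits a locally weighted linear trend (one-pass lowess, span `span`) of
#' slope on per-bin GC fraction over all finite bins, subtracts the trend
#' at each bin's GC, then flips the sign: accessible nucleosomes are
#' released preferentially at LOW MNase, giving a negative raw frequency
#' slope across increasing digestion, while accessibility is reported as
#' positive MACC. The trend removal leaves |cor(MACC, GC)| near zero.
#'
#' With fewer than 100 usable bins the smoother is unreliable and a global
#' linear trend is used instead (with a warning).
#'
#' @param slopes `binned_track` of raw slopes (from [fit_titration_slope()]).
#' @param gc `binned_track` of GC fractions on the same grid.
#' @param span lowess span (default 0.3).
#' @param sign_flip apply the accessibility orientation (default TRUE).
#' @return Object of class `macc_track`: list with `macc` (binned_track),
#'   `slope`, `gc` and the correction parameters.
#' @export
gc_correct <- function(slopes, gc, span = 0.3, sign_flip = TRUE) {
  stopifnot_same_grid(slopes, gc)
  s <- unlist(slopes$values, use.names = FALSE)
  g <- unlist(gc$values, use.names = FALSE)
  if (any(g < 0 | g > 1, na.rm = TRUE)) stop("GC fractions must be in [0,1]")
  ok <- is.finite(s) & is.finite(g)
  if (sum(ok) < 2) stop("not enough finite bins for GC correction")
  if (stats::sd(g[ok]) == 0) {
    # constant GC: the conditional mean is the global mean (mean-centering)
    trend <- rep(mean(s[ok]), length(s))
  } else if (sum(ok) < 100) {
    warning("fewer than 100 bins; falling back to a linear GC trend")
    fit <- lm(s[ok] ~ g[ok])
    trend <- coef(fit)[1] + coef(fit)[2] * g
  } else {
    lw <- lowess(g[ok], s[ok], f = span, iter = 0)
    trend <- approx(lw$x, lw$y, xout = g, rule = 2, ties = mean)$y
  }
  corrected <- s - trend
  if (sign_flip) corrected <- -corrected
  values <- relist_values(corrected, slopes$values)
  structure(list(macc = binned_track(values, slopes$bin_size,
                                     slopes$chrom_lengths),
                 slope = slopes, gc = gc, span = span, sign_flip = sign_flip),
            class = "macc_track")
}

relist_values <- function(flat, template) {
  out <- list()
  i <- 0L
  for (ch in names(template)) {
    n <- length(template[[ch]])
    out[[ch]] <- flat[(i + 1L):(i + n)]
    i <- i + n
  }
  out
}

#' @export
print.macc_track <- function(x, ...) {
  v <- track_values(x$macc)
  cat(sprintf("macc_track: %d bins, bin_size=%d, MACC range [%.3g, %.3g]\n",
              n_bins(x$macc), x$macc$bin_size,
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

#' Compute MACC from four fragment sets
#'
#' End-to-end accessibility scoring: bin + CPM-normalize each level, fit
#' the per-bin titration slope, GC-correct and orient.
#'
#' @param fragment_sets list of four filtered `fragment_set`s (levels 1..4).
#' @param gc per-bin GC `binned_track` on the same grid.
#' @param bin_size bin width (bp).
#' @param span lowess span for the GC trend.
#' @param sign_flip orient so accessible is positive (default TRUE).
#' @param levels regression abscissa (default `1:4`).
#' @return A `macc_track`.
#' @export
compute_macc <- function(fragment_sets, gc, bin_size = 200, span = 0.3,
                         sign_flip = TRUE, levels = 1:4) {
  series <- titration_series_from_fragments(fragment_sets, bin_size,
                                            chrom_lengths = gc$chrom_lengths,
                                            levels = levels)
  gc_correct(fit_titration_slope(series), gc, span = span,
             sign_flip = sign_flip)
}

#' Titration-averaged occupancy
#'
#' Occupancy is the tag frequency averaged over all four titration points.
#' Variants: `raw` (mean frequency), `chip_over_input` (mean ChIP frequency
#' divided by mean input frequency; undefined where the input mean is 0) and
#' `input_subtracted` (difference of means).
#'
#' @param series a `titration_series` (H3 ChIP).
#' @param mode one of `"raw"`, `"chip_over_input"`, `"input_subtracted"`.
#' @param input_series matching input `titration_series` (required for the
#'   two corrected modes).
#' @return A `binned_track` with attribute `mode`; undefined bins are NaN.
#' @export
compute_occupancy <- function(series,
                              mode = c("raw", "chip_over_input",
                                       "input_subtracted"),
                              input_series = NULL) {
  mode <- match.arg(mode)
  avg <- combine_tracks(series$tracks, rowMeans)
  if (mode == "raw") {
    attr(avg, "mode") <- mode
    return(avg)
  }
  if (is.null(input_series))
    stop("input_series required for mode ", mode)
  avg_in <- combine_tracks(input_series$tracks, rowMeans)
  stopifnot_same_grid(avg, avg_in)
  values <- lapply(names(avg$values), function(ch) {
    a <- avg$values[[ch]]; b <- avg_in$values[[ch]]
    if (mode == "chip_over_input") {
      out <- a / b
      out[b == 0] <- NaN
      out
    } else a - b
  })
  names(values) <- names(avg$values)
  n_undef <- sum(vapply(values, function(v) sum(is.nan(v)), numeric(1)))
  if (mode == "chip_over_input" && n_undef > 0)
    message(sprintf("compute_occupancy: %d bin(s) undefined (zero input)",
                    as.integer(n_undef)))
  out <- binned_track(values, avg$bin_size, avg$chrom_lengths)
  attr(out, "mode") <- mode
  out
}

#' Quantile-group scaling of a metric
#'
#' Values are split into `n_groups` equal-count quantile groups; the medians
#' of the first and last groups are mapped to 0 and 1 and all values are
#' transformed linearly: `(v - m_lo) / (m_hi - m_lo)`. Values outside the
#' two medians fall outside \[0, 1\] and are not clipped. Affine transforms
#' of the input give identical scaled output.
#'
#' @param x numeric vector or `binned_track` (scaling parameters are then
#'   estimated genome-wide, excluding partial terminal bins, and applied to
#'   every bin).
#' @param n_groups number of quantile groups (default 20).
#' @param reference optional numeric vector the scaling parameters are
#'   estimated from (defaults to `x` itself); lets new values be placed on
#'   an existing scale.
#' @return Same shape as `x`, scaled.
#' @export
scale_metric <- function(x, n_groups = 20, reference = NULL) {
  if (inherits(x, "binned_track")) {
    ref <- reference %||% track_values(x, drop_partial = TRUE)
    par <- .scale_params(ref, n_groups)
    values <- lapply(x$values, function(v) (v - par[1]) / (par[2] - par[1]))
    return(binned_track(values, x$bin_size, x$chrom_lengths))
  }
  par <- .scale_params(reference %||% x, n_groups)
  (x - par[1]) / (par[2] - par[1])
}

.scale_params <- function(v, n_groups) {
  v <- v[is.finite(v)]
  n <- length(v)
  if (n < n_groups) stop("need at least n_groups finite values")
  r <- rank(v, ties.method = "first")
  grp <- ceiling(r * n_groups / n)
  m_lo <- median(v[grp == 1])
  m_hi <- median(v[grp == n_groups])
  if (m_hi == m_lo) stop("degenerate distribution: group medians coincide")
  c(m_lo, m_hi)
}
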