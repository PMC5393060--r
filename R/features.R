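#' Select up-regulated genes from an expression table
#'
#' Primary rule (`rule = "timecourse"`): at least twofold up 0 to 1 h AND
#' not decreasing after 1 h beyond tolerance (further up-regulated or
#' |log2 fold(1-4 h)| within `epsilon`). Alternative (`rule = "endpoints"`):
#' twofold changes over both 0-1 h and 0-4 h with the significance flag —
#' the differential-expression-style definition.
#'
#' @param expr data.frame/data.table with columns `gene_id`, `expr_0h`,
#'   `expr_1h`, `expr_4h` (and `significant` for the endpoints rule).
#' @param rule `"timecourse"` (default) or `"endpoints"`.
#' @param epsilon tolerance on log2 fold(1-4 h) counted as "did not further
#'   change" (default 0.5).
#' @return Character vector of gene ids.
#' @export
classify_upregulated_genes <- function(expr, rule = c("timecourse", "endpoints"),
                                       epsilon = 0.5) {
  rule <- match.arg(rule)
  expr <- as.data.table(expr)
  need <- c("gene_id", "expr_0h", "expr_1h", "expr_4h")
  if (!all(need %in% names(expr)))
    stop("expression table must have columns ", paste(need, collapse = ", "))
  if (anyNA(expr[, ..need])) stop("missing expression values")
  l01 <- log2(expr$expr_1h / expr$expr_0h)
  l14 <- log2(expr$expr_4h / expr$expr_1h)
  sel <- if (rule == "timecourse") {
    l01 >= 1 & l14 >= -epsilon
  } else {
    if (!"significant" %in% names(expr))
      stop("endpoints rule needs a 'significant' column")
    l04 <- l01 + l14
    l01 >= 1 & l04 >= 1 & expr$significant
  }
  expr$gene_id[sel]
}

#' Gene-body comparison region: 500 bp upstream of the TSS through the TTS
#'
#' Strand-aware: the 500 bp flank extends upstream in transcription
#' orientation. Regions running off the chromosome are clipped with a
#' warning.
#'
#' @param genes data.frame with columns chrom, tss, tts, strand.
#' @param chrom_lengths named vector for clipping (optional).
#' @param upstream flank upstream of the TSS (default 500).
#' @return data.table(chrom, start, end) 0-based half-open, one row per gene.
#' @export
gene_body_region <- function(genes, chrom_lengths = NULL, upstream = 500) {
  g <- as.data.table(genes)
  start <- ifelse(g$strand == "+", g$tss - upstream, pmin(g$tss, g$tts))
  end <- ifelse(g$strand == "+", pmax(g$tss, g$tts), g$tss + upstream)
  out <- data.table(chrom = g$chrom, start = as.integer(start),
                    end = as.integer(end))
  clip_regions(out, chrom_lengths)
}

#' Promoter region: TSS +/- flank (strand-independent span)
#'
#' @param genes data.frame with columns chrom, tss.
#' @param flank half-width in bp (default 1000); must be positive.
#' @param chrom_lengths named vector for clipping (optional).
#' @return data.table(chrom, start, end).
#' @export
promoter_region <- function(genes, flank = 1000, chrom_lengths = NULL) {
  if (flank <= 0) stop("flank must be positive")
  g <- as.data.table(genes)
  out <- data.table(chrom = g$chrom, start = as.integer(g$tss - flank),
                    end = as.integer(g$tss + flank))
  clip_regions(out, chrom_lengths)
}

clip_regions <- function(regions, chrom_lengths) {
  if (any(regions$start < 0)) {
    warning("region(s) extend past chromosome start; clipped at 0")
    regions[, start := pmax(start, 0L)]
  }
  if (!is.null(chrom_lengths)) {
    over <- regions$end > chrom_lengths[regions$chrom]
    if (any(over)) {
      warning("region(s) extend past chromosome end; clipped")
      regions[, end := pmin(end, as.integer(chrom_lengths[chrom]))]
    }
  }
  regions[]
}

#' Overlap-weighted mean of a binned track over regions
#'
#' Bin values overlapping each region contribute in proportion to the
#' overlap width; regions touching no bin get NA.
#'
#' @param track a `binned_track`.
#' @param regions data.frame with chrom, start, end (0-based half-open).
#' @return Numeric vector, one value per region.
#' @export
per_region_mean <- function(track, regions) {
  regions <- as.data.table(regions)
  bs <- track$bin_size
  vapply(seq_len(nrow(regions)), function(i) {
    ch <- regions$chrom[i]
    v <- track$values[[ch]]
    if (is.null(v)) return(NA_real_)
    a <- regions$start[i]; b <- regions$end[i]
    if (b <= a) return(NA_real_)
    b0 <- a %/% bs                       # first bin index (0-based)
    b1 <- (b - 1L) %/% bs
    b1 <- min(b1, length(v) - 1L)
    if (b0 > b1) return(NA_real_)
    bins <- b0:b1
    ov_lo <- pmax(bins * bs, a)
    ov_hi <- pmin((bins + 1L) * bs, b)
    w <- as.numeric(ov_hi - ov_lo)
    vals <- v[bins + 1L]
    ok <- is.finite(vals) & w > 0
    if (!any(ok)) return(NA_real_)
    sum(vals[ok] * w[ok]) / sum(w[ok])
  }, numeric(1))
}

#' Strand-aware metagene profile with SEM
#'
#' Extracts the track value at each offset around each anchor (minus-strand
#' anchors are read 3' to 5', i.e. their rows are reversed before
#' aggregation) and returns per-offset mean and standard error of the mean.
#' Works on `binned_track` (value looked up by bin) or `bp_track`.
#'
#' @param track `binned_track` or `bp_track`.
#' @param anchors data.frame with chrom, pos (0-based bp), strand.
#' @param flank half-window in bp.
#' @param step offset step in bp (defaults to the bin size, or 10 bp for
#'   per-bp tracks).
#' @return Object of class `profile_matrix`: list(offsets, matrix, mean,
#'   sem, n).
#' @export
metagene_profile <- function(track, anchors, flank = 1000, step = NULL) {
  anchors <- as.data.table(anchors)
  if (!nrow(anchors)) stop("anchor set is empty")
  if (is.null(anchors$strand)) anchors[, strand := "+"]
  binned <- inherits(track, "binned_track")
  if (is.null(step)) step <- if (binned) track$bin_size else 10L
  offsets <- seq(-flank, flank, by = step)
  lookup <- function(ch, p) {
    v <- track$values[[ch]]
    if (is.null(v)) return(rep(NA_real_, length(p)))
    idx <- if (binned) p %/% track$bin_size + 1L else p + 1L
    idx[p < 0 | idx > length(v)] <- NA_integer_
    v[idx]
  }
  raw <- vapply(seq_len(nrow(anchors)), function(i) {
    sgn <- if (anchors$strand[i] == "-") -1L else 1L
    lookup(anchors$chrom[i], anchors$pos[i] + sgn * offsets)
  }, numeric(length(offsets)))
  m <- t(matrix(raw, nrow = length(offsets)))   # anchors x offsets, robust to 1-offset windows
  mu <- colMeans(m, na.rm = TRUE)
  nn <- colSums(is.finite(m))
  sem <- apply(m, 2, function(col) {
    col <- col[is.finite(col)]
    if (length(col) < 2) return(0)
    sd(col) / sqrt(length(col))
  })
  structure(list(offsets = offsets, matrix = m, mean = mu, sem = sem, n = nn),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d anchors x %d offsets (%d..%d bp)\n",
              nrow(x$matrix), length(x$offsets), min(x$offsets),
              max(x$offsets)))
  invisible(x)
}

#' Mann-Whitney comparison of per-gene values between time points
#'
#' Two-sided rank-sum test between the two (unpaired) groups of per-gene
#' metric values.
#'
#' @param values_t0,values_t1 numeric vectors of per-gene values.
#' @return list(statistic, p.value, method) from [mann_whitney_test()].
#' @export
compare_group_timepoints <- function(values_t0, values_t1) {
  mann_whitney_test(values_t0, values_t1, alternative = "two.sided")
}

#' One-sided signed-rank comparison of two tracks over a region
#'
#' Pairs the per-bin values of the two tracks over `region` and tests the
#' stated alternative: `"increase"` (track_b above track_a; used for
#' accessibility) or `"decrease"` (used for occupancy). Zero differences
#' are dropped.
#'
#' @param track_a,track_b `binned_track`s on one grid (e.g. 0 h vs 4 h).
#' @param region list/row with chrom, start, end; NULL compares all bins.
#' @param alternative `"increase"` or `"decrease"`.
#' @return list(statistic, p.value, n_used, method).
#' @export
compare_profiles_signed_rank <- function(track_a, track_b, region = NULL,
                                         alternative = c("increase",
                                                         "decrease")) {
  alternative <- match.arg(alternative)
  stopifnot_same_grid(track_a, track_b)
  if (is.null(region)) {
    a <- track_values(track_a); b <- track_values(track_b)
  } else {
    region <- as.list(region)
    bs <- track_a$bin_size
    b0 <- region$start %/% bs + 1L
    b1 <- (region$end - 1L) %/% bs + 1L
    v <- track_a$values[[region$chrom]]
    b1 <- min(b1, length(v))
    a <- v[b0:b1]
    b <- track_b$values[[region$chrom]][b0:b1]
  }
  ok <- is.finite(a) & is.finite(b)
  d <- b[ok] - a[ok]
  signed_rank_test(d, alternative = if (alternative == "increase") "greater"
                   else "less")
}

#' Spearman correlation of a per-gene metric with expression
#'
#' @param metric,expression numeric vectors, one value per gene.
#' @return list(rho, p.value, n); rho is NA for constant input.
#' @export
correlate_with_expression <- function(metric, expression) {
  ok <- is.finite(metric) & is.finite(expression)
  m <- metric[ok]; e <- expression[ok]
  if (length(m) < 3 || length(unique(m)) == 1 || length(unique(e)) == 1)
    return(list(rho = NA_real_, p.value = NA_real_, n = length(m)))
  ct <- suppressWarnings(cor.test(m, e, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p.value = ct$p.value, n = length(m))
}

#' Fraction of the genome with significant metric changes
#'
#' Per bin, a two-sample t-test across replicate tracks compares the two
#' time points; a bin counts as changed when `p < alpha` AND the absolute
#' mean change is at least the threshold. Reported as a percentage of
#' testable bins for each threshold (monotonically non-increasing). No
#' multiple-testing correction is applied: the output mirrors raw
#' `P < 0.05` genome fractions.
#'
#' @param tracks_t0,tracks_t4 lists (>= 2 each) of replicate
#'   `binned_track`s at the two time points.
#' @param thresholds numeric vector of |mean change| thresholds.
#' @param alpha significance level (0.05).
#' @param var_equal pooled-variance Student t (default TRUE; exact test
#'   size under the null at small replicate counts) or Welch.
#' @return data.table(threshold, percent).
#' @export
fraction_significant_changes <- function(tracks_t0, tracks_t4, thresholds = 0,
                                         alpha = 0.05, var_equal = TRUE) {
  n0 <- length(tracks_t0); n4 <- length(tracks_t4)
  if (n0 < 2 || n4 < 2) stop("need >= 2 replicates per time point")
  m0 <- do.call(cbind, lapply(tracks_t0, track_values, drop_partial = TRUE))
  m4 <- do.call(cbind, lapply(tracks_t4, track_values, drop_partial = TRUE))
  mu0 <- rowMeans(m0); mu4 <- rowMeans(m4)
  v0 <- rowSums((m0 - mu0)^2) / (n0 - 1)
  v4 <- rowSums((m4 - mu4)^2) / (n4 - 1)
  if (var_equal) {
    sp2 <- ((n0 - 1) * v0 + (n4 - 1) * v4) / (n0 + n4 - 2)
    se <- sqrt(sp2 * (1 / n0 + 1 / n4))
    df <- rep(n0 + n4 - 2, length(se))
  } else {
    se2 <- v0 / n0 + v4 / n4
    se <- sqrt(se2)
    df <- se2^2 / ((v0 / n0)^2 / (n0 - 1) + (v4 / n4)^2 / (n4 - 1))
  }
  delta <- mu4 - mu0
  tstat <- delta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  testable <- is.finite(p)
  out <- data.table(threshold = thresholds,
                    percent = vapply(thresholds, function(th)
                      100 * sum(p[testable] < alpha &
                                  abs(delta[testable]) >= th) /
                        sum(testable), numeric(1)))
  out[]
}

#' Uniformly sample random anchor sites
#'
#' Deterministic under `seed`; positions are at least `flank` away from
#' chromosome ends so profile windows never clip.
#'
#' @param n number of sites (about 7000 matches the expressed-gene count
#'   this kind of control emulates).
#' @param chrom_lengths named vector.
#' @param flank excluded margin at chromosome ends (bp).
#' @param seed integer seed.
#' @return data.table(chrom, pos, strand = "+").
#' @export
sample_random_sites <- function(n, chrom_lengths, flank = 1000, seed = 1L) {
  if (n == 0)
    return(data.table(chrom = character(), pos = integer(),
                      strand = character()))
  avail <- pmax(chrom_lengths - 2 * flank, 0)
  if (sum(avail) < n) stop("n exceeds available positions")
  set.seed(seed)
  ch <- sample(names(chrom_lengths), n, replace = TRUE,
               prob = avail / sum(avail))
  pos <- as.integer(flank + floor(runif(n) * avail[ch]))
  data.table(chrom = ch, pos = pos, strand = "+")
}
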