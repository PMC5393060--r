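#' MNase release kernel
#'
#' Fraction of a nucleosome's release that falls at titration level `level`
#' (index 1..4). A unimodal Gaussian kernel in the level index whose
#' optimum shifts down as accessibility rises:
#' `K = exp(-(level - mu(a))^2 / (2 sigma^2))` with `mu(a) = mu0 - shift * a`,
#' normalized so the kernel sums to 1 over the level grid. The
#' normalization means accessibility decides WHICH digestion depth releases
#' a nucleosome — not how much of it is released in total — so the
#' titration-averaged frequency estimates occupancy free of accessibility
#' cross-talk. With the defaults, fully accessible nucleosomes (`a = +1`,
#' mu = 1) give strictly decreasing release shares over levels 1 to 4 and
#' fully inaccessible ones (`a = -1`, mu = 4) strictly increasing shares:
#' accessible chromatin is released by gentle digestion and over-digested
#' away at high enzyme levels.
#'
#' @param level titration level index (1..4), vectorized.
#' @param accessibility accessibility in \[-1, 1\], vectorized.
#' @param mu0 kernel center at accessibility 0 (default 2.5).
#' @param shift displacement of the optimum per unit accessibility (1.5).
#' @param sigma kernel width in level units (1.2).
#' @param normalize divide by the kernel's sum over `levels_grid` (default
#'   TRUE).
#' @param levels_grid the titration grid used for normalization (1:4).
#' @export
mnase_release <- function(level, accessibility, mu0 = 2.5, shift = 1.5,
                          sigma = 1.2, normalize = TRUE, levels_grid = 1:4) {
  mu <- mu0 - shift * accessibility
  k <- exp(-(level - mu)^2 / (2 * sigma^2))
  if (!normalize) return(k)
  tot <- Reduce(`+`, lapply(levels_grid, function(l)
    exp(-(l - mu)^2 / (2 * sigma^2))))
  k / tot
}

.concat_offsets <- function(chrom_lengths) {
  off <- cumsum(c(0, as.numeric(chrom_lengths)))
  names(off) <- c(names(chrom_lengths), ".total")
  off
}

# draw fragment lengths: truncated normal core plus contaminants outside
# the [50, 500] insert window so the filter has work to do
.draw_lengths <- function(n, len_mean, len_sd, contaminant_fraction) {
  len <- as.integer(round(rnorm(n, len_mean, len_sd)))
  bad <- which(len < 50 | len > 500)
  while (length(bad)) {
    len[bad] <- as.integer(round(rnorm(length(bad), len_mean, len_sd)))
    bad <- bad[len[bad] < 50 | len[bad] > 500]
  }
  if (contaminant_fraction > 0 && n > 0) {
    is_cont <- runif(n) < contaminant_fraction
    nc <- sum(is_cont)
    if (nc) {
      short <- runif(nc) < 0.5
      clen <- integer(nc)
      clen[short] <- as.integer(floor(runif(sum(short), 20, 50)))
      clen[!short] <- as.integer(floor(runif(sum(!short), 501, 700)))
      len[is_cont] <- clen
    }
  }
  len
}

# centers (0-based) + lengths -> clipped fragment table
.fragments_from_centers <- function(chrom, center, len, chrom_lengths) {
  L <- chrom_lengths[chrom]
  start <- center - len %/% 2L
  start <- pmax(0L, pmin(start, L - len))
  start <- pmax(0L, start)               # fragments longer than the chromosome
  end <- pmin(L, start + len)
  data.table(chrom = chrom, start = as.integer(start), end = as.integer(end))
}

#' Simulate one MNase titration library
#'
#' Forward model of a single digestion depth: the expected fragment count at
#' a nucleosome is proportional to
#' `occupancy x release(level, accessibility) x exp(gc_bias_strength x (GC - 0.5))`,
#' plus a uniform background component. Fragment centers scatter around the
#' dyad (sd 8 bp); lengths follow a truncated normal (mean 147, sd 15 bp)
#' with a small contaminant fraction outside the 50-500 bp insert window.
#' Total expected counts equal `depth`.
#'
#' @param genome a `synthetic_genome`.
#' @param time_point `"0h"`, `"1h"` or `"4h"`.
#' @param titration_level integer in 1..4.
#' @param depth number of fragments to draw.
#' @param gc_bias_strength GC bias exponent beta. The bias has an overall
#'   multiplicative part `exp(beta * (GC - 0.5))` and a digestion-coupled
#'   part `exp(2 * beta * (GC - 0.5) * (level - 2.5))` (GC-rich sequence is
#'   released relatively more at deeper digestion), so injected bias
#'   confounds both coverage and the titration slope; 0 disables bias.
#' @param seed integer seed.
#' @param replicate replicate index recorded in metadata.
#' @param bg_fraction uniform background fraction of fragments (0.05).
#' @param len_mean,len_sd fragment length distribution (147, 15).
#' @param contaminant_fraction fraction of fragments outside \[50, 500\] bp
#'   (0.02).
#' @param release_args list of overrides passed to [mnase_release()].
#' @return A `fragment_set` (assay `"mnase_h3"`).
#' @export
simulate_titration_fragments <- function(genome, time_point, titration_level,
                                         depth, gc_bias_strength = 0,
                                         seed = 1L, replicate = 1L,
                                         bg_fraction = 0.05,
                                         len_mean = 147, len_sd = 15,
                                         contaminant_fraction = 0.02,
                                         release_args = list()) {
  if (!titration_level %in% 1:4) stop("titration_level must be in 1..4")
  stopifnot(depth >= 0)
  time_point <- match.arg(time_point, c("0h", "1h", "4h"))
  set.seed(seed)
  md <- list(assay = "mnase_h3", time_point = time_point,
             level = as.integer(titration_level),
             replicate = as.integer(replicate),
             gc_bias_strength = gc_bias_strength)
  cl <- genome$spec$chrom_lengths
  if (depth == 0)
    return(fragment_set(data.table(chrom = character(), start = integer(),
                                   end = integer()), md, cl))
  nucs <- genome$nucleosomes
  occ <- nucs[[paste0("occ_", time_point)]]
  acc <- nucs[[paste0("acc_", time_point)]]
  rel <- do.call(mnase_release,
                 c(list(level = titration_level, accessibility = acc),
                   release_args))
  gc_c <- nucs$gc - 0.5
  w <- occ * rel * exp(gc_bias_strength * gc_c *
                         (1 + 2 * (titration_level - 2.5)))
  n_bg <- rbinom(1, depth, bg_fraction)
  n_nuc <- depth - n_bg
  pieces <- list()
  if (n_nuc > 0) {
    idx <- sample.int(nrow(nucs), n_nuc, replace = TRUE, prob = w)
    center <- nucs$dyad[idx] + as.integer(round(rnorm(n_nuc, 0, 8)))
    len <- .draw_lengths(n_nuc, len_mean, len_sd, contaminant_fraction)
    pieces$nuc <- .fragments_from_centers(nucs$chrom[idx], center, len, cl)
  }
  if (n_bg > 0) {
    off <- .concat_offsets(cl)
    u <- floor(runif(n_bg) * sum(as.numeric(cl)))
    ci <- findInterval(u, off[-length(off)], rightmost.closed = FALSE)
    chrom <- names(cl)[ci]
    center <- as.integer(u - off[ci])
    len <- .draw_lengths(n_bg, len_mean, len_sd, contaminant_fraction)
    pieces$bg <- .fragments_from_centers(chrom, center, len, cl)
  }
  fragment_set(rbindlist(pieces), md, cl)
}

#' Simulate a full titration series (4 levels) for one sample
#'
#' @inheritParams simulate_titration_fragments
#' @param depth_per_level fragments per titration level.
#' @param ... passed on to [simulate_titration_fragments()].
#' @return List of four `fragment_set`s, one per level.
#' @export
simulate_titration_set <- function(genome, time_point, depth_per_level,
                                   gc_bias_strength = 0, seed = 1L,
                                   replicate = 1L, ...) {
  lapply(1:4, function(lv)
    simulate_titration_fragments(genome, time_point, lv, depth_per_level,
                                 gc_bias_strength = gc_bias_strength,
                                 seed = seed + lv, replicate = replicate, ...))
}

# per-bin expected weights for bin-resolved assays (ChIP, input, ATAC)
.sample_bin_fragments <- function(genome, bin_weights, depth, len_mean,
                                  len_sd, metadata) {
  cl <- genome$spec$chrom_lengths
  bs <- genome$spec$bin_size
  if (depth == 0)
    return(fragment_set(data.table(chrom = character(), start = integer(),
                                   end = integer()), metadata, cl))
  nb <- vapply(names(cl), function(ch) as.integer(ceiling(cl[[ch]] / bs)),
               integer(1))
  w <- unlist(bin_weights, use.names = FALSE)
  idx <- sample.int(length(w), depth, replace = TRUE, prob = w)
  chrom_of <- rep(names(cl), nb)
  bin0 <- unlist(lapply(nb, function(n) seq_len(n) - 1L), use.names = FALSE)
  ch <- chrom_of[idx]
  lo <- bin0[idx] * bs
  width <- pmin(bs, cl[ch] - lo)
  center <- as.integer(lo + floor(runif(depth) * width))
  len <- as.integer(round(clamp(rnorm(depth, len_mean, len_sd), 60, 500)))
  fragment_set(.fragments_from_centers(ch, center, len, cl), metadata, cl)
}

.bin_fold_track <- function(genome, intervals, folds) {
  cl <- genome$spec$chrom_lengths
  bs <- genome$spec$bin_size
  out <- lapply(names(cl), function(ch) rep(1, ceiling(cl[[ch]] / bs)))
  names(out) <- names(cl)
  if (length(folds)) {
    for (i in seq_along(folds)) {
      ch <- intervals$chrom[i]
      b0 <- intervals$start[i] %/% bs + 1L
      b1 <- min((intervals$end[i] - 1L) %/% bs + 1L, length(out[[ch]]))
      out[[ch]][b0:b1] <- pmax(out[[ch]][b0:b1], folds[i])
    }
  }
  out
}

#' Simulate a ChIP / input fragment pair
#'
#' Input coverage is uniform per bin up to optional GC bias; ChIP expected
#' coverage equals input coverage times the planted enrichment fold at
#' enhancer intervals (H3K27ac; up-gene promoters also carry acetylation)
#' or expressed gene bodies (Pol II), and 1 elsewhere.
#'
#' @param genome a `synthetic_genome`.
#' @param mark `"H3K27ac"` or `"PolII"`.
#' @param time_point `"0h"`, `"1h"` or `"4h"`.
#' @param depth fragments per library (same for ChIP and input).
#' @param gc_bias_strength GC bias exponent applied to both libraries.
#' @param seed integer seed.
#' @param replicate replicate index recorded in metadata.
#' @return list(chip = `fragment_set`, input = `fragment_set`).
#' @export
simulate_chip_pair <- function(genome, mark = c("H3K27ac", "PolII"),
                               time_point, depth, gc_bias_strength = 0,
                               seed = 1L, replicate = 1L) {
  mark <- match.arg(mark)
  time_point <- match.arg(time_point, c("0h", "1h", "4h"))
  set.seed(seed)
  fold_col <- paste0("fold_", time_point)
  if (mark == "H3K27ac") {
    iv <- genome$enhancers[, .(chrom, start, end)]
    fl <- genome$enhancers[[fold_col]]
    g <- genome$genes[class %in% c("up_access_only", "up_access_and_occ_loss")]
    if (nrow(g)) {
      prom <- data.table(chrom = g$chrom,
                         start = pmax(0L, g$tss - 500L), end = g$tss + 500L)
      pf <- rep(if (time_point == "0h") 2 else 4, nrow(g))
      iv <- rbind(iv, prom); fl <- c(fl, pf)
    }
  } else {
    g <- genome$genes
    iv <- data.table(chrom = g$chrom, start = pmin(g$tss, g$tts),
                     end = pmax(g$tss, g$tts))
    lfc <- if (time_point == "0h") 0 else if (time_point == "1h")
      g$log2fc_0_1 else g$log2fc_0_1 + g$log2fc_1_4
    fl <- pmax(1, 2 * 2^lfc / 2)        # baseline 2x body signal scaled by expression
  }
  folds <- if (nrow(iv)) fl else numeric()
  fold_bins <- .bin_fold_track(genome, iv, folds)
  gcb <- lapply(genome$gc_bins$values, function(g)
    exp(gc_bias_strength * (g - 0.5)))
  input_w <- gcb
  chip_w <- lapply(names(gcb), function(ch) gcb[[ch]] * fold_bins[[ch]])
  names(chip_w) <- names(gcb)
  chip <- .sample_bin_fragments(
    genome, chip_w, depth, 250, 60,
    list(assay = paste0("chip_", mark), time_point = time_point,
         replicate = as.integer(replicate)))
  # advance RNG state is shared; input drawn after chip, still seed-determined
  input <- .sample_bin_fragments(
    genome, input_w, depth, 250, 60,
    list(assay = "input", time_point = time_point,
         replicate = as.integer(replicate)))
  list(chip = chip, input = input)
}

#' Simulate an ATAC-seq fragment set
#'
#' Expected count per bin is proportional to `max(accessibility, 0)` plus a
#' small uniform floor, so fully closed chromatin yields only the floor and
#' expectations scale linearly with depth.
#'
#' @param genome a `synthetic_genome`.
#' @param time_point `"0h"`, `"1h"` or `"4h"`.
#' @param depth number of fragments.
#' @param seed integer seed.
#' @param floor uniform floor added to every bin weight (0.05).
#' @param replicate replicate index.
#' @return A `fragment_set` (assay `"atac"`).
#' @export
simulate_atac <- function(genome, time_point, depth, seed = 1L, floor = 0.05,
                          replicate = 1L) {
  time_point <- match.arg(time_point, c("0h", "1h", "4h"))
  set.seed(seed)
  acc <- genome$truth[[time_point]]$accessibility$values
  w <- lapply(acc, function(a) pmax(ifelse(is.na(a), 0, a), 0) + floor)
  .sample_bin_fragments(genome, w, depth, 100, 25,
                        list(assay = "atac", time_point = time_point,
                             replicate = as.integer(replicate)))
}

#' Simulate the per-gene expression table
#'
#' Emulates the output format of an RNA-seq differential-expression step:
#' per-gene expression at 0/1/4 h, log2 fold-changes over 0-1 h, 1-4 h and
#' 0-4 h, and a significance flag. Fold-changes are the planted class
#' effects plus optional log-scale noise; at `noise_sd = 0` the table
#' reproduces the planted classes exactly.
#'
#' @param genome a `synthetic_genome`.
#' @param seed integer seed.
#' @param noise_sd sd of noise added to each log2 fold-change (default
#'   0.05, small enough never to cross the twofold class boundaries).
#' @return data.table with one row per gene.
#' @export
simulate_expression_table <- function(genome, seed = 1L, noise_sd = 0.05) {
  set.seed(seed)
  g <- copy(genome$genes)
  n <- nrow(g)
  if (n == 0) return(g)
  l01 <- g$log2fc_0_1 + rnorm(n, 0, noise_sd)
  l14 <- g$log2fc_1_4 + rnorm(n, 0, noise_sd)
  g[, `:=`(expr_0h = base_expr,
           expr_1h = base_expr * 2^l01,
           expr_4h = base_expr * 2^(l01 + l14),
           log2fc_0_1 = l01, log2fc_1_4 = l14, log2fc_0_4 = l01 + l14)]
  g[, significant := class %in% c("up_access_only", "up_access_and_occ_loss",
                                  "down")]
  g[, .(gene_id, chrom, tss, tts, strand, class, expr_0h, expr_1h, expr_4h,
        log2fc_0_1, log2fc_1_4, log2fc_0_4, significant)]
}
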