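#' Specification for a synthetic genome with planted chromatin ground truth
#'
#' Describes the world the MNase-digestion simulator generates: chromosome
#' lengths, a smoothly varying GC landscape, gene and enhancer counts with
#' time-course class proportions, and the nucleosome lattice. All randomness
#' is governed by `seed`; identical specs give byte-identical outputs.
#'
#' Defaults emulate a compact fly-like genome: GC around 0.42 drifting
#' sinusoidally (amplitude 0.10, wavelength 20 kb, clamped to \[0.2, 0.8\]),
#' nucleosome repeat length 180 bp, genes of 2-6 kb. Gene classes follow the
#' view that acute activation mostly changes accessibility: by default 15%
#' of genes gain accessibility only, 5% additionally lose occupancy, 15% are
#' down-regulated, and the rest are unchanged.
#'
#' @param chrom_lengths named integer vector of chromosome lengths (bp).
#' @param gc_mean,gc_amplitude,gc_wavelength parameters of the sinusoidal
#'   GC-fraction track (wavelength in bp).
#' @param n_genes,n_enhancers how many genes / TSS-distal enhancers to plant.
#' @param nucleosome_spacing nucleosome repeat length in bp (default 180).
#' @param bin_size analysis bin grid (bp); the planted per-bin truth tracks
#'   use this same grid.
#' @param accessibility_sd spread of baseline nucleosome accessibility
#'   outside planted effects; 0 gives a uniform accessibility-0 background.
#' @param gene_class_props named proportions over
#'   `up_access_only`, `up_access_and_occ_loss`, `down`, `unchanged`.
#' @param enhancer_class_props named proportions over `enhancer_up`,
#'   `enhancer_constitutive`.
#' @param seed integer; fully determines all outputs.
#' @return Object of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(chrom_lengths = c(chrS = 1e6L),
                                  gc_mean = 0.42, gc_amplitude = 0.10,
                                  gc_wavelength = 20000,
                                  n_genes = 60L, n_enhancers = 20L,
                                  nucleosome_spacing = 180L,
                                  bin_size = 200L,
                                  accessibility_sd = 0.35,
                                  gene_class_props = c(up_access_only = 0.15,
                                                       up_access_and_occ_loss = 0.05,
                                                       down = 0.15,
                                                       unchanged = 0.65),
                                  enhancer_class_props = c(enhancer_up = 0.5,
                                                           enhancer_constitutive = 0.5),
                                  seed = 1L) {
  stopifnot(all(chrom_lengths > 0), !is.null(names(chrom_lengths)),
            nucleosome_spacing > 0, bin_size > 0,
            n_genes >= 0, n_enhancers >= 0, accessibility_sd >= 0)
  gc_lo <- gc_mean - gc_amplitude
  gc_hi <- gc_mean + gc_amplitude
  if (gc_lo < 0.2 - 1e-9 || gc_hi > 0.8 + 1e-9)
    stop("GC profile must stay within [0.2, 0.8]")
  structure(list(chrom_lengths = as.integer(round(chrom_lengths)) |>
                   setNames(names(chrom_lengths)),
                 gc_mean = gc_mean, gc_amplitude = gc_amplitude,
                 gc_wavelength = gc_wavelength,
                 n_genes = as.integer(n_genes),
                 n_enhancers = as.integer(n_enhancers),
                 nucleosome_spacing = as.integer(nucleosome_spacing),
                 bin_size = as.integer(bin_size),
                 accessibility_sd = accessibility_sd,
                 gene_class_props = gene_class_props,
                 enhancer_class_props = enhancer_class_props,
                 seed = as.integer(seed)),
            class = "synthetic_genome_spec")
}

#' GC target fraction at positions `x` (0-based) under a spec
#' @keywords internal
gc_target <- function(spec, x) {
  pmin(0.8, pmax(0.2, spec$gc_mean +
    spec$gc_amplitude * sin(2 * pi * x / spec$gc_wavelength)))
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# class deltas: accessibility added at 1h/4h, occupancy multiplier at 1h/4h
.gene_class_effects <- list(
  up_access_only         = list(d_acc = c(0.55, 0.75), occ_mult = c(1, 1)),
  up_access_and_occ_loss = list(d_acc = c(0.55, 0.75), occ_mult = c(0.6, 0.5)),
  down                   = list(d_acc = c(-0.35, -0.55), occ_mult = c(1, 1)),
  unchanged              = list(d_acc = c(0, 0), occ_mult = c(1, 1)))

.enhancer_class_folds <- list(
  enhancer_up           = c(1.0, 2.5, 6.0),
  enhancer_constitutive = c(5.0, 5.5, 5.2))

#' Build a synthetic genome with planted nucleosome/enhancer/gene truth
#'
#' Generates chromosome sequences following the spec's GC landscape, a
#' jittered nucleosome lattice with per-nucleosome occupancy and
#' accessibility at each time point (0/1/4 h), non-overlapping genes with
#' promoter nucleosome-depleted regions and expression time-course classes,
#' TSS-distal enhancers with planted H3K27ac fold time courses, and per-bin
#' truth tracks on the analysis grid.
#'
#' Baseline nucleosome occupancy mixes well-occupied (80%, 0.6-0.95) and
#' weakly occupied (20%, 0.2-0.6) positions; promoter-proximal nucleosomes
#' (dyad within TSS +/- 100 bp) are attenuated fourfold to carve the
#' nucleosome-depleted dip. Gene-body accessibility tracks baseline
#' expression so that accessibility correlates positively (and occupancy
#' weakly negatively) with expression, as active chromatin does.
#'
#' @param spec a [synthetic_genome_spec()].
#' @return Object of class `synthetic_genome`: list with `sequences`
#'   (DNAStringSet), `nucleosomes` (data.table: chrom, dyad, gc, occupancy /
#'   accessibility at each time point), `genes`, `enhancers`, `effects`
#'   (time-course effect table), `gc_bins` (binned GC track) and `truth`
#'   (per-time-point binned occupancy/accessibility tracks).
#' @export
build_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  set.seed(spec$seed)
  chroms <- names(spec$chrom_lengths)

  ## --- sequences following the GC landscape ---------------------------
  # stratified GC placement: within each 500-bp chunk the GC base count is
  # the rounded local target (fractional part resolved by one Bernoulli
  # draw), so 1-kb windows track the profile to within rounding error
  # rather than binomial noise
  seqs <- lapply(chroms, function(ch) {
    L <- spec$chrom_lengths[[ch]]
    chunk <- 500L
    is_gc <- logical(L)
    for (s in seq(1L, L, by = chunk)) {
      e <- min(s + chunk - 1L, L)
      w <- e - s + 1L
      p <- mean(gc_target(spec, (s:e) - 1L))
      k <- floor(w * p) + (runif(1) < (w * p) %% 1)
      if (k > 0) is_gc[s - 1L + sample.int(w, k)] <- TRUE
    }
    pick <- runif(L) < 0.5
    base <- character(L)
    base[is_gc & pick] <- "G"; base[is_gc & !pick] <- "C"
    base[!is_gc & pick] <- "A"; base[!is_gc & !pick] <- "T"
    paste(base, collapse = "")
  })
  sequences <- Biostrings::DNAStringSet(unlist(seqs))
  names(sequences) <- chroms

  ## --- genes: non-overlapping, strand-aware, classed -------------------
  genes <- .place_genes(spec)
  ## --- enhancers: intergenic, outside promoter zones --------------------
  enhancers <- .place_enhancers(spec, genes)

  ## --- nucleosome lattice ----------------------------------------------
  nucs <- rbindlist(lapply(chroms, function(ch) {
    L <- spec$chrom_lengths[[ch]]
    base_dyads <- seq(100L, L - 100L, by = spec$nucleosome_spacing)
    jit <- as.integer(round(runif(length(base_dyads), -15, 15)))
    data.table(chrom = ch, dyad = pmin(L - 73L, pmax(73L, base_dyads + jit)))
  }))

  # baseline occupancy: mixture of well- and weakly-occupied positions
  n <- nrow(nucs)
  weak <- runif(n) < 0.2
  nucs[, occupancy := ifelse(weak, runif(n, 0.2, 0.6), runif(n, 0.6, 0.95))]
  nucs[, accessibility := clamp(rnorm(n, 0, spec$accessibility_sd), -0.95, 0.95)]

  if (nrow(genes)) {
    # expression-coupled baseline structure in gene bodies
    ez <- scale(log(genes$base_expr))[, 1]
    for (i in seq_len(nrow(genes))) {
      g <- genes[i]
      lo <- min(g$tss, g$tts); hi <- max(g$tss, g$tts)
      in_body <- nucs$chrom == g$chrom & nucs$dyad >= lo & nucs$dyad <= hi
      nucs[in_body, accessibility := clamp(accessibility + 0.3 * ez[i], -0.95, 0.95)]
      nucs[in_body, occupancy := clamp(occupancy * (1 - 0.08 * ez[i]), 0.05, 1)]
      # promoter nucleosome-depleted dip (covers TSS +/- 100 bp plus the
      # flanking dyads whose footprints reach into it)
      in_ndr <- nucs$chrom == g$chrom & abs(nucs$dyad - g$tss) <= 150
      nucs[in_ndr, occupancy := occupancy * 0.15]
    }
  }

  ## --- time-course deltas ----------------------------------------------
  nucs[, `:=`(occ_0h = occupancy, occ_1h = occupancy, occ_4h = occupancy,
              acc_0h = accessibility, acc_1h = accessibility,
              acc_4h = accessibility)]
  effects <- list()
  apply_effect <- function(ch, lo, hi, d_acc, occ_mult) {
    idx <- nucs$chrom == ch & nucs$dyad >= lo & nucs$dyad <= hi
    nucs[idx, `:=`(acc_1h = clamp(acc_0h + d_acc[1], -1, 1),
                   acc_4h = clamp(acc_0h + d_acc[2], -1, 1),
                   occ_1h = clamp(occ_0h * occ_mult[1], 0, 1),
                   occ_4h = clamp(occ_0h * occ_mult[2], 0, 1))]
  }
  if (nrow(genes)) {
    for (i in seq_len(nrow(genes))) {
      g <- genes[i]
      eff <- .gene_class_effects[[g$class]]
      lo <- min(g$tss, g$tts) - 1000L
      hi <- max(g$tss, g$tts) + 1000L
      apply_effect(g$chrom, lo, hi, eff$d_acc, eff$occ_mult)
      effects[[length(effects) + 1L]] <- data.table(
        region_chrom = g$chrom, region_start = lo, region_end = hi,
        class_label = g$class,
        d_acc_1h = eff$d_acc[1], d_acc_4h = eff$d_acc[2],
        occ_mult_1h = eff$occ_mult[1], occ_mult_4h = eff$occ_mult[2],
        expression_log2fc_1h = g$log2fc_0_1, expression_log2fc_4h =
          g$log2fc_0_1 + g$log2fc_1_4,
        h3k27ac_fold_0h = NA_real_, h3k27ac_fold_1h = NA_real_,
        h3k27ac_fold_4h = NA_real_)
    }
  }
  if (nrow(enhancers)) {
    for (i in seq_len(nrow(enhancers))) {
      e <- enhancers[i]
      d_acc <- if (e$class == "enhancer_up") c(0.55, 0.75) else c(0, 0)
      apply_effect(e$chrom, e$start - 100L, e$end + 100L, d_acc, c(1, 1))
      f <- .enhancer_class_folds[[e$class]]
      effects[[length(effects) + 1L]] <- data.table(
        region_chrom = e$chrom, region_start = e$start, region_end = e$end,
        class_label = e$class,
        d_acc_1h = d_acc[1], d_acc_4h = d_acc[2],
        occ_mult_1h = 1, occ_mult_4h = 1,
        expression_log2fc_1h = NA_real_, expression_log2fc_4h = NA_real_,
        h3k27ac_fold_0h = f[1], h3k27ac_fold_1h = f[2], h3k27ac_fold_4h = f[3])
    }
  }
  effects <- if (length(effects)) rbindlist(effects) else
    data.table(region_chrom = character(), region_start = integer(),
               region_end = integer(), class_label = character())

  ## --- per-nucleosome GC (dyad +/- 73 bp) -------------------------------
  nucs[, gc := {
    g <- numeric(.N)
    for (ch in chroms) {
      idx <- which(nucs$chrom == ch)
      if (!length(idx)) next
      L <- spec$chrom_lengths[[ch]]
      s <- pmax(1L, nucs$dyad[idx] - 72L)     # 1-based view coords
      e <- pmin(L, nucs$dyad[idx] + 74L)
      v <- Biostrings::Views(sequences[[ch]], start = s, end = e)
      g[idx] <- Biostrings::letterFrequency(v, "GC", as.prob = TRUE)[, 1]
    }
    g
  }]

  gc_bins <- gc_track(sequences, spec$bin_size)

  gen <- structure(list(spec = spec, sequences = sequences,
                        nucleosomes = nucs[], genes = genes,
                        enhancers = enhancers, effects = effects,
                        gc_bins = gc_bins),
                   class = "synthetic_genome")
  gen$truth <- lapply(setNames(c("0h", "1h", "4h"), c("0h", "1h", "4h")),
                      function(tp) truth_tracks(gen, tp))
  gen
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf(
    "synthetic_genome: %d chrom (%.2f Mb), %d nucleosomes, %d genes, %d enhancers\n",
    length(x$sequences), sum(x$spec$chrom_lengths) / 1e6,
    nrow(x$nucleosomes), nrow(x$genes), nrow(x$enhancers)))
  invisible(x)
}

.place_genes <- function(spec) {
  cols <- data.table(gene_id = character(), chrom = character(),
                     tss = integer(), tts = integer(), strand = character(),
                     class = character(), base_expr = numeric(),
                     log2fc_0_1 = numeric(), log2fc_1_4 = numeric())
  if (spec$n_genes == 0) return(cols)
  chroms <- names(spec$chrom_lengths)
  per_chrom <- table(factor(
    sample(chroms, spec$n_genes, replace = TRUE,
           prob = spec$chrom_lengths / sum(spec$chrom_lengths)),
    levels = chroms))
  out <- list()
  k <- 0L
  for (ch in chroms) {
    ng <- per_chrom[[ch]]
    if (ng == 0) next
    L <- spec$chrom_lengths[[ch]]
    lens <- as.integer(round(runif(ng, 2000, 6000)))
    gap <- 4000L            # room for promoters and distal enhancers
    need <- sum(lens) + (ng + 1L) * gap
    if (need > L)
      stop("cannot place ", ng, " genes with spacing on ", ch,
           " (need ", need, " bp, have ", L, ")")
    slack <- L - need
    extra <- floor(slack * sort(runif(ng)))   # spread leftover space
    pos <- gap + cumsum(c(0L, lens[-ng] + gap)) + extra
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    for (i in seq_len(ng)) {
      k <- k + 1L
      lo <- pos[i]; hi <- pos[i] + lens[i]
      out[[k]] <- data.table(
        gene_id = sprintf("g%04d", k), chrom = ch,
        tss = if (strand[i] == "+") lo else hi,
        tts = if (strand[i] == "+") hi else lo,
        strand = strand[i])
    }
  }
  genes <- rbindlist(out)
  n <- nrow(genes)
  props <- spec$gene_class_props / sum(spec$gene_class_props)
  counts <- floor(props * n)
  rem <- n - sum(counts)
  if (rem > 0) counts[order(props * n - counts, decreasing = TRUE)[seq_len(rem)]] <-
    counts[order(props * n - counts, decreasing = TRUE)[seq_len(rem)]] + 1
  labels <- sample(rep(names(counts), counts))
  genes[, class := labels]
  genes[, base_expr := exp(rnorm(n, 3, 1))]
  genes[, `:=`(log2fc_0_1 = 0, log2fc_1_4 = 0)]
  up <- genes$class %in% c("up_access_only", "up_access_and_occ_loss")
  genes[up, `:=`(log2fc_0_1 = runif(sum(up), 1.2, 3),
                 log2fc_1_4 = runif(sum(up), 0, 1))]
  dn <- genes$class == "down"
  genes[dn, `:=`(log2fc_0_1 = runif(sum(dn), -3, -1.2),
                 log2fc_1_4 = runif(sum(dn), -1, 0))]
  genes[]
}

.place_enhancers <- function(spec, genes) {
  cols <- data.table(enh_id = character(), chrom = character(),
                     start = integer(), end = integer(), class = character(),
                     fold_0h = numeric(), fold_1h = numeric(),
                     fold_4h = numeric())
  if (spec$n_enhancers == 0) return(cols)
  width <- 400L
  # candidate midpoints: intergenic, clear of promoter exclusion zones
  cand <- list()
  for (ch in names(spec$chrom_lengths)) {
    L <- spec$chrom_lengths[[ch]]
    occupied <- IRanges::IRanges()
    g <- genes[genes$chrom == ch]
    if (nrow(g)) {
      lo <- pmin(g$tss, g$tts); hi <- pmax(g$tss, g$tts)
      occupied <- IRanges::reduce(IRanges::IRanges(
        start = pmax(1L, lo - 1500L), end = pmin(L, hi + 1500L)))
    }
    free <- IRanges::setdiff(IRanges::IRanges(1L, L), occupied)
    free <- free[IRanges::width(free) >= width + 400L]
    if (length(free))
      cand[[ch]] <- data.table(chrom = ch,
                               lo = IRanges::start(free) + 200L,
                               hi = IRanges::end(free) - 200L - width)
  }
  cand <- rbindlist(cand)
  if (!nrow(cand)) stop("no intergenic space available for enhancers")
  # spread enhancers over free blocks proportional to block size, one per
  # block segment to keep them well separated
  cand <- cand[hi > lo]
  seg <- cand[rep(seq_len(.N), ceiling((hi - lo) / 50000))]
  if (nrow(seg) < spec$n_enhancers)
    seg <- cand[sample(.N, spec$n_enhancers, replace = TRUE)]
  pick <- seg[sample(.N, spec$n_enhancers, replace = FALSE)]
  starts <- as.integer(pick$lo + round(runif(spec$n_enhancers) * (pick$hi - pick$lo)))
  enh <- data.table(enh_id = sprintf("e%03d", seq_len(spec$n_enhancers)),
                    chrom = pick$chrom, start = starts,
                    end = starts + width)
  props <- spec$enhancer_class_props / sum(spec$enhancer_class_props)
  n_up <- round(props[["enhancer_up"]] * spec$n_enhancers)
  cls <- sample(c(rep("enhancer_up", n_up),
                  rep("enhancer_constitutive", spec$n_enhancers - n_up)))
  enh[, class := cls]
  fm <- do.call(rbind, .enhancer_class_folds[enh$class])
  enh[, `:=`(fold_0h = fm[, 1], fold_1h = fm[, 2], fold_4h = fm[, 3])]
  setkey(enh, chrom, start)
  enh[]
}

#' Per-bin GC-fraction track from sequences
#'
#' @param sequences DNAStringSet.
#' @param bin_size bin width (bp).
#' @return `binned_track` of GC fractions.
#' @export
gc_track <- function(sequences, bin_size = 200) {
  chrom_lengths <- setNames(Biostrings::width(sequences), names(sequences))
  values <- lapply(names(sequences), function(ch) {
    L <- chrom_lengths[[ch]]
    nb <- ceiling(L / bin_size)
    s <- (seq_len(nb) - 1L) * bin_size + 1L
    e <- pmin(seq_len(nb) * bin_size, L)
    v <- Biostrings::Views(sequences[[ch]], start = s, end = e)
    Biostrings::letterFrequency(v, "GC", as.prob = TRUE)[, 1]
  })
  names(values) <- names(sequences)
  binned_track(values, bin_size, chrom_lengths)
}

#' Planted per-bin truth tracks at a time point
#'
#' Per-bin true occupancy is the summed occupancy of nucleosomes whose dyad
#' falls in the bin; true accessibility is the occupancy-weighted mean
#' accessibility (NA where the bin holds no dyad).
#'
#' @param genome a `synthetic_genome`.
#' @param time_point one of `"0h"`, `"1h"`, `"4h"`.
#' @return list with `occupancy` and `accessibility` binned tracks.
#' @export
truth_tracks <- function(genome, time_point = c("0h", "1h", "4h")) {
  time_point <- match.arg(time_point)
  spec <- genome$spec
  occ_col <- paste0("occ_", time_point)
  acc_col <- paste0("acc_", time_point)
  occ_v <- list(); acc_v <- list()
  for (ch in names(spec$chrom_lengths)) {
    L <- spec$chrom_lengths[[ch]]
    nb <- ceiling(L / spec$bin_size)
    nd <- genome$nucleosomes[chrom == ch]
    b <- nd$dyad %/% spec$bin_size + 1L
    occ <- nd[[occ_col]]; acc <- nd[[acc_col]]
    sum_occ <- numeric(nb); sum_wacc <- numeric(nb)
    tmp <- tapply(occ, b, sum)
    sum_occ[as.integer(names(tmp))] <- tmp
    tmp <- tapply(occ * acc, b, sum)
    sum_wacc[as.integer(names(tmp))] <- tmp
    acc_bin <- ifelse(sum_occ > 0, sum_wacc / sum_occ, NA_real_)
    occ_v[[ch]] <- sum_occ
    acc_v[[ch]] <- acc_bin
  }
  list(occupancy = binned_track(occ_v, spec$bin_size, spec$chrom_lengths),
       accessibility = binned_track(acc_v, spec$bin_size, spec$chrom_lengths))
}

#' Write the synthetic world to plain-text files
#'
#' Genome as FASTA, genes and enhancers as TSV, nucleosome-level truth and
#' per-bin truth tracks as TSV; coordinates 0-based half-open.
#'
#' @param genome a `synthetic_genome`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_genome <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             genes = file.path(dir, "genes.tsv"),
             enhancers = file.path(dir, "enhancers.tsv"),
             nucleosomes = file.path(dir, "nucleosome_truth.tsv"))
  Biostrings::writeXStringSet(genome$sequences, paths[["fasta"]])
  fwrite(genome$genes, paths[["genes"]], sep = "\t")
  fwrite(genome$enhancers, paths[["enhancers"]], sep = "\t")
  fwrite(genome$nucleosomes, paths[["nucleosomes"]], sep = "\t")
  invisible(paths)
}
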